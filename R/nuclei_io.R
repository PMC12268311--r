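#' @importFrom stats rnorm runif rbinom rexp rpois quantile sd pchisq pnorm
#'   qnorm dnorm optimize glm binomial plogis qlogis as.formula setNames
#'   fitted var coef
#' @importFrom graphics plot lines legend abline
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# Canonical vocabularies -------------------------------------------------

NUCLEUS_CLASSES <- c("TUMOR", "LYMPHOCYTE", "OTHER")
REGION_LABELS   <- c("INTRATUMOR", "PERITUMORAL", "STROMAL", "UNASSIGNED")

# Alias table for class strings seen in common nuclei-export conventions.
# Matching is case-insensitive after trimming; unknown strings are rejected.
CLASS_ALIASES <- c(
  "tumor"            = "TUMOR",
  "tumour"           = "TUMOR",
  "tumor cell"       = "TUMOR",
  "tumor nuclei"     = "TUMOR",
  "tumor nucleus"    = "TUMOR",
  "neoplastic"       = "TUMOR",
  "lymphocyte"       = "LYMPHOCYTE",
  "lymphocyte nuclei" = "LYMPHOCYTE",
  "lymph"            = "LYMPHOCYTE",
  "til"              = "LYMPHOCYTE",
  "inflammatory"     = "LYMPHOCYTE",
  "other"            = "OTHER",
  "other nuclei"     = "OTHER",
  "stromal cell"     = "OTHER",
  "connective"       = "OTHER",
  "epithelial"       = "OTHER",
  "misc"             = "OTHER"
)

normalize_class <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- ifelse(toupper(x0) %in% NUCLEUS_CLASSES, toupper(x0),
                unname(CLASS_ALIASES[x0]))
  bad <- unique(x[is.na(out)])
  if (length(bad))
    stop("unknown nucleus class value(s) with no alias: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  out
}

# slide_nuclei ------------------------------------------------------------

#' Classified-nuclei point cloud for one slide
#'
#' Container for the raw input of the spatial TIL pipeline: one record per
#' segmented nucleus, with planar centroid coordinates in micrometers and a
#' class label (`TUMOR`, `LYMPHOCYTE` or `OTHER`).  The `region_label` column
#' stays `UNASSIGNED` until [assign_nuclei_regions()] has run.
#'
#' @param nuclei data.frame with columns `nucleus_id`, `x_um`, `y_um`,
#'   `class_label` (and optionally `region_label`).
#' @param slide_id,patient_id identifiers.
#' @param extent_um numeric length-2 `(width, height)` in micrometers; if
#'   `NULL`, taken as the ceiling of the coordinate range.
#' @param microns_per_pixel scanner resolution used when converting
#'   pixel-space coordinates; default 0.25 um/px (40x scan).
#'
#' @details The coordinate convention is continuous Cartesian micrometers with
#' the origin at the slide top-left and y increasing downward (image
#' convention).
#'
#' @return An object of class `slide_nuclei`.
#' @export
slide_nuclei <- function(nuclei, slide_id = "slide1", patient_id = slide_id,
                         extent_um = NULL, microns_per_pixel = 0.25) {
  stopifnot(is.data.frame(nuclei))
  req <- c("nucleus_id", "x_um", "y_um", "class_label")
  miss <- setdiff(req, names(nuclei))
  if (length(miss))
    stop("nuclei table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!(is.numeric(microns_per_pixel) && length(microns_per_pixel) == 1 &&
        microns_per_pixel > 0))
    stop("microns_per_pixel must be a single positive number", call. = FALSE)
  nuc <- data.frame(
    nucleus_id   = as.character(nuclei$nucleus_id),
    x_um         = as.numeric(nuclei$x_um),
    y_um         = as.numeric(nuclei$y_um),
    class_label  = normalize_class(nuclei$class_label),
    region_label = if ("region_label" %in% names(nuclei))
      as.character(nuclei$region_label) else
        rep("UNASSIGNED", nrow(nuclei)),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(nuc$x_um) | !is.finite(nuc$y_um) |
                 nuc$x_um < 0 | nuc$y_um < 0)
  if (length(bad))
    stop("non-finite or negative coordinate at row(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  if (!all(nuc$region_label %in% REGION_LABELS))
    stop("invalid region_label values", call. = FALSE)
  if (is.null(extent_um)) {
    extent_um <- if (nrow(nuc)) ceiling(c(max(nuc$x_um), max(nuc$y_um)) + 1)
                 else c(1, 1)
  }
  extent_um <- as.numeric(extent_um)
  stopifnot(length(extent_um) == 2, all(extent_um > 0))
  out_of_extent <- nuc$x_um > extent_um[1] | nuc$y_um > extent_um[2]
  if (any(out_of_extent))
    stop(sum(out_of_extent), " nuclei lie outside extent_um", call. = FALSE)
  structure(
    list(slide_id = as.character(slide_id),
         patient_id = as.character(patient_id),
         nuclei = nuc, extent_um = extent_um,
         microns_per_pixel = microns_per_pixel),
    class = "slide_nuclei")
}

#' @export
print.slide_nuclei <- function(x, ...) {
  cat("<slide_nuclei> slide", x$slide_id, "patient", x$patient_id, "\n")
  cat(sprintf("  extent: %.0f x %.0f um,  %.2f um/px\n",
              x$extent_um[1], x$extent_um[2], x$microns_per_pixel))
  tab <- table(factor(x$nuclei$class_label, NUCLEUS_CLASSES))
  cat("  nuclei:", nrow(x$nuclei),
      sprintf("(%s)", paste(names(tab), as.integer(tab), sep = "=",
                            collapse = ", ")), "\n")
  if (any(x$nuclei$region_label != "UNASSIGNED")) {
    rt <- table(factor(x$nuclei$region_label, REGION_LABELS))
    cat("  regions:", paste(names(rt), as.integer(rt), sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# Readers / writers -------------------------------------------------------

#' Read a classified-nuclei table
#'
#' Reads nuclei from CSV (columns `nucleus_id,x_um,y_um,class_label`, or
#' `x_px,y_px` when `coords = "px"`) or from a GeoJSON FeatureCollection of
#' Point/Polygon features whose `properties.classification` holds the class
#' string.  Polygon features are reduced to their area centroid: all
#' downstream geometry in this package is centroid-based.
#'
#' @param path file path.
#' @param format `"csv"` or `"geojson"`.
#' @param coords `"um"` (default) if coordinates are already micrometers,
#'   `"px"` if they are pixels to be scaled by `microns_per_pixel`.
#' @param microns_per_pixel um per pixel (default 0.25).
#' @inheritParams slide_nuclei
#' @return A [slide_nuclei()] object.
#' @export
read_nuclei <- function(path, format = c("csv", "geojson"),
                        coords = c("um", "px"), microns_per_pixel = 0.25,
                        slide_id = basename(path), patient_id = slide_id,
                        extent_um = NULL) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    xy <- c("x_um", "y_um")
    if (coords == "px") {
      pxcols <- intersect(c("x_px", "y_px"), names(df))
      if (length(pxcols) == 2) xy <- c("x_px", "y_px")
    }
    miss <- setdiff(c("nucleus_id", xy, "class_label"), names(df))
    if (length(miss))
      stop("CSV schema error: missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    nuc <- data.frame(nucleus_id = df$nucleus_id,
                      x_um = df[[xy[1]]], y_um = df[[xy[2]]],
                      class_label = df$class_label,
                      stringsAsFactors = FALSE)
    if ("region_label" %in% names(df)) nuc$region_label <- df$region_label
  } else {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$features))
      stop("GeoJSON schema error: no 'features' member", call. = FALSE)
    recs <- lapply(seq_along(gj$features), function(i) {
      f <- gj$features[[i]]
      cls <- f$properties$classification
      if (is.list(cls)) cls <- cls$name   # QuPath-style nested classification
      if (is.null(cls))
        stop("GeoJSON schema error: feature ", i,
             " lacks properties.classification", call. = FALSE)
      g <- f$geometry
      if (identical(g$type, "Point")) {
        xy <- unlist(g$coordinates)
      } else if (identical(g$type, "Polygon")) {
        ring <- do.call(rbind, lapply(g$coordinates[[1]], unlist))
        xy <- polygon_centroid(ring[, 1], ring[, 2])
      } else stop("unsupported GeoJSON geometry type: ", g$type, call. = FALSE)
      id <- f$properties$nucleus_id
      if (is.null(id)) id <- if (!is.null(f$id)) f$id else as.character(i)
      rec <- data.frame(nucleus_id = as.character(id), x_um = xy[1],
                        y_um = xy[2], class_label = as.character(cls),
                        stringsAsFactors = FALSE)
      if (!is.null(f$properties$region_label))
        rec$region_label <- as.character(f$properties$region_label)
      rec
    })
    nuc <- do.call(rbind, recs)
    if (is.null(nuc)) nuc <- data.frame(nucleus_id = character(),
                                        x_um = numeric(), y_um = numeric(),
                                        class_label = character())
  }
  if (coords == "px") {
    nuc$x_um <- nuc$x_um * microns_per_pixel
    nuc$y_um <- nuc$y_um * microns_per_pixel
  }
  slide_nuclei(nuc, slide_id = slide_id, patient_id = patient_id,
               extent_um = extent_um, microns_per_pixel = microns_per_pixel)
}

# Area centroid of a closed polygon ring (shoelace); falls back to the
# vertex mean for degenerate (zero-area) rings.
polygon_centroid <- function(x, y) {
  n <- length(x)
  if (n && (x[1] != x[n] || y[1] != y[n])) { x <- c(x, x[1]); y <- c(y, y[1]) }
  n <- length(x)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x[-n]), mean(y[-n])))
  c(sum((x[-n] + x[-1]) * cr), sum((y[-n] + y[-1]) * cr)) / (6 * a)
}

#' Write a classified-nuclei table
#'
#' Inverse of [read_nuclei()]: `read_nuclei(write_nuclei(s))` reproduces `s`
#' (coordinates to 6 decimals, labels exactly).  Output is byte-stable under
#' a fixed column order.
#'
#' @param slide a [slide_nuclei()] object.
#' @param path output path.
#' @param format `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_nuclei <- function(slide, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  stopifnot(inherits(slide, "slide_nuclei"))
  nuc <- slide$nuclei
  assigned <- any(nuc$region_label != "UNASSIGNED")
  if (format == "csv") {
    header <- c("nucleus_id", "x_um", "y_um", "class_label",
                if (assigned) "region_label")
    lines <- paste(header, collapse = ",")
    if (nrow(nuc)) {
      body <- sprintf("%s,%.6f,%.6f,%s", nuc$nucleus_id, nuc$x_um, nuc$y_um,
                      nuc$class_label)
      if (assigned) body <- sprintf("%s,%s", body, nuc$region_label)
      lines <- c(lines, body)
    }
    writeLines(lines, path)
  } else {
    feats <- lapply(seq_len(nrow(nuc)), function(i) {
      props <- list(nucleus_id = nuc$nucleus_id[i],
                    classification = nuc$class_label[i])
      if (assigned) props$region_label <- nuc$region_label[i]
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(round(nuc$x_um[i], 6),
                                           round(nuc$y_um[i], 6))),
           properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Cohort tables -----------------------------------------------------------

COHORT_VOCAB <- list(
  sex       = c("female", "male"),
  location  = c("distal", "mid", "proximal"),
  pT        = c("T1", "T2", "T3", "T4"),
  pN        = c("N0", "N1", "N2", "N3"),
  pTNM      = c("I", "II", "III", "IV"),
  grade     = c("G1", "G2", "G3", "Gx"),
  margin    = c("R0", "R1"),
  lvi       = c("negative", "positive"),
  treatment = c("surgery", "neoadjuvant+surgery")
)
COHORT_COLUMNS <- c("patient_id", "age", names(COHORT_VOCAB)[1:2],
                    "pT", "pN", "pTNM", "grade", "margin", "lvi", "treatment",
                    "os_months", "os_event", "rfs_months", "rfs_event")

#' Read a clinical cohort table
#'
#' Reads per-patient clinical covariates and survival outcomes from CSV with
#' columns `patient_id,age,sex,location,pT,pN,pTNM,grade,margin,lvi,
#' treatment,os_months,os_event,rfs_months,rfs_event`.  Categorical levels
#' are validated against the study vocabularies; rows with a missing or
#' invalid covariate are excluded and reported row-by-row, mirroring the
#' exclusion of records with missing essential clinical data.  Missing
#' outcome columns are fatal.
#'
#' @param path CSV path.
#' @return A list with `patients` (validated data.frame, factor covariates
#'   with study reference levels) and `excluded` (data.frame `row`,
#'   `patient_id`, `reason`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(COHORT_COLUMNS, names(df))
  fatal <- intersect(miss, c("os_months", "os_event", "rfs_months",
                             "rfs_event", "patient_id"))
  if (length(fatal))
    stop("cohort table is missing outcome/id column(s): ",
         paste(fatal, collapse = ", "), call. = FALSE)
  if (length(miss))
    stop("cohort table is missing covariate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  reasons <- character(nrow(df))
  note <- function(i, what) reasons[i] <<- ifelse(reasons[i] == "", what,
                                                  paste(reasons[i], what, sep = "; "))
  for (v in names(COHORT_VOCAB)) {
    val <- trimws(as.character(df[[v]]))
    bad <- is.na(df[[v]]) | val == "" | !(val %in% COHORT_VOCAB[[v]])
    for (i in which(bad)) note(i, paste0("missing/invalid ", v))
    df[[v]] <- val
  }
  bad_age <- !is.finite(suppressWarnings(as.numeric(df$age)))
  for (i in which(bad_age)) note(i, "missing/invalid age")
  for (v in c("os_months", "rfs_months")) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    for (i in which(!is.finite(x) | x < 0)) note(i, paste0("invalid ", v))
    df[[v]] <- x
  }
  for (v in c("os_event", "rfs_event")) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    for (i in which(!(x %in% c(0, 1)))) note(i, paste0("invalid ", v))
    df[[v]] <- x
  }
  keep <- reasons == ""
  excluded <- data.frame(row = which(!keep),
                         patient_id = as.character(df$patient_id[!keep]),
                         reason = reasons[!keep], stringsAsFactors = FALSE)
  out <- df[keep, COHORT_COLUMNS, drop = FALSE]
  out$age <- as.numeric(out$age)
  for (v in names(COHORT_VOCAB))
    out[[v]] <- factor(out[[v]], levels = COHORT_VOCAB[[v]])
  late <- which(out$rfs_months > out$os_months + 1e-9)
  if (length(late))
    warning(length(late), " patient(s) have rfs_months > os_months",
            call. = FALSE)
  rownames(out) <- NULL
  list(patients = out, excluded = excluded)
}

#' Write a clinical cohort table
#'
#' @param cohort data.frame in the [read_cohort()] schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort[, COHORT_COLUMNS, drop = FALSE], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
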