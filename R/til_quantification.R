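# Regional TIL counting and joint high/low stratification.

#' Per-patient TIL profile
#'
#' @param patient_id identifier.
#' @param i_tils,p_tils,s_tils non-negative integer lymphocyte counts in the
#'   intratumor, peritumoral and stromal zones.
#' @param areas_um2 optional named region areas (from [region_areas()]).
#' @param tumorless flag: the slide had no tumor region (all lymphocytes are
#'   then stromal by construction).
#' @return An object of class `til_profile`; `total_tils` is always the sum
#'   of the three regional counts.
#' @export
til_profile <- function(patient_id, i_tils, p_tils, s_tils,
                        areas_um2 = NULL, tumorless = FALSE) {
  counts <- c(i_tils, p_tils, s_tils)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("TIL counts must be non-negative integers", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 i_tils = as.integer(i_tils), p_tils = as.integer(p_tils),
                 s_tils = as.integer(s_tils),
                 total_tils = as.integer(i_tils + p_tils + s_tils),
                 areas_um2 = areas_um2, tumorless = isTRUE(tumorless)),
            class = "til_profile")
}

#' @export
print.til_profile <- function(x, ...) {
  cat(sprintf("<til_profile> patient %s: I=%d P=%d S=%d total=%d%s\n",
              x$patient_id, x$i_tils, x$p_tils, x$s_tils, x$total_tils,
              if (x$tumorless) " [tumorless]" else ""))
  invisible(x)
}

#' @export
as.data.frame.til_profile <- function(x, ...) {
  out <- data.frame(patient_id = x$patient_id, i_tils = x$i_tils,
                    p_tils = x$p_tils, s_tils = x$s_tils,
                    total_tils = x$total_tils, stringsAsFactors = FALSE)
  if (!is.null(x$areas_um2)) {
    out$area_i_um2 <- unname(x$areas_um2[["INTRATUMOR"]])
    out$area_p_um2 <- unname(x$areas_um2[["PERITUMORAL"]])
    out$area_s_um2 <- unname(x$areas_um2[["STROMAL"]])
  }
  out
}

#' Count TILs per tissue region
#'
#' Counts `LYMPHOCYTE` nuclei per assigned region; tumor and other nuclei
#' are never counted.  Raw counts are the primary feature; region areas are
#' attached when a region mask is supplied so that densities are derivable.
#'
#' @param slide a [slide_nuclei()] object with regions assigned by
#'   [assign_nuclei_regions()].
#' @param mask optional [label_regions()] result; supplies region areas.
#' @return A [til_profile()].
#' @export
count_tils <- function(slide, mask = NULL) {
  stopifnot(inherits(slide, "slide_nuclei"))
  nuc <- slide$nuclei
  if (any(nuc$region_label == "UNASSIGNED"))
    stop("unassigned nuclei present: run assign_nuclei_regions() first",
         call. = FALSE)
  ly <- nuc[nuc$class_label == "LYMPHOCYTE", , drop = FALSE]
  tab <- table(factor(ly$region_label,
                      c("INTRATUMOR", "PERITUMORAL", "STROMAL")))
  til_profile(slide$patient_id,
              i_tils = tab[["INTRATUMOR"]], p_tils = tab[["PERITUMORAL"]],
              s_tils = tab[["STROMAL"]],
              areas_um2 = if (!is.null(mask)) region_areas(mask),
              tumorless = isTRUE(attr(slide, "tumorless")))
}

#' Joint I-TIL / P-TIL cutoffs
#'
#' @param c_i,c_p cutoffs for the intratumor and peritumoral counts.
#' @param c_s optional stromal cutoff (reported by the cutoff search but
#'   unused in the headline joint rule).
#' @return An object of class `joint_cutoffs`.
#' @export
joint_cutoffs <- function(c_i, c_p, c_s = NULL) {
  stopifnot(is.finite(c_i), is.finite(c_p), c_i > 0, c_p > 0)
  if (!is.null(c_s)) stopifnot(is.finite(c_s), c_s > 0)
  structure(list(c_i = c_i, c_p = c_p, c_s = c_s), class = "joint_cutoffs")
}

#' @export
print.joint_cutoffs <- function(x, ...) {
  cat(sprintf("<joint_cutoffs> I > %.7g and P > %.7g%s\n", x$c_i, x$c_p,
              if (!is.null(x$c_s)) sprintf(" (S cutoff %.7g, unused)", x$c_s)
              else ""))
  invisible(x)
}

#' Stratify patients by the joint I-TIL / P-TIL rule
#'
#' A patient is `HIGH` if and only if both the I-TIL count strictly exceeds
#' `c_i` and the P-TIL count strictly exceeds `c_p`; everyone else is `LOW`
#' ("exceeding" is read as strict inequality, so equality with a cutoff is
#' `LOW`).
#'
#' @param profiles data.frame with `i_tils` and `p_tils` columns (e.g. rows
#'   of [as.data.frame.til_profile()]), or a single [til_profile()].
#' @param cutoffs a [joint_cutoffs()] object.
#' @return Factor of `HIGH`/`LOW` per patient (levels `LOW`, `HIGH`).
#' @export
classify_joint <- function(profiles, cutoffs) {
  stopifnot(inherits(cutoffs, "joint_cutoffs"))
  if (inherits(profiles, "til_profile")) profiles <- as.data.frame(profiles)
  stopifnot(all(c("i_tils", "p_tils") %in% names(profiles)))
  high <- profiles$i_tils > cutoffs$c_i & profiles$p_tils > cutoffs$c_p
  factor(ifelse(high, "HIGH", "LOW"), levels = c("LOW", "HIGH"))
}

#' Rank alternative TIL stratification rules by prognostic separation
#'
#' Explores single-marker and pairwise-AND rules over the regional TIL
#' counts.  Each single-marker rule is split at its own survival-optimal
#' cutoff from [scan_cutpoints()]; a pairwise rule combines the two markers'
#' optimal cutoffs with the joint strict-exceed rule.  Rules are ranked by
#' the log-rank chi-square of the induced two-group split; single-marker
#' rules also carry the selection-corrected p-value.
#'
#' @param profiles data.frame with columns `i_tils`, `p_tils`, `s_tils`,
#'   `total_tils`.
#' @param times,events survival outcome aligned with `profiles` rows.
#' @param rules character vector of rules; markers from
#'   `c("i_tils","p_tils","s_tils","total_tils")`, pairs joined by `"&"`
#'   (default: all singles and all pairs).
#' @param epsilon_low,epsilon_high,min_group_size passed to
#'   [scan_cutpoints()]; a rule inducing a group smaller than
#'   `min_group_size` is skipped and reported.
#' @return data.frame ranked by decreasing chi-square, with columns `rule`,
#'   `cutoff_1`, `cutoff_2`, `n_high`, `n_low`, `chi2`, `p`, `p_corrected`
#'   (NA for pairwise rules), `skipped`.
#' @export
alternative_combinations <- function(profiles, times, events, rules = NULL,
                                     epsilon_low = 0.10, epsilon_high = 0.90,
                                     min_group_size = 10) {
  markers <- c("i_tils", "p_tils", "s_tils", "total_tils")
  stopifnot(all(markers %in% names(profiles)),
            nrow(profiles) == length(times), length(times) == length(events))
  if (is.null(rules)) {
    pairs <- utils::combn(markers, 2, paste, collapse = "&")
    rules <- c(markers, pairs)
  }
  res <- lapply(rules, function(rule) {
    parts <- strsplit(rule, "&", fixed = TRUE)[[1]]
    stopifnot(all(parts %in% markers))
    cuts <- lapply(parts, function(m)
      tryCatch(scan_cutpoints(profiles[[m]], times, events,
                              epsilon_low = epsilon_low,
                              epsilon_high = epsilon_high,
                              min_group_size = min_group_size),
               error = function(e) NULL))
    if (any(vapply(cuts, is.null, logical(1))))
      return(data.frame(rule = rule, cutoff_1 = NA_real_, cutoff_2 = NA_real_,
                        n_high = NA_integer_, n_low = NA_integer_,
                        chi2 = NA_real_, p = NA_real_, p_corrected = NA_real_,
                        skipped = "cutpoint scan failed"))
    high <- Reduce(`&`, lapply(seq_along(parts), function(i)
      profiles[[parts[i]]] > cuts[[i]]$best_cutoff))
    n_high <- sum(high); n_low <- sum(!high)
    if (min(n_high, n_low) < min_group_size)
      return(data.frame(rule = rule,
                        cutoff_1 = cuts[[1]]$best_cutoff,
                        cutoff_2 = if (length(cuts) > 1) cuts[[2]]$best_cutoff else NA_real_,
                        n_high = n_high, n_low = n_low,
                        chi2 = NA_real_, p = NA_real_, p_corrected = NA_real_,
                        skipped = sprintf("group smaller than %d", min_group_size)))
    lr <- logrank(times, events, factor(ifelse(high, "HIGH", "LOW")))
    data.frame(rule = rule,
               cutoff_1 = cuts[[1]]$best_cutoff,
               cutoff_2 = if (length(cuts) > 1) cuts[[2]]$best_cutoff else NA_real_,
               n_high = n_high, n_low = n_low,
               chi2 = lr$chi2, p = lr$p,
               p_corrected = if (length(parts) == 1) cuts[[1]]$p_corrected
                             else NA_real_,
               skipped = "")
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chi2, decreasing = TRUE, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
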