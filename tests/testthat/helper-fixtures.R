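# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; no stored data.

# small random classified-nuclei table
rand_nuclei <- function(n = 20, extent = c(1000, 1000)) {
  data.frame(
    nucleus_id = paste0("n", seq_len(n)),
    x_um = round(runif(n, 0, extent[1]), 3),
    y_um = round(runif(n, 0, extent[2]), 3),
    class_label = sample(c("TUMOR", "LYMPHOCYTE", "OTHER"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

rand_slide <- function(seed, n = 20, extent = c(1000, 1000)) {
  set.seed(seed)
  slide_nuclei(rand_nuclei(n, extent), slide_id = paste0("s", seed),
               extent_um = extent)
}

# a complete valid cohort row set
make_cohort_df <- function(n = 5) {
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = 55 + seq_len(n),
    sex = rep(c("female", "male"), length.out = n),
    location = rep(c("distal", "mid", "proximal"), length.out = n),
    pT = rep(c("T1", "T2", "T3", "T4"), length.out = n),
    pN = rep(c("N0", "N1", "N2", "N3"), length.out = n),
    pTNM = rep(c("I", "II", "III", "IV"), length.out = n),
    grade = rep(c("G1", "G2", "G3", "Gx"), length.out = n),
    margin = rep(c("R0", "R1"), length.out = n),
    lvi = rep(c("negative", "positive"), length.out = n),
    treatment = rep(c("surgery", "neoadjuvant+surgery"), length.out = n),
    os_months = 20 + 2 * seq_len(n),
    os_event = rep(c(1, 0), length.out = n),
    rfs_months = 15 + 2 * seq_len(n),
    rfs_event = rep(c(1, 0), length.out = n),
    stringsAsFactors = FALSE)
}

# a slide with a dense disk tumor (centroids on a grid inside the disk)
disk_tumor_slide <- function(radius = 200, center = c(1000, 1000),
                             extent = c(2000, 2000), spacing = 10,
                             lymph = NULL) {
  gx <- seq(spacing / 2, extent[1], by = spacing)
  gy <- seq(spacing / 2, extent[2], by = spacing)
  pts <- expand.grid(x = gx, y = gy)
  inside <- (pts$x - center[1])^2 + (pts$y - center[2])^2 <= radius^2
  tum <- pts[inside, ]
  nuc <- data.frame(nucleus_id = paste0("t", seq_len(nrow(tum))),
                    x_um = tum$x, y_um = tum$y, class_label = "TUMOR",
                    stringsAsFactors = FALSE)
  if (!is.null(lymph)) {
    ln <- data.frame(nucleus_id = paste0("l", seq_len(nrow(lymph))),
                     x_um = lymph[, 1], y_um = lymph[, 2],
                     class_label = "LYMPHOCYTE", stringsAsFactors = FALSE)
    nuc <- rbind(nuc, ln)
  }
  slide_nuclei(nuc, extent_um = extent)
}

# exact point-to-mask distance: minimum Euclidean distance from (x, y) to
# the center of any tumor cell (0 if the containing cell is tumor).  The
# distance transform measures cell-center to cell-center, so its label can
# differ from the point-based one only when the point distance is within
# pixel_um * sqrt(2)/2 of the band edge.
brute_force_mask_distance <- function(x, y, tumor_mask) {
  m <- tumor_mask$mask; px <- tumor_mask$pixel_um
  idx <- which(m == 1L, arr.ind = TRUE)
  if (!nrow(idx)) return(rep(Inf, length(x)))
  cx <- (idx[, 1] - 0.5) * px; cy <- (idx[, 2] - 0.5) * px
  vapply(seq_along(x), function(i) {
    ix <- floor(x[i] / px) + 1; iy <- floor(y[i] / px) + 1
    if (ix >= 1 && ix <= nrow(m) && iy >= 1 && iy <= ncol(m) &&
        m[ix, iy] == 1L) return(0)
    sqrt(min((cx - x[i])^2 + (cy - y[i])^2))
  }, numeric(1))
}
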