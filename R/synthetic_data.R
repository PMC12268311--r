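# Seeded generators for synthetic slides (clustered tumor-nucleus point
# patterns with region-dependent lymphocyte intensities) and synthetic
# cohorts (log-normal TIL counts, exponential survival calibrated to
# printed group-specific 5-year OS), each with exact ground truth so every
# pipeline stage is testable without real data.

#' Parameters of the slide simulator
#'
#' Tumor nests are disks with uniformly placed centers (kept fully inside
#' the slide) and per-nest radii drawn from a normal distribution; tumor
#' nuclei are uniform within each disk at `tumor_density`.  Lymphocytes and
#' other nuclei are Poisson point processes; the lymphocyte intensity
#' depends on the true region (intratumor / peritumoral band / stroma)
#' computed analytically from the nest geometry, so the generator's truth is
#' exact.
#'
#' @param extent_um slide width and height (default 4000 x 4000 um).
#' @param n_tumor_nests number of nests (default 3).
#' @param nest_radius_um mean and sd of nest radius (default 600, 100 um).
#' @param tumor_density tumor nuclei per um2 inside nests (default 0.005,
#'   i.e. 5000 nuclei/mm2, a dense carcinoma nest).
#' @param lambda_i,lambda_p,lambda_s lymphocyte intensity per um2 in the
#'   intratumor, peritumoral and stromal zones (defaults 8e-4, 1.2e-3,
#'   5e-4: infiltration densest in the band, as in inflamed tumor margins).
#' @param lambda_other background intensity of other nuclei (default 1e-3).
#' @param band_um peritumoral band width (default 300 um).
#' @param seed mandatory integer seed.
#' @return Object of class `slide_sim_params`.
#' @export
slide_sim_params <- function(extent_um = c(4000, 4000), n_tumor_nests = 3,
                             nest_radius_um = c(mean = 600, sd = 100),
                             tumor_density = 0.005,
                             lambda_i = 8e-4, lambda_p = 1.2e-3,
                             lambda_s = 5e-4, lambda_other = 1e-3,
                             band_um = 300, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(extent_um) == 2, all(extent_um > 0), n_tumor_nests >= 0,
            nest_radius_um[1] > 0, tumor_density >= 0,
            lambda_i >= 0, lambda_p >= 0, lambda_s >= 0, lambda_other >= 0,
            band_um >= 0)
  structure(list(extent_um = as.numeric(extent_um),
                 n_tumor_nests = as.integer(n_tumor_nests),
                 nest_radius_um = unname(as.numeric(nest_radius_um)),
                 tumor_density = tumor_density,
                 lambda_i = lambda_i, lambda_p = lambda_p,
                 lambda_s = lambda_s, lambda_other = lambda_other,
                 band_um = band_um, seed = as.integer(seed)),
            class = "slide_sim_params")
}

#' True region label from nest geometry
#'
#' Signed distance to the union-of-disks tumor: `d <= 0` is intratumor,
#' `0 < d <= band_um` peritumoral (band closed above), `d > band_um`
#' stromal.  With no nests everything is stromal.
#'
#' @param x,y point coordinates in um.
#' @param nests data.frame with `x`, `y`, `r` (disk centers and radii).
#' @param band_um band width.
#' @return Character vector of region labels.
#' @export
true_region <- function(x, y, nests, band_um = 300) {
  if (is.null(nests) || nrow(nests) == 0)
    return(rep("STROMAL", length(x)))
  d <- rep(Inf, length(x))
  for (k in seq_len(nrow(nests)))
    d <- pmin(d, sqrt((x - nests$x[k])^2 + (y - nests$y[k])^2) - nests$r[k])
  ifelse(d <= 0, "INTRATUMOR",
         ifelse(d <= band_um, "PERITUMORAL", "STROMAL"))
}

#' True region areas by fine-grid quadrature
#'
#' Areas of the intratumor / peritumoral / stromal zones implied by a nest
#' geometry, integrated on a `grid_um` midpoint grid over the slide window.
#'
#' @param nests nest table (`x`, `y`, `r`).
#' @param extent_um slide extent.
#' @param band_um band width.
#' @param grid_um quadrature cell size (default 2 um).
#' @return Named vector `INTRATUMOR`, `PERITUMORAL`, `STROMAL` in um2.
#' @export
true_region_areas <- function(nests, extent_um, band_um = 300, grid_um = 2) {
  gx <- seq(grid_um / 2, extent_um[1], by = grid_um)
  gy <- seq(grid_um / 2, extent_um[2], by = grid_um)
  lab <- true_region(rep(gx, times = length(gy)),
                     rep(gy, each = length(gx)), nests, band_um)
  counts <- table(factor(lab, c("INTRATUMOR", "PERITUMORAL", "STROMAL")))
  setNames(as.numeric(counts) * grid_um^2, names(counts))
}

#' Simulate a classified-nuclei slide with known ground truth
#'
#' @param params a [slide_sim_params()] object.
#' @return List with `slide` (a [slide_nuclei()], regions `UNASSIGNED`) and
#'   `truth`: `nests` (centers/radii), `region` (true per-nucleus region),
#'   `band_um`, and `lambda` (the region intensities used).
#' @export
simulate_slide <- function(params) {
  stopifnot(inherits(params, "slide_sim_params"))
  W <- params$extent_um[1]; H <- params$extent_um[2]
  lam_max <- max(params$lambda_i, params$lambda_p, params$lambda_s)
  expected <- params$n_tumor_nests * params$tumor_density *
    pi * params$nest_radius_um[1]^2 +
    (lam_max + params$lambda_other) * W * H
  if (expected > 1e7)
    stop("parameters imply > 1e7 nuclei; reduce densities or extent",
         call. = FALSE)
  set.seed(params$seed)
  # nests: radius first, then a center keeping the disk inside the window
  nests <- NULL
  if (params$n_tumor_nests > 0) {
    r <- pmax(50, rnorm(params$n_tumor_nests, params$nest_radius_um[1],
                        params$nest_radius_um[2]))
    r <- pmin(r, (min(W, H) / 2) - 1)
    cx <- runif(params$n_tumor_nests, r, W - r)
    cy <- runif(params$n_tumor_nests, r, H - r)
    nests <- data.frame(x = cx, y = cy, r = r)
  }
  # tumor nuclei uniform in each disk
  tum <- NULL
  if (!is.null(nests) && params$tumor_density > 0) {
    pts <- lapply(seq_len(nrow(nests)), function(k) {
      n_k <- rpois(1, params$tumor_density * pi * nests$r[k]^2)
      if (!n_k) return(NULL)
      rho <- nests$r[k] * sqrt(runif(n_k)); th <- runif(n_k, 0, 2 * pi)
      data.frame(x = nests$x[k] + rho * cos(th),
                 y = nests$y[k] + rho * sin(th))
    })
    tum <- do.call(rbind, pts)
  }
  # lymphocytes: thinning of a homogeneous process at lam_max
  lym <- NULL
  if (lam_max > 0) {
    n0 <- rpois(1, lam_max * W * H)
    if (n0) {
      x <- runif(n0, 0, W); y <- runif(n0, 0, H)
      reg <- true_region(x, y, nests, params$band_um)
      lam <- c(INTRATUMOR = params$lambda_i, PERITUMORAL = params$lambda_p,
               STROMAL = params$lambda_s)[reg]
      keep <- runif(n0) < lam / lam_max
      lym <- data.frame(x = x[keep], y = y[keep])
    }
  }
  oth <- NULL
  if (params$lambda_other > 0) {
    n0 <- rpois(1, params$lambda_other * W * H)
    if (n0) oth <- data.frame(x = runif(n0, 0, W), y = runif(n0, 0, H))
  }
  mk <- function(df, prefix, cls) {
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(nucleus_id = paste0(prefix, seq_len(nrow(df))),
               x_um = pmin(df$x, W), y_um = pmin(df$y, H),
               class_label = cls, stringsAsFactors = FALSE)
  }
  nuc <- rbind(mk(tum, "t", "TUMOR"), mk(lym, "l", "LYMPHOCYTE"),
               mk(oth, "o", "OTHER"))
  if (is.null(nuc))
    nuc <- data.frame(nucleus_id = character(), x_um = numeric(),
                      y_um = numeric(), class_label = character())
  slide <- slide_nuclei(nuc, slide_id = paste0("sim", params$seed),
                        extent_um = params$extent_um)
  truth_region <- true_region(nuc$x_um, nuc$y_um, nests, params$band_um)
  list(slide = slide,
       truth = list(nests = nests, region = truth_region,
                    band_um = params$band_um,
                    lambda = c(I = params$lambda_i, P = params$lambda_p,
                               S = params$lambda_s)))
}

# Study-cohort category frequencies used by the cohort simulator (printed
# composition of the pooled cohort; proportions, renormalized internally).
COHORT_FREQS <- list(
  sex       = c(female = 0.227, male = 0.773),
  location  = c(distal = 0.250, mid = 0.622, proximal = 0.128),
  pT        = c(T1 = 0.164, T2 = 0.248, T3 = 0.577, T4 = 0.010),
  pN        = c(N0 = 0.619, N1 = 0.218, N2 = 0.114, N3 = 0.050),
  pTNM      = c(I = 0.149, II = 0.492, III = 0.310, IV = 0.049),
  grade     = c(G1 = 0.116, G2 = 0.698, G3 = 0.176, Gx = 0.010),
  margin    = c(R0 = 0.966, R1 = 0.034),
  lvi       = c(negative = 0.894, positive = 0.106),
  treatment = c(surgery = 0.847, `neoadjuvant+surgery` = 0.153)
)

#' Parameters of the cohort simulator
#'
#' Regional TIL counts are drawn from log-normal marginals moment-matched to
#' the study means/SDs, joined by a Gaussian copula with correlation
#' `rho_ip` between the intratumor and peritumoral counts.  Patients are
#' stratified by the joint strict-exceed rule at `cutoffs`; overall survival
#' is exponential per group with rate `-log(s_group)/horizon_months`, so the
#' true hazard ratio is `log(s_high)/log(s_low)`.  Administrative censoring
#' is uniform over `censor_range` (default 0-86 months: median potential
#' follow-up 43 months).  Recurrence-free survival is generated as
#' min(recurrence, death) with the recurrence hazard set so group RFS at the
#' horizon matches `rfs_high`/`rfs_low`.
#'
#' @param n_patients cohort size (default 596).
#' @param count_means,count_sds named (`i`, `p`, `s`) means and SDs of the
#'   regional counts; defaults are the study values 9566.1/12687.6/70807.6
#'   and 4806.3/4500.9/45095.1.
#' @param rho_ip Gaussian-copula correlation between I and P counts
#'   (default 0; see the methods vignette for why independence is the
#'   calibration default).
#' @param cutoffs a [joint_cutoffs()]; default the study values 9377 / 9483
#'   (stromal 33580, unused).
#' @param s_high,s_low 5-year OS per group (defaults 0.679, 0.544).
#' @param rfs_high,rfs_low 5-year RFS per group (defaults 0.621, 0.509).
#' @param horizon_months calibration horizon (default 60 = 5 years).
#' @param censor_range administrative censoring window in months.
#' @param confounding strength of an optional covariate link: positive
#'   values make advanced nodal stage lower the I/P counts and raise the
#'   hazard (default 0 = none).
#' @param seed mandatory integer seed.
#' @return Object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 596,
                              count_means = c(i = 9566.1, p = 12687.6,
                                              s = 70807.6),
                              count_sds = c(i = 4806.3, p = 4500.9,
                                            s = 45095.1),
                              rho_ip = 0,
                              cutoffs = joint_cutoffs(9377, 9483, 33580),
                              s_high = 0.679, s_low = 0.544,
                              rfs_high = 0.621, rfs_low = 0.509,
                              horizon_months = 60,
                              censor_range = c(0, 86),
                              confounding = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_patients >= 2, s_high > 0, s_high < 1, s_low > 0, s_low < 1,
            rfs_high > 0, rfs_high < 1, rfs_low > 0, rfs_low < 1,
            abs(rho_ip) < 1, horizon_months > 0,
            length(censor_range) == 2, censor_range[2] > censor_range[1],
            inherits(cutoffs, "joint_cutoffs"))
  structure(list(n_patients = as.integer(n_patients),
                 count_means = count_means, count_sds = count_sds,
                 rho_ip = rho_ip, cutoffs = cutoffs,
                 s_high = s_high, s_low = s_low,
                 rfs_high = rfs_high, rfs_low = rfs_low,
                 horizon_months = horizon_months,
                 censor_range = as.numeric(censor_range),
                 confounding = confounding, seed = as.integer(seed)),
            class = "cohort_sim_params")
}

# lognormal (mu, sigma) matching a target mean and sd
lognormal_moments <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(mu = log(m) - s2 / 2, sigma = sqrt(s2))
}

#' Simulate a clinical cohort with TIL profiles and known ground truth
#'
#' @param params a [cohort_sim_params()] object.
#' @return List with `cohort` (data.frame in the [read_cohort()] schema plus
#'   `group`), `profiles` (patient_id + regional counts), and `truth`:
#'   `group`, per-group OS hazards, and `true_hr = log(s_high)/log(s_low)`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  n <- params$n_patients
  # counts: Gaussian copula (I-P correlated, S independent) + lognormal
  z1 <- rnorm(n); z2 <- params$rho_ip * z1 +
    sqrt(1 - params$rho_ip^2) * rnorm(n); z3 <- rnorm(n)
  mi <- lognormal_moments(params$count_means[["i"]], params$count_sds[["i"]])
  mp <- lognormal_moments(params$count_means[["p"]], params$count_sds[["p"]])
  ms <- lognormal_moments(params$count_means[["s"]], params$count_sds[["s"]])
  # covariates from the study category frequencies
  draw <- function(v) factor(
    sample(names(COHORT_FREQS[[v]]), n, replace = TRUE,
           prob = COHORT_FREQS[[v]]), levels = names(COHORT_FREQS[[v]]))
  cov <- data.frame(sex = draw("sex"), location = draw("location"),
                    pT = draw("pT"), pN = draw("pN"), pTNM = draw("pTNM"),
                    grade = draw("grade"), margin = draw("margin"),
                    lvi = draw("lvi"), treatment = draw("treatment"))
  cov$age <- pmin(90, pmax(30, round(rnorm(n, 61, 8))))
  conf_lin <- params$confounding * 0.25 * (as.integer(cov$pN) - 1)
  i_tils <- round(exp(mi["mu"] + mi["sigma"] * z1 - conf_lin))
  p_tils <- round(exp(mp["mu"] + mp["sigma"] * z2 - conf_lin))
  s_tils <- round(exp(ms["mu"] + ms["sigma"] * z3))
  profiles <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                         i_tils = as.integer(i_tils),
                         p_tils = as.integer(p_tils),
                         s_tils = as.integer(s_tils))
  profiles$total_tils <- profiles$i_tils + profiles$p_tils + profiles$s_tils
  group <- classify_joint(profiles, params$cutoffs)
  # exponential OS calibrated to group 5-year survival
  h <- params$horizon_months
  lam_os <- ifelse(group == "HIGH", -log(params$s_high) / h,
                   -log(params$s_low) / h) * exp(conf_lin * 0.5)
  t_death <- rexp(n, lam_os)
  # recurrence hazard: total RFS hazard minus the death hazard
  lam_rec <- pmax(ifelse(group == "HIGH", -log(params$rfs_high) / h,
                         -log(params$rfs_low) / h) - lam_os, 1e-8)
  t_rec <- rexp(n, lam_rec)
  t_rfs <- pmin(t_rec, t_death)
  cens <- runif(n, params$censor_range[1], params$censor_range[2])
  cohort <- cbind(data.frame(patient_id = profiles$patient_id), cov)
  cohort$os_months <- pmin(t_death, cens)
  cohort$os_event <- as.integer(t_death <= cens)
  cohort$rfs_months <- pmin(t_rfs, cens)
  cohort$rfs_event <- as.integer(t_rfs <= cens)
  cohort <- cohort[, c("patient_id", "age", "sex", "location", "pT", "pN",
                       "pTNM", "grade", "margin", "lvi", "treatment",
                       "os_months", "os_event", "rfs_months", "rfs_event")]
  cohort$group <- group
  list(cohort = cohort, profiles = profiles,
       truth = list(group = group,
                    lambda_high = -log(params$s_high) / h,
                    lambda_low = -log(params$s_low) / h,
                    true_hr = log(params$s_high) / log(params$s_low)))
}

#' Simulate a balanced two-group cohort calibrated to 5-year survival
#'
#' Exponential overall survival with rates `-log(s_high)/horizon` and
#' `-log(s_low)/horizon` per month and administrative censoring at a fixed
#' time, emulating a matched high/low comparison of a given size.
#'
#' @param n_high,n_low group sizes (defaults 163 each, the matched design).
#' @param s_high,s_low survival fractions at `horizon` (defaults 0.679,
#'   0.544).
#' @param horizon_months calibration horizon (default 60).
#' @param censor_months administrative censoring time (default 120).
#' @param seed integer seed.
#' @return data.frame `group` (factor LOW/HIGH), `os_months`, `os_event`;
#'   attribute `true_hr`.
#' @export
simulate_matched_groups <- function(n_high = 163, n_low = 163,
                                    s_high = 0.679, s_low = 0.544,
                                    horizon_months = 60, censor_months = 120,
                                    seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  lam <- c(rep(-log(s_low) / horizon_months, n_low),
           rep(-log(s_high) / horizon_months, n_high))
  grp <- factor(rep(c("LOW", "HIGH"), c(n_low, n_high)),
                levels = c("LOW", "HIGH"))
  t <- rexp(n_low + n_high, lam)
  out <- data.frame(group = grp,
                    os_months = pmin(t, censor_months),
                    os_event = as.integer(t <= censor_months))
  attr(out, "true_hr") <- log(s_high) / log(s_low)
  out
}
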