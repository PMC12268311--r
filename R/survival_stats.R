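# Kaplan-Meier estimation, Cox proportional-hazards modelling, propensity
# score matching and subgroup hazard-ratio tables.  Product-limit and
# partial-likelihood machinery is delegated to the survival package; the
# greedy caliper matcher and balance diagnostics are implemented here.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood variance and log-log transformed
#' 95% confidence limits.
#'
#' @param times non-negative times; @param events 0/1 indicators.
#' @return Object of class `km_curve`: `time`, `n_risk`, `n_event`, `surv`,
#'   `greenwood_var`, `lower`, `upper` at each distinct observed time.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (!length(times)) stop("empty input", call. = FALSE)
  if (any(times < 0) || !all(events %in% c(0, 1)))
    stop("times must be >= 0 and events 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  # survfit std.err is the se of log S(t); Greenwood var(S) = S^2 * se^2
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv,
                 greenwood_var = (fit$surv * fit$std.err)^2,
                 lower = fit$lower, upper = fit$upper,
                 n = length(times), n_events = sum(events)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, max time %.4g\n",
              x$n, x$n_events, max(x$time)))
  invisible(x)
}

#' Survival probability (with 95% CI) at given times
#'
#' Step-function accessor for a [km_estimate()] curve.
#'
#' @param km a `km_curve`.
#' @param t times at which to evaluate.
#' @return data.frame `time`, `surv`, `lower`, `upper`.
#' @export
survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(t, km$time)
  pick <- function(v, default) ifelse(idx == 0, default, v[pmax(idx, 1)])
  data.frame(time = t,
             surv  = pick(km$surv, 1),
             lower = pick(km$lower, NA_real_),
             upper = pick(km$upper, NA_real_))
}

#' @export
plot.km_curve <- function(x, add = FALSE, conf = TRUE, col = 1, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  if (!add)
    graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = "time",
                   ylab = "survival", col = col, ...)
  else graphics::lines(tt, ss, col = col, ...)
  if (conf) {
    graphics::lines(x$time, x$lower, lty = 3, col = col, type = "s")
    graphics::lines(x$time, x$upper, lty = 3, col = col, type = "s")
  }
  invisible(x)
}

# Covariate encoding ------------------------------------------------------

# Reference levels follow the study table ordering: female, distal, T1, N0,
# stage I, G1, R0, LVI-negative, surgery-only.  Gx is retained as its own
# grade level, not imputed.
encode_cohort <- function(data) {
  for (v in intersect(names(COHORT_VOCAB), names(data))) {
    lv <- COHORT_VOCAB[[v]]
    if (v == "treatment") lv <- c("surgery", "neoadjuvant+surgery")
    data[[v]] <- factor(as.character(data[[v]]), levels = lv)
  }
  data
}

#' Cox proportional-hazards fit
#'
#' Multivariable proportional-hazards regression on a cohort table in the
#' [read_cohort()] schema (optionally with extra columns such as a TIL
#' `group`).  The partial likelihood is maximized with Efron tie handling;
#' categorical covariates are encoded against study reference levels
#' (female, distal, T1, N0, stage I, G1, R0, LVI-negative, surgery-only;
#' `LOW` for the TIL group).
#'
#' @param data cohort data.frame.
#' @param outcome `"os"` or `"rfs"` (uses `<outcome>_months` /
#'   `<outcome>_event` columns).
#' @param covariates character vector of column names.
#' @return Object of class `ph_fit`: `table` (term, hr, lower, upper, p,
#'   and the coefficient and its se), the underlying `coxph` fit, outcome,
#'   ties method, reference levels, and `flagged` covariates (suspected
#'   separation / non-convergence).
#' @export
fit_ph <- function(data, outcome = c("os", "rfs"), covariates) {
  outcome <- match.arg(outcome)
  tcol <- paste0(outcome, "_months"); ecol <- paste0(outcome, "_event")
  stopifnot(all(c(tcol, ecol, covariates) %in% names(data)))
  if (sum(data[[ecol]]) < 1) stop("no events", call. = FALSE)
  data <- encode_cohort(data)
  if ("group" %in% covariates && !is.factor(data$group))
    data$group <- factor(data$group, levels = c("LOW", "HIGH"))
  fml <- as.formula(paste0("survival::Surv(", tcol, ", ", ecol, ") ~ ",
                           paste(covariates, collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) { warn <<- c(warn, conditionMessage(w))
                            invokeRestart("muffleWarning") })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  tab <- data.frame(term = rownames(co),
                    coef = co[, "coef"], se = co[, "se(coef)"],
                    hr = ci[, "exp(coef)"],
                    lower = ci[, "lower .95"], upper = ci[, "upper .95"],
                    p = co[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  flagged <- tab$term[!is.finite(tab$se) | tab$se > 10 | abs(tab$coef) > 10]
  if (length(flagged))
    warning("possible separation / non-convergence for: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  refs <- lapply(data[intersect(covariates, names(data))], function(x)
    if (is.factor(x)) levels(x)[1] else NULL)
  structure(list(table = tab, fit = fit, outcome = outcome, ties = "efron",
                 covariates = covariates,
                 reference_levels = Filter(Negate(is.null), refs),
                 n = s$n, n_events = s$nevent,
                 warnings = warn, flagged = flagged),
            class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<ph_fit> outcome %s, ties %s, n = %d, events = %d\n",
              toupper(x$outcome), x$ties, x$n, x$n_events))
  tab <- x$table
  tab$hr <- signif(tab$hr, digits); tab$lower <- signif(tab$lower, digits)
  tab$upper <- signif(tab$upper, digits); tab$p <- signif(tab$p, digits)
  print(tab[, c("term", "hr", "lower", "upper", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.ph_fit <- function(object, ...) setNames(object$table$coef,
                                              object$table$term)

#' Propensity scores for the high-TIL group
#'
#' Logistic regression of group membership on covariates, by maximum
#' likelihood; returns fitted probabilities in (0, 1).  Constant covariates
#' are dropped with a warning; suspected separation is flagged.
#'
#' @param data cohort data.frame.
#' @param covariates covariate column names.
#' @param group column name (factor with `HIGH` as the second level) or a
#'   vector of labels.
#' @return Numeric vector of scores, with attributes `model` (the glm) and
#'   `dropped` (constant covariates removed).
#' @export
estimate_propensity <- function(data, covariates, group = "group") {
  g <- if (is.character(group) && length(group) == 1) data[[group]] else group
  g <- factor(g)
  if (nlevels(g) != 2) stop("group must be binary", call. = FALSE)
  pos <- if ("HIGH" %in% levels(g)) "HIGH" else levels(g)[2]
  y <- as.integer(g == pos)
  data <- encode_cohort(data)
  keep <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]])) > 1, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped))
    warning("constant covariate(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!length(keep)) {
    sc <- rep(mean(y), length(y))
    attr(sc, "dropped") <- dropped
    return(sc)
  }
  fml <- as.formula(paste("y ~", paste(keep, collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    glm(fml, data = cbind(data, y = y), family = binomial()),
    warning = function(w) { warn <<- c(warn, conditionMessage(w))
                            invokeRestart("muffleWarning") })
  if (any(grepl("fitted probabilities numerically 0 or 1", warn)))
    warning("possible separation in the propensity model", call. = FALSE)
  sc <- as.numeric(fitted(fit))
  attr(sc, "model") <- fit
  attr(sc, "dropped") <- dropped
  sc
}

# Standardized mean difference of a covariate between groups; factors are
# expanded to indicator columns and the max |SMD| over levels is reported.
smd_one <- function(x, treated) {
  if (is.factor(x) || is.character(x)) {
    x <- factor(x)
    vals <- vapply(levels(x), function(l)
      smd_one(as.numeric(x == l), treated), numeric(1))
    return(max(abs(vals), na.rm = TRUE))
  }
  m1 <- mean(x[treated]); m0 <- mean(x[!treated])
  v <- (stats::var(x[treated]) + stats::var(x[!treated])) / 2
  if (!is.finite(v) || v <= 0) return(0)
  (m1 - m0) / sqrt(v)
}

#' Greedy 1:1 nearest-neighbour propensity matching
#'
#' Matches each high-group ("treated") patient to the nearest unused
#' low-group control on the logit of the propensity score, without
#' replacement, within a caliper of `caliper_sd_logit` standard deviations
#' of the logit scores.  Treated patients are processed in random order
#' under `seed`.  Pre/post standardized mean differences are reported when
#' covariates are supplied.
#'
#' @param scores propensity scores in (0, 1).
#' @param labels binary group labels; `HIGH` (or the second factor level) is
#'   treated.
#' @param covariates optional data.frame for balance diagnostics.
#' @param caliper_sd_logit caliper width in SDs of the logit score
#'   (default 0.2).
#' @param seed integer seed for the processing order.
#' @return Object of class `match_result`: `pairs` (data.frame `treated`,
#'   `control` row indices and `delta`, the absolute logit-score gap),
#'   `caliper` (logit scale), `smd` (pre/post per covariate), counts.
#' @export
match_nearest <- function(scores, labels, covariates = NULL,
                          caliper_sd_logit = 0.2, seed = 1) {
  g <- factor(labels)
  if (nlevels(g) != 2) stop("labels must be binary", call. = FALSE)
  treated_lab <- if ("HIGH" %in% levels(g)) "HIGH" else levels(g)[2]
  treated <- g == treated_lab
  if (!any(treated) || all(treated))
    stop("both groups must be non-empty", call. = FALSE)
  lg <- qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  caliper <- caliper_sd_logit * sd(lg)
  if (!is.finite(caliper) || caliper <= 0) caliper <- Inf
  idx_t <- which(treated); idx_c <- which(!treated)
  ord <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    o <- sample(length(idx_t))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    o
  })
  used <- logical(length(idx_c))
  pairs <- vector("list", length(idx_t))
  for (k in ord) {
    free <- which(!used)
    if (!length(free)) break
    gaps <- abs(lg[idx_c[free]] - lg[idx_t[k]])
    j <- free[which.min(gaps)]
    if (min(gaps) <= caliper) {
      used[j] <- TRUE
      pairs[[k]] <- data.frame(treated = idx_t[k], control = idx_c[j],
                               delta = min(gaps))
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    stop(errorCondition("zero matches within the caliper",
                        class = c("tilzone_match_failure", "error",
                                  "condition")))
  smd <- NULL
  if (!is.null(covariates)) {
    midx <- c(pairs$treated, pairs$control)
    smd <- data.frame(
      covariate = names(covariates),
      smd_pre = vapply(covariates, function(x) smd_one(x, treated),
                       numeric(1)),
      smd_post = vapply(covariates, function(x)
        smd_one(x[midx], treated[midx]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs[order(pairs$treated), , drop = FALSE],
                 caliper = caliper, caliper_sd_logit = caliper_sd_logit,
                 n_treated = length(idx_t), n_control = length(idx_c),
                 n_matched = nrow(pairs), smd = smd, seed = seed),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d/%d treated matched 1:1 (caliper %.4g logit SD units = %.4g)\n",
              x$n_matched, x$n_treated, x$caliper_sd_logit, x$caliper))
  if (!is.null(x$smd)) {
    s <- x$smd; s$smd_pre <- signif(s$smd_pre, 3); s$smd_post <- signif(s$smd_post, 3)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Per-stratum hazard ratios for the high- vs low-TIL comparison
#'
#' Fits a two-group proportional-hazards model within each level of a
#' stratifying covariate; strata with fewer than `min_events` events are
#' reported as not estimable.  The output is forest-plot-ready.
#'
#' @param data cohort data.frame with a `group` column (`LOW`/`HIGH`).
#' @param stratifier column name to stratify on.
#' @param outcome `"os"` or `"rfs"`.
#' @param min_events minimum events for a stratum fit (default 5).
#' @return data.frame `stratum`, `n`, `n_events`, `hr`, `lower`, `upper`,
#'   `p`, `estimable`.
#' @export
subgroup_hr <- function(data, stratifier, outcome = c("os", "rfs"),
                        min_events = 5) {
  outcome <- match.arg(outcome)
  stopifnot(stratifier %in% names(data), "group" %in% names(data))
  ecol <- paste0(outcome, "_event")
  strata <- unique(as.character(data[[stratifier]]))
  rows <- lapply(strata, function(s) {
    d <- data[as.character(data[[stratifier]]) == s, , drop = FALSE]
    ne <- sum(d[[ecol]])
    base <- data.frame(stratum = s, n = nrow(d), n_events = ne,
                       hr = NA_real_, lower = NA_real_, upper = NA_real_,
                       p = NA_real_, estimable = FALSE,
                       stringsAsFactors = FALSE)
    if (ne < min_events || length(unique(d$group)) < 2) return(base)
    f <- tryCatch(suppressWarnings(fit_ph(d, outcome, "group")),
                  error = function(e) NULL)
    if (is.null(f)) return(base)
    base[c("hr", "lower", "upper", "p")] <-
      f$table[1, c("hr", "lower", "upper", "p")]
    base$estimable <- TRUE
    base
  })
  do.call(rbind, rows)
}
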