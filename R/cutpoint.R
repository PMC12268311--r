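# Survival-optimal cutoff derivation: maximally selected log-rank
# statistics over the distinct marker values inside a quantile window, with
# the Miller-Siegmund minimum-p correction for the selection optimism.

# Vectorized two-sample log-rank chi-squares for every split "value > c"
# over a sorted candidate grid.  Uses the hypergeometric (ties-corrected)
# variance at each distinct event time.  O(n log n + J*K) via 2-D suffix
# sums of an incidence matrix, so scanning all candidates costs little more
# than one test.
logrank_scan <- function(values, times, events, candidates) {
  stopifnot(length(values) == length(times), length(times) == length(events))
  K <- length(candidates)
  ut <- sort(unique(times[events == 1]))
  J <- length(ut)
  if (J == 0L || K == 0L) return(numeric(K))
  n_j <- vapply(ut, function(t) sum(times >= t), numeric(1))
  d_j <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  r_i <- findInterval(times, ut)                      # event times <= time_i
  m_i <- findInterval(values, candidates, left.open = TRUE)  # candidates < x_i
  # n1_j(k) = #{i: time_i >= ut_j, x_i > c_k} = suffix sum over (r, m)
  B <- matrix(0, J, K)
  inb <- r_i >= 1L & m_i >= 1L
  if (any(inb)) {
    tb <- table(factor(r_i[inb], levels = seq_len(J)),
                factor(m_i[inb], levels = seq_len(K)))
    B <- matrix(as.numeric(tb), J, K)
  }
  suffix_rows <- function(M) {
    if (nrow(M) > 1)
      for (j in (nrow(M) - 1):1) M[j, ] <- M[j, ] + M[j + 1, ]
    M
  }
  suffix_cols <- function(M) {
    if (ncol(M) > 1)
      for (k in (ncol(M) - 1):1) M[, k] <- M[, k] + M[, k + 1]
    M
  }
  n1 <- suffix_cols(suffix_rows(B))
  # d1_j(k): events at ut_j in the high group = column suffix sum
  D <- matrix(0, J, K)
  ine <- events == 1 & m_i >= 1L
  if (any(ine)) {
    td <- table(factor(r_i[ine], levels = seq_len(J)),
                factor(m_i[ine], levels = seq_len(K)))
    D <- suffix_cols(matrix(as.numeric(td), J, K))
  }
  d1 <- D
  w <- ifelse(n_j > 1, d_j * (n_j - d_j) / ((n_j - 1) * n_j^2), 0)
  U <- colSums(matrix(d1 - (d_j / n_j) * n1, J, K))
  V <- colSums(matrix(w * n1 * (n_j - n1), J, K))
  chi2 <- ifelse(V > 1e-12, U^2 / V, 0)
  as.numeric(chi2)
}

#' Log-rank test
#'
#' Standard log-rank test for two or more groups: at each distinct event
#' time the observed events per group are compared with their expectation
#' under the hypergeometric model, with the ties-corrected hypergeometric
#' variance; the statistic is chi-square with (groups - 1) degrees of
#' freedom.
#'
#' @param times non-negative survival/censoring times.
#' @param events 0/1 event indicators.
#' @param group group membership (factor or coercible).
#' @return An object of class `logrank_test`: `chi2`, `df`, `p`, and the
#'   per-group `observed` and `expected` event totals.
#' @export
logrank <- function(times, events, group) {
  group <- factor(group)
  group <- droplevels(group)
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (nlevels(group) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (sum(events) < 1) stop("no events", call. = FALSE)
  G <- nlevels(group)
  ut <- sort(unique(times[events == 1]))
  O <- E <- setNames(numeric(G), levels(group))
  Vm <- matrix(0, G, G)
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    dg <- vapply(levels(group), function(g)
      sum(times == t & events == 1 & group == g), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      # diagonal f*ng*(n-ng)/n^2, off-diagonal -f*ng*nh/n^2
      Vm <- Vm + f * (diag(ng) * n - outer(ng, ng)) / n^2
    }
  }
  u <- (O - E)[-G]
  V <- Vm[-G, -G, drop = FALSE]
  chi2 <- if (all(abs(u) < 1e-12)) 0 else
    as.numeric(t(u) %*% solve(V, u))
  df <- G - 1
  structure(list(chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE),
                 observed = O, expected = E, n = as.integer(table(group))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  tab <- data.frame(n = x$n, observed = x$observed, expected = x$expected)
  print(tab)
  invisible(x)
}

#' Survival-optimal cutoff by minimum-p log-rank scanning
#'
#' Re-implements the core of optimal-cutpoint software such as X-tile:
#' candidate cutoffs are the distinct marker values between the
#' `epsilon_low` and `epsilon_high` order-statistic quantiles; for each, the
#' cohort is split at `value > cutoff` (the high side, matching the joint
#' strict-exceed stratification rule) and the two-sample log-rank chi-square
#' computed.  The maximizing cutoff is returned with the Miller-Siegmund
#' approximation for the p-value of the maximally selected statistic; ties
#' in the chi-square go to the smallest cutoff.
#'
#' @param values marker values (one per subject).
#' @param times,events survival outcome aligned with `values`.
#' @param epsilon_low,epsilon_high scanned quantile window (defaults 0.10
#'   and 0.90).
#' @param min_group_size smallest admissible group (default 10); candidates
#'   inducing a smaller group are not scanned.
#' @return An object of class `cutpoint_result`: `grid` (data.frame
#'   `cutoff`, `n_high`, `n_low`, `chi2`), `best_cutoff`, `max_chi2`,
#'   `p_uncorrected`, `p_corrected`, `epsilon_low`, `epsilon_high` and the
#'   realized scan bounds.
#' @export
scan_cutpoints <- function(values, times, events,
                           epsilon_low = 0.10, epsilon_high = 0.90,
                           min_group_size = 10) {
  stopifnot(length(values) == length(times), length(times) == length(events),
            epsilon_low >= 0, epsilon_high <= 1, epsilon_low < epsilon_high,
            min_group_size >= 1)
  if (any(!is.finite(values))) stop("non-finite marker values", call. = FALSE)
  if (sum(events) < 1)
    stop(errorCondition("no events in the cohort",
                        class = c("tilzone_no_events", "error", "condition")))
  uv <- sort(unique(values))
  if (length(uv) < 2)
    stop(errorCondition("all marker values identical: no cutoff exists",
                        class = c("tilzone_degenerate_marker", "error",
                                  "condition")))
  qlo <- as.numeric(quantile(values, epsilon_low, type = 1))
  qhi <- as.numeric(quantile(values, epsilon_high, type = 1))
  cand <- uv[uv >= qlo & uv <= qhi]
  n <- length(values)
  n_high <- vapply(cand, function(c) sum(values > c), numeric(1))
  keep <- n_high >= min_group_size & (n - n_high) >= min_group_size
  cand <- cand[keep]; n_high <- n_high[keep]
  if (length(cand) < 1)
    stop("no admissible cutoff: every split leaves a group smaller than ",
         min_group_size, call. = FALSE)
  chi2 <- logrank_scan(values, times, events, cand)
  best <- which.max(chi2)               # first max = smallest cutoff on ties
  max_chi2 <- chi2[best]
  p_unc <- pchisq(max_chi2, 1, lower.tail = FALSE)
  eps1 <- mean(values <= cand[1])
  eps2 <- mean(values <= cand[length(cand)])
  if (length(cand) == 1L) {
    p_cor <- p_unc
  } else {
    b <- sqrt(max(max_chi2, 1e-12))
    p_ms <- dnorm(b) * (b - 1 / b) *
      log((eps2 * (1 - eps1)) / (eps1 * (1 - eps2))) + 4 * dnorm(b) / b
    p_cor <- min(1, max(p_ms, p_unc))
  }
  structure(list(
    grid = data.frame(cutoff = cand, n_high = as.integer(n_high),
                      n_low = as.integer(n - n_high), chi2 = chi2),
    best_cutoff = cand[best], max_chi2 = max_chi2,
    p_uncorrected = p_unc, p_corrected = p_cor,
    epsilon_low = epsilon_low, epsilon_high = epsilon_high,
    scan_low = eps1, scan_high = eps2,
    min_group_size = min_group_size, n = n, n_events = sum(events)),
    class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result> %d candidates in [%.3g, %.3g] quantile window\n",
              nrow(x$grid), x$epsilon_low, x$epsilon_high))
  cat(sprintf("  best cutoff %.7g (high n=%d, low n=%d), chi2 = %.4g\n",
              x$best_cutoff, x$grid$n_high[match(x$best_cutoff, x$grid$cutoff)],
              x$grid$n_low[match(x$best_cutoff, x$grid$cutoff)], x$max_chi2))
  cat(sprintf("  p uncorrected %.4g, min-p corrected %.4g\n",
              x$p_uncorrected, x$p_corrected))
  invisible(x)
}

#' @export
plot.cutpoint_result <- function(x, ...) {
  graphics::plot(x$grid$cutoff, x$grid$chi2, type = "l",
                 xlab = "cutoff", ylab = "log-rank chi-square", ...)
  graphics::abline(v = x$best_cutoff, lty = 2)
  invisible(x)
}
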