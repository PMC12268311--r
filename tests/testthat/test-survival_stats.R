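test_that("KM equals the empirical survival function without censoring", {
  set.seed(1)
  t <- sample(1:50, 20, replace = TRUE)
  km <- km_estimate(t, rep(1, 20))
  for (tt in c(0, 10, 25, 49))
    expect_equal(survival_at(km, tt)$surv, mean(t > tt))
})

test_that("all-censored input gives survival identically 1", {
  km <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_equal(survival_at(km, 100)$surv, 1)
})

test_that("6-subject product-limit and Greenwood values match hand computation", {
  # times 1(e) 2(c) 3(e) 4(e) 5(c) 6(e)
  km <- km_estimate(1:6, c(1, 0, 1, 1, 0, 1))
  s <- survival_at(km, c(1, 3, 4, 6))$surv
  expect_equal(s, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)
  # Greenwood: S(t)^2 * sum d/(n(n-d)) over event times <= t
  gv <- km$greenwood_var[km$time %in% c(1, 3, 4)]
  expect_equal(gv[1], (5 / 6)^2 * (1 / 30), tolerance = 1e-12)
  expect_equal(gv[2], 0.625^2 * (1 / 30 + 1 / 12), tolerance = 1e-12)
  expect_equal(gv[3], (0.625 * 2 / 3)^2 * (1 / 30 + 1 / 12 + 1 / 6),
               tolerance = 1e-12)
  expect_error(km_estimate(numeric(), numeric()), "empty")
})

test_that("survival is non-increasing from 1 with non-negative variance", {
  set.seed(2)
  t <- rexp(100, 0.1); c0 <- runif(100, 0, 20)
  km <- km_estimate(pmin(t, c0), as.integer(t <= c0))
  expect_true(all(diff(c(1, km$surv)) <= 1e-12))
  expect_true(all(km$greenwood_var >= 0))
  expect_true(all(km$lower[!is.na(km$lower)] <=
                    km$surv[!is.na(km$lower)] + 1e-12))
})

test_that("Cox coefficient equals brute-force partial likelihood maximization", {
  # n = 6, single binary covariate, distinct times, Efron = Breslow (no ties)
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 0, 1, 1, 0)
  z <- c(1, 0, 1, 0, 1, 0)
  nll <- function(b) {
    ll <- 0
    for (i in which(events == 1)) {
      rs <- which(times >= times[i])
      ll <- ll + b * z[i] - log(sum(exp(b * z[rs])))
    }
    -ll
  }
  bhat <- optimize(nll, c(-5, 5))$minimum
  d <- data.frame(os_months = times, os_event = events, z = z)
  fit <- fit_ph(d, "os", "z")
  expect_equal(fit$table$coef, bhat, tolerance = 1e-4)
  expect_equal(fit$table$hr, exp(bhat), tolerance = 1e-3)
  expect_true(fit$table$lower < fit$table$hr & fit$table$hr < fit$table$upper)
})

test_that("two-group exponential simulation recovers the true hazard ratio", {
  set.seed(3)
  inside <- replicate(30, {
    n <- 2000
    z <- rep(0:1, each = n / 2)
    t <- rexp(n, 0.05 * exp(log(0.5) * z))
    cens <- quantile(t, 0.8)   # administrative ~20% censoring
    d <- data.frame(os_months = pmin(t, cens),
                    os_event = as.integer(t <= cens), z = z)
    hr <- fit_ph(d, "os", "z")$table$hr
    hr >= 0.42 && hr <= 0.59
  })
  expect_gte(mean(inside), 0.95)
})

test_that("log-HR error shrinks as the cohort grows", {
  set.seed(4)
  err <- sapply(c(200, 2000), function(n) {
    mean(replicate(25, {
      z <- rep(0:1, each = n / 2)
      t <- rexp(n, 0.05 * exp(log(0.5) * z))
      cens <- runif(n, 0, quantile(t, 0.95) * 2)
      d <- data.frame(os_months = pmin(t, cens),
                      os_event = as.integer(t <= cens), z = z)
      abs(fit_ph(d, "os", "z")$table$coef - log(0.5))
    }))
  })
  expect_lt(err[2], err[1])
})

test_that("null-covariate confidence intervals cover 1 at the nominal rate", {
  set.seed(5)
  covered <- replicate(200, {
    n <- 100
    z <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.05)
    cens <- runif(n, 0, 40)
    d <- data.frame(os_months = pmin(t, cens),
                    os_event = as.integer(t <= cens), z = z)
    tab <- suppressWarnings(fit_ph(d, "os", "z"))$table
    tab$lower <= 1 && 1 <= tab$upper
  })
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("identical covariates give every patient the group prevalence as score", {
  d <- data.frame(grade = factor(rep("G2", 100)), age = rep(60, 100))
  g <- rep(c("HIGH", "LOW"), c(27, 73))
  expect_warning(sc <- estimate_propensity(d, c("grade", "age"), g),
                 "constant covariate")
  expect_equal(as.numeric(sc), rep(0.27, 100))
})

test_that("a planted logistic model is recovered by the propensity fit", {
  set.seed(6)
  n <- 4000
  age <- rnorm(n, 60, 8)
  lvi <- factor(sample(c("negative", "positive"), n, TRUE),
                c("negative", "positive"))
  eta <- -0.5 + 0.05 * (age - 60) + 0.8 * (lvi == "positive")
  g <- ifelse(runif(n) < plogis(eta), "HIGH", "LOW")
  d <- data.frame(age = age, lvi = lvi)
  sc <- estimate_propensity(d, c("age", "lvi"), g)
  co <- coef(attr(sc, "model"))
  expect_equal(unname(co["age"]), 0.05, tolerance = 0.3)
  expect_equal(unname(co["lvipositive"]), 0.8, tolerance = 0.25)
  expect_equal(mean(sc), mean(g == "HIGH"), tolerance = 1e-6)
})

test_that("matching is 1:1 without replacement and respects the caliper", {
  set.seed(7)
  n <- 300
  g <- rep(c("HIGH", "LOW"), c(100, 200))
  sc <- plogis(rnorm(n, ifelse(g == "HIGH", 0.3, -0.3), 1))
  conf <- rnorm(n, ifelse(g == "HIGH", 1, 0))   # planted confounder
  mt <- match_nearest(sc, g, covariates = data.frame(conf = conf), seed = 2)
  expect_true(all(table(mt$pairs$control) == 1))
  expect_true(all(table(mt$pairs$treated) == 1))
  expect_true(all(mt$pairs$delta <= mt$caliper + 1e-12))
  smd <- mt$smd
  expect_lte(abs(smd$smd_post), abs(smd$smd_pre))
})

test_that("fully overlapping scores match every treated patient", {
  set.seed(8)
  g <- rep(c("HIGH", "LOW"), c(163, 433))
  sc <- plogis(rnorm(596))   # same distribution in both groups
  mt <- match_nearest(sc, g, caliper_sd_logit = 10, seed = 1)  # non-binding
  expect_equal(mt$n_matched, 163L)
})

test_that("disjoint score distributions beyond the caliper match nothing", {
  g <- rep(c("HIGH", "LOW"), each = 20)
  sc <- c(rep(0.9, 20), rep(0.1, 20))
  sc <- sc + rep(c(0.005, -0.005), each = 20) * runif(40)
  expect_error(match_nearest(sc, g, seed = 1),
               class = "tilzone_match_failure")
})

test_that("subgroup table brackets planted stratum-specific hazard ratios", {
  set.seed(9)
  n <- 3000
  strat <- rep(c("A", "B"), each = n / 2)
  grp <- factor(sample(c("LOW", "HIGH"), n, TRUE), c("LOW", "HIGH"))
  hr_true <- ifelse(strat == "A", 0.6, 1.0)
  t <- rexp(n, 0.03 * ifelse(grp == "HIGH", hr_true, 1))
  cens <- runif(n, 10, 100)
  d <- data.frame(stratum = strat, group = grp,
                  os_months = pmin(t, cens),
                  os_event = as.integer(t <= cens))
  tab <- subgroup_hr(d, "stratum", "os")
  a <- tab[tab$stratum == "A", ]; b <- tab[tab$stratum == "B", ]
  expect_true(a$lower < 0.6 && 0.6 < a$upper)
  expect_true(b$lower < 1.0 && 1.0 < b$upper)
  # single-level stratifier equals the overall fit
  d$one <- "all"
  tab1 <- subgroup_hr(d, "one", "os")
  overall <- fit_ph(d, "os", "group")$table
  expect_equal(tab1$hr, overall$hr[1], tolerance = 1e-9)
})

test_that("an event-free stratum is reported as not estimable without crashing", {
  d <- data.frame(stratum = rep(c("A", "B"), each = 30),
                  group = factor(rep(c("LOW", "HIGH"), 30), c("LOW", "HIGH")),
                  os_months = rep(10, 60),
                  os_event = rep(c(1, 0), each = 30))
  tab <- subgroup_hr(d, "stratum", "os")
  expect_false(tab$estimable[tab$stratum == "B"])
  expect_true(is.na(tab$hr[tab$stratum == "B"]))
})

test_that("log-rank p and the PH score test agree on large two-group cohorts", {
  set.seed(10)
  ps <- replicate(25, {
    n <- 2000
    z <- rbinom(n, 1, 0.4)
    hr <- exp(runif(1, -0.4, 0.4))
    t <- rexp(n, 0.04 * hr^z)
    cens <- runif(n, 0, 60)
    tm <- pmin(t, cens); ev <- as.integer(t <= cens)
    lrp <- logrank(tm, ev, factor(z))$p
    scp <- summary(survival::coxph(survival::Surv(tm, ev) ~ z))$sctest["pvalue"]
    c(lrp, scp)
  })
  expect_gt(cor(ps[1, ], ps[2, ]), 0.99)
})
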