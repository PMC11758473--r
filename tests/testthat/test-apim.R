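make_people <- function(n_dyads, seed = 1) {
  sim <- generate_dyads(synthetic_config(n_dyads = n_dyads, seed = seed))
  summ <- emotion_summaries(sim$data)
  list(summ = summ, baseline = sim$data$baseline, sim = sim)
}

test_that("the design matrix has the documented shape and centering", {
  pp <- make_people(30, seed = 12)
  d <- build_design(pp$summ, pp$baseline, valence = "negative", symptom = "anxious")
  expect_equal(nrow(d$data), 30)
  expect_setequal(
    setdiff(names(d$data), c("dyad_id", "group")),
    c(TERMS, "y_adolescent", "y_caregiver")
  )
  for (col in c("a_mean", "a_gini", "c_mean", "c_gini")) {
    expect_lt(abs(mean(d$data[[col]])), 1e-12)
  }
  expect_equal(d$data$a_mean_x_gini, d$data$a_mean * d$data$a_gini)
  expect_equal(d$data$c_mean_x_gini, d$data$c_mean * d$data$c_gini)

  raw <- build_design(pp$summ, pp$baseline, valence = "negative",
    symptom = "anxious", center = FALSE)
  expect_gt(abs(mean(raw$data$a_mean)), 0.1)
})

test_that("a noise-free outcome recovers its generating path exactly", {
  set.seed(42)
  sd0 <- simulate_design(80, b1 = c(1, 0, 0, 0, 0, 0), b2 = rep(0, 6),
    resid_sd = c(0, 0), rho = 0)
  # y_adolescent == a_mean, y_caregiver == 0
  f <- fit_apim(sd0$design)
  expect_equal(unname(coef(f)["a_mean", "y_adolescent"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(coef(f)[c("(Intercept)", TERMS[-1]), "y_adolescent"])), 1e-10)
  expect_lt(max(abs(coef(f)[, "y_caregiver"])), 1e-10)
  expect_lt(max(abs(f$sigma)), 1e-20)
})

test_that("complete-data estimates equal the least-squares oracle", {
  set.seed(7)
  sd1 <- simulate_design(150, calib_b1, calib_b2)
  f <- fit_apim(sd1$design)
  dat <- sd1$design$data
  for (g in c("y_adolescent", "y_caregiver")) {
    ols <- stats::lm(
      stats::reformulate(TERMS, response = g),
      data = dat
    )
    expect_equal(unname(coef(f)[, g]), unname(stats::coef(ols)),
      tolerance = 1e-10)
  }
  # ML residual covariance = (1/n) cross-moment of OLS residuals
  r1 <- stats::residuals(stats::lm(stats::reformulate(TERMS, "y_adolescent"), dat))
  r2 <- stats::residuals(stats::lm(stats::reformulate(TERMS, "y_caregiver"), dat))
  n <- nrow(dat)
  expect_equal(f$sigma[1, 1], sum(r1^2) / n, tolerance = 1e-10)
  expect_equal(f$sigma[1, 2], sum(r1 * r2) / n, tolerance = 1e-10)
  # closed-form Gaussian log-likelihood at the ML solution
  S <- matrix(c(sum(r1^2), sum(r1 * r2), sum(r1 * r2), sum(r2^2)), 2) / n
  ll <- -n * log(2 * pi) - n / 2 * log(det(S)) - n
  expect_equal(f$loglik, ll, tolerance = 1e-8)
})

test_that("the iterative FIML route matches the closed form on complete data", {
  set.seed(8)
  sd1 <- simulate_design(120, calib_b1, calib_b2)
  closed <- fit_apim(sd1$design)
  iter <- fit_apim(sd1$design, method = "iterative")
  expect_equal(coef(iter), coef(closed), tolerance = 1e-8)
  expect_equal(iter$sigma, closed$sigma, tolerance = 1e-8)
  expect_equal(iter$loglik, closed$loglik, tolerance = 1e-8)
})

test_that("per-case scores sum to zero at the FIML optimum", {
  set.seed(9)
  sdm <- simulate_design(400, calib_b1, calib_b2, miss = 0.2)
  f <- fit_apim(sdm$design)
  expect_true(f$converged)
  s <- colSums(emodyad:::apim_score_contribs(f$theta, f$X, f$Y))
  expect_lt(max(abs(s)), 1e-6)
})

test_that("dyads missing both outcomes drop out without changing the fit", {
  set.seed(10)
  sd1 <- simulate_design(100, calib_b1, calib_b2)
  dat <- sd1$design$data
  extra <- dat[1:5, ]
  extra$dyad_id <- paste0("x", 1:5)
  extra$y_adolescent <- NA_real_
  extra$y_caregiver <- NA_real_
  padded <- sd1$design
  padded$data <- dplyr::bind_rows(dat, extra)
  f0 <- fit_apim(sd1$design)
  f1 <- fit_apim(padded)
  expect_equal(coef(f1), coef(f0))
  expect_equal(f1$n, 100)
})

test_that("rank deficiency and tiny samples are informative errors", {
  set.seed(11)
  sd1 <- simulate_design(50, calib_b1, calib_b2)
  broken <- sd1$design
  broken$data$c_gini <- broken$data$c_mean
  expect_error(fit_apim(broken), "collinear")
  small <- sd1$design
  small$data <- small$data[1:10, ]
  expect_error(fit_apim(small), "at least 20")
})

test_that("robust and classical SEs agree under homoskedastic normality", {
  set.seed(13)
  sd1 <- simulate_design(2000, calib_b1, calib_b2)
  f <- robust_se(fit_apim(sd1$design))
  idx <- c(2:7, 9:14) # slope coefficients of both equations
  ratio <- sqrt(diag(f$vcov_robust)[idx]) / sqrt(diag(f$vcov_classical)[idx])
  expect_true(all(ratio > 0.95 & ratio < 1.05))
})

test_that("robust CIs keep coverage under heteroskedasticity where classical fail", {
  reps <- 400
  n <- 300
  hit_rob <- hit_cls <- 0L
  total <- 0L
  set.seed(14)
  for (r in seq_len(reps)) {
    sdh <- simulate_design(n, calib_b1, calib_b2, het = TRUE)
    f <- robust_se(fit_apim(sdh$design))
    truth <- c(0, calib_b1, 0, calib_b2) # intercepts are 0
    for (g in 1:2) {
      for (j in 2:7) {
        idx <- (g - 1) * 7 + j
        b <- f$theta[idx]
        tr <- truth[idx]
        se_r <- sqrt(f$vcov_robust[idx, idx])
        se_c <- sqrt(f$vcov_classical[idx, idx])
        hit_rob <- hit_rob + (abs(b - tr) <= 1.96 * se_r)
        hit_cls <- hit_cls + (abs(b - tr) <= 1.96 * se_c)
        total <- total + 1L
      }
    }
  }
  cov_rob <- hit_rob / total
  cov_cls <- hit_cls / total
  expect_gte(cov_rob, 0.93)
  expect_lte(cov_rob, 0.97)
  expect_lt(cov_cls, cov_rob - 0.01)
})

test_that("standardized paths equal a refit on z-scored variables", {
  set.seed(15)
  sd1 <- simulate_design(200, calib_b1, calib_b2)
  f <- standardize(fit_apim(sd1$design))
  dat <- sd1$design$data
  zdat <- dat
  for (col in c(TERMS, "y_adolescent", "y_caregiver")) {
    zdat[[col]] <- as.numeric(scale(dat[[col]]))
  }
  zfit <- stats::lm(stats::reformulate(TERMS, "y_adolescent"), zdat)
  got <- f$paths$beta[f$paths$outcome == "adolescent"]
  expect_equal(got, unname(stats::coef(zfit)[-1]), tolerance = 1e-10)
})

test_that("standardized coefficients are invariant to predictor rescaling", {
  set.seed(16)
  sd1 <- simulate_design(150, calib_b1, calib_b2)
  f1 <- standardize(fit_apim(sd1$design))
  scaled <- sd1$design
  scaled$data$a_mean <- scaled$data$a_mean * 10
  scaled$data$a_mean_x_gini <- scaled$data$a_mean * scaled$data$a_gini
  f2 <- standardize(fit_apim(scaled))
  expect_equal(f2$paths$beta, f1$paths$beta, tolerance = 1e-12)
  expect_equal(f2$paths$p, f1$paths$p, tolerance = 1e-10)
})

test_that("path table carries normal-theory p and symmetric CI", {
  set.seed(17)
  sd1 <- simulate_design(120, calib_b1, calib_b2)
  f <- standardize(fit_apim(sd1$design))
  tb <- f$paths
  expect_equal(tb$p, 2 * stats::pnorm(-abs(tb$z)))
  expect_equal(tb$ci_upper - tb$beta, tb$beta - tb$ci_lower, tolerance = 1e-12)
  expect_equal(tb$ci_upper - tb$beta, stats::qnorm(0.975) * tb$se,
    tolerance = 1e-12)
})

test_that("duplicated groups give identical multigroup fits", {
  set.seed(18)
  sd1 <- simulate_design(80, calib_b1, calib_b2)
  dat <- sd1$design$data
  dat2 <- dat
  dat2$dyad_id <- paste0("copy_", dat2$dyad_id)
  dd <- sd1$design
  dd$data <- dplyr::bind_rows(dat, dat2)
  groups <- rep(c("g1", "g2"), each = nrow(dat))
  gf <- fit_multigroup(dd, groups = groups, min_group_n = 10)
  expect_equal(coef(gf$fits$g1), coef(gf$fits$g2))
  expect_equal(gf$fits$g1$paths$beta, gf$fits$g2$paths$beta)
})

test_that("undersized groups are excluded and reported, not fitted", {
  set.seed(19)
  sd1 <- simulate_design(60, calib_b1, calib_b2)
  groups <- c(rep("big", 56), rep("tiny", 4))
  gf <- fit_multigroup(sd1$design, groups = groups, min_group_n = 10)
  expect_named(gf$fits, "big")
  expect_equal(gf$excluded$group, "tiny")
  expect_equal(gf$excluded$n, 4L)
  expect_error(
    fit_multigroup(sd1$design, groups = rep(letters[1:10], 6), min_group_n = 10),
    "below min_group_n"
  )
})

test_that("group-specific generator effects are recovered by multigroup fits", {
  eff_of <- function(a_mean_eff) {
    eff <- default_effects()
    eff$anxious$b["adolescent", ] <- c(a_mean_eff, 0, 0, 0, 0, 0)
    eff
  }
  est <- sapply(1:5, function(r) {
    cfg <- synthetic_config(
      n_dyads = 2000, seed = 230 + r, baseline_missing = 0,
      gender_probs = c(boy = 0.5, girl = 0.5, other = 0, unreported = 0),
      effects = eff_of(0.2),
      effects_by_group = list(boy = eff_of(0.2), girl = eff_of(0.6))
    )
    sim <- generate_dyads(cfg)
    summ <- emotion_summaries(sim$data)
    design <- build_design(summ, sim$data$baseline,
      valence = "negative", symptom = "anxious")
    gf <- fit_multigroup(design, min_group_n = 10)
    c(
      boy = unname(coef(gf$fits$boy)["a_mean", "y_adolescent"]),
      girl = unname(coef(gf$fits$girl)["a_mean", "y_adolescent"])
    )
  })
  expect_equal(mean(est["boy", ]), 0.2, tolerance = 0.06 / 0.2)
  expect_equal(mean(est["girl", ]), 0.6, tolerance = 0.06 / 0.6)
})
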