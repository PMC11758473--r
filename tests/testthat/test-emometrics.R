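test_that("daily composites average the available items of one valence", {
  r <- diary_row("d1", "adolescent", 1, ratings = list(
    anxious = 0, sad = 1, angry = 2, frustrated = 3, disgusted = 0,
    lonely = 1, ashamed = 0
  ))
  expect_equal(daily_composite(r, "negative"), 1.0)

  r4 <- diary_row("d1", "adolescent", 1,
    ratings = setNames(as.list(rep(4, 9)), POS_ITEMS))
  expect_equal(daily_composite(r4, "positive"), 4.0)

  # one missing among 7 -> mean of the 6 available
  partial <- diary_row("d1", "adolescent", 1,
    ratings = setNames(as.list(rep(2, 6)), NEG_ITEMS[1:6]))
  partial$ashamed <- NA_integer_
  expect_equal(daily_composite(partial, "negative"), 2.0)

  all_na <- diary_row("d1", "adolescent", 1, fill = NA)
  expect_true(is.na(daily_composite(all_na, "negative")))
})

test_that("person mean averages daily composites unweighted", {
  d1 <- diary_row("d1", "adolescent", 1,
    ratings = setNames(as.list(rep(1, 7)), NEG_ITEMS))
  d2 <- diary_row("d1", "adolescent", 2,
    ratings = setNames(as.list(rep(3, 7)), NEG_ITEMS))
  expect_equal(person_mean(dplyr::bind_rows(d1, d2), "negative"), 2.0)

  const <- person_diary("d1", "caregiver", 14, fill = 2)
  expect_equal(person_mean(const, "positive"), 2.0)

  expect_warning(
    out <- person_mean(person_diary("d1", "adolescent", 3, fill = NA), "negative"),
    "no usable days"
  )
  expect_true(is.na(out))
})

test_that("emotion totals sum raw ratings across days", {
  d1 <- diary_row("d1", "adolescent", 1, ratings = list(sad = 3))
  d2 <- diary_row("d1", "adolescent", 2, ratings = list(sad = 1))
  tot <- emotion_totals(dplyr::bind_rows(d1, d2), "negative")
  expect_equal(tot[["sad"]], 4)
  expect_equal(sum(tot), 4)

  zero <- emotion_totals(person_diary("d1", "adolescent", 3, fill = 0), "positive")
  expect_equal(unname(zero), rep(0, 9))
})

test_that("emotion totals match a brute-force sum over the emitted table", {
  sim <- generate_dyads(synthetic_config(n_dyads = 10, seed = 5))
  diary <- sim$data$diary
  one <- diary[diary$dyad_id == "d0003" & diary$role == "caregiver", ]
  tot <- emotion_totals(one, "negative")
  for (item in NEG_ITEMS) {
    manual <- 0
    for (i in seq_len(nrow(one))) {
      v <- one[[item]][i]
      if (!is.na(v)) manual <- manual + v
    }
    expect_identical(unname(tot[item]), as.numeric(manual))
  }
})

test_that("Gini emodiversity reproduces closed-form anchor cases", {
  expect_equal(gini_emodiversity(rep(5, 9)), 1.0)
  expect_equal(gini_emodiversity(c(1, 3)), 0.75)
  expect_equal(gini_emodiversity(c(0, 0, 0, 0, 0, 0, 3)), 1 / 7)
  expect_warning(out <- gini_emodiversity(rep(0, 7)), "undefined")
  expect_true(is.na(out))
  expect_error(gini_emodiversity(c(-1, 2)), "non-negative")
})

test_that("Gini agrees with the mean-absolute-difference oracle and is invariant", {
  set.seed(101)
  for (i in 1:200) {
    m <- sample(2:12, 1)
    x <- stats::rgamma(m, shape = 1.2, rate = 0.5)
    g <- gini_emodiversity(x)
    expect_equal(g, gini_mad_oracle(x), tolerance = 1e-12)
    expect_equal(gini_emodiversity(sample(x)), g, tolerance = 1e-12)
    expect_equal(gini_emodiversity(x * stats::runif(1, 0.1, 50)), g,
      tolerance = 1e-12)
    expect_gte(g + 1e-12, 1 / m)
    expect_lte(g, 1 + 1e-12)
  }
})

test_that("equal totals uniquely maximize the Gini score", {
  set.seed(202)
  for (i in 1:50) {
    m <- sample(3:9, 1)
    x <- as.numeric(sample(1:6, m, replace = TRUE))
    if (stats::sd(x) == 0) x[1] <- x[1] + 1
    expect_lt(gini_emodiversity(x), 1)
  }
})

test_that("moving mass into an empty category increases diversity", {
  # exhaustive for m <= 4, integer totals <= 6, against the oracle
  for (m in 3:4) {
    grids <- expand.grid(rep(list(0:6), m - 1))
    for (r in seq_len(nrow(grids))) {
      x <- c(as.numeric(grids[r, ]), 0)
      if (sum(x) == 0) next
      y <- x
      y[m] <- max(x) # duplicate the maximal category's mass into the zero slot
      g_x <- suppressWarnings(gini_emodiversity(x))
      g_y <- suppressWarnings(gini_emodiversity(y))
      expect_gt(g_y, g_x)
      expect_equal(g_y, gini_mad_oracle(y), tolerance = 1e-12)
    }
  }
})

# simulate the three-component generalizability model directly
simulate_gt_diary <- function(n, k, d, s_p, s_pi, s_e, mu = 2) {
  stopifnot(k == 7) # negative item set
  person <- rep(seq_len(n), each = d)
  a_p <- stats::rnorm(n, 0, s_p)
  b_pi <- matrix(stats::rnorm(n * k, 0, s_pi), n, k)
  diary <- tibble::tibble(
    dyad_id = sprintf("d%04d", person),
    role = "adolescent",
    day = rep(seq_len(d), times = n)
  )
  for (j in seq_len(k)) {
    diary[[NEG_ITEMS[j]]] <- mu + a_p[person] + b_pi[cbind(person, j)] +
      stats::rnorm(n * d, 0, s_e)
  }
  diary
}

test_that("reliability is 1 in the noise-free limit", {
  set.seed(7)
  diary <- simulate_gt_diary(30, 7, 8, s_p = 1, s_pi = 0.5, s_e = 0)
  vc <- between_person_reliability(diary, "negative")
  expect_equal(vc$sigma2_residual, 0)
  expect_equal(vc$reliability, 1)
})

test_that("reliability recovers the closed-form value under the generating model", {
  # sigma2_p = 1, sigma2_pi = 0.25, sigma2_e = 1, k = 7, d = 14
  r_true <- (1 + 0.25 / 7) / (1 + 0.25 / 7 + 1 / (7 * 14))
  set.seed(21)
  diary <- simulate_gt_diary(500, 7, 14, s_p = 1, s_pi = 0.5, s_e = 1)
  vc <- between_person_reliability(diary, "negative")
  expect_equal(vc$reliability, r_true, tolerance = 0.03)
  expect_equal(vc$sigma2_person, 1, tolerance = 0.2)
  expect_equal(vc$sigma2_person_item, 0.25, tolerance = 0.1)
  expect_equal(vc$sigma2_residual, 1, tolerance = 0.05)
})

test_that("method-of-moments components agree with a mixed-model cross-check", {
  skip_if_not_installed("lme4")
  set.seed(33)
  diary <- simulate_gt_diary(80, 7, 10, s_p = 0.8, s_pi = 0.5, s_e = 1)
  vc <- between_person_reliability(diary, "negative")
  long <- tidyr::pivot_longer(diary, dplyr::all_of(NEG_ITEMS),
    names_to = "item", values_to = "y")
  fit <- suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | dyad_id) + (1 | dyad_id:item), data = long)
  )
  vcs <- as.data.frame(lme4::VarCorr(fit))
  s_p_lmm <- vcs$vcov[vcs$grp == "dyad_id"]
  s_pi_lmm <- vcs$vcov[vcs$grp == "dyad_id:item"]
  s_e_lmm <- vcs$vcov[vcs$grp == "Residual"]
  expect_equal(vc$sigma2_person, s_p_lmm, tolerance = 0.1)
  expect_equal(vc$sigma2_person_item, s_pi_lmm, tolerance = 0.05)
  expect_equal(vc$sigma2_residual, s_e_lmm, tolerance = 0.05)
})

test_that("unbalanced day counts are handled through person-specific weights", {
  set.seed(9)
  diary <- simulate_gt_diary(40, 7, 12, s_p = 1, s_pi = 0.5, s_e = 1)
  # unbalance: drop most days for a third of the sample
  keep <- !(diary$dyad_id %in% sprintf("d%04d", 1:13)) | diary$day <= 2
  vc <- between_person_reliability(diary[keep, ], "negative")
  expect_true(vc$d_bar < 12 && vc$d_bar > 2)
  expect_true(vc$reliability > 0 && vc$reliability <= 1)
})

test_that("Cronbach's alpha matches hand computation and brute force", {
  # perfectly correlated items with equal variances
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(2, 3, 4))), 1.0)
  expect_equal(cronbach_alpha(rbind(c(1, 2), c(2, 3), c(3, 5))), 18 / 19)

  set.seed(14)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    n <- sample(10:40, 1)
    m <- matrix(stats::rnorm(n * k), n, k) + stats::rnorm(n)
    brute <- {
      kk <- ncol(m)
      kk / (kk - 1) * (1 - sum(apply(m, 2, stats::var)) / stats::var(rowSums(m)))
    }
    expect_equal(cronbach_alpha(m), brute, tolerance = 1e-12)
  }

  expect_warning(out <- cronbach_alpha(matrix(1, 5, 3)), "zero total")
  expect_true(is.na(out))
})

test_that("person summaries respect scale bounds and day counts", {
  sim <- generate_dyads(synthetic_config(n_dyads = 30, seed = 8))
  summ <- emotion_summaries(sim$data)
  expect_true(all(summ$mean_pos >= 0 & summ$mean_pos <= 4, na.rm = TRUE))
  expect_true(all(summ$mean_neg >= 0 & summ$mean_neg <= 4, na.rm = TRUE))
  expect_true(all(summ$gini_pos >= 1 / 9 - 1e-12 & summ$gini_pos <= 1 + 1e-12,
    na.rm = TRUE))
  expect_true(all(summ$gini_neg >= 1 / 7 - 1e-12 & summ$gini_neg <= 1 + 1e-12,
    na.rm = TRUE))
  expect_equal(nrow(summ), 60)
})
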