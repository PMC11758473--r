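# Shared fixtures and independent oracles used across the suite.

ALL_ITEMS <- emotion_items()
NEG_ITEMS <- emotion_items("negative")
POS_ITEMS <- emotion_items("positive")
TERMS <- c("a_mean", "a_gini", "a_mean_x_gini", "c_mean", "c_gini", "c_mean_x_gini")

# one diary row; unspecified items default to `fill`
diary_row <- function(dyad_id, role, day, ratings = list(), fill = 0L) {
  row <- tibble::tibble(dyad_id = dyad_id, role = role, day = as.integer(day))
  for (item in ALL_ITEMS) {
    row[[item]] <- if (item %in% names(ratings)) {
      as.integer(ratings[[item]])
    } else if (is.na(fill)) NA_integer_ else as.integer(fill)
  }
  row
}

# a complete n_days diary for one person
person_diary <- function(dyad_id, role, n_days, fill = 0L) {
  dplyr::bind_rows(lapply(seq_len(n_days), function(d) {
    diary_row(dyad_id, role, d, fill = fill)
  }))
}

baseline_row <- function(dyad_id, role, anxious = 1, depressive = 1,
                         gender = "unreported") {
  tibble::tibble(
    dyad_id = dyad_id, role = role,
    anxious_mean = anxious, depressive_mean = depressive,
    gender_group = gender
  )
}

# independent Gini oracle: 1 - mean absolute difference form of the
# classical inequality coefficient
gini_mad_oracle <- function(x) {
  n <- length(x)
  1 - sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# draw n rows from MVN(0, R) via Cholesky
rmvn <- function(n, R) {
  matrix(stats::rnorm(n * ncol(R)), n) %*% chol(R)
}

# Build an apim_design directly with known coefficients: four base
# predictors from a correlated normal, products of the (already centered)
# factors, bivariate-normal residuals with correlation rho, optional MCAR
# missingness on each outcome. Returns the design plus the truth.
simulate_design <- function(n, b1, b2, resid_sd = c(0.85, 0.85), rho = 0.3,
                            miss = 0, base_cor = 0.3,
                            het = FALSE) {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- base_cor # a_mean ~ a_gini
  R[3, 4] <- R[4, 3] <- base_cor # c_mean ~ c_gini
  R[1, 3] <- R[3, 1] <- 0.2      # partners' means
  base <- rmvn(n, R)
  x <- tibble::tibble(
    a_mean = base[, 1], a_gini = base[, 2],
    c_mean = base[, 3], c_gini = base[, 4]
  )
  x$a_mean_x_gini <- x$a_mean * x$a_gini
  x$c_mean_x_gini <- x$c_mean * x$c_gini
  x <- x[TERMS]
  xm <- as.matrix(x)
  z <- matrix(stats::rnorm(2 * n), n, 2)
  e1 <- z[, 1]
  e2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  if (het) { # error SD proportional to |a_mean|
    s <- 0.2 + abs(x$a_mean)
    e1 <- e1 * s
    e2 <- e2 * s
  }
  dat <- x
  dat$dyad_id <- sprintf("d%05d", seq_len(n))
  dat$y_adolescent <- as.numeric(xm %*% b1 + resid_sd[1] * e1)
  dat$y_caregiver <- as.numeric(xm %*% b2 + resid_sd[2] * e2)
  if (miss > 0) {
    dat$y_adolescent[stats::runif(n) < miss] <- NA
    dat$y_caregiver[stats::runif(n) < miss] <- NA
  }
  dat$group <- "unreported"
  design <- structure(
    list(
      data = dat[c("dyad_id", TERMS, "y_adolescent", "y_caregiver", "group")],
      terms = TERMS,
      outcomes = c("y_adolescent", "y_caregiver"),
      valence = "negative", symptom = "anxious",
      centered = TRUE,
      centers = c(a_mean = 0, a_gini = 0, c_mean = 0, c_gini = 0)
    ),
    class = "apim_design"
  )
  list(design = design, b1 = b1, b2 = b2, resid_sd = resid_sd, rho = rho)
}

# paper-like standardized-scale coefficient sets (actor mean-emotion effects
# dominant, null emodiversity partner paths)
calib_b1 <- c(a_mean = 0.5, a_gini = 0.1, a_mean_x_gini = 0,
              c_mean = 0.2, c_gini = 0, c_mean_x_gini = 0)
calib_b2 <- c(a_mean = 0.05, a_gini = 0, a_mean_x_gini = 0,
              c_mean = 0.55, c_gini = 0.1, c_mean_x_gini = 0)
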