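#' Specify a bivariate actor-partner interdependence model
#'
#' An APIM here regresses the two dyad members' symptom outcomes (adolescent
#' and caregiver anxious or depressive symptom means) on the identical
#' six-term predictor set: each member's mean emotion of one valence, their
#' Gini emodiversity of that valence, and the mean-by-emodiversity product.
#' Every path is estimated, so the model is just identified.
#'
#' @param valence `"negative"` or `"positive"` emotion features.
#' @param symptom `"anxious"` or `"depressive"` outcomes.
#' @param group_by Optional grouping variable name (e.g. `"gender_group"`)
#'   for multigroup estimation.
#' @return An `apim_spec` list.
#' @export
apim_spec <- function(valence = c("negative", "positive"),
                      symptom = c("anxious", "depressive"),
                      group_by = NULL) {
  structure(
    list(
      valence = match.arg(valence),
      symptom = match.arg(symptom),
      group_by = group_by
    ),
    class = "apim_spec"
  )
}

#' Build the APIM design matrix
#'
#' One row per dyad. Mean-emotion and emodiversity columns are grand-mean
#' centered (by default) and the interaction columns are products of the
#' centered factors, so main effects are interpretable at average levels.
#' Outcomes stay on their original scale with missingness preserved; dyads
#' missing a member's emotion features are dropped with a message (the
#' exclusion stage normally guarantees completeness).
#'
#' @param summaries Per-person feature table from [emotion_summaries()].
#' @param baselines Baseline symptom table (`dyad_id`, `role`,
#'   `anxious_mean`, `depressive_mean`, `gender_group`).
#' @param spec An [apim_spec()], or `NULL` to use `valence`/`symptom` directly.
#' @param valence,symptom Used when `spec` is `NULL`.
#' @param center Grand-mean center predictors before forming products
#'   (default `TRUE`).
#' @return An `apim_design` object: the per-dyad data plus term/outcome
#'   metadata and the centering constants.
#' @export
build_design <- function(summaries, baselines, spec = NULL,
                         valence = c("negative", "positive"),
                         symptom = c("anxious", "depressive"),
                         center = TRUE) {
  if (!is.null(spec)) {
    valence <- spec$valence
    symptom <- spec$symptom
  } else {
    valence <- match.arg(valence)
    symptom <- match.arg(symptom)
  }
  summaries <- tibble::as_tibble(summaries)
  baselines <- tibble::as_tibble(baselines)

  dyad_ids <- sort(unique(summaries$dyad_id))
  feat <- dyad_features(summaries, valence, dyad_ids)
  usable <- stats::complete.cases(feat[c("a_mean", "a_gini", "c_mean", "c_gini")])
  if (any(!usable)) {
    message("dropping ", sum(!usable),
      " dyad(s) without both members' emotion features")
    feat <- feat[usable, , drop = FALSE]
    dyad_ids <- feat$dyad_id
  }
  if (nrow(feat) == 0) stop("no analyzable dyads", call. = FALSE)

  centers <- if (center) {
    colMeans(feat[c("a_mean", "a_gini", "c_mean", "c_gini")])
  } else {
    c(a_mean = 0, a_gini = 0, c_mean = 0, c_gini = 0)
  }
  x <- design_terms(feat, centers)

  sym_col <- paste0(symptom, "_mean")
  grab <- function(role, col) {
    sub <- baselines[baselines$role == role, ]
    sub[[col]][match(dyad_ids, sub$dyad_id)]
  }
  dat <- tibble::tibble(dyad_id = dyad_ids)
  dat <- dplyr::bind_cols(dat, x)
  dat$y_adolescent <- grab("adolescent", sym_col)
  dat$y_caregiver <- grab("caregiver", sym_col)
  dat$group <- grab("adolescent", "gender_group")

  sds <- vapply(dat[APIM_TERMS], stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
      paste(APIM_TERMS[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      data = dat,
      terms = APIM_TERMS,
      outcomes = c("y_adolescent", "y_caregiver"),
      valence = valence,
      symptom = symptom,
      centered = center,
      centers = centers
    ),
    class = "apim_design"
  )
}

#' @export
print.apim_design <- function(x, ...) {
  cat("<apim_design> ", x$valence, " emotion -> ", x$symptom, " symptoms\n",
    sep = "")
  cat("  dyads:", nrow(x$data), " predictors:",
    paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

# ---- likelihood machinery ---------------------------------------------------
# theta = (b_adolescent (p), b_caregiver (p), v1, v2, c); Sigma = [[v1,c],[c,v2]]

theta_index <- function(p) {
  list(b1 = seq_len(p), b2 = p + seq_len(p), v1 = 2 * p + 1,
    v2 = 2 * p + 2, cc = 2 * p + 3)
}

apim_ll_contribs <- function(theta, X, Y) {
  p <- ncol(X)
  ix <- theta_index(p)
  v1 <- theta[ix$v1]; v2 <- theta[ix$v2]; cc <- theta[ix$cc]
  dt <- v1 * v2 - cc^2
  n <- nrow(X)
  if (v1 <= 0 || v2 <= 0 || dt <= 0) return(rep(-Inf, n))
  B <- cbind(theta[ix$b1], theta[ix$b2])
  R <- Y - X %*% B
  ll <- numeric(n)
  both <- !is.na(Y[, 1]) & !is.na(Y[, 2])
  o1 <- !is.na(Y[, 1]) & is.na(Y[, 2])
  o2 <- is.na(Y[, 1]) & !is.na(Y[, 2])
  if (any(both)) {
    r1 <- R[both, 1]; r2 <- R[both, 2]
    q <- (v2 * r1^2 - 2 * cc * r1 * r2 + v1 * r2^2) / dt
    ll[both] <- -log(2 * pi) - 0.5 * log(dt) - 0.5 * q
  }
  if (any(o1)) {
    r1 <- R[o1, 1]
    ll[o1] <- -0.5 * log(2 * pi * v1) - r1^2 / (2 * v1)
  }
  if (any(o2)) {
    r2 <- R[o2, 2]
    ll[o2] <- -0.5 * log(2 * pi * v2) - r2^2 / (2 * v2)
  }
  ll
}

# n x (2p+3) matrix of per-case score vectors on the natural parameters
apim_score_contribs <- function(theta, X, Y) {
  p <- ncol(X)
  ix <- theta_index(p)
  v1 <- theta[ix$v1]; v2 <- theta[ix$v2]; cc <- theta[ix$cc]
  dt <- v1 * v2 - cc^2
  B <- cbind(theta[ix$b1], theta[ix$b2])
  R <- Y - X %*% B
  n <- nrow(X)
  S <- matrix(0, n, 2 * p + 3)
  both <- !is.na(Y[, 1]) & !is.na(Y[, 2])
  o1 <- !is.na(Y[, 1]) & is.na(Y[, 2])
  o2 <- is.na(Y[, 1]) & !is.na(Y[, 2])
  if (any(both)) {
    W11 <- v2 / dt; W22 <- v1 / dt; W12 <- -cc / dt
    r1 <- R[both, 1]; r2 <- R[both, 2]
    u1 <- W11 * r1 + W12 * r2
    u2 <- W12 * r1 + W22 * r2
    S[both, ix$b1] <- u1 * X[both, , drop = FALSE]
    S[both, ix$b2] <- u2 * X[both, , drop = FALSE]
    S[both, ix$v1] <- 0.5 * (u1^2 - W11)
    S[both, ix$v2] <- 0.5 * (u2^2 - W22)
    S[both, ix$cc] <- u1 * u2 - W12
  }
  if (any(o1)) {
    r1 <- R[o1, 1]
    S[o1, ix$b1] <- (r1 / v1) * X[o1, , drop = FALSE]
    S[o1, ix$v1] <- 0.5 * (r1^2 / v1^2 - 1 / v1)
  }
  if (any(o2)) {
    r2 <- R[o2, 2]
    S[o2, ix$b2] <- (r2 / v2) * X[o2, , drop = FALSE]
    S[o2, ix$v2] <- 0.5 * (r2^2 / v2^2 - 1 / v2)
  }
  S
}

# central-difference Jacobian of the total score: the likelihood Hessian
apim_hessian <- function(theta, X, Y) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    up <- dn <- theta
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    H[, j] <- (colSums(apim_score_contribs(up, X, Y)) -
      colSums(apim_score_contribs(dn, X, Y))) / (2 * h)
  }
  (H + t(H)) / 2
}

phi_to_theta <- function(phi, p) {
  ix <- theta_index(p)
  v1 <- exp(phi[ix$v1]); v2 <- exp(phi[ix$v2])
  tz <- tanh(phi[ix$cc])
  theta <- phi
  theta[ix$v1] <- v1
  theta[ix$v2] <- v2
  theta[ix$cc] <- tz * sqrt(v1 * v2)
  theta
}

#' Fit the bivariate APIM by full-information maximum likelihood
#'
#' Maximizes the observed-data log-likelihood of a bivariate normal for the
#' two outcomes given the predictors: dyads with both outcomes observed
#' contribute the bivariate density, dyads missing one outcome contribute the
#' univariate marginal of the observed one. With no missing outcomes the ML
#' solution is closed-form and identical to equation-by-equation least
#' squares with the ML residual cross-moment (the model is just identified);
#' with missingness a quasi-Newton search from least-squares starting values
#' is polished by Newton steps until the total score's infinity norm is
#' below `tol`.
#'
#' @param design An [build_design()] result.
#' @param tol Convergence tolerance on the total-score infinity norm.
#' @param method `"auto"` uses the closed form when no outcome is missing and
#'   the iterative FIML search otherwise; `"iterative"` forces the search
#'   (useful for validating that both routes agree on complete data).
#' @return An `apim_fit`: path coefficients, residual covariance,
#'   log-likelihood, exogenous correlations, and the per-case data needed for
#'   [robust_se()] and [standardize()].
#' @export
fit_apim <- function(design, tol = 1e-8, method = c("auto", "iterative")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "apim_design"))
  dat <- design$data
  X <- cbind("(Intercept)" = 1, as.matrix(dat[design$terms]))
  Y <- as.matrix(dat[design$outcomes])
  analyzable <- rowSums(!is.na(Y)) > 0
  X <- X[analyzable, , drop = FALSE]
  Y <- Y[analyzable, , drop = FALSE]
  n <- nrow(X)
  if (n < 20) stop("need at least 20 analyzable dyads", call. = FALSE)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
      paste(bad, collapse = ", "), call. = FALSE)
  }
  ix <- theta_index(p)
  complete <- !is.na(Y[, 1]) & !is.na(Y[, 2])

  if (all(complete) && method == "auto") {
    b <- qr.coef(qx, Y)
    Res <- Y - X %*% b
    Sigma <- crossprod(Res) / n
    theta <- c(b[, 1], b[, 2], Sigma[1, 1], Sigma[2, 2], Sigma[1, 2])
    converged <- TRUE
  } else {
    # available-case OLS starts per equation
    b0 <- vapply(1:2, function(g) {
      ok <- !is.na(Y[, g])
      qr.coef(qr(X[ok, , drop = FALSE]), Y[ok, g])
    }, numeric(p))
    v0 <- vapply(1:2, function(g) {
      ok <- !is.na(Y[, g])
      r <- Y[ok, g] - X[ok, , drop = FALSE] %*% b0[, g]
      max(mean(r^2), 1e-6)
    }, numeric(1))
    c0 <- if (sum(complete) > 2) {
      r1 <- Y[complete, 1] - X[complete, , drop = FALSE] %*% b0[, 1]
      r2 <- Y[complete, 2] - X[complete, , drop = FALSE] %*% b0[, 2]
      mean(r1 * r2)
    } else {
      0
    }
    rho0 <- max(min(c0 / sqrt(v0[1] * v0[2]), 0.95), -0.95)
    phi0 <- c(b0[, 1], b0[, 2], log(v0[1]), log(v0[2]), atanh(rho0))

    negll <- function(phi) {
      -sum(apim_ll_contribs(phi_to_theta(phi, p), X, Y))
    }
    neggrad <- function(phi) {
      theta <- phi_to_theta(phi, p)
      s <- colSums(apim_score_contribs(theta, X, Y))
      g <- s
      v1 <- theta[ix$v1]; v2 <- theta[ix$v2]; cc <- theta[ix$cc]
      tz <- tanh(phi[ix$cc])
      g[ix$v1] <- s[ix$v1] * v1 + s[ix$cc] * cc / 2
      g[ix$v2] <- s[ix$v2] * v2 + s[ix$cc] * cc / 2
      g[ix$cc] <- s[ix$cc] * sqrt(v1 * v2) * (1 - tz^2)
      -g
    }
    opt <- stats::nlminb(phi0, negll, neggrad,
      control = list(iter.max = 500, eval.max = 1000, rel.tol = 1e-14))
    theta <- phi_to_theta(opt$par, p)

    # Newton polish on the natural scale to drive the score to ~0
    for (it in 1:20) {
      s <- colSums(apim_score_contribs(theta, X, Y))
      if (max(abs(s)) < tol) break
      H <- apim_hessian(theta, X, Y)
      step <- tryCatch(solve(H, s), error = function(e) NULL)
      if (is.null(step)) break
      cand <- theta - step
      ok <- cand[ix$v1] > 0 && cand[ix$v2] > 0 &&
        cand[ix$v1] * cand[ix$v2] - cand[ix$cc]^2 > 0
      if (!ok) break
      if (sum(apim_ll_contribs(cand, X, Y)) <
          sum(apim_ll_contribs(theta, X, Y)) - 1e-8) break
      theta <- cand
    }
    converged <- max(abs(colSums(apim_score_contribs(theta, X, Y)))) < 1e-6
    if (!converged) {
      stop("FIML estimation did not converge (score norm ",
        format(max(abs(colSums(apim_score_contribs(theta, X, Y))))),
        ")", call. = FALSE)
    }
    b <- cbind(theta[ix$b1], theta[ix$b2])
    rownames(b) <- colnames(X)
    Sigma <- matrix(c(theta[ix$v1], theta[ix$cc], theta[ix$cc], theta[ix$v2]), 2)
  }
  dimnames(b) <- list(colnames(X), design$outcomes)
  dimnames(Sigma) <- list(design$outcomes, design$outcomes)

  # moments used by standardization and conditional-effect grids
  stats_list <- list(
    x_mean = colMeans(X[, -1, drop = FALSE]),
    x_sd = apply(X[, -1, drop = FALSE], 2, stats::sd),
    y_sd = apply(Y, 2, stats::sd, na.rm = TRUE),
    y_mean = colMeans(Y, na.rm = TRUE)
  )

  structure(
    list(
      b = b,
      sigma = Sigma,
      resid_cor = Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2]),
      loglik = sum(apim_ll_contribs(theta, X, Y)),
      n = n,
      n_complete = sum(complete),
      theta = theta,
      converged = converged,
      X = X,
      Y = Y,
      terms = design$terms,
      outcomes = design$outcomes,
      valence = design$valence,
      symptom = design$symptom,
      stats = stats_list,
      exog_cor = stats::cor(X[, -1, drop = FALSE]),
      vcov_robust = NULL,
      vcov_classical = NULL,
      paths = NULL
    ),
    class = "apim_fit"
  )
}

#' Sandwich (robust) covariance for an APIM fit
#'
#' Fills the MLR-style robust covariance `A^-1 B A^-1 / n`, where `A` is the
#' average per-case likelihood Hessian and `B` the average outer product of
#' per-case score vectors. Valid under non-normality of the outcomes. The
#' small-sample factor is configurable: the default `"n-p"` scales by
#' `n/(n-p)` with `p` the per-equation coefficient count (HC1-style; better
#' calibrated at a couple hundred dyads in the package's own Monte-Carlo
#' checks), `"n-1"` gives the conventional `n/(n-1)`, `"none"` no scaling.
#'
#' @param fit An [fit_apim()] result.
#' @param df_adjust Small-sample factor: `"n-p"` (default), `"n-1"`, `"none"`.
#' @return The fit with `vcov_robust` and `vcov_classical` filled.
#' @export
robust_se <- function(fit, df_adjust = c("n-p", "n-1", "none")) {
  stopifnot(inherits(fit, "apim_fit"), fit$converged)
  df_adjust <- match.arg(df_adjust)
  n <- fit$n
  S <- apim_score_contribs(fit$theta, fit$X, fit$Y)
  H <- apim_hessian(fit$theta, fit$X, fit$Y)
  A <- H / n
  B <- crossprod(S) / n
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("singular Hessian in sandwich covariance", call. = FALSE)
  })
  V <- Ainv %*% B %*% t(Ainv) / n
  V <- V * switch(df_adjust,
    "n-p" = n / (n - ncol(fit$X)),
    "n-1" = n / (n - 1),
    "none" = 1
  )
  fit$vcov_robust <- V
  fit$vcov_classical <- tryCatch(solve(-H), error = function(e) {
    stop("singular Hessian", call. = FALSE)
  })
  param_names <- c(
    paste0(fit$outcomes[1], ":", rownames(fit$b)),
    paste0(fit$outcomes[2], ":", rownames(fit$b)),
    "v1", "v2", "cov12"
  )
  dimnames(fit$vcov_robust) <- list(param_names, param_names)
  dimnames(fit$vcov_classical) <- list(param_names, param_names)
  fit
}

#' Standardized paths with robust inference
#'
#' Scales each path by the sample SD of its realized predictor column (the
#' product column's own SD for interactions) over the sample SD of its
#' outcome: `beta = b * SD(x) / SD(y)`. Robust standard errors propagate by
#' the same fixed-SD factor (delta rule); z and p come from the standard
#' normal, and the CI is `beta +/- z * SE`.
#'
#' @param fit An `apim_fit`; [robust_se()] is applied first if it has not
#'   been already.
#' @param level Confidence level for the CI (default 0.95).
#' @param se Which covariance feeds the SEs: `"robust"` (default) or
#'   `"classical"`.
#' @return The fit with a `paths` tibble: `outcome`, `term`, `b`, `beta`,
#'   `se`, `z`, `p`, `ci_lower`, `ci_upper`.
#' @export
standardize <- function(fit, level = 0.95, se = c("robust", "classical")) {
  stopifnot(inherits(fit, "apim_fit"))
  se <- match.arg(se)
  if (is.null(fit$vcov_robust)) fit <- robust_se(fit)
  V <- if (se == "robust") fit$vcov_robust else fit$vcov_classical
  if (any(fit$stats$y_sd == 0)) stop("zero-variance outcome", call. = FALSE)
  p <- nrow(fit$b)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (g in 1:2) {
    for (j in 2:p) { # skip intercept
      idx <- (g - 1) * p + j
      b <- fit$b[j, g]
      scale <- fit$stats$x_sd[[rownames(fit$b)[j]]] / fit$stats$y_sd[[g]]
      beta <- b * scale
      se_b <- sqrt(V[idx, idx])
      se_beta <- se_b * scale
      z <- if (se_b > 0) b / se_b else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        outcome = sub("^y_", "", fit$outcomes[g]),
        term = rownames(fit$b)[j],
        b = b, beta = beta, se = se_beta, z = z,
        p = 2 * stats::pnorm(-abs(z)),
        ci_lower = beta - zq * se_beta,
        ci_upper = beta + zq * se_beta
      )
    }
  }
  fit$paths <- dplyr::bind_rows(rows)
  fit$ci_level <- level
  fit$se_type <- se
  fit
}

#' One-call APIM estimation
#'
#' [fit_apim()] + [robust_se()] + [standardize()].
#'
#' @inheritParams fit_apim
#' @inheritParams standardize
#' @export
apim <- function(design, level = 0.95, se = c("robust", "classical")) {
  standardize(robust_se(fit_apim(design)), level = level, se = match.arg(se))
}

#' @export
print.apim_fit <- function(x, digits = 3, ...) {
  cat("<apim_fit> ", x$valence, " emotion -> ", x$symptom,
    " symptoms (n = ", x$n, ", ", x$n_complete, " complete)\n",
    sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  cat(sprintf("  residual correlation: %.3f\n", x$resid_cor))
  if (!is.null(x$paths)) {
    cat("  standardized paths (", x$se_type, " SE, ",
      format(100 * x$ci_level), "% CI):\n", sep = "")
    print(as.data.frame(x$paths[c("outcome", "term", "beta", "se", "p",
      "ci_lower", "ci_upper")]), digits = digits, row.names = FALSE)
  } else {
    cat("  (run standardize() for the path table)\n")
  }
  invisible(x)
}

#' @export
coef.apim_fit <- function(object, ...) object$b

#' @export
logLik.apim_fit <- function(object, ...) {
  structure(object$loglik,
    df = length(object$theta), nobs = object$n, class = "logLik")
}

#' @export
vcov.apim_fit <- function(object, type = c("robust", "classical"), ...) {
  type <- match.arg(type)
  v <- if (type == "robust") object$vcov_robust else object$vcov_classical
  if (is.null(v)) stop("run robust_se() first", call. = FALSE)
  v
}

#' Multigroup APIM estimation
#'
#' Fits the same model independently within each stratum (typically
#' adolescent gender group); strata smaller than `min_group_n` are excluded
#' and reported rather than fitted.
#'
#' @param design An `apim_design`; its `group` column (adolescent gender by
#'   default) defines strata unless `groups` is supplied.
#' @param groups Optional explicit group label per dyad.
#' @param min_group_n Minimum analyzable dyads per stratum (default 10).
#' @inheritParams standardize
#' @return A `grouped_apim`: named list of fits plus an excluded-group table.
#' @export
fit_multigroup <- function(design, groups = NULL, min_group_n = 10L,
                           level = 0.95) {
  stopifnot(inherits(design, "apim_design"))
  dat <- design$data
  if (is.null(groups)) groups <- dat$group
  stopifnot(length(groups) == nrow(dat))
  groups <- as.character(groups)
  sizes <- table(groups)
  eligible <- names(sizes)[sizes >= min_group_n]
  if (length(eligible) == 0) {
    stop("all groups are below min_group_n = ", min_group_n, call. = FALSE)
  }
  fits <- list()
  for (g in eligible) {
    sub <- design
    sub$data <- dat[groups == g, , drop = FALSE]
    fits[[g]] <- apim(sub, level = level)
  }
  excluded <- tibble::tibble(
    group = names(sizes)[!names(sizes) %in% eligible],
    n = as.integer(sizes[!names(sizes) %in% eligible])
  )
  structure(
    list(fits = fits, excluded = excluded, min_group_n = min_group_n),
    class = "grouped_apim"
  )
}

#' @export
print.grouped_apim <- function(x, ...) {
  cat("<grouped_apim> ", length(x$fits), " group fit(s)\n", sep = "")
  for (g in names(x$fits)) {
    cat("--- group:", g, "---\n")
    print(x$fits[[g]])
  }
  if (nrow(x$excluded) > 0) {
    cat("excluded (below n =", x$min_group_n, "):",
      paste0(x$excluded$group, " (", x$excluded$n, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Table of standardized APIM results
#'
#' Flattens one or more fits into the familiar results-table shape: one row
#' per path with standardized coefficient, robust SE, p, and CI.
#'
#' @param fit An `apim_fit` or `grouped_apim`.
#' @param model_id Optional model label column.
#' @return A tibble.
#' @export
apim_table <- function(fit, model_id = NULL) {
  if (inherits(fit, "grouped_apim")) {
    out <- dplyr::bind_rows(lapply(names(fit$fits), function(g) {
      tb <- apim_table(fit$fits[[g]], model_id = model_id)
      tb$group <- g
      tb
    }))
    return(out)
  }
  stopifnot(inherits(fit, "apim_fit"))
  if (is.null(fit$paths)) fit <- standardize(fit)
  tb <- fit$paths
  tb$model <- if (is.null(model_id)) {
    paste(fit$valence, fit$symptom, sep = "_")
  } else {
    model_id
  }
  tb$group <- "all"
  tb
}
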