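#' Conditional-effect (simple-slopes) curve
#'
#' For a fitted APIM with a mean-emotion by emodiversity interaction, the
#' effect of the focal predictor on one outcome as a function of the
#' moderator is `effect(x) = b_focal + b_product * x` on the centered
#' moderator scale, with the delta-method variance
#' `V(b_focal) + x^2 V(b_product) + 2x Cov(b_focal, b_product)` taken from
#' the robust covariance. At `x = 0` (the moderator's mean under centering)
#' the effect equals `b_focal` exactly.
#'
#' @param fit An `apim_fit` with the robust covariance filled (it is filled
#'   on demand).
#' @param outcome `"adolescent"` or `"caregiver"`: which equation's paths.
#' @param focal Focal predictor term (e.g. `"a_gini"`).
#' @param moderator Moderator term (e.g. `"a_mean"`); must share its role
#'   prefix with `focal` so the fitted product term exists.
#' @param grid Moderator values (centered scale). Default: moderator mean
#'   +/- 2 SD in 41 steps (which is -2 SD .. +2 SD when predictors were
#'   centered).
#' @param level Confidence level for the band (0.95 or 0.99; Wald, normal
#'   quantile).
#' @return A `conditional_effect_curve`: tibble with `x`, `effect`, `lower`,
#'   `upper`, plus attributes recording the paths and covariance terms used.
#' @export
conditional_effect <- function(fit, outcome = c("adolescent", "caregiver"),
                               focal, moderator, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "apim_fit"))
  outcome <- match.arg(outcome)
  if (is.null(fit$vcov_robust)) fit <- robust_se(fit)
  terms <- rownames(fit$b)[-1]
  if (!focal %in% terms) stop("unknown focal term: ", focal, call. = FALSE)
  if (!moderator %in% terms) stop("unknown moderator term: ", moderator, call. = FALSE)
  prefix_f <- substr(focal, 1, 2)
  prefix_m <- substr(moderator, 1, 2)
  if (prefix_f != prefix_m) {
    stop("focal and moderator must belong to the same dyad member", call. = FALSE)
  }
  product <- paste0(prefix_f, "mean_x_gini")
  if (!product %in% terms) stop("no fitted product term ", product, call. = FALSE)

  g <- match(paste0("y_", outcome), fit$outcomes)
  p <- nrow(fit$b)
  idx_of <- function(term) (g - 1) * p + match(term, rownames(fit$b))
  i_f <- idx_of(focal)
  i_p <- idx_of(product)
  V <- fit$vcov_robust
  b_f <- fit$b[match(focal, rownames(fit$b)), g]
  b_p <- fit$b[match(product, rownames(fit$b)), g]
  v_f <- V[i_f, i_f]
  v_p <- V[i_p, i_p]
  cv <- V[i_f, i_p]

  if (is.null(grid)) {
    mu <- fit$stats$x_mean[[moderator]]
    sd <- fit$stats$x_sd[[moderator]]
    grid <- seq(mu - 2 * sd, mu + 2 * sd, length.out = 41)
  }
  eff <- b_f + b_p * grid
  var_eff <- v_f + grid^2 * v_p + 2 * grid * cv
  var_eff[var_eff < 0] <- 0
  zq <- stats::qnorm(1 - (1 - level) / 2)
  band <- zq * sqrt(var_eff)
  out <- tibble::tibble(
    x = grid, effect = eff, lower = eff - band, upper = eff + band
  )
  structure(out,
    class = c("conditional_effect_curve", class(out)),
    level = level, outcome = outcome, focal = focal, moderator = moderator,
    product = product, b_focal = b_f, b_product = b_p,
    v_focal = v_f, v_product = v_p, cov_fp = cv
  )
}

#' @export
print.conditional_effect_curve <- function(x, ...) {
  cat("<conditional_effect_curve> effect of ", attr(x, "focal"),
    " on ", attr(x, "outcome"), " outcome across ", attr(x, "moderator"),
    " (", format(100 * attr(x, "level")), "% band)\n",
    sep = "")
  NextMethod()
}

#' Plot a conditional-effect curve
#'
#' Simple line plot of the effect with its confidence band; requires
#' ggplot2.
#'
#' @param x A `conditional_effect_curve`.
#' @param ... Unused.
#' @export
plot.conditional_effect_curve <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(tibble::as_tibble(x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$effect)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = paste0(attr(x, "moderator"), " (centered)"),
      y = paste0("effect of ", attr(x, "focal"), " on ", attr(x, "outcome")),
      title = paste0(format(100 * attr(x, "level")), "% confidence band")
    )
}
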