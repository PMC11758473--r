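#' Study-variable table in the standard order
#'
#' Joins per-person emotion features with baseline symptoms into the
#' 12-variable wide table used for descriptives and correlations: caregiver
#' mean positive/negative emotion, positive/negative emodiversity, depressive
#' and anxious symptoms, then the same six for adolescents.
#'
#' @param summaries [emotion_summaries()] output.
#' @param baselines Baseline table.
#' @return One row per dyad, columns prefixed `cg_` / `ad_`.
#' @export
study_variables <- function(summaries, baselines) {
  dyad_ids <- sort(unique(summaries$dyad_id))
  grab <- function(tbl, role, col) {
    sub <- tbl[tbl$role == role, ]
    sub[[col]][match(dyad_ids, sub$dyad_id)]
  }
  tibble::tibble(
    dyad_id = dyad_ids,
    cg_mean_pos = grab(summaries, "caregiver", "mean_pos"),
    cg_mean_neg = grab(summaries, "caregiver", "mean_neg"),
    cg_gini_pos = grab(summaries, "caregiver", "gini_pos"),
    cg_gini_neg = grab(summaries, "caregiver", "gini_neg"),
    cg_depressive = grab(baselines, "caregiver", "depressive_mean"),
    cg_anxious = grab(baselines, "caregiver", "anxious_mean"),
    ad_mean_pos = grab(summaries, "adolescent", "mean_pos"),
    ad_mean_neg = grab(summaries, "adolescent", "mean_neg"),
    ad_gini_pos = grab(summaries, "adolescent", "gini_pos"),
    ad_gini_neg = grab(summaries, "adolescent", "gini_neg"),
    ad_depressive = grab(baselines, "adolescent", "depressive_mean"),
    ad_anxious = grab(baselines, "adolescent", "anxious_mean")
  )
}

#' Descriptive statistics and correlation matrix
#'
#' Per-variable mean, SD and observed range on available cases, plus the
#' pairwise-complete Pearson correlation matrix with t-based p-values,
#' per-pair n, and significance stars (`*` p < .05, `**` p < .01).
#'
#' @param variables Numeric data frame (e.g. [study_variables()] without the
#'   id column).
#' @return A `descriptives_table`: list with `stats` (tibble), `r`, `p`, `n`,
#'   `stars` (matrices), and `flagged` (constant variables whose correlations
#'   are undefined).
#' @export
descriptives <- function(variables) {
  variables <- tibble::as_tibble(variables)
  variables <- variables[vapply(variables, is.numeric, logical(1))]
  k <- ncol(variables)
  stopifnot(k >= 1)
  nm <- names(variables)

  stats_tbl <- tibble::tibble(
    variable = nm,
    mean = vapply(variables, function(v) mean(v, na.rm = TRUE), numeric(1),
      USE.NAMES = FALSE),
    sd = vapply(variables, function(v) stats::sd(v, na.rm = TRUE), numeric(1),
      USE.NAMES = FALSE),
    min = vapply(variables, function(v) suppressWarnings(min(v, na.rm = TRUE)),
      numeric(1), USE.NAMES = FALSE),
    max = vapply(variables, function(v) suppressWarnings(max(v, na.rm = TRUE)),
      numeric(1), USE.NAMES = FALSE),
    n = vapply(variables, function(v) sum(!is.na(v)), integer(1),
      USE.NAMES = FALSE)
  )

  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n_mat <- matrix(0L, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  diag(p) <- 0
  flagged <- character()
  for (i in seq_len(k)) {
    n_mat[i, i] <- sum(!is.na(variables[[i]]))
    for (j in seq_len(k)) {
      if (j >= i) next
      ok <- stats::complete.cases(variables[[i]], variables[[j]])
      n_ij <- sum(ok)
      n_mat[i, j] <- n_mat[j, i] <- n_ij
      if (n_ij < 3) next
      xi <- variables[[i]][ok]
      xj <- variables[[j]][ok]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        flagged <- union(flagged, nm[c(i, j)][c(stats::sd(xi) == 0, stats::sd(xj) == 0)])
        next
      }
      ct <- stats::cor.test(xi, xj)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = list(nm, nm))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""

  structure(
    list(stats = stats_tbl, r = r, p = p, n = n_mat, stars = stars,
      flagged = flagged),
    class = "descriptives_table"
  )
}

#' @export
print.descriptives_table <- function(x, digits = 2, ...) {
  cat("<descriptives_table> ", nrow(x$stats), " variables\n", sep = "")
  tb <- x$stats
  tb$`mean (SD)` <- sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
    tb$mean, tb$sd)
  print(as.data.frame(tb[c("variable", "mean (SD)", "min", "max", "n")]),
    row.names = FALSE, digits = digits + 2)
  if (length(x$flagged) > 0) {
    cat("constant variable(s) with undefined correlations:",
      paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

new_test_result <- function(statistic, df, p, mean_diff, kind) {
  structure(
    list(statistic = unname(statistic), df = unname(df), p = unname(p),
      mean_diff = unname(mean_diff), kind = kind),
    class = "dyad_test_result"
  )
}

#' @export
print.dyad_test_result <- function(x, ...) {
  cat(sprintf("%s t-test: t(%.4g) = %.3f, p = %.4g, mean difference = %.4f\n",
    x$kind, x$df, x$statistic, x$p, x$mean_diff))
  invisible(x)
}

#' Paired-sample t-test between dyad roles
#'
#' Classical two-tailed paired t-test on complete pairs, with the sign
#' convention first argument minus second.
#'
#' @param x,y Per-dyad values for the two roles, aligned by position.
#' @return A `dyad_test_result`: `statistic`, `df` (pairs minus one), `p`,
#'   `mean_diff`, `kind`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x[ok] - y[ok]
  if (stats::sd(d) == 0) {
    if (all(d == 0)) { # no difference at all: t = 0 by convention
      return(new_test_result(0, length(d) - 1, 1, 0, "paired"))
    }
    stop("zero variance of differences", call. = FALSE)
  }
  tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
  new_test_result(tt$statistic, tt$parameter, tt$p.value, mean(d), "paired")
}

#' Welch t-test of an outcome by missing-data status
#'
#' Compares an observed outcome between cases that do and do not have
#' missing data elsewhere (an MCAR screen): unequal-variance independent
#' samples t-test.
#'
#' @param outcome Numeric outcome values (its own missing values are dropped).
#' @param has_missing Logical indicator that the case has missing data on the
#'   other outcomes.
#' @return A `dyad_test_result` with `kind = "independent-Welch"`.
#' @export
missingness_ttest <- function(outcome, has_missing) {
  stopifnot(length(outcome) == length(has_missing))
  ok <- !is.na(outcome) & !is.na(has_missing)
  outcome <- outcome[ok]
  has_missing <- as.logical(has_missing[ok])
  n1 <- sum(has_missing)
  n0 <- sum(!has_missing)
  if (n1 < 2 || n0 < 2) {
    stop("each group needs at least 2 observed values (got ", n1, " and ", n0, ")",
      call. = FALSE
    )
  }
  tt <- stats::t.test(outcome[has_missing], outcome[!has_missing],
    var.equal = FALSE)
  new_test_result(tt$statistic, tt$parameter, tt$p.value,
    mean(outcome[has_missing]) - mean(outcome[!has_missing]),
    "independent-Welch")
}

#' Multicollinearity screen
#'
#' Flags predictor pairs whose absolute pairwise-complete Pearson correlation
#' exceeds the threshold (conventionally .80).
#'
#' @param predictors Numeric data frame of predictors.
#' @param threshold Absolute-correlation cut (default 0.80).
#' @return Tibble of flagged pairs (`var1`, `var2`, `r`); zero rows when no
#'   pair exceeds the threshold.
#' @export
collinearity_screen <- function(predictors, threshold = 0.80) {
  predictors <- tibble::as_tibble(predictors)
  predictors <- predictors[vapply(predictors, is.numeric, logical(1))]
  stopifnot(ncol(predictors) >= 2)
  r <- suppressWarnings(stats::cor(predictors, use = "pairwise.complete.obs"))
  nm <- colnames(r)
  rows <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      if (!is.na(r[i, j]) && abs(r[i, j]) > threshold) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          var1 = nm[i], var2 = nm[j], r = r[i, j]
        )
      }
    }
  }
  if (length(rows) == 0) {
    tibble::tibble(var1 = character(), var2 = character(), r = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' Normality screen
#'
#' Advisory skewness / excess-kurtosis screen per variable; flags
#' `|skewness| > 2` or `excess kurtosis > 7`.
#'
#' @param variables Numeric data frame.
#' @return Tibble with `variable`, `skewness`, `kurtosis_excess`, `flag`.
#' @export
normality_screen <- function(variables) {
  variables <- tibble::as_tibble(variables)
  variables <- variables[vapply(variables, is.numeric, logical(1))]
  res <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    v <- v[!is.na(v)]
    m <- mean(v)
    s <- stats::sd(v)
    sk <- if (s > 0) mean((v - m)^3) / s^3 else NA_real_
    ku <- if (s > 0) mean((v - m)^4) / s^4 - 3 else NA_real_
    tibble::tibble(
      variable = nm, skewness = sk, kurtosis_excess = ku,
      flag = isTRUE(abs(sk) > 2 || ku > 7)
    )
  })
  dplyr::bind_rows(res)
}
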