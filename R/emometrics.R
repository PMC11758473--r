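#' Daily emotion composite
#'
#' The mean of the non-missing items of one valence for a single daily
#' report: the seven negative items average to the daily negative composite,
#' the nine positive items to the daily positive composite. If every item of
#' the valence is missing the composite is missing.
#'
#' @param report A single daily report: a named numeric vector of item
#'   ratings, or a one-row data frame containing the item columns.
#' @param valence `"negative"` or `"positive"`.
#' @return A value in \[0, 4\], or `NA` if no item of the valence was rated.
#' @export
daily_composite <- function(report, valence = c("negative", "positive")) {
  valence <- match.arg(valence)
  items <- emotion_items(valence)
  if (is.data.frame(report)) {
    stopifnot(nrow(report) == 1)
    report <- unlist(report[items])
  }
  vals <- as.numeric(report[items])
  if (all(is.na(vals))) {
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

daily_composites <- function(diary, valence) {
  items <- emotion_items(valence)
  m <- as.matrix(diary[items])
  k <- rowSums(!is.na(m))
  out <- rowSums(m, na.rm = TRUE) / k
  out[k == 0] <- NA_real_
  out
}

#' Person-level mean emotion
#'
#' Daily composites are averaged, unweighted, across the person's available
#' measurement occasions to give the person's mean negative or positive
#' emotion.
#'
#' @param diary Diary rows for a single person.
#' @inheritParams daily_composite
#' @return A value in \[0, 4\], or `NA` (with a warning) if no day yields a
#'   composite.
#' @export
person_mean <- function(diary, valence = c("negative", "positive")) {
  valence <- match.arg(valence)
  comp <- daily_composites(diary, valence)
  if (all(is.na(comp))) {
    warning("no usable days for ", valence, " composite; person mean is missing",
      call. = FALSE
    )
    return(NA_real_)
  }
  mean(comp, na.rm = TRUE)
}

#' Per-emotion aggregated totals
#'
#' For one person and one valence, sums each item's raw 0-4 ratings across
#' days (missing ratings contribute 0). The totals carry both richness (how
#' many emotions were ever endorsed) and relative abundance (how often within
#' days), and are the input to [gini_emodiversity()].
#'
#' @inheritParams person_mean
#' @return Named numeric vector `c_j >= 0`, one entry per item of the valence.
#' @export
emotion_totals <- function(diary, valence = c("negative", "positive")) {
  valence <- match.arg(valence)
  items <- emotion_items(valence)
  stopifnot(nrow(diary) > 0)
  colSums(as.matrix(diary[items]), na.rm = TRUE)
}

#' Gini-based emodiversity
#'
#' One minus the classical Gini inequality coefficient of the per-emotion
#' totals. With `c_(1) <= ... <= c_(m)` the totals in non-decreasing order,
#'
#' \deqn{G = 1 - \left( \frac{2 \sum_{j=1}^m j\,c_{(j)}}{m \sum_{j=1}^m c_{(j)}}
#'   - \frac{m+1}{m} \right)}
#'
#' Equal nonzero totals give exactly 1 (all emotions experienced equally
#' often); a single nonzero total gives `1/m`, the index's analytic floor for
#' a person who expressed only one emotion. Higher values mean more diverse
#' emotion experience. The score is invariant to permuting the categories and
#' to rescaling all totals by a positive constant.
#'
#' @param totals Non-negative numeric vector of per-emotion totals
#'   (length `m`; 7 for negative, 9 for positive valence).
#' @return The emodiversity score, or `NA` (with a warning) when all totals
#'   are zero, where diversity is undefined.
#' @examples
#' gini_emodiversity(rep(5, 9)) # 1
#' gini_emodiversity(c(0, 0, 0, 0, 0, 0, 3)) # 1/7
#' @export
gini_emodiversity <- function(totals) {
  totals <- as.numeric(totals)
  if (length(totals) < 2) {
    stop("need at least 2 emotion categories", call. = FALSE)
  }
  if (anyNA(totals) || any(totals < 0)) {
    stop("totals must be non-negative and non-missing", call. = FALSE)
  }
  m <- length(totals)
  s <- sum(totals)
  if (s == 0) {
    warning("all totals zero: emodiversity undefined", call. = FALSE)
    return(NA_real_)
  }
  cs <- sort(totals, method = "radix") # stable non-decreasing
  j <- seq_len(m)
  1 - (2 * sum(j * cs) / (m * s) - (m + 1) / m)
}

#' Per-person emotion summary table
#'
#' Runs the composite, mean, and emodiversity computations over every person
#' in a diary and returns the per-person feature table consumed by the APIM
#' stage.
#'
#' @param dyads A `dyad_data` object (or a bare diary tibble).
#' @return A tibble with one row per person: `dyad_id`, `role`, `mean_pos`,
#'   `mean_neg`, `gini_pos`, `gini_neg`, `n_days`.
#' @export
emotion_summaries <- function(dyads) {
  diary <- if (inherits(dyads, "dyad_data")) dyads$diary else
    tibble::as_tibble(dyads)
  pid <- paste(diary$dyad_id, diary$role, sep = "\r")

  comp <- tibble::tibble(
    pid = pid,
    pos = daily_composites(diary, "positive"),
    neg = daily_composites(diary, "negative"),
    usable = rowSums(!is.na(as.matrix(diary[emotion_items()]))) > 0
  )
  means <- comp |>
    dplyr::group_by(.data$pid) |>
    dplyr::summarise(
      mean_pos = if (all(is.na(.data$pos))) NA_real_ else mean(.data$pos, na.rm = TRUE),
      mean_neg = if (all(is.na(.data$neg))) NA_real_ else mean(.data$neg, na.rm = TRUE),
      n_days = sum(.data$usable),
      .groups = "drop"
    )

  items <- as.matrix(diary[emotion_items()])
  items[is.na(items)] <- 0L
  totals <- rowsum(items, pid) # persons x 16, ordered by pid
  gini_by_valence <- function(v) {
    t_v <- totals[, emotion_items(v), drop = FALSE]
    apply(t_v, 1, function(x) suppressWarnings(gini_emodiversity(x)))
  }
  gini_tbl <- tibble::tibble(
    pid = rownames(totals),
    gini_pos = unname(gini_by_valence("positive")),
    gini_neg = unname(gini_by_valence("negative"))
  )

  out <- dplyr::left_join(means, gini_tbl, by = "pid")
  parts <- strsplit(out$pid, "\r", fixed = TRUE)
  out$dyad_id <- vapply(parts, `[[`, character(1), 1)
  out$role <- vapply(parts, `[[`, character(1), 2)
  out <- out[c("dyad_id", "role", "mean_pos", "mean_neg", "gini_pos", "gini_neg", "n_days")]
  out[order(out$dyad_id, out$role), ]
}

#' Between-person reliability of diary items
#'
#' Decomposes person x day x item ratings of one valence into person,
#' person-by-item and residual variance components (a generalizability-theory
#' decomposition for multi-item intensive longitudinal data) by method of
#' moments, and forms the reliability of person-level mean scores:
#'
#' \deqn{R = \frac{\sigma^2_p + \sigma^2_{pi}/k}
#'   {\sigma^2_p + \sigma^2_{pi}/k + \sigma^2_e/(k\,\bar d)}}
#'
#' with `k` items and `d-bar` the harmonic mean of person day counts
#' (persons contribute with their own day counts, so unbalanced diaries are
#' handled). Negative moment estimates are truncated at zero.
#'
#' @param diary Diary tibble covering at least 2 persons, 2 days, 2 items.
#' @inheritParams daily_composite
#' @return A `variance_components` object: `sigma2_person`,
#'   `sigma2_person_item`, `sigma2_residual`, `k`, `d_bar`, `reliability`.
#' @export
between_person_reliability <- function(diary, valence = c("negative", "positive")) {
  valence <- match.arg(valence)
  items <- emotion_items(valence)
  k <- length(items)
  diary <- tibble::as_tibble(diary)
  pid <- paste(diary$dyad_id, diary$role, sep = "\r")
  persons <- unique(pid)
  if (length(persons) < 2) stop("need at least 2 persons", call. = FALSE)

  m <- as.matrix(diary[items])

  # residual: pooled within-(person, item)-cell variance across days
  ss_res <- 0
  df_res <- 0
  cell_means <- matrix(NA_real_, length(persons), k,
    dimnames = list(persons, items)
  )
  inv_d <- matrix(NA_real_, length(persons), k)
  for (p in seq_along(persons)) {
    rows <- which(pid == persons[p])
    for (i in seq_len(k)) {
      v <- m[rows, i]
      v <- v[!is.na(v)]
      if (length(v) >= 1) {
        cell_means[p, i] <- mean(v)
        inv_d[p, i] <- 1 / length(v)
      }
      if (length(v) >= 2) {
        ss_res <- ss_res + sum((v - mean(v))^2)
        df_res <- df_res + length(v) - 1
      }
    }
  }
  if (df_res == 0) stop("need at least 2 days for some person-item cell", call. = FALSE)
  sigma2_res <- ss_res / df_res

  # person x item: across-item variance of cell means, within person,
  # corrected for the residual share each cell mean carries
  per_person_pi <- rep(NA_real_, length(persons))
  for (p in seq_along(persons)) {
    mu_pi <- cell_means[p, ]
    ok <- !is.na(mu_pi)
    if (sum(ok) >= 2) {
      per_person_pi[p] <- stats::var(mu_pi[ok]) -
        sigma2_res * mean(inv_d[p, ok])
    }
  }
  sigma2_pi <- max(0, mean(per_person_pi, na.rm = TRUE))

  # person: across-person variance of person means, minus the shares the
  # person-item and residual components contribute to a k-item, d-day mean
  person_means <- rowMeans(cell_means, na.rm = TRUE)
  d_p <- vapply(seq_along(persons), function(p) {
    1 / mean(inv_d[p, !is.na(inv_d[p, ])])
  }, numeric(1))
  d_bar <- length(d_p) / sum(1 / d_p) # harmonic mean
  s2_between <- stats::var(person_means)
  sigma2_p <- max(0, s2_between - sigma2_pi / k - sigma2_res / (k * d_bar))

  num <- sigma2_p + sigma2_pi / k
  den <- num + sigma2_res / (k * d_bar)
  if (den == 0) {
    warning("all-constant ratings: reliability undefined", call. = FALSE)
    reliability <- NA_real_
  } else {
    reliability <- num / den
  }
  structure(
    list(
      sigma2_person = sigma2_p,
      sigma2_person_item = sigma2_pi,
      sigma2_residual = sigma2_res,
      k = k,
      d_bar = d_bar,
      reliability = reliability,
      valence = valence
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> (", x$valence, " items)\n", sep = "")
  cat(sprintf("  person:      %.4f\n", x$sigma2_person))
  cat(sprintf("  person:item: %.4f\n", x$sigma2_person_item))
  cat(sprintf("  residual:    %.4f\n", x$sigma2_residual))
  cat(sprintf("  k = %d items, d-bar = %.2f days\n", x$k, x$d_bar))
  cat(sprintf("  between-person reliability R = %.3f\n", x$reliability))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal consistency of a person-by-item score matrix,
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))`, computed on
#' persons with complete item responses.
#'
#' @param items A numeric matrix or data frame, persons in rows, items in
#'   columns.
#' @return Alpha, or `NA` with a warning when the total-score variance is zero.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2) stop("need at least 2 items", call. = FALSE)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 complete persons", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    warning("zero total-score variance: alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
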