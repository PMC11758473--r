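#' Configuration for the synthetic dyad generator
#'
#' Bundles and validates every generating value: sample size and schedule,
#' per-role latent trait distributions for positive and negative affect, the
#' item measurement model (discrimination spread, item noise), per-role
#' compliance, the true actor-partner coefficient sets linking realized
#' emotion features to the two symptom outcomes, residual structure, and the
#' baseline-symptom missingness rate. The defaults mirror a 175-dyad, 14-day
#' caregiver-adolescent diary study with adolescent compliance 0.84 and
#' caregiver compliance 0.88 and trait scales matched to typical community
#' samples (caregiver positive affect around 2.15, adolescent negative affect
#' around 0.90 on the 0-4 scale).
#'
#' @param n_dyads Number of dyads to generate.
#' @param n_days Scheduled diary days per person.
#' @param seed Integer seed; all randomness derives from it.
#' @param traits Per-role latent trait means/SDs, a nested list
#'   `list(role = list(pos = c(mean=, sd=), neg = c(mean=, sd=)))`.
#' @param day_sd SD of the day-to-day latent affect deviation around the trait.
#' @param disc_spread SD of per-person, per-item discriminations around 1.
#'   Larger spread concentrates totals on fewer items and so lowers expected
#'   emodiversity; this is the (emergent, monotone) Gini knob.
#' @param item_noise_sd SD of the item-level rating noise.
#' @param compliance Named per-role probability that a scheduled day is
#'   completed; days drop independently (missing completely at random).
#' @param effects True outcome model per symptom (`anxious`, `depressive`):
#'   each a list with `valence` (which valence's features drive the symptom),
#'   `b` (2 x 6 coefficient matrix, rows = adolescent/caregiver outcome,
#'   columns = `a_mean`, `a_gini`, `a_mean_x_gini`, `c_mean`, `c_gini`,
#'   `c_mean_x_gini`, applied to sample-centered predictors), `intercept`
#'   (length 2), `resid_sd` (length 2), `resid_cor` (scalar).
#' @param effects_by_group Optional named list (by adolescent gender group)
#'   of `effects`-shaped overrides, for generating group-specific paths.
#' @param gender_probs Adolescent gender-group probabilities
#'   (boy, girl, other, unreported).
#' @param baseline_missing Probability each symptom value is missing.
#'
#' @return A validated `synthetic_config` list.
#' @seealso [generate_dyads()]
#' @export
synthetic_config <- function(n_dyads = 175L,
                             n_days = 14L,
                             seed = 1L,
                             traits = default_traits(),
                             day_sd = 0.45,
                             disc_spread = 0.15,
                             item_noise_sd = 0.6,
                             compliance = c(adolescent = 0.84, caregiver = 0.88),
                             effects = default_effects(),
                             effects_by_group = NULL,
                             gender_probs = c(boy = 0.44, girl = 0.49,
                                              other = 0.03, unreported = 0.04),
                             baseline_missing = 0.05) {
  stopifnot(
    n_dyads >= 1, n_days >= 1,
    day_sd > 0, disc_spread >= 0, item_noise_sd >= 0,
    all(compliance >= 0 & compliance <= 1),
    all(sort(names(compliance)) == sort(DYAD_ROLES)),
    baseline_missing >= 0 && baseline_missing <= 1,
    abs(sum(gender_probs) - 1) < 1e-8
  )
  for (role in DYAD_ROLES) {
    for (v in c("pos", "neg")) {
      tr <- traits[[role]][[v]]
      if (is.null(tr) || is.na(tr["sd"]) || tr["sd"] <= 0) {
        stop("traits$", role, "$", v, " must supply mean and sd > 0", call. = FALSE)
      }
    }
  }
  for (sym in c("anxious", "depressive")) {
    eff <- effects[[sym]]
    check_effect_set(eff, sym)
  }
  if (!is.null(effects_by_group)) {
    for (g in names(effects_by_group)) {
      stopifnot(g %in% GENDER_GROUPS)
      for (sym in c("anxious", "depressive")) {
        check_effect_set(effects_by_group[[g]][[sym]], paste0(g, "$", sym))
      }
    }
  }
  structure(
    list(
      n_dyads = as.integer(n_dyads), n_days = as.integer(n_days),
      seed = as.integer(seed), traits = traits, day_sd = day_sd,
      disc_spread = disc_spread, item_noise_sd = item_noise_sd,
      compliance = compliance, effects = effects,
      effects_by_group = effects_by_group, gender_probs = gender_probs,
      baseline_missing = baseline_missing
    ),
    class = "synthetic_config"
  )
}

check_effect_set <- function(eff, label) {
  if (is.null(eff)) stop("effects$", label, " missing", call. = FALSE)
  stopifnot(
    eff$valence %in% c("negative", "positive"),
    is.matrix(eff$b), nrow(eff$b) == 2, ncol(eff$b) == 6,
    length(eff$intercept) == 2,
    length(eff$resid_sd) == 2, all(eff$resid_sd > 0),
    abs(eff$resid_cor) < 1
  )
  invisible(eff)
}

APIM_TERMS <- c("a_mean", "a_gini", "a_mean_x_gini",
                "c_mean", "c_gini", "c_mean_x_gini")

#' @rdname synthetic_config
#' @export
default_traits <- function() {
  list(
    adolescent = list(pos = c(mean = 2.05, sd = 0.60), neg = c(mean = 0.90, sd = 0.40)),
    caregiver  = list(pos = c(mean = 2.15, sd = 0.55), neg = c(mean = 0.65, sd = 0.35))
  )
}

#' @rdname synthetic_config
#' @export
default_effects <- function() {
  b_anx <- rbind(
    adolescent = c(a_mean = 0.75, a_gini = 0, a_mean_x_gini = 0,
                   c_mean = 0.40, c_gini = 0, c_mean_x_gini = 0),
    caregiver  = c(a_mean = 0.05, a_gini = 0, a_mean_x_gini = 0,
                   c_mean = 0.60, c_gini = 0, c_mean_x_gini = 0)
  )
  b_dep <- rbind(
    adolescent = c(a_mean = 0.45, a_gini = 0, a_mean_x_gini = 0,
                   c_mean = 0.05, c_gini = 0, c_mean_x_gini = 0),
    caregiver  = c(a_mean = 0.05, a_gini = 0, a_mean_x_gini = 0,
                   c_mean = 0.80, c_gini = 0, c_mean_x_gini = 0)
  )
  list(
    anxious = list(valence = "negative", b = b_anx,
                   intercept = c(adolescent = 0.88, caregiver = 0.40),
                   resid_sd = c(adolescent = 0.45, caregiver = 0.30),
                   resid_cor = 0.25),
    depressive = list(valence = "negative", b = b_dep,
                      intercept = c(adolescent = 1.47, caregiver = 0.49),
                      resid_sd = c(adolescent = 0.23, caregiver = 0.33),
                      resid_cor = 0.20)
  )
}

#' Generate a dyadic daily-diary dataset with known structure
#'
#' Person-day ratings come from a latent-affect measurement model: each
#' person draws a positive and a negative trait, each day adds an independent
#' normal deviation, and each item's rating is latent affect times the
#' person-item discrimination plus item noise, rounded and clamped to the
#' 0-4 scale. Scheduled days drop independently with probability
#' 1 - compliance. Baseline symptoms follow the configured linear
#' actor-partner model in each person's realized (sample-centered) mean
#' emotion and Gini emodiversity, plus correlated bivariate-normal residuals
#' between the two dyad members; symptom values then go missing completely
#' at random at the configured rate. Symptom values are not clamped to the
#' questionnaire range, so coefficient recovery is exact in expectation.
#'
#' @param config A [synthetic_config()].
#' @return A list: `data` (a `dyad_data` object) and `truth` (the generating
#'   values actually realized: config echo, per-dyad gender groups, predictor
#'   centering constants, and the coefficient set used per dyad).
#' @export
generate_dyads <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  n_dyads <- config$n_dyads
  n_days <- config$n_days
  items <- emotion_items()
  n_items <- length(items)
  valence_of <- item_valence()

  dyad_ids <- sprintf("d%04d", seq_len(n_dyads))
  persons <- tibble::tibble(
    dyad_id = rep(dyad_ids, each = 2),
    role = rep(DYAD_ROLES, times = n_dyads)
  )
  n_persons <- nrow(persons)

  # latent traits and daily latent affect
  trait <- function(v) {
    out <- numeric(n_persons)
    for (role in DYAD_ROLES) {
      idx <- persons$role == role
      tr <- config$traits[[role]][[v]]
      out[idx] <- stats::rnorm(sum(idx), tr["mean"], tr["sd"])
    }
    out
  }
  trait_pos <- trait("pos")
  trait_neg <- trait("neg")
  latent_pos <- trait_pos + matrix(stats::rnorm(n_persons * n_days, 0, config$day_sd),
    n_persons, n_days)
  latent_neg <- trait_neg + matrix(stats::rnorm(n_persons * n_days, 0, config$day_sd),
    n_persons, n_days)

  # per-person, per-item discriminations (positive by construction)
  disc <- abs(1 + matrix(stats::rnorm(n_persons * n_items, 0, config$disc_spread),
    n_persons, n_items, dimnames = list(NULL, items)))

  # ratings: person-day rows stacked day-major (row = person + (day-1)*P)
  rating_cols <- vector("list", n_items)
  names(rating_cols) <- items
  for (i in seq_len(n_items)) {
    latent <- if (valence_of[[items[i]]] == "positive") latent_pos else latent_neg
    r <- latent * disc[, i] +
      matrix(stats::rnorm(n_persons * n_days, 0, config$item_noise_sd),
        n_persons, n_days)
    r <- round(r)
    r[r < RATING_MIN] <- RATING_MIN
    r[r > RATING_MAX] <- RATING_MAX
    rating_cols[[i]] <- as.integer(r) # column-major: day-major stacking
  }

  diary <- tibble::tibble(
    dyad_id = rep(persons$dyad_id, times = n_days),
    role = rep(persons$role, times = n_days),
    day = rep(seq_len(n_days), each = n_persons)
  )
  for (i in seq_len(n_items)) diary[[items[i]]] <- rating_cols[[i]]

  # compliance: drop scheduled days independently per person-day
  keep_prob <- config$compliance[diary$role]
  keep <- stats::runif(nrow(diary)) < keep_prob
  diary <- diary[keep, , drop = FALSE]
  diary <- diary[order(diary$dyad_id, diary$role, diary$day), , drop = FALSE]

  # gender groups (adolescent identity; attached to both members' records)
  groups <- sample(GENDER_GROUPS, n_dyads, replace = TRUE,
    prob = config$gender_probs[GENDER_GROUPS])
  names(groups) <- dyad_ids

  # realized emotion features drive the true outcome model
  summ <- emotion_summaries(diary)
  baseline <- tibble::tibble(
    dyad_id = rep(dyad_ids, each = 2),
    role = rep(DYAD_ROLES, times = n_dyads),
    anxious_mean = NA_real_,
    depressive_mean = NA_real_,
    gender_group = ifelse(rep(DYAD_ROLES, times = n_dyads) == "adolescent",
      groups[rep(dyad_ids, each = 2)], "unreported")
  )

  centering <- list()
  for (sym in c("anxious", "depressive")) {
    eff <- config$effects[[sym]]
    feat <- dyad_features(summ, eff$valence, dyad_ids)
    centers <- colMeans(feat[c("a_mean", "a_gini", "c_mean", "c_gini")],
      na.rm = TRUE)
    centering[[sym]] <- centers
    x <- design_terms(feat, centers)

    z <- matrix(stats::rnorm(2 * n_dyads), n_dyads, 2)
    y <- matrix(NA_real_, n_dyads, 2, dimnames = list(dyad_ids, DYAD_ROLES))
    for (d in seq_len(n_dyads)) {
      eff_d <- eff
      g <- groups[[d]]
      if (!is.null(config$effects_by_group) &&
          !is.null(config$effects_by_group[[g]])) {
        eff_d <- config$effects_by_group[[g]][[sym]]
      }
      rho <- eff_d$resid_cor
      e <- c(
        z[d, 1] * eff_d$resid_sd[1],
        (rho * z[d, 1] + sqrt(1 - rho^2) * z[d, 2]) * eff_d$resid_sd[2]
      )
      xb <- as.numeric(eff_d$b %*% as.numeric(x[d, APIM_TERMS]))
      y[d, ] <- eff_d$intercept + xb + e
    }
    if (anyNA(x)) y[apply(is.na(x), 1, any), ] <- NA_real_
    miss <- matrix(stats::runif(2 * n_dyads) < config$baseline_missing,
      n_dyads, 2)
    y[miss] <- NA_real_
    # baseline rows are dyad-major (adolescent, caregiver); t(y) matches
    baseline[[paste0(sym, "_mean")]] <- as.numeric(t(y))
  }

  data <- structure(
    list(
      diary = validate_diary(diary),
      baseline = validate_baseline(baseline, check_bounds = FALSE)
    ),
    class = "dyad_data"
  )
  truth <- list(
    config = config,
    groups = groups,
    centering = centering,
    effects = config$effects,
    effects_by_group = config$effects_by_group,
    traits = tibble::tibble(
      dyad_id = persons$dyad_id, role = persons$role,
      trait_pos = trait_pos, trait_neg = trait_neg
    )
  )
  list(data = data, truth = truth)
}

# per-dyad feature block (adolescent and caregiver mean/gini of one valence)
dyad_features <- function(summ, valence, dyad_ids) {
  mean_col <- if (valence == "negative") "mean_neg" else "mean_pos"
  gini_col <- if (valence == "negative") "gini_neg" else "gini_pos"
  grab <- function(role, col) {
    sub <- summ[summ$role == role, ]
    sub[[col]][match(dyad_ids, sub$dyad_id)]
  }
  tibble::tibble(
    dyad_id = dyad_ids,
    a_mean = grab("adolescent", mean_col),
    a_gini = grab("adolescent", gini_col),
    c_mean = grab("caregiver", mean_col),
    c_gini = grab("caregiver", gini_col)
  )
}

# center mean/gini columns and form products of centered factors
design_terms <- function(feat, centers) {
  out <- tibble::tibble(
    a_mean = feat$a_mean - centers[["a_mean"]],
    a_gini = feat$a_gini - centers[["a_gini"]],
    c_mean = feat$c_mean - centers[["c_mean"]],
    c_gini = feat$c_gini - centers[["c_gini"]]
  )
  out$a_mean_x_gini <- out$a_mean * out$a_gini
  out$c_mean_x_gini <- out$c_mean * out$c_gini
  out[APIM_TERMS]
}

#' Diary compliance summary
#'
#' Completion rate (completed person-days over scheduled person-days) and
#' mean daily responses per person, by role.
#'
#' @param dyads A `dyad_data` object or diary tibble.
#' @param n_scheduled Scheduled days per person (default 14).
#' @return A tibble with one row per role: `role`, `n_persons`,
#'   `completion_rate`, `mean_daily_responses`.
#' @export
compliance_summary <- function(dyads, n_scheduled = 14L) {
  diary <- if (inherits(dyads, "dyad_data")) dyads$diary else
    tibble::as_tibble(dyads)
  stopifnot(nrow(diary) > 0, n_scheduled >= 1)
  counts <- diary_day_counts(diary)
  counts |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(
      n_persons = dplyr::n(),
      completion_rate = sum(.data$n_days) / (dplyr::n() * n_scheduled),
      mean_daily_responses = mean(.data$n_days),
      .groups = "drop"
    )
}
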