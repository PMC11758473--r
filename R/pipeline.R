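#' Pipeline run configuration
#'
#' Collects everything one analysis run needs: either input file paths or a
#' synthetic-generator configuration, the exclusion threshold, centering and
#' confidence-level choices, the optional multigroup variable, the model
#' list (by default the four valence-by-symptom combinations), the output
#' directory and the seed.
#'
#' @param diary,baseline Input CSV paths (ignored when `synthetic` is given).
#' @param synthetic Optional [synthetic_config()] (or a list of its
#'   arguments) to simulate the inputs instead of reading them.
#' @param min_days Exclusion threshold, usable diary days per member.
#' @param center Grand-mean center predictors before products.
#' @param level CI level for fit tables; `curve_level` for the
#'   conditional-effect bands.
#' @param curve_level Confidence level for conditional-effect curves.
#' @param group_by Optional multigroup variable (only `"gender_group"` is
#'   meaningful) and `min_group_n` its minimum stratum size.
#' @param min_group_n Minimum analyzable dyads per stratum.
#' @param models List of `c(valence, symptom)` pairs; default the four
#'   standard models.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for any stochastic stage.
#' @param check_bounds Enforce the 0-3 symptom range when reading baseline
#'   files.
#' @return A `run_config` list.
#' @export
run_config <- function(diary = NULL, baseline = NULL, synthetic = NULL,
                       min_days = 6L, center = TRUE, level = 0.95,
                       curve_level = 0.99, group_by = NULL, min_group_n = 10L,
                       models = default_models(), outdir = tempfile("emodyad_run_"),
                       seed = 1L, check_bounds = TRUE) {
  if (is.null(synthetic) && (is.null(diary) || is.null(baseline))) {
    stop("supply either input paths (diary + baseline) or a synthetic config",
      call. = FALSE
    )
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    synthetic$seed <- synthetic$seed %||% seed
    synthetic <- do.call(synthetic_config, synthetic)
  }
  structure(
    list(
      diary = diary, baseline = baseline, synthetic = synthetic,
      min_days = as.integer(min_days), center = isTRUE(center),
      level = level, curve_level = curve_level,
      group_by = group_by, min_group_n = as.integer(min_group_n),
      models = models, outdir = outdir, seed = as.integer(seed),
      check_bounds = isTRUE(check_bounds)
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_config
#' @export
default_models <- function() {
  list(
    m1 = c(valence = "negative", symptom = "anxious"),
    m2 = c(valence = "positive", symptom = "anxious"),
    m3 = c(valence = "negative", symptom = "depressive"),
    m4 = c(valence = "positive", symptom = "depressive")
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain any [run_config()] argument; a `synthetic`
#' block is passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$synthetic)) {
    if (!is.null(cfg$synthetic$compliance)) {
      cfg$synthetic$compliance <- unlist(cfg$synthetic$compliance)
    }
    if (!is.null(cfg$synthetic$gender_probs)) {
      cfg$synthetic$gender_probs <- unlist(cfg$synthetic$gender_probs)
    }
  }
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Reproduces the complete analysis in order: load (or simulate) the diary
#' and baseline tables, apply the exclusion rules, build per-person emotion
#' summaries, produce descriptives and the exploratory t-tests, fit the four
#' bivariate APIMs, export conditional-effect curves for each interaction,
#' and (optionally) the per-group multigroup fits. Every stage writes CSV
#' into `config$outdir`; the run is deterministic given the config and seed.
#' Any stage error aborts with the stage named; outputs of earlier stages
#' are preserved.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` (invisibly written as `manifest.yaml`): config
#'   echo, package version, input checksums, per-stage record counts,
#'   aggregated warnings, and the output-file checksums.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character()
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  counts <- list()
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = note),
      error = function(e) {
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
  }
  emit <- function(df, file) {
    path <- file.path(config$outdir, file)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    outputs <<- c(outputs, path)
    path
  }

  set.seed(config$seed)

  # ---- load or simulate -----------------------------------------------------
  input_checksums <- character()
  dyads <- stage("load", {
    if (!is.null(config$synthetic)) {
      sim <- generate_dyads(config$synthetic)
      emit(sim$data$diary, "simulated_diary.csv")
      emit(sim$data$baseline, "simulated_baseline.csv")
      truth_path <- file.path(config$outdir, "truth.yaml")
      yaml::write_yaml(serialize_truth(sim$truth), truth_path)
      outputs <<- c(outputs, truth_path)
      sim$data
    } else {
      input_checksums <<- tools::md5sum(c(config$diary, config$baseline))
      diary <- read_diary_table(config$diary)
      baseline <- read_baseline_table(config$baseline,
        check_bounds = config$check_bounds)
      structure(list(diary = diary, baseline = baseline), class = "dyad_data")
    }
  })
  counts$input_dyads <- length(unique(dyads$diary$dyad_id))

  # ---- exclusions -----------------------------------------------------------
  excl <- stage("exclusions", apply_exclusions(dyads, config$min_days))
  dyads <- excl$data
  counts$retained_dyads <- excl$report$n_retained
  emit(
    tibble::tibble(
      n_input = excl$report$n_input,
      n_retained = excl$report$n_retained,
      min_days = excl$report$min_days
    ),
    "exclusion_summary.csv"
  )
  emit(excl$report$reasons, "exclusion_reasons.csv")

  # ---- summaries ------------------------------------------------------------
  summ <- stage("summaries", emotion_summaries(dyads))
  counts$persons_summarised <- nrow(summ)
  emit(summ, "emotion_summary.csv")

  vars <- stage("study-variables", study_variables(summ, dyads$baseline))

  # ---- descriptives and exploratory tests -----------------------------------
  desc <- stage("descriptives", descriptives(vars[-1]))
  stats_tbl <- desc$stats
  stats_tbl$mean_sd <- sprintf("%.2f (%.2f)", stats_tbl$mean, stats_tbl$sd)
  emit(stats_tbl, "table1_descriptives.csv")
  emit(correlation_long(desc), "table1_correlations.csv")

  ttests <- stage("paired-tests", {
    pairs <- list(
      mean_pos = c("ad_mean_pos", "cg_mean_pos"),
      mean_neg = c("ad_mean_neg", "cg_mean_neg"),
      gini_pos = c("ad_gini_pos", "cg_gini_pos"),
      gini_neg = c("ad_gini_neg", "cg_gini_neg")
    )
    dplyr::bind_rows(lapply(names(pairs), function(nm) {
      tt <- paired_ttest(vars[[pairs[[nm]][1]]], vars[[pairs[[nm]][2]]])
      tibble::tibble(
        comparison = paste0("adolescent_minus_caregiver_", nm),
        t = tt$statistic, df = tt$df, p = tt$p, mean_diff = tt$mean_diff
      )
    }))
  })
  emit(ttests, "paired_ttests.csv")

  miss_tests <- stage("missingness-tests", {
    out_cols <- c("ad_anxious", "ad_depressive", "cg_anxious", "cg_depressive")
    rows <- list()
    for (col in out_cols) {
      others <- setdiff(out_cols, col)
      has_missing <- rowSums(is.na(vars[others])) > 0
      res <- tryCatch(missingness_ttest(vars[[col]], has_missing),
        error = function(e) NULL)
      if (!is.null(res)) {
        rows[[col]] <- tibble::tibble(
          outcome = col, t = res$statistic, df = res$df, p = res$p,
          mean_diff = res$mean_diff
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  emit(miss_tests, "missingness_ttests.csv")

  screen <- stage("collinearity", collinearity_screen(
    vars[c("ad_mean_pos", "ad_mean_neg", "ad_gini_pos", "ad_gini_neg",
      "cg_mean_pos", "cg_mean_neg", "cg_gini_pos", "cg_gini_neg")]
  ))
  emit(screen, "collinearity_flags.csv")
  emit(stage("normality", normality_screen(vars[-1])), "normality_screen.csv")

  # ---- the four APIMs -------------------------------------------------------
  fit_tables <- list()
  curve_tables <- list()
  group_tables <- list()
  for (mid in names(config$models)) {
    m <- config$models[[mid]]
    design <- stage(paste0("design-", mid), build_design(
      summ, dyads$baseline,
      valence = m[["valence"]], symptom = m[["symptom"]],
      center = config$center
    ))
    fit <- stage(paste0("fit-", mid), apim(design, level = config$level))
    fit_tables[[mid]] <- apim_table(fit, model_id = mid)

    for (outcome in c("adolescent", "caregiver")) {
      for (prefix in c("a", "c")) {
        curve <- stage(paste0("curve-", mid), conditional_effect(
          fit,
          outcome = outcome,
          focal = paste0(prefix, "_gini"),
          moderator = paste0(prefix, "_mean"),
          level = config$curve_level
        ))
        ct <- tibble::as_tibble(curve)
        ct$model <- mid
        ct$outcome <- outcome
        ct$focal <- paste0(prefix, "_gini")
        ct$level <- config$curve_level
        curve_tables[[paste(mid, outcome, prefix)]] <- ct
      }
    }

    if (!is.null(config$group_by)) {
      grouped <- stage(paste0("multigroup-", mid), {
        keep <- design$data$group %in% c("boy", "girl")
        sub <- design
        sub$data <- design$data[keep, , drop = FALSE]
        fit_multigroup(sub, min_group_n = config$min_group_n,
          level = config$level)
      })
      group_tables[[mid]] <- apim_table(grouped, model_id = mid)
    }
  }
  emit(dplyr::bind_rows(fit_tables), "apim_fits.csv")
  emit(dplyr::bind_rows(curve_tables), "conditional_effects.csv")
  if (length(group_tables) > 0) {
    emit(dplyr::bind_rows(group_tables), "apim_fits_by_group.csv")
  }
  counts$models_fit <- length(fit_tables)

  manifest <- structure(
    list(
      package_version = as.character(utils::packageVersion("emodyad")),
      seed = config$seed,
      config = serialize_config(config),
      input_checksums = as.list(input_checksums),
      counts = counts,
      warnings = warnings_seen,
      outputs = as.list(tools::md5sum(outputs))
    ),
    class = "run_manifest"
  )
  yaml::write_yaml(unclass(manifest), file.path(config$outdir, "manifest.yaml"))
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> emodyad", x$package_version, "seed", x$seed, "\n")
  cat("  dyads in/retained:", x$counts$input_dyads, "/",
    x$counts$retained_dyads, "\n")
  cat("  models fit:", x$counts$models_fit, "\n")
  cat("  outputs:", length(x$outputs), "file(s)\n")
  if (length(x$warnings) > 0) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

correlation_long <- function(desc) {
  nm <- rownames(desc$r)
  rows <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        var1 = nm[i], var2 = nm[j],
        r = desc$r[i, j], p = desc$p[i, j], n = desc$n[i, j],
        stars = desc$stars[i, j]
      )
    }
  }
  dplyr::bind_rows(rows)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$synthetic <- if (!is.null(config$synthetic)) {
    serialize_synth_config(config$synthetic)
  }
  out$models <- lapply(config$models, as.list)
  out
}

serialize_synth_config <- function(sc) {
  out <- unclass(sc)
  out$compliance <- as.list(sc$compliance)
  out$gender_probs <- as.list(sc$gender_probs)
  out$traits <- lapply(sc$traits, function(role) lapply(role, as.list))
  out$effects <- lapply(sc$effects, serialize_effect)
  out$effects_by_group <- if (!is.null(sc$effects_by_group)) {
    lapply(sc$effects_by_group, function(g) lapply(g, serialize_effect))
  }
  out
}

serialize_effect <- function(eff) {
  list(
    valence = eff$valence,
    b_adolescent = as.list(setNames(eff$b[1, ], APIM_TERMS)),
    b_caregiver = as.list(setNames(eff$b[2, ], APIM_TERMS)),
    intercept = as.list(eff$intercept),
    resid_sd = as.list(eff$resid_sd),
    resid_cor = eff$resid_cor
  )
}

serialize_truth <- function(truth) {
  list(
    seed = truth$config$seed,
    groups = as.list(truth$groups),
    centering = lapply(truth$centering, as.list),
    effects = lapply(truth$effects, serialize_effect),
    effects_by_group = if (!is.null(truth$effects_by_group)) {
      lapply(truth$effects_by_group, function(g) lapply(g, serialize_effect))
    },
    traits = lapply(as.list(truth$traits), as.vector)
  )
}
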