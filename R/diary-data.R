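#' Assemble a dyadic daily-diary dataset
#'
#' Bundles a long-format diary table (one row per person-day, 16 emotion-item
#' columns rated 0-4) with a baseline table (one row per person: anxious and
#' depressive symptom means, adolescent gender group) into a validated
#' `dyad_data` object, the common currency of the pipeline.
#'
#' @param diary Tibble/data frame with columns `dyad_id`, `role`
#'   (`"adolescent"` or `"caregiver"`), `day` (integer, 1-based), and one
#'   integer column per canonical emotion item (see [emotion_items()]);
#'   ratings may be `NA`.
#' @param baseline Tibble/data frame with columns `dyad_id`, `role`,
#'   `anxious_mean`, `depressive_mean` (numeric, `NA` allowed), and
#'   `gender_group` (one of `"boy"`, `"girl"`, `"other"`, `"unreported"`;
#'   only meaningful for adolescents). May be `NULL` for diary-only work.
#'
#' @return An object of class `dyad_data`: a list with elements `diary` and
#'   `baseline`, both tibbles.
#' @export
dyad_data <- function(diary, baseline = NULL) {
  diary <- validate_diary(tibble::as_tibble(diary))
  if (!is.null(baseline)) {
    baseline <- validate_baseline(tibble::as_tibble(baseline))
  }
  structure(list(diary = diary, baseline = baseline), class = "dyad_data")
}

#' @export
print.dyad_data <- function(x, ...) {
  n_dyads <- length(unique(x$diary$dyad_id))
  cat("<dyad_data>\n")
  cat("  dyads:      ", n_dyads, "\n", sep = "")
  cat("  person-days:", nrow(x$diary), "\n")
  cat("  baseline:   ", if (is.null(x$baseline)) "absent" else
    paste0(nrow(x$baseline), " persons"), "\n", sep = " ")
  invisible(x)
}

validate_diary <- function(diary) {
  required <- c("dyad_id", "role", "day", emotion_items())
  missing_cols <- setdiff(required, names(diary))
  if (length(missing_cols) > 0) {
    stop("diary table is missing mandatory columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  diary$dyad_id <- as.character(diary$dyad_id)
  diary$role <- as.character(diary$role)
  bad_role <- !diary$role %in% DYAD_ROLES
  if (any(bad_role)) {
    stop("invalid role(s): ", paste(unique(diary$role[bad_role]), collapse = ", "),
      call. = FALSE
    )
  }
  diary$day <- as.integer(diary$day)
  if (anyNA(diary$day) || any(diary$day < 1L)) {
    stop("diary day must be a positive integer", call. = FALSE)
  }
  key <- paste(diary$dyad_id, diary$role, diary$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (dyad_id, role, day) rows: ",
      paste(gsub("\r", "/", utils::head(dup, 5L)), collapse = "; "),
      call. = FALSE
    )
  }
  for (item in emotion_items()) {
    v <- diary[[item]]
    if (!is.numeric(v)) {
      stop("item column '", item, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.na(v) & (v < RATING_MIN | v > RATING_MAX | v != round(v)))
    if (length(bad) > 0) {
      stop("rating outside 0..4 for item '", item, "' at row(s): ",
        paste(utils::head(bad, 10L), collapse = ", "),
        call. = FALSE
      )
    }
    diary[[item]] <- as.integer(v)
  }
  diary[c("dyad_id", "role", "day", emotion_items())]
}

validate_baseline <- function(baseline, check_bounds = TRUE) {
  required <- c("dyad_id", "role", "anxious_mean", "depressive_mean", "gender_group")
  missing_cols <- setdiff(required, names(baseline))
  if (length(missing_cols) > 0) {
    stop("baseline table is missing mandatory columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  baseline$dyad_id <- as.character(baseline$dyad_id)
  baseline$role <- as.character(baseline$role)
  if (any(!baseline$role %in% DYAD_ROLES)) {
    stop("invalid role(s) in baseline table", call. = FALSE)
  }
  if (anyDuplicated(paste(baseline$dyad_id, baseline$role))) {
    stop("duplicate (dyad_id, role) rows in baseline table", call. = FALSE)
  }
  baseline$gender_group <- as.character(baseline$gender_group)
  baseline$gender_group[is.na(baseline$gender_group)] <- "unreported"
  bad_g <- !baseline$gender_group %in% GENDER_GROUPS
  if (any(bad_g)) {
    stop("invalid gender_group value(s): ",
      paste(unique(baseline$gender_group[bad_g]), collapse = ", "),
      call. = FALSE
    )
  }
  for (col in c("anxious_mean", "depressive_mean")) {
    v <- as.numeric(baseline[[col]])
    if (check_bounds) {
      bad <- which(!is.na(v) & (v < 0 | v > 3))
      if (length(bad) > 0) {
        stop(col, " outside the instrument's 0..3 range at row(s): ",
          paste(utils::head(bad, 10L), collapse = ", "),
          call. = FALSE
        )
      }
    }
    baseline[[col]] <- v
  }
  baseline[required]
}

#' Read and write diary and baseline tables
#'
#' Plain CSV (comma-separated, UTF-8, header row) is the canonical on-disk
#' form: one row per person-day for the diary, one row per person for the
#' baseline. `schema` renames non-standard column headers to the canonical
#' ones before validation. Ratings that fail to parse as numbers become
#' missing with a warning; ratings outside 0-4 and duplicated
#' (dyad, role, day) keys are errors.
#'
#' @param path File path.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(dyad_id = "family", sad = "SAD")`.
#'   Columns not mentioned are taken as already canonical.
#'
#' @return `read_diary_table()` / `read_baseline_table()` return validated
#'   tibbles; the writers return `path` invisibly.
#' @export
read_diary_table <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = "character")
  raw <- apply_schema(raw, schema)
  required <- c("dyad_id", "role", "day", emotion_items())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("diary file is missing mandatory columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (item in emotion_items()) {
    v <- raw[[item]]
    blank <- is.na(v) | trimws(v) == ""
    parsed <- suppressWarnings(as.numeric(v))
    unparseable <- which(!blank & is.na(parsed))
    if (length(unparseable) > 0) {
      warning("unparseable rating(s) for item '", item, "' at row(s) ",
        paste(utils::head(unparseable, 10L), collapse = ", "),
        "; treated as missing",
        call. = FALSE
      )
    }
    raw[[item]] <- parsed
  }
  validate_diary(tibble::as_tibble(raw))
}

#' @rdname read_diary_table
#' @param check_bounds Enforce the 0-3 instrument range on symptom means
#'   (default `TRUE`; synthetic data generated from an unbounded linear model
#'   is read back with `FALSE`).
#' @export
read_baseline_table <- function(path, schema = NULL, check_bounds = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  raw <- apply_schema(raw, schema)
  validate_baseline(tibble::as_tibble(raw), check_bounds = check_bounds)
}

#' @rdname read_diary_table
#' @param diary,baseline Validated tables as produced by the readers or the
#'   synthetic generator.
#' @export
write_diary_table <- function(diary, path) {
  utils::write.csv(diary, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_diary_table
#' @export
write_baseline_table <- function(baseline, path) {
  utils::write.csv(baseline, path, row.names = FALSE, na = "")
  invisible(path)
}

apply_schema <- function(df, schema) {
  if (is.null(schema)) {
    return(df)
  }
  if (is.null(names(schema)) || any(names(schema) == "")) {
    stop("schema must be a named character vector (canonical = file column)",
      call. = FALSE
    )
  }
  for (canonical in names(schema)) {
    file_col <- schema[[canonical]]
    if (!file_col %in% names(df)) {
      stop("schema column '", file_col, "' not found in file", call. = FALSE)
    }
    names(df)[names(df) == file_col] <- canonical
  }
  df
}

#' Count usable diary days per person
#'
#' A day counts as a "day of data" when at least one emotion rating is
#' non-missing, matching how prompt completion is counted.
#'
#' @param diary A validated diary tibble.
#' @return Tibble with `dyad_id`, `role`, `n_days`.
#' @export
diary_day_counts <- function(diary) {
  items <- as.matrix(diary[emotion_items()])
  usable <- rowSums(!is.na(items)) > 0
  diary |>
    dplyr::mutate(.usable = usable) |>
    dplyr::group_by(.data$dyad_id, .data$role) |>
    dplyr::summarise(n_days = sum(.data$.usable), .groups = "drop")
}

#' Apply the sample-exclusion rules
#'
#' A dyad is retained only if both members individually qualify: each member
#' must have daily-diary (Part 2) data at all, and each must have at least
#' `min_days` days with at least one non-missing emotion rating — the minimum
#' needed for a reliable emodiversity calculation. The rules are applied
#' jointly, so the retained set does not depend on the order in which rules
#' are stated.
#'
#' @param dyads A `dyad_data` object.
#' @param min_days Minimum usable diary days per member (default 6).
#'
#' @return A list with `data` (the retained `dyad_data`) and `report` (an
#'   `exclusion_report`: counts plus per-dyad reason codes, of which a dyad
#'   may carry several — `no_partner_part2`, `fewer_than_min_days`,
#'   `partner_insufficient`).
#' @export
apply_exclusions <- function(dyads, min_days = 6L) {
  stopifnot(inherits(dyads, "dyad_data"), min_days >= 1)
  diary <- dyads$diary
  baseline <- dyads$baseline
  all_ids <- unique(c(diary$dyad_id, if (!is.null(baseline)) baseline$dyad_id))

  if (length(all_ids) == 0) {
    report <- new_exclusion_report(0L, 0L, tibble::tibble(
      dyad_id = character(), reason = character()
    ), min_days)
    return(list(data = dyads, report = report))
  }

  counts <- diary_day_counts(diary)
  n_days_of <- function(id, role) {
    hit <- counts$n_days[counts$dyad_id == id & counts$role == role]
    if (length(hit) == 0) NA_integer_ else hit
  }

  reasons <- list()
  retained <- character()
  for (id in all_ids) {
    member_ok <- logical(2)
    member_reason <- vector("list", 2)
    for (k in seq_along(DYAD_ROLES)) {
      nd <- n_days_of(id, DYAD_ROLES[[k]])
      if (is.na(nd)) {
        member_reason[[k]] <- "no_partner_part2"
      } else if (nd < min_days) {
        member_reason[[k]] <- "fewer_than_min_days"
      } else {
        member_ok[k] <- TRUE
      }
    }
    if (all(member_ok)) {
      retained <- c(retained, id)
    } else {
      rs <- unlist(member_reason)
      if (any(member_ok)) rs <- c(rs, "partner_insufficient")
      reasons[[id]] <- tibble::tibble(dyad_id = id, reason = unique(rs))
    }
  }

  reason_tbl <- if (length(reasons) > 0) {
    dplyr::bind_rows(reasons)
  } else {
    tibble::tibble(dyad_id = character(), reason = character())
  }

  kept <- structure(list(
    diary = diary[diary$dyad_id %in% retained, , drop = FALSE],
    baseline = if (is.null(baseline)) NULL else
      baseline[baseline$dyad_id %in% retained, , drop = FALSE]
  ), class = "dyad_data")

  report <- new_exclusion_report(
    n_input = length(all_ids), n_retained = length(retained),
    reasons = reason_tbl, min_days = min_days
  )
  for (id in unique(reason_tbl$dyad_id)) {
    message("excluding dyad ", id, ": ",
      paste(reason_tbl$reason[reason_tbl$dyad_id == id], collapse = ", "))
  }
  list(data = kept, report = report)
}

new_exclusion_report <- function(n_input, n_retained, reasons, min_days) {
  structure(
    list(
      n_input = as.integer(n_input),
      n_retained = as.integer(n_retained),
      reasons = reasons,
      min_days = as.integer(min_days)
    ),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> min_days =", x$min_days, "\n")
  cat("  input dyads:   ", x$n_input, "\n")
  cat("  retained dyads:", x$n_retained, "\n")
  if (nrow(x$reasons) > 0) {
    tab <- table(x$reasons$reason)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], " dyad(s)\n", sep = "")
  }
  invisible(x)
}
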