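#' Long-format intensive longitudinal data
#'
#' Constructs the container used throughout the package for sparse,
#' irregularly observed longitudinal predictor data (for example daily
#' self-measured blood glucose). Rows with missing or non-numeric values are
#' dropped at construction and counted in the attached load report.
#'
#' @param df a data.frame in long format.
#' @param col_map optional named character vector remapping input column names
#'   onto the canonical names, e.g.
#'   \code{c(subject_id = "subj", time = "day", value = "bg")}. Canonical
#'   columns are \code{subject_id}, \code{time}, \code{value} and the
#'   optional \code{label}.
#' @return An object of class \code{"ild"}: a list with \code{obs} (the
#'   cleaned long-format data.frame), \code{subjects} (ordered unique ids),
#'   \code{n}, and \code{report} (a list of drop counts).
#' @export
as_ild <- function(df, col_map = NULL) {
  df <- as.data.frame(df)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        stop(sprintf("configuration error: mapped column '%s' (for '%s') not found",
                     src, canon))
      }
      names(df)[names(df) == src] <- canon
    }
  }
  required <- c("subject_id", "time", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("configuration error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) stop("empty dataset: no observation rows")
  value <- suppressWarnings(as.numeric(df$value))
  keep <- is.finite(value)
  dropped <- sum(!keep)
  obs <- data.frame(subject_id = as.character(df$subject_id)[keep],
                    time = df$time[keep],
                    value = value[keep],
                    stringsAsFactors = FALSE)
  if ("label" %in% names(df)) obs$label <- as.character(df$label)[keep]
  if (nrow(obs) == 0L) stop("empty dataset: all rows had missing values")
  new_ild(obs, report = list(rows_dropped = dropped))
}

new_ild <- function(obs, report = list()) {
  rownames(obs) <- NULL
  subjects <- unique(obs$subject_id)
  structure(list(obs = obs, subjects = subjects, n = length(subjects),
                 report = report),
            class = "ild")
}

#' Read long-format longitudinal data from a delimited text file
#'
#' @param path path to a delimited text file with a header row. Comma and tab
#'   separators are auto-detected unless \code{sep} is given.
#' @param sep field separator; \code{NULL} auto-detects comma vs tab.
#' @inheritParams as_ild
#' @return An \code{"ild"} object; see [as_ild()].
#' @export
read_ild <- function(path, col_map = NULL, sep = NULL) {
  df <- read_delimited(path, sep)
  as_ild(df, col_map = col_map)
}

read_delimited <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), fileEncoding = "UTF-8")
}

#' Read per-subject scalar outcomes
#'
#' Reads a table with canonical columns \code{subject_id}, \code{outcome} and
#' optional \code{outcome_date}. When a subject has several outcome records
#' and \code{anchor_date} is supplied, the record whose date is closest to the
#' anchor is kept (the later one on ties), mirroring "the value closest to the
#' follow-up date"; without an anchor the first record per subject is kept.
#'
#' @param path path to a delimited text file.
#' @param col_map optional named remapping as in [as_ild()].
#' @param anchor_date optional ISO-8601 date used to break ties between
#'   multiple outcome records per subject.
#' @param sep field separator; \code{NULL} auto-detects comma vs tab.
#' @return A data.frame with one row per subject.
#' @export
read_outcomes <- function(path, col_map = NULL, anchor_date = NULL, sep = NULL) {
  df <- read_delimited(path, sep)
  as_outcomes(df, col_map = col_map, anchor_date = anchor_date)
}

#' @rdname read_outcomes
#' @param df a data.frame of outcome records.
#' @export
as_outcomes <- function(df, col_map = NULL, anchor_date = NULL) {
  df <- as.data.frame(df)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        stop(sprintf("configuration error: mapped column '%s' (for '%s') not found",
                     src, canon))
      }
      names(df)[names(df) == src] <- canon
    }
  }
  if (!all(c("subject_id", "outcome") %in% names(df))) {
    stop("configuration error: outcome table needs subject_id and outcome columns")
  }
  df$subject_id <- as.character(df$subject_id)
  df$outcome <- suppressWarnings(as.numeric(df$outcome))
  df <- df[is.finite(df$outcome), , drop = FALSE]
  if ("outcome_date" %in% names(df)) df$outcome_date <- parse_day(df$outcome_date)
  if (anyDuplicated(df$subject_id)) {
    if (!is.null(anchor_date) && "outcome_date" %in% names(df)) {
      anchor <- parse_day(anchor_date)
      df <- df[order(df$subject_id, abs(as.numeric(df$outcome_date - anchor)),
                     -as.numeric(df$outcome_date)), , drop = FALSE]
    }
    df <- df[!duplicated(df$subject_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

## ISO-8601 dates; sub-day timestamps are truncated to the day
parse_day <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(substr(as.character(x), 1L, 10L))
}

#' Keep only observations carrying a given measurement label
#'
#' Device measurements often carry a context label (e.g. the meal label of a
#' glucose reading); analyses typically restrict to a single label such as
#' "before-breakfast". Subjects left without observations are removed.
#'
#' @param ds an \code{"ild"} object with a populated \code{label} column.
#' @param label the label to keep.
#' @return A filtered \code{"ild"} object. If the label is absent from the
#'   data entirely, an empty dataset is returned with a warning.
#' @export
filter_label <- function(ds, label) {
  stopifnot(inherits(ds, "ild"))
  if (!"label" %in% names(ds$obs)) stop("dataset has no label column")
  keep <- !is.na(ds$obs$label) & ds$obs$label == label
  if (!any(keep)) {
    warning(sprintf("label '%s' not present in the data; result is empty", label))
  }
  report <- ds$report
  report$rows_dropped_label <- sum(!keep)
  new_ild(ds$obs[keep, , drop = FALSE], report = report)
}

#' Collapse duplicated same-day measurements
#'
#' Keeps one observation per subject-day. Under \code{policy = "first"} the
#' earliest row (input order) survives; under \code{"mean"} the within-day
#' average is used.
#'
#' @param ds an \code{"ild"} object with integer day times (or dates).
#' @param policy \code{"first"} (default) or \code{"mean"}.
#' @return A deduplicated \code{"ild"} object; the number of removed rows is
#'   recorded in the report.
#' @export
dedup_daily <- function(ds, policy = c("first", "mean")) {
  stopifnot(inherits(ds, "ild"))
  policy <- match.arg(policy)
  obs <- ds$obs
  key <- paste(obs$subject_id, as.character(obs$time), sep = "\r")
  n_in <- nrow(obs)
  if (policy == "first") {
    out <- obs[!duplicated(key), , drop = FALSE]
  } else {
    first_idx <- which(!duplicated(key))
    out <- obs[first_idx, , drop = FALSE]
    out$value <- as.numeric(tapply(obs$value, key, mean)[key[first_idx]])
  }
  report <- ds$report
  report$rows_dropped_duplicate <- n_in - nrow(out)
  new_ild(out, report = report)
}

#' Align calendar-dated observations to the outcome window
#'
#' Re-indexes each observation as an integer day relative to the subject's
#' outcome date (day 0), and drops observations outside the analysis window
#' \code{[-(window_length - 1), 0]} (the default 91-day window gives
#' \code{[-90, 0]}, day 0 inclusive). Observations for subjects with no
#' outcome record are dropped and counted.
#'
#' @param ds an \code{"ild"} object whose \code{time} column holds calendar
#'   dates (ISO-8601 strings or \code{Date}).
#' @param outcomes a per-subject outcome data.frame with \code{outcome_date}
#'   (see [read_outcomes()]).
#' @param window_length_days length of the observation window, default 91.
#' @return An \code{"ild"} object with integer day times in
#'   \code{[-(window_length - 1), 0]}.
#' @export
align_window <- function(ds, outcomes, window_length_days = 91L) {
  stopifnot(inherits(ds, "ild"))
  if (!"outcome_date" %in% names(outcomes)) {
    stop("outcomes need an outcome_date column for window alignment")
  }
  obs <- ds$obs
  dates <- parse_day(obs$time)
  anchor <- outcomes$outcome_date[match(obs$subject_id, outcomes$subject_id)]
  no_outcome <- is.na(anchor)
  day <- as.integer(round(as.numeric(dates - anchor)))
  lower <- -(window_length_days - 1L)
  in_window <- !no_outcome & !is.na(day) & day >= lower & day <= 0L
  out <- obs[in_window, , drop = FALSE]
  out$time <- day[in_window]
  report <- ds$report
  report$rows_dropped_no_outcome <- sum(no_outcome)
  report$rows_dropped_out_of_window <- sum(!in_window & !no_outcome)
  new_ild(out, report = report)
}

#' Pair predictors with outcomes and apply eligibility
#'
#' Builds the analysis dataset: subjects must have an outcome record and at
#' least one in-window predictor observation. Exclusion counts are reported by
#' reason, mirroring the usual cohort-flow accounting (all enrolled, with
#' outcome, eligible).
#'
#' @param ds an aligned, deduplicated \code{"ild"} object.
#' @param outcomes per-subject outcome data.frame (one row per subject).
#' @return An object of class \code{"fpcr_data"}: a list with \code{obs},
#'   \code{outcomes} (same subject order), \code{subjects}, \code{n},
#'   \code{centered}, \code{mean_reference} and \code{exclusions}.
#' @export
analysis_dataset <- function(ds, outcomes) {
  stopifnot(inherits(ds, "ild"))
  if (anyDuplicated(outcomes$subject_id)) {
    stop("outcomes must have at most one record per subject")
  }
  with_pred <- ds$subjects
  with_out <- unique(as.character(outcomes$subject_id))
  all_subj <- union(with_pred, with_out)
  eligible <- intersect(with_out, with_pred)   # outcome order not imposed yet
  eligible <- with_pred[with_pred %in% eligible]  # keep predictor order
  exclusions <- list(
    no_outcome = length(setdiff(with_pred, with_out)),
    no_predictor = length(setdiff(with_out, with_pred))
  )
  if (length(eligible) == 0L) {
    stop("empty analysis: no subject has both an outcome and in-window observations")
  }
  obs <- ds$obs[ds$obs$subject_id %in% eligible, , drop = FALSE]
  rownames(obs) <- NULL
  out <- outcomes[match(eligible, as.character(outcomes$subject_id)), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(obs = obs, outcomes = out, subjects = eligible,
                 n = length(eligible), centered = FALSE,
                 mean_reference = NULL,
                 exclusions = c(exclusions, list(n_enrolled = length(all_subj))),
                 report = ds$report),
            class = "fpcr_data")
}

#' Center an analysis dataset around a mean function
#'
#' Subtracts the cross-subject mean curve, evaluated at each observation
#' time, from every observation. Centering twice is an error; the mean is
#' stored so trajectories can be reported back on the original scale.
#'
#' @param ads an \code{"fpcr_data"} object.
#' @param mean_fn a \code{"mean_function"} from [estimate_mean()].
#' @return The centered \code{"fpcr_data"} with \code{centered = TRUE} and
#'   \code{mean_reference} set.
#' @export
center_ild <- function(ads, mean_fn) {
  stopifnot(inherits(ads, "fpcr_data"), inherits(mean_fn, "mean_function"))
  if (isTRUE(ads$centered)) stop("dataset is already centered")
  mu <- grid_interp(mean_fn$grid, mean_fn$values, ads$obs$time)[, 1L]
  ads$obs$value <- ads$obs$value - mu
  ads$centered <- TRUE
  ads$mean_reference <- mean_fn
  ads
}

#' @rdname center_ild
#' @export
uncenter_ild <- function(ads) {
  stopifnot(inherits(ads, "fpcr_data"))
  if (!isTRUE(ads$centered)) stop("dataset is not centered")
  mu <- grid_interp(ads$mean_reference$grid, ads$mean_reference$values,
                    ads$obs$time)[, 1L]
  ads$obs$value <- ads$obs$value + mu
  ads$centered <- FALSE
  ads$mean_reference <- NULL
  ads
}

#' @export
print.ild <- function(x, ...) {
  cat(sprintf("ild: %d observations, %d subjects\n", nrow(x$obs), x$n))
  if (length(x$report)) {
    cat("  report:", paste(names(x$report), unlist(x$report), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.fpcr_data <- function(x, ...) {
  cat(sprintf("fpcr_data: %d subjects, %d observations%s\n",
              x$n, nrow(x$obs), if (isTRUE(x$centered)) " (centered)" else ""))
  ex <- x$exclusions
  cat(sprintf("  enrolled %d; excluded: no_outcome=%d, no_predictor=%d\n",
              ex$n_enrolled, ex$no_outcome, ex$no_predictor))
  invisible(x)
}

#' Write an analysis or long-format dataset back to delimited text
#'
#' @param x an \code{"ild"} or \code{"fpcr_data"} object.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
write_ild <- function(x, path, sep = ",") {
  obs <- if (inherits(x, "ild") || inherits(x, "fpcr_data")) x$obs else as.data.frame(x)
  utils::write.table(obs, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
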