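#' Read a behavior event sequence from TSV
#'
#' The canonical raw input is a tab-separated file with columns `start_s`,
#' `end_s`, `label`: ordered, non-overlapping intervals in seconds from
#' recording start, each labeled with one of the 45 raw vocabulary labels
#' (see [hcs_labels()]). Proprietary binary exports are converted to this
#' dialect upstream; `read_events` is the single import hook.
#'
#' @param file path to the event TSV.
#' @param animal_id,test_id identifiers attached to the sequence.
#' @param recording_start optional POSIXct recording start.
#' @return a `behavior_sequence`: list with `animal_id`, `test_id`,
#'   `recording_start` and `events` (tibble `start_s`, `end_s`, `label`).
#' @export
read_events <- function(file, animal_id = NA_character_,
                        test_id = NA_character_, recording_start = NULL) {
  ev <- readr::read_tsv(file, col_types = "ddc", show_col_types = FALSE)
  if (!identical(names(ev), c("start_s", "end_s", "label"))) {
    bseq_abort("event file must have columns start_s, end_s, label", "bad_header")
  }
  if (nrow(ev) == 0) bseq_abort(paste0("empty event file: ", file), "empty_events")
  behavior_sequence(ev, animal_id = animal_id, test_id = test_id,
                    recording_start = recording_start)
}

#' Construct and validate a behavior sequence
#' @param events tibble with `start_s`, `end_s`, `label`.
#' @inheritParams read_events
#' @return a validated `behavior_sequence`.
#' @export
behavior_sequence <- function(events, animal_id = NA_character_,
                              test_id = NA_character_, recording_start = NULL) {
  events <- as_tibble(events)
  bad <- setdiff(unique(events$label), hcs_labels(behaviors_only = TRUE))
  if (length(bad) > 0) {
    bseq_abort(paste0("unknown behavior label(s): ", paste(bad, collapse = ", ")),
               "unknown_label")
  }
  if (any(events$end_s <= events$start_s)) {
    bseq_abort("event intervals must satisfy end_s > start_s", "bad_interval")
  }
  if (is.unsorted(events$start_s)) {
    bseq_warn("events out of order; sorting by start_s", "unsorted_events")
    events <- arrange(events, .data$start_s, .data$end_s)
  }
  if (nrow(events) > 1 &&
      any(events$start_s[-1] < events$end_s[-nrow(events)] - 1e-9)) {
    bseq_abort("overlapping event intervals", "overlap")
  }
  structure(list(animal_id = animal_id, test_id = test_id,
                 recording_start = recording_start, events = events),
            class = "behavior_sequence")
}

#' @export
print.behavior_sequence <- function(x, ...) {
  cat("<behavior_sequence>", x$animal_id, "/", x$test_id, "-",
      nrow(x$events), "events,",
      round(max(x$events$end_s) / 3600, 2), "h\n")
  invisible(x)
}

#' Convert an event sequence to a per-minute summary
#'
#' Each event's duration is apportioned to the minutes it spans, so the
#' per-minute column sums equal the covered time within each minute
#' (at most 60 s). The trailing incomplete minute is dropped, keeping the
#' per-minute denominator uniform at 60 s.
#'
#' @param seq a `behavior_sequence`.
#' @return tibble: `minute_index` (0-based) plus one seconds column per raw
#'   label occurring in the sequence (all 44 behavior labels, zero-filled).
#' @export
events_to_minutes <- function(seq) {
  stopifnot(inherits(seq, "behavior_sequence"))
  ev <- seq$events
  n_min <- floor(max(ev$end_s) / 60)
  labels <- hcs_labels(behaviors_only = TRUE)
  mat <- matrix(0, nrow = n_min, ncol = length(labels),
                dimnames = list(NULL, labels))
  if (n_min == 0) {
    return(as_tibble(cbind(tibble(minute_index = integer(0)), as_tibble(mat))))
  }
  for (i in seq_len(nrow(ev))) {
    s <- ev$start_s[i]; e <- min(ev$end_s[i], n_min * 60)
    if (e <= s) next
    m0 <- floor(s / 60); m1 <- ceiling(e / 60) - 1
    mins <- m0:m1
    secs <- pmin(e, (mins + 1) * 60) - pmax(s, mins * 60)
    mat[mins + 1, ev$label[i]] <- mat[mins + 1, ev$label[i]] + secs
  }
  out <- as_tibble(mat)
  out$minute_index <- seq_len(n_min) - 1L
  select(out, "minute_index", everything())
}

#' Expand an hourly summary into a per-minute table
#'
#' Each hour's value divided by 60 is used for each minute of that hour, so
#' re-aggregating the minutes by hour reproduces the input exactly.
#'
#' @param file CSV with one row per hour: optional `hour_index` column, one
#'   column per raw label (seconds per hour), optional `Travel.m.`.
#' @return per-minute tibble (`minute_index` + value columns, seconds).
#' @export
read_hour_summary <- function(file) {
  tab <- readr::read_csv(file, col_types = readr::cols(.default = "d"),
                         show_col_types = FALSE)
  hour_expand(tab)
}

hour_expand <- function(tab) {
  if ("hour_index" %in% names(tab)) {
    tab <- arrange(tab, .data$hour_index)
    tab$hour_index <- NULL
  }
  vals <- as.matrix(tab)
  if (any(is.na(vals))) bseq_abort("non-numeric or missing cells in hour summary", "bad_cell")
  if (any(vals < 0)) bseq_abort("negative values in hour summary", "bad_cell")
  idx <- rep(seq_len(nrow(vals)), each = 60)
  out <- as_tibble(vals[idx, , drop = FALSE] / 60)
  out$minute_index <- seq_along(idx) - 1L
  select(out, "minute_index", everything())
}

#' Read a per-minute summary CSV
#'
#' Minute exports store seconds per behavior per minute (0-60). Values in
#' (60, 61] are clamped to 60 with a warning (export rounding); larger
#' values are an error.
#'
#' @param file CSV with optional `minute_index`, one column per raw label,
#'   optional `Travel.m.` distance column.
#' @return per-minute tibble.
#' @export
read_minute_summary <- function(file) {
  tab <- readr::read_csv(file, col_types = readr::cols(.default = "d"),
                         show_col_types = FALSE)
  if (!"minute_index" %in% names(tab)) {
    tab$minute_index <- seq_len(nrow(tab)) - 1L
  }
  parts <- split_minute_cols(tab)
  for (cl in parts$labels) {
    v <- tab[[cl]]
    if (any(is.na(v))) bseq_abort("non-numeric cells in minute summary", "bad_cell")
    if (any(v < 0)) bseq_abort("negative values in minute summary", "bad_cell")
    over <- v > 60
    if (any(v > 61)) {
      bseq_abort(paste0("minute values above 61 s in column ", cl), "bad_cell")
    }
    if (any(over)) {
      bseq_warn(paste0("clamping ", sum(over), " value(s) in (60, 61] to 60 s in ",
                       cl), "clamped_minutes")
      tab[[cl]][over] <- 60
    }
  }
  select(tab, "minute_index", everything())
}

#' Synchronize a minute table to the light/dark cycle
#'
#' Adds `bintodark` — signed minutes of each minute's start relative to the
#' anchor light-off event (the first lights-off at or after
#' `recording_start`) — and `phase` (`DAY`/`NIGHT`), derived from the lab
#' light schedule. Also attaches `animal_id`, `test_id` and the group value.
#' Behavior values are never changed.
#'
#' @param minute_table per-minute table (`minute_index` + value columns).
#' @param row experiment row (named list / 1-row tibble) with `animal_id`,
#'   `test_id`, `recording_start` and the group column.
#' @param lab lab record from [load_project()] (with `light_off_min`,
#'   `light_on_min`).
#' @param group_by name of the group column in `row` (optional).
#' @return synchronized minute tibble.
#' @export
synchronize <- function(minute_table, row, lab, group_by = NULL) {
  if (is.null(row$recording_start) || is.na(row$recording_start[[1]]) ||
      !nzchar(as.character(row$recording_start[[1]]))) {
    bseq_abort("recording_start missing from experiment row", "bad_datetime")
  }
  start <- row$recording_start[[1]]
  if (!inherits(start, "POSIXct")) start <- parse_datetime(start, "recording_start")
  if (is.null(lab$light_off_min) || is.null(lab$light_on_min) ||
      lab$light_off_min == lab$light_on_min) {
    bseq_abort("degenerate light schedule", "bad_schedule")
  }
  night_len <- (lab$light_on_min - lab$light_off_min) %% 1440

  # minutes from recording start to the first light-off at/after it
  midnight <- as.POSIXct(trunc(start, "days"), tz = "UTC")
  start_min_of_day <- as.numeric(difftime(start, midnight, units = "mins"))
  to_dark <- (lab$light_off_min - start_min_of_day) %% 1440

  bintodark <- minute_table$minute_index - to_dark
  phase <- ifelse(((bintodark %% 1440) < night_len), "NIGHT", "DAY")
  group <- if (!is.null(group_by) && group_by %in% names(row)) {
    as.character(row[[group_by]][[1]])
  } else NA_character_
  out <- mutate(minute_table,
                animal_id = as.character(row$animal_id[[1]]),
                test_id = as.character(row$test_id[[1]]),
                group = group,
                bintodark = bintodark, phase = phase)
  select(out, all_of(c("animal_id", "test_id", "group", "minute_index",
                       "bintodark", "phase")), everything())
}

#' Compare two minute tables for consistency
#'
#' Flags every overlapping minute where any shared behavior column differs
#' by more than `tol_s` seconds — the check that caught corrupted summary
#' exports whose values no longer matched the raw behavior sequence.
#'
#' @param from_events,from_summary minute tables (same animal/test); joined
#'   on `minute_index`.
#' @param tol_s tolerance in seconds per category per minute.
#' @return a `consistency_report`: list with `consistent` (logical),
#'   `flagged` (tibble `minute_index`, `column`, `a`, `b`, `diff`),
#'   `n_compared`, `columns`.
#' @export
check_consistency <- function(from_events, from_summary, tol_s = 1) {
  pa <- split_minute_cols(from_events)
  pb <- split_minute_cols(from_summary)
  common_min <- intersect(from_events$minute_index, from_summary$minute_index)
  if (length(common_min) == 0) {
    bseq_abort("minute ranges do not overlap", "disjoint_minutes")
  }
  cols <- intersect(pa$labels, pb$labels)
  a <- from_events[match(common_min, from_events$minute_index), cols, drop = FALSE]
  b <- from_summary[match(common_min, from_summary$minute_index), cols, drop = FALSE]
  d <- abs(as.matrix(a) - as.matrix(b))
  hit <- which(d > tol_s, arr.ind = TRUE)
  flagged <- tibble(
    minute_index = common_min[hit[, 1]],
    column = cols[hit[, 2]],
    a = as.matrix(a)[hit], b = as.matrix(b)[hit],
    diff = d[hit]
  ) %>% arrange(.data$minute_index, .data$column)
  structure(list(consistent = nrow(flagged) == 0, flagged = flagged,
                 n_compared = length(common_min), columns = cols),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report>",
      if (x$consistent) "consistent" else
        paste0(nrow(x$flagged), " discrepancies over ",
               length(unique(x$flagged$minute_index)), " minute(s)"),
      "-", x$n_compared, "minutes compared\n")
  invisible(x)
}

#' Read one experiment row's data file as a per-minute table
#'
#' Dispatches on `data_kind` (`events`, `minute_summary`, `hour_summary`)
#' and returns an unsynchronized minute table in raw-label columns.
#'
#' @param bundle project bundle; @param row one experiment row.
#' @return per-minute tibble.
#' @export
read_test_data <- function(bundle, row) {
  path <- data_file_path(bundle, row)
  kind <- row$data_kind[[1]]
  switch(kind,
    events = events_to_minutes(read_events(path, animal_id = row$animal_id[[1]],
                                           test_id = row$test_id[[1]])),
    minute_summary = read_minute_summary(path),
    hour_summary = read_hour_summary(path),
    bseq_abort(paste0("unknown data kind '", kind, "'"), "bad_data_kind")
  )
}
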