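#' Define the nine light-cycle-anchored time windows
#'
#' All windows are expressed in `bintodark` minutes (signed minutes relative
#' to the anchor light-off event) and resolved against a concrete recording
#' span:
#' \describe{
#'   \item{W1}{first 2 h of recording}
#'   \item{W2}{last 2 h before nightfall, `[-120, 0)`}
#'   \item{W3}{first 3 h of the night, `[0, 180)`}
#'   \item{W4}{last 3 h of the night}
#'   \item{W5}{first 3 h after light-on (second day)}
#'   \item{W6}{from 2 h before lights off to the end of the recording}
#'   \item{W7}{the whole DAY phase before light-off}
#'   \item{W8}{the whole NIGHT phase}
#'   \item{W9}{the entire recording}
#' }
#' W7-W9 are the overlapping trio spanning the six disjoint-style windows;
#' their composition is configurable via `overrides`.
#'
#' @param lab lab record (with `light_off_min`, `light_on_min`).
#' @param recording_span numeric length-2: first minute's `bintodark` and
#'   one past the last covered minute's `bintodark` (e.g.
#'   `c(min(bintodark), max(bintodark) + 1)` of a synchronized table).
#' @param overrides optional named list `W7 = c(start, end)`, ... replacing
#'   individual window definitions.
#' @return tibble `id`, `start`, `end` (bintodark minutes), `description`.
#' @export
define_windows <- function(lab, recording_span, overrides = NULL) {
  stopifnot(length(recording_span) == 2, recording_span[2] > recording_span[1])
  night_len <- (lab$light_on_min - lab$light_off_min) %% 1440
  s <- recording_span[1]; e <- recording_span[2]
  if (s > 0 || e <= 0) {
    bseq_abort("recording does not span a light-off event", "no_light_off")
  }
  w <- tibble(
    id = paste0("W", 1:9),
    start = c(s, -120, 0, night_len - 180, night_len, -120, s, 0, s),
    end = c(s + 120, 0, 180, night_len, night_len + 180, e, 0, night_len, e),
    description = c(
      "first 2 h of recording", "last 2 h before nightfall",
      "first 3 h of the night", "last 3 h of the night",
      "first 3 h of the second day",
      "2 h before lights off to end of recording",
      "day phase before light-off", "whole night phase", "entire recording")
  )
  for (id in names(overrides)) {
    w$start[w$id == id] <- overrides[[id]][1]
    w$end[w$id == id] <- overrides[[id]][2]
  }
  if (any(w$end <= w$start)) {
    bseq_abort("window resolution produced an empty window", "bad_window")
  }
  w
}

#' Keep only the windows every animal fully covers
#'
#' A window is available iff each synchronized table's minutes cover every
#' minute of the window — data cleansing that keeps each sample of
#' equivalent valence for the multivariate analysis.
#'
#' @param tables list of synchronized minute tables (one per test).
#' @param windows window tibble from [define_windows()].
#' @return subset of `windows` (possibly 0 rows).
#' @export
available_windows <- function(tables, windows) {
  if (length(tables) == 0) bseq_abort("no animals provided", "no_animals")
  # minute tables are contiguous, so coverage is a range check
  lo <- vapply(tables, function(tb) min(tb$bintodark), numeric(1))
  hi <- vapply(tables, function(tb) max(tb$bintodark) + 1, numeric(1))
  ok <- vapply(seq_len(nrow(windows)), function(i) {
    all(lo <= windows$start[i]) && all(hi >= windows$end[i])
  }, logical(1))
  windows[ok, , drop = FALSE]
}

#' Build the sqrt-proportion multivariate feature matrix
#'
#' For each test, window and pooled behavior category, computes the square
#' root of the proportion of window time spent in that category
#' (denominator: total behavior seconds recorded in the window). The sqrt
#' transform stabilizes variance without requiring non-null values. With
#' the 18-category scheme and all nine windows the matrix has
#' 18 x 9 = 162 columns (distance included).
#'
#' The distance channel, when present and not dropped, enters as the square
#' root of the window's share of the recording's total distance — it is on
#' the same [0, 1] scale but excluded from the per-window behavior
#' normalization.
#'
#' @param tables list of synchronized minute tables (raw or base-38 columns).
#' @param windows window tibble (must be [available_windows()]-checked).
#' @param scheme a [category_scheme()].
#' @param drop_distance drop the distance columns (recommended for
#'   multidimensional analysis, since the distance channel's spread differs
#'   from time proportions).
#' @return `feature_matrix` tibble: `animal_id`, `test_id`, `group`, then
#'   `<category>__<window>` columns in [0, 1].
#' @export
build_features <- function(tables, windows, scheme, drop_distance = FALSE) {
  stopifnot(inherits(scheme, "category_scheme"))
  avail <- available_windows(tables, windows)
  if (nrow(avail) < nrow(windows)) {
    bseq_abort(paste0("window(s) not covered by all animals: ",
                      paste(setdiff(windows$id, avail$id), collapse = ", ")),
               "window_uncovered")
  }
  rows <- purrr::map(tables, function(tb) {
    pooled <- pool(tb, scheme)
    cats <- scheme$pooled_levels
    has_dist <- "distance" %in% names(pooled) && !drop_distance
    total_dist <- if (has_dist) sum(pooled$distance) else NA_real_
    feats <- purrr::map(seq_len(nrow(windows)), function(i) {
      inw <- pooled$bintodark >= windows$start[i] & pooled$bintodark < windows$end[i]
      secs <- colSums(as.matrix(pooled[inw, cats, drop = FALSE]))
      tot <- sum(secs)
      if (tot <= 0) {
        bseq_abort(paste0("window ", windows$id[i], " has zero behavior time"),
                   "empty_window")
      }
      v <- sqrt(secs / tot)
      names(v) <- paste0(cats, "__", windows$id[i])
      if (has_dist) {
        dv <- if (total_dist > 0) sqrt(sum(pooled$distance[inw]) / total_dist) else 0
        v <- c(v, setNames(dv, paste0(scheme$distance_label, "__", windows$id[i])))
      }
      v
    })
    c(list(animal_id = tb$animal_id[1], test_id = tb$test_id[1],
           group = tb$group[1]), as.list(unlist(feats)))
  })
  out <- bind_rows(purrr::map(rows, as_tibble))
  attr(out, "scheme") <- scheme$name
  attr(out, "windows") <- windows$id
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Feature column names of a feature matrix
#' @param matrix a feature matrix.
#' @return character vector of `<category>__<window>` columns.
#' @export
feature_cols <- function(matrix) {
  setdiff(names(matrix), c("animal_id", "test_id", "group",
                           "project", "age_months"))
}

#' Remove tests flagged as excluded in the experiment metadata
#'
#' @param matrix feature matrix (rows keyed by `animal_id`, `test_id`).
#' @param rows experiment tibble with `animal_id`, `test_id` and an
#'   optional `exclude` column.
#' @return feature matrix without the excluded rows.
#' @export
apply_exclusions <- function(matrix, rows) {
  if (!"exclude" %in% names(rows)) return(matrix)
  drop <- rows[is_excluded(rows$exclude), c("animal_id", "test_id")]
  keep <- !(paste(matrix$animal_id, matrix$test_id) %in%
              paste(drop$animal_id, drop$test_id))
  if (!any(keep)) bseq_abort("all rows excluded", "all_excluded")
  matrix[keep, , drop = FALSE]
}
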