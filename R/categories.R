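#' The canonical 45-label home-cage vocabulary
#'
#' The fixed vocabulary of raw behavior labels emitted by frame-wise
#' video classification of singly housed rodents, plus the horizontal
#' distance-traveled channel (`Travel.m.`). All event and summary inputs
#' are validated against this set.
#'
#' @param behaviors_only if `TRUE`, drop `Travel.m.` (the distance channel,
#'   which is not a behavior state).
#' @return character vector of labels (45, or 44 with `behaviors_only`).
#' @export
hcs_labels <- function(behaviors_only = FALSE) {
  tab <- scheme_table()
  out <- tab$raw_label
  if (behaviors_only) out <- setdiff(out, "Travel.m.")
  out
}

# cached read of the shipped scheme table
scheme_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "category_schemes.csv", package = "bseqlab")
      cache <<- readr::read_csv(path, col_types = "ccc", na = character())
    }
    cache
  }
})

#' Category pooling schemes
#'
#' Builds one of the three shipped pooling schemes over the 45 raw labels:
#' \describe{
#'   \item{berlin}{18 pooled categories (incl. `Distance_traveled`): rare
#'     behavior types merged so every category has reasonable occupancy.}
#'   \item{jhuang}{10 pooled categories (incl. `Distance_traveled`):
#'     the label set an open-source classifier can detect.}
#'   \item{raw38}{the 38 base behavior categories obtained from the raw 45 by
#'     dropping `No.Data` and `Arousal`, pooling the three drink and three eat
#'     zones into `Drink`/`Eat`, and moving `Travel.m.` to the distance slot.}
#' }
#' Labels mapped to the empty string are discarded. The mapping also covers
#' the 38 base labels so pooled schemes can be applied to base-38 tables.
#'
#' @param name one of `"berlin"`, `"jhuang"`, `"raw38"`.
#' @return a `category_scheme`: list with `name`, `mapping` (tibble
#'   `source_label`, `pooled_label`, `""` = discard), `pooled_levels`
#'   (behavior categories, distance excluded), and `distance_label`.
#' @export
category_scheme <- function(name = c("berlin", "jhuang", "raw38")) {
  name <- match.arg(name)
  tab <- scheme_table()
  base38 <- base38_map()
  if (name == "raw38") {
    mapping <- base38
  } else {
    col <- if (name == "berlin") tab$berlin_label else tab$jhuang_label
    mapping <- tibble(source_label = tab$raw_label, pooled_label = col)
    # extend over the base-38 labels (identity through the drink/eat pools)
    extra <- mapping %>%
      left_join(base38, by = c(source_label = "source_label")) %>%
      filter(.data$pooled_label.y != "", .data$pooled_label.y != .data$source_label) %>%
      distinct(source_label = .data$pooled_label.y, pooled_label = .data$pooled_label.x)
    mapping <- bind_rows(mapping, extra) %>% distinct()
  }
  pooled <- setdiff(unique(mapping$pooled_label), c("", "Distance_traveled"))
  structure(
    list(name = name, mapping = mapping,
         pooled_levels = sort(pooled), distance_label = "Distance_traveled"),
    class = "category_scheme"
  )
}

# raw 45 -> base 38 (+ distance slot, + discards)
base38_map <- function() {
  tab <- scheme_table()
  raw <- tab$raw_label
  pooled <- raw
  pooled[raw %in% c("No.Data", "Arousal")] <- ""
  pooled[grepl("^Drnk\\.", raw)] <- "Drink"
  pooled[grepl("^Eat\\.", raw)] <- "Eat"
  pooled[raw == "Travel.m."] <- "Distance_traveled"
  tibble(source_label = raw, pooled_label = pooled)
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme>", x$name, "-", length(x$pooled_levels),
      "behavior categories (+ distance)\n")
  invisible(x)
}

minute_meta_cols <- c("animal_id", "test_id", "group", "minute_index",
                      "bintodark", "phase")

# split a minute table into metadata / behavior label / distance columns
split_minute_cols <- function(minute_table) {
  cols <- names(minute_table)
  meta <- intersect(minute_meta_cols, cols)
  dist <- intersect(c("Travel.m.", "Distance_traveled", "distance"), cols)
  list(meta = meta, labels = setdiff(cols, c(meta, dist)), distance = dist)
}

#' Derive the 38 base behavior categories from a raw 45-label minute table
#'
#' Pools the three drink zones into `Drink` and the three eat zones into
#' `Eat`, drops `No.Data` and `Arousal`, and moves `Travel.m.` to a
#' `distance` column (the horizontal distance traveled is not a behavior
#' category). Exactly 38 behavior columns remain.
#'
#' @param minute_table a minute table whose behavior columns are raw labels.
#' @return minute table with 38 behavior columns and an optional `distance`.
#' @export
derive_base38 <- function(minute_table) {
  pool(minute_table, category_scheme("raw38"))
}

#' Pool minute-table behavior columns under a category scheme
#'
#' Each pooled column is the sum of its source columns; per-minute total
#' time is conserved, apart from discarded labels. A `Travel.m.` (or
#' already-derived `distance`) column is carried through unchanged as
#' `distance`, never pooled into behavior.
#'
#' @param minute_table minute table (raw 45 or base 38 behavior columns).
#' @param scheme a [category_scheme()].
#' @return pooled minute table: metadata columns, one column per pooled
#'   behavior category (all scheme levels present, zero-filled), optional
#'   `distance`.
#' @export
pool <- function(minute_table, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  parts <- split_minute_cols(minute_table)
  map <- setNames(scheme$mapping$pooled_label, scheme$mapping$source_label)
  unknown <- setdiff(parts$labels, names(map))
  if (length(unknown) > 0) {
    bseq_abort(paste0("unmapped behavior column(s): ",
                      paste(unknown, collapse = ", ")), "unmapped_label")
  }
  out <- minute_table[parts$meta]
  vals <- as.matrix(minute_table[parts$labels])
  targets <- map[parts$labels]
  for (lvl in scheme$pooled_levels) {
    src <- parts$labels[targets == lvl]
    out[[lvl]] <- if (length(src) > 0) rowSums(vals[, src, drop = FALSE]) else 0
  }
  if (length(parts$distance) > 0) {
    out$distance <- minute_table[[parts$distance[[1]]]]
  }
  out
}
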