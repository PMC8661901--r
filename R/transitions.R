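#' Behavior-transition context around a focal behavior
#'
#' For every occurrence of the focal behavior in each animal's event
#' sequence, records the immediately preceding and immediately following
#' behavior. Consecutive identical labels are first merged into runs, so
#' "preceding" means the previous \emph{distinct} state (frame-wise
#' classifiers emit repeated labels). Each focal occurrence counts equally,
#' regardless of duration. Occurrences at the start (end) of a sequence
#' contribute no before (after) observation.
#'
#' @param seqs list of `behavior_sequence` objects.
#' @param focal focal raw label (e.g. `"LandVert"`).
#' @param top_k number of context labels to keep in the summary, ranked by
#'   median per-animal percentage.
#' @return a `transition_context`: list with `per_animal` (tibble
#'   `animal_id`, `side`, `label`, `n`, `pct` — per animal and side the
#'   percentages sum to 100), `summary` (per side the `top_k` labels with
#'   `mean_pct`, `median_pct`, `n_animals`), `focal`, `n_occurrences`.
#' @export
transition_context <- function(seqs, focal, top_k = 8L) {
  if (!focal %in% hcs_labels(behaviors_only = TRUE)) {
    bseq_abort(paste0("unknown focal label: ", focal), "unknown_label")
  }
  per <- purrr::map(seqs, function(sq) {
    runs <- rle(sq$events$label)$values
    pos <- which(runs == focal)
    before <- runs[pos[pos > 1] - 1]
    after <- runs[pos[pos < length(runs)] + 1]
    if (length(pos) == 0) return(NULL)
    bind_rows(
      tibble(side = "before", label = before),
      tibble(side = "after", label = after)
    ) %>%
      group_by(.data$side, .data$label) %>%
      summarise(n = n(), .groups = "drop_last") %>%
      mutate(pct = 100 * .data$n / sum(.data$n)) %>%
      ungroup() %>%
      mutate(animal_id = sq$animal_id, n_focal = length(pos))
  })
  per <- bind_rows(per)
  if (nrow(per) == 0) {
    bseq_warn(paste0("focal behavior '", focal, "' never occurs"), "no_focal")
    return(structure(list(per_animal = per, summary = tibble(),
                          focal = focal, n_occurrences = 0L),
                     class = "transition_context"))
  }
  # within each side, animals that observed the side but not a given context
  # label contribute 0% for that label
  full <- per %>%
    group_by(.data$side) %>%
    tidyr::complete(.data$animal_id, .data$label, fill = list(n = 0L, pct = 0)) %>%
    ungroup()
  summ <- full %>%
    group_by(.data$side, .data$label) %>%
    summarise(mean_pct = mean(.data$pct), median_pct = median(.data$pct),
              n_animals = sum(.data$n > 0), .groups = "drop") %>%
    group_by(.data$side) %>%
    arrange(desc(.data$median_pct), desc(.data$mean_pct), .data$label,
            .by_group = TRUE) %>%
    dplyr::slice_head(n = top_k) %>%
    ungroup()
  structure(list(per_animal = select(per, "animal_id", "side", "label",
                                     "n", "pct"),
                 summary = summ, focal = focal,
                 n_occurrences = sum(distinct(per, .data$animal_id,
                                              .data$n_focal)$n_focal)),
            class = "transition_context")
}

#' @export
print.transition_context <- function(x, ...) {
  cat("<transition_context> focal =", x$focal, "-", x$n_occurrences,
      "occurrence(s)\n")
  if (nrow(x$summary) > 0) print(as.data.frame(x$summary))
  invisible(x)
}
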