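# Fixture builders shared across the suite. Everything is generated in code;
# no data files are read from disk except those a test writes itself.

# a random contiguous behavior sequence over a label subset (integer seconds)
rand_sequence <- function(n_events = 50, seed = 1,
                          labels = c("Sleep", "WalkLeft", "Eat.Z1.", "Groom",
                                     "Sniff", "RearUp"),
                          max_dwell = 90, animal_id = "A01") {
  set.seed(seed)
  dwell <- sample.int(max_dwell, n_events, replace = TRUE)
  ends <- cumsum(dwell)
  starts <- c(0, ends[-n_events])
  behavior_sequence(
    tibble::tibble(start_s = starts, end_s = ends,
                   label = sample(labels, n_events, replace = TRUE)),
    animal_id = animal_id, test_id = "T1"
  )
}

# per-second brute-force oracle: seconds per label per minute
second_oracle <- function(seq) {
  ev <- seq$events
  n_min <- floor(max(ev$end_s) / 60)
  lab_per_sec <- character(n_min * 60)
  for (i in seq_len(nrow(ev))) {
    s <- ev$start_s[i]; e <- min(ev$end_s[i], n_min * 60)
    if (e > s) lab_per_sec[(s + 1):e] <- ev$label[i]
  }
  minute <- rep(seq_len(n_min) - 1L, each = 60)
  tab <- table(minute = minute[lab_per_sec != ""],
               label = lab_per_sec[lab_per_sec != ""])
  as.data.frame.matrix(tab)
}

# Gaussian feature matrix with an optional planted mean shift on the first
# `n_shift` columns of the second group
gauss_matrix <- function(n_per_group = 10, p = 20, delta = 0, n_shift = 3,
                         seed = 1, groups = c("g1", "g2")) {
  set.seed(seed)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * p), n, p)
  n_shift <- min(n_shift, p)
  X[(n_per_group + 1):n, seq_len(n_shift)] <-
    X[(n_per_group + 1):n, seq_len(n_shift)] + delta
  colnames(X) <- sprintf("V%02d__W1", seq_len(p))
  out <- tibble::as_tibble(X)
  out$animal_id <- sprintf("A%02d", seq_len(n))
  out$test_id <- "T1"
  out$group <- rep(groups, each = n_per_group)
  dplyr::select(out, animal_id, test_id, group, dplyr::everything())
}

# small synthetic lab schedule: lights off 19:00, on 07:00
test_lab <- function() list(lab_id = "L", light_off_min = 19L * 60L,
                            light_on_min = 7L * 60L)

# in-memory synthetic cohort: sequences -> synchronized minute tables,
# skipping the disk round-trip (the on-disk path is tested separately)
sim_cohort_tables <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  start0 <- as.POSIXct(cfg$recording_start, tz = "UTC")
  lab <- list(light_off_min = bseqlab:::parse_hhmm(cfg$light_off, "off"),
              light_on_min = bseqlab:::parse_hhmm(cfg$light_on, "on"))
  idx <- 0
  out <- list()
  for (g in seq_along(cfg$groups)) {
    for (a in seq_len(cfg$n_per_group)) {
      idx <- idx + 1
      animal <- sprintf("A%02d", idx)
      sq <- bseqlab:::simulate_sequence(cfg, g, animal, "T1", start0)
      row <- list(animal_id = animal, test_id = "T1",
                  recording_start = start0, grp = cfg$groups[g])
      out[[idx]] <- synchronize(events_to_minutes(sq), row, lab,
                                group_by = "grp")
    }
  }
  out
}

# full in-memory cohort feature matrix under the generator's default
# conditions (Berlin scheme, all nine windows, no distance channel)
sim_cohort_features <- function(cfg, seed = cfg$seed) {
  tables <- sim_cohort_tables(cfg, seed)
  span <- c(min(tables[[1]]$bintodark), max(tables[[1]]$bintodark) + 1)
  win <- define_windows(list(light_off_min = bseqlab:::parse_hhmm(cfg$light_off, "off"),
                             light_on_min = bseqlab:::parse_hhmm(cfg$light_on, "on")),
                        span)
  win <- available_windows(tables, win)
  build_features(tables, win, category_scheme("berlin"))
}
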