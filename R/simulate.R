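#' Configuration for the synthetic project generator
#'
#' Defines a fake single-housed home-cage study: each animal is recorded
#' once for ~23 h spanning one light-off event, behavior is generated by a
#' semi-Markov chain over the 44 raw behavior labels (propensity-weighted
#' state draws, no immediate self-transitions, exponential dwell times
#' rounded to whole seconds), with circadian modulation (active labels
#' up-weighted at NIGHT, resting labels at DAY) and optional multiplicative
#' group effects on chosen labels in a chosen phase.
#'
#' Defaults mirror a typical cohort: 11 animals per group, a 1380-min
#' (23-h) recording starting at 12:00 with lights off 19:00 and on 07:00
#' (so all nine time windows are covered), and a planted strong night
#' activity phenotype in the second group: walking propensity doubled and
#' sleep propensity reduced (x0.6) during NIGHT. Shifting only a minor
#' category such as walking is detectable variable-by-variable but barely
#' moves a variance-based first principal component; the paired shift on
#' the dominant rest category makes the planted effect strong in the
#' multivariate sense as well.
#'
#' @param n_per_group animals per group.
#' @param groups group labels (the value of `group_by`).
#' @param group_by experiment-metadata grouping column name.
#' @param recording_min recording length in minutes.
#' @param recording_start first recording's start (`"YYYY-MM-DD HH:MM"`);
#'   successive animals start on successive days at the same time.
#' @param light_off,light_on facility light schedule (`"HH:MM"`).
#' @param circadian_amp weight multiplier applied to active labels at NIGHT
#'   and to resting labels at DAY.
#' @param effect data frame `label`, `phase` (`"DAY"`/`"NIGHT"`/`"BOTH"`),
#'   `mult` — multiplicative propensity shifts applied to every group after
#'   the first; `NULL` for exchangeable groups.
#' @param baseline data frame `label`, `weight`, `dwell_s` overriding the
#'   built-in propensity table.
#' @param data_kind which file the experiment metadata points at as primary
#'   data: `"minute_summary"` (default; carries the simulated distance
#'   channel, so the full 162-column feature path is exercised) or
#'   `"events"`. Both files are always written.
#' @param proj_name project name used in the master registry.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group = 11L, groups = c("young", "old"),
                       group_by = "Treatment", recording_min = 1380L,
                       recording_start = "2015-03-02 12:00",
                       light_off = "19:00", light_on = "07:00",
                       circadian_amp = 2,
                       effect = data.frame(
                         label = c("WalkLeft", "WalkRght", "WalkSlow", "Sleep"),
                         phase = "NIGHT", mult = c(2, 2, 2, 0.6)),
                       baseline = NULL,
                       data_kind = c("minute_summary", "events"),
                       proj_name = "SYN_testdata", seed = 1L) {
  data_kind <- match.arg(data_kind)
  stopifnot(n_per_group >= 1, recording_min >= 60, circadian_amp > 0)
  base <- baseline %||% default_baseline()
  stopifnot(all(base$weight > 0), all(base$dwell_s > 0))
  if (!is.null(effect)) stopifnot(all(effect$mult > 0))
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 group_by = group_by, recording_min = as.integer(recording_min),
                 recording_start = recording_start, light_off = light_off,
                 light_on = light_on, circadian_amp = circadian_amp,
                 effect = effect, baseline = base, data_kind = data_kind,
                 proj_name = proj_name, seed = as.integer(seed)),
            class = "sim_config")
}

# built-in dwell/propensity table over the 44 behavior labels; weights are
# relative draw propensities, dwell_s the mean exponential dwell. "rest"
# labels are down-weighted at NIGHT by the circadian modulation.
default_baseline <- function() {
  tab <- tibble(
    label = c("Sleep", "Stationa", "Pause", "Twitch", "Groom",
              "Eat.Z1.", "Eat.Z2.", "Eat.Z3.", "Chew",
              "Drnk.S1.", "Drnk.S2.", "Drnk.S3.",
              "WalkLeft", "WalkRght", "WalkSlow", "Turn", "Circle",
              "RearUp", "ComeDown", "Stretch", "CDfromPR", "CDtoPR",
              "RUfromPR", "RUtoPR", "RemainRU", "RemainPR", "RemainLw",
              "HangCudl", "HangVert", "HVfromRU", "HVfromHC", "LandVert",
              "RemainHV", "RemainHC",
              "Sniff", "Awaken", "Jump", "ReptJump", "Dig", "Forage",
              "Unknown", "Urinate", "Arousal", "No.Data"),
    weight = c(30, 10, 10, 5, 8,
               4, 2, 1, 2,
               3, 1.5, 0.5,
               6, 6, 3, 2, 1,
               4, 3, 2, 0.8, 0.8,
               0.8, 0.8, 1.5, 0.8, 3,
               1.5, 1.5, 0.6, 0.6, 1.2,
               0.8, 0.8,
               6, 1, 0.5, 0.3, 2, 2,
               1, 0.3, 0.3, 0.2),
    dwell_s = c(300, 120, 30, 5, 60,
                40, 40, 40, 20,
                15, 15, 15,
                8, 8, 10, 4, 5,
                6, 4, 5, 3, 3,
                3, 3, 10, 8, 20,
                12, 10, 5, 5, 3,
                8, 8,
                10, 10, 3, 3, 20, 15,
                5, 5, 10, 10),
    rest = FALSE
  )
  tab$rest[tab$label %in% c("Sleep", "Stationa", "Pause", "Twitch")] <- TRUE
  tab
}

# generate one animal's behavior sequence (integer-second events)
simulate_sequence <- function(cfg, group_index, animal_id, test_id,
                              recording_start) {
  base <- cfg$baseline
  night_len <- (parse_hhmm(cfg$light_on, "light_on") -
                  parse_hhmm(cfg$light_off, "light_off")) %% 1440
  midnight_min <- as.numeric(format(recording_start, "%H")) * 60 +
    as.numeric(format(recording_start, "%M"))
  to_dark <- (parse_hhmm(cfg$light_off, "light_off") - midnight_min) %% 1440

  w_phase <- function(phase) {
    w <- base$weight
    if (phase == "NIGHT") {
      w <- ifelse(base$rest, w / cfg$circadian_amp, w * cfg$circadian_amp)
    } else {
      w <- ifelse(base$rest, w * cfg$circadian_amp, w / cfg$circadian_amp)
    }
    if (group_index > 1 && !is.null(cfg$effect)) {
      for (i in seq_len(nrow(cfg$effect))) {
        if (cfg$effect$phase[i] %in% c(phase, "BOTH")) {
          w[base$label == cfg$effect$label[i]] <-
            w[base$label == cfg$effect$label[i]] * cfg$effect$mult[i]
        }
      }
    }
    w
  }
  w_day <- w_phase("DAY"); w_night <- w_phase("NIGHT")

  T_s <- cfg$recording_min * 60
  starts <- ends <- numeric(0); labels <- character(0)
  t <- 0; prev <- 0L
  while (t < T_s) {
    btd <- floor(t / 60) - to_dark
    night <- (btd %% 1440) < night_len
    w <- if (night) w_night else w_day
    if (prev > 0L) w[prev] <- 0  # no immediate self-transition
    i <- sample.int(nrow(base), 1, prob = w)
    dwell <- max(1, round(rexp(1, 1 / base$dwell_s[i])))
    starts <- c(starts, t); ends <- c(ends, min(t + dwell, T_s))
    labels <- c(labels, base$label[i])
    t <- t + dwell
    prev <- i
  }
  behavior_sequence(tibble(start_s = starts, end_s = ends, label = labels),
                    animal_id = animal_id, test_id = test_id,
                    recording_start = recording_start)
}

#' Generate a complete synthetic project on disk
#'
#' Writes a master registry row, experiment and lab metadata, one event TSV
#' and one minute-summary CSV per animal (the summary is the exact
#' [events_to_minutes()] aggregation of the events plus a simulated
#' `Travel.m.` distance column — a noisy linear function of walking
#' seconds). The generated project passes [validate_project()] with an
#' empty report. Output is deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @param out_dir directory to create the project in.
#' @return invisibly, a list with `master_file`, `project_id` and the
#'   generated `sequences`.
#' @export
simulate_project <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  root <- file.path(out_dir, cfg$proj_name)
  dir.create(file.path(root, "raw"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "metadata"), recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  start0 <- parse_datetime(cfg$recording_start, "recording_start")
  walk_cols <- c("WalkLeft", "WalkRght", "WalkSlow", "Turn", "Circle")
  rows <- list(); seqs <- list()
  idx <- 0
  for (g in seq_along(cfg$groups)) {
    for (a in seq_len(cfg$n_per_group)) {
      idx <- idx + 1
      animal <- sprintf("A%02d", idx)
      rs <- start0 + (idx - 1) * 86400  # one animal per day, same clock time
      sq <- simulate_sequence(cfg, g, animal, "T1", rs)
      seqs[[idx]] <- sq
      ev_file <- file.path("raw", paste0(animal, "_T1.tsv"))
      readr::write_tsv(sq$events, file.path(root, ev_file))
      mins <- events_to_minutes(sq)
      walk_s <- rowSums(as.matrix(mins[walk_cols]))
      mins$Travel.m. <- round(pmax(0, 0.05 * walk_s + rnorm(nrow(mins), 0, 0.05)), 3)
      min_file <- file.path("raw", paste0(animal, "_T1_min.csv"))
      readr::write_csv(mins, file.path(root, min_file))
      rows[[idx]] <- tibble(
        animal_id = animal, test_id = "T1",
        "{cfg$group_by}" := cfg$groups[g],
        birth_date = format(start0 - 90 * 86400, "%Y-%m-%d"),
        recording_start = format(rs, "%Y-%m-%d %H:%M"),
        data_file = if (cfg$data_kind == "events") basename(ev_file) else
          basename(min_file),
        data_kind = cfg$data_kind,
        event_file = basename(ev_file), minute_file = basename(min_file),
        exclude = "")
    }
  }
  experiment <- bind_rows(rows)
  master <- list(
    identifier = paste0("SYN-", cfg$seed), proj_name = cfg$proj_name,
    title = "Synthetic home-cage recordings (generated)",
    creator = "bseqlab simulate", production_year = "2015",
    subject_area = "Behavioral neurobiology", resource = "Dataset",
    rights = "CC0",
    description_comments = "Synthetic semi-Markov behavior sequences for testing.",
    video_acquisition = "synthetic", video_analysis = "synthetic",
    group_by = cfg$group_by, confound_by = "", source_data = "local",
    folder_path = cfg$proj_name, raw_data_folder = "raw",
    animal_metadata = "metadata/experiment.csv",
    lab_metadata = "metadata/lab.csv", identifier_metadata = "")
  lab <- list(lab_id = "SYNLAB", light_off_time = cfg$light_off,
              light_on_time = cfg$light_on, timezone_note = "simulated, UTC")
  master_file <- file.path(out_dir, "master.csv")
  write_project(master, experiment, lab, master_file)
  invisible(list(master_file = master_file, project_id = master$identifier,
                 sequences = seqs))
}

#' Inject a known defect into one animal's minute-summary file
#'
#' Emulates a corrupted spreadsheet export: the defect is written into the
#' animal's minute summary (never its event file) and the experiment row is
#' repointed at the corrupted summary (`data_kind = "minute_summary"`), so
#' the downstream pipeline actually consumes it and [check_consistency()]
#' against the untouched events must flag it.
#'
#' Modes: `shift_minutes` (behavior rows displaced by `minutes`),
#' `scale_category` (one behavior column multiplied by `factor`),
#' `truncate` (last `minutes` rows removed).
#'
#' @param master_file,project_id project to corrupt (modified in place).
#' @param animal_id,test_id target test (defaults to the first row).
#' @param mode one of `"shift_minutes"`, `"scale_category"`, `"truncate"`.
#' @param minutes shift/truncation size in minutes.
#' @param category behavior column for `scale_category`.
#' @param factor multiplier for `scale_category`.
#' @return the ground-truth defect description (list), invisibly.
#' @export
corrupt_project <- function(master_file, project_id,
                            animal_id = NULL, test_id = NULL,
                            mode = c("scale_category", "shift_minutes", "truncate"),
                            minutes = 120L, category = "Eat.Z1.", factor = 0.5) {
  mode <- match.arg(mode)
  bundle <- load_project(master_file, project_id)
  ex <- bundle$experiment
  i <- if (is.null(animal_id)) 1L else {
    which(ex$animal_id == animal_id &
            (is.null(test_id) | ex$test_id == (test_id %||% ex$test_id)))[1]
  }
  if (is.na(i)) bseq_abort("target test not found", "unknown_test")
  raw_dir <- file.path(bundle$root, bundle$master$raw_data_folder)
  min_path <- file.path(raw_dir, ex$minute_file[i])
  tab <- readr::read_csv(min_path, col_types = readr::cols(.default = "d"),
                         show_col_types = FALSE)
  parts <- split_minute_cols(tab)
  if (mode == "scale_category") {
    if (!category %in% parts$labels) bseq_abort("unknown category", "unknown_label")
    tab[[category]] <- tab[[category]] * factor
  } else if (mode == "shift_minutes") {
    k <- as.integer(minutes)
    vals <- tab[c(parts$labels, parts$distance)]
    tab[c(parts$labels, parts$distance)] <-
      vals[c((nrow(vals) - k + 1):nrow(vals), 1:(nrow(vals) - k)), ]
  } else {
    tab <- tab[seq_len(max(1, nrow(tab) - as.integer(minutes))), ]
  }
  readr::write_csv(tab, min_path)
  ex$data_file[i] <- ex$minute_file[i]
  ex$data_kind[i] <- "minute_summary"
  write_project(bundle$master, ex, bundle$lab, master_file)
  invisible(list(mode = mode, animal_id = ex$animal_id[i],
                 test_id = ex$test_id[i], minutes = minutes,
                 category = category, factor = factor, file = min_path))
}
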