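#' Load and synchronize every (non-excluded) test of a project
#'
#' Reads each experiment row's data file ([read_test_data()]) and
#' synchronizes it to the light/dark cycle ([synchronize()]).
#'
#' @param bundle a [load_project()] result.
#' @param keep_excluded keep rows flagged `exclude` (they are still loaded
#'   but dropped from analyses by default).
#' @return named list of synchronized minute tables (`animal_id/test_id`).
#' @export
load_sync_tables <- function(bundle, keep_excluded = FALSE) {
  ex <- bundle$experiment
  if (!keep_excluded && "exclude" %in% names(ex)) {
    ex <- ex[!is_excluded(ex$exclude), , drop = FALSE]
  }
  gb <- bundle$master$group_by
  out <- lapply(seq_len(nrow(ex)), function(i) {
    row <- ex[i, , drop = FALSE]
    synchronize(read_test_data(bundle, row), row, bundle$lab, group_by = gb)
  })
  names(out) <- paste(ex$animal_id, ex$test_id, sep = "/")
  out
}

#' Hourly activity summary synchronized to light-off
#'
#' Aggregates synchronized minutes into hours relative to the light-off
#' event (hour 0 starts at lights-off) and reports, per group, category and
#' hour, the mean and SD across animals of the percentage of covered time
#' spent in the category.
#'
#' @param tables list of synchronized minute tables.
#' @param scheme a [category_scheme()].
#' @param full_hours_only drop hours not fully covered (60 minutes) by an
#'   animal.
#' @return `hourly_summary` tibble: `group`, `category`, `hour`,
#'   `mean_pct`, `sd_pct`, `n`.
#' @export
hourly_summary <- function(tables, scheme, full_hours_only = TRUE) {
  per_animal <- purrr::map(tables, function(tb) {
    pooled <- pool(tb, scheme)
    cats <- scheme$pooled_levels
    pooled %>%
      mutate(hour = floor(.data$bintodark / 60)) %>%
      group_by(.data$animal_id, .data$test_id, .data$group, .data$hour) %>%
      summarise(n_min = n(),
                covered = sum(rowSums(as.matrix(dplyr::pick(all_of(cats))))),
                across(all_of(cats), sum), .groups = "drop")
  }) %>% bind_rows()
  if (full_hours_only) per_animal <- filter(per_animal, .data$n_min == 60)
  long <- per_animal %>%
    tidyr::pivot_longer(all_of(scheme$pooled_levels), names_to = "category",
                        values_to = "seconds") %>%
    mutate(pct = 100 * .data$seconds / .data$covered)
  out <- long %>%
    group_by(.data$group, .data$category, .data$hour) %>%
    summarise(mean_pct = mean(.data$pct), sd_pct = sd(.data$pct), n = n(),
              .groups = "drop")
  class(out) <- c("hourly_summary", class(out))
  out
}

#' Plot one category's hourly time course (mean +/- SD per group)
#' @param summary an [hourly_summary()] result.
#' @param category pooled category to plot.
#' @return a ggplot (x axis: hours, lights off at 0).
#' @export
plot_hourly <- function(summary, category) {
  dat <- filter(summary, .data$category == !!category)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hour, y = .data$mean_pct,
                                    color = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean_pct - .data$sd_pct),
                                      ymax = .data$mean_pct + .data$sd_pct,
                                      fill = .data$group),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time (h, lights off at 0)",
                  y = paste0("% time in ", category),
                  title = category) +
    ggplot2::theme_minimal()
}

#' Histogram of the permutation accuracy cloud with the observed value
#' @param ml an `ml_result` from [permutation_pvalue()].
#' @return a ggplot.
#' @export
plot_permutation_cloud <- function(ml) {
  stopifnot(!is.null(ml$perm_accuracies))
  ggplot2::ggplot(tibble(accuracy = ml$perm_accuracies),
                  ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = ml$accuracy, color = "red") +
    ggplot2::labs(x = "pooled validation accuracy",
                  y = "permutations",
                  title = sprintf("%s SVM, %s validation (%d permutations)",
                                  ml$kernel, ml$scheme, ml$n_permutations)) +
    ggplot2::theme_minimal()
}

#' Pool feature matrices across projects for meta-analysis
#'
#' Builds features per project with an identical scheme and window set,
#' concatenates them, runs a pooled PCA, and returns PC1 against the
#' animal's age (months, from `birth_date` to `recording_start` at 30.44
#' days/month) with the group value as covariate. Projects missing a
#' required covariate or not covering the requested windows are rejected
#' with the reason recorded.
#'
#' @param bundles list of [load_project()] results.
#' @param window_ids window ids (e.g. `paste0("W", 1:9)`).
#' @param scheme a [category_scheme()].
#' @param drop_distance see [build_features()].
#' @return list with `table` (tibble `animal_id`, `test_id`, `project`,
#'   `group`, `age_months`, `pc1`), `features` (pooled matrix), `rejected`
#'   (tibble `project`, `reason`).
#' @export
pool_projects <- function(bundles, window_ids = paste0("W", 1:9), scheme,
                          drop_distance = TRUE) {
  rejected <- list(); mats <- list()
  for (b in bundles) {
    pid <- b$master$proj_name
    reason <- NULL
    if (!"birth_date" %in% names(b$experiment) ||
        any(!nzchar(trimws(b$experiment$birth_date)))) {
      reason <- "birth date of the animals not provided"
    } else {
      tables <- load_sync_tables(b)
      span <- range_span(tables)
      win <- tryCatch(define_windows(b$lab, span), bseqlab_error = conditionMessage)
      if (is.character(win)) {
        reason <- win
      } else {
        avail <- available_windows(tables, win)
        missing <- setdiff(window_ids, avail$id)
        if (length(missing) > 0) {
          reason <- paste0("window(s) without data: ", paste(missing, collapse = ", "))
        }
      }
    }
    if (!is.null(reason)) {
      rejected[[length(rejected) + 1]] <- tibble(project = pid, reason = reason)
      next
    }
    m <- build_features(tables, win[win$id %in% window_ids, ], scheme,
                        drop_distance = drop_distance)
    ex <- b$experiment
    age <- as.numeric(difftime(
      vapply(ex$recording_start, function(x) parse_datetime(x, "recording_start"),
             numeric(1)) |> as.POSIXct(tz = "UTC", origin = "1970-01-01"),
      as.POSIXct(ex$birth_date, tz = "UTC"), units = "days")) / 30.44
    m <- left_join(m, tibble(animal_id = ex$animal_id, test_id = ex$test_id,
                             age_months = age),
                   by = c("animal_id", "test_id"))
    m$project <- pid
    mats[[length(mats) + 1]] <- m
  }
  if (length(mats) == 0) bseq_abort("no project could be pooled", "nothing_pooled")
  pooled <- bind_rows(mats)
  cols <- feature_cols(pooled)
  pc <- prcomp(as.matrix(pooled[cols]), center = TRUE, scale. = FALSE)
  tab <- bind_cols(pooled[c("animal_id", "test_id", "project", "group",
                            "age_months")],
                   tibble(pc1 = unname(pc$x[, 1])))
  list(table = tab, features = pooled,
       rejected = if (length(rejected)) bind_rows(rejected) else
         tibble(project = character(), reason = character()))
}

range_span <- function(tables) {
  c(min(vapply(tables, function(tb) min(tb$bintodark), numeric(1))),
    max(vapply(tables, function(tb) max(tb$bintodark), numeric(1))) + 1)
}

software_label <- function() {
  paste0("bseqlab_", as.character(utils::packageVersion("bseqlab")))
}

#' Run the full analysis pipeline on one project
#'
#' End-to-end driver: load and validate the project, ingest and synchronize
#' every test, apply metadata exclusions, resolve the time windows, build
#' the sqrt-proportion feature matrix, run the double-RF selection, the ICA
#' embedding and the PCA first-component group test, optionally the SVM
#' permutation analysis, and write a markdown report plus CSV artifacts.
#' Reports go into a versioned folder (`bseqlab_<version>/`) under
#' `out_dir`; derived data (synchronized minute summaries, feature matrix)
#' into the unversioned `bseqlab/` folder. Input data files are never
#' modified. Every stochastic step's seed is recorded in the report.
#'
#' @param master_file,project_id project to analyze.
#' @param out_dir output directory (default: the project root).
#' @param scheme_name `"berlin"` or `"jhuang"`.
#' @param window_ids window ids to use (intersected with availability is an
#'   error — choose available ones).
#' @param drop_distance drop the distance feature columns.
#' @param do_ml run the SVM permutation analysis.
#' @param kernel SVM kernel for `do_ml`.
#' @param n_perm permutations for `do_ml`.
#' @param repeats two-out repeats.
#' @param seed integer seed for all stochastic steps.
#' @return invisibly, a list with `features`, `selection`, `embedding`,
#'   `pca_test`, `ml` (or NULL), `report_dir`, `derived_dir`,
#'   `report_file`.
#' @export
run_analysis <- function(master_file, project_id, out_dir = NULL,
                         scheme_name = c("berlin", "jhuang"),
                         window_ids = paste0("W", 1:9), drop_distance = FALSE,
                         do_ml = FALSE, kernel = "radial", n_perm = 100L,
                         repeats = 100L, seed = 1L) {
  scheme_name <- match.arg(scheme_name)
  bundle <- load_project(master_file, project_id)
  report <- validate_project(bundle)
  if (any(report$severity == "error")) {
    bseq_abort(paste0("[metadata] project fails validation: ",
                      paste(report$message[report$severity == "error"],
                            collapse = "; ")), "invalid_project")
  }
  out_dir <- out_dir %||% bundle$root
  report_dir <- file.path(out_dir, software_label())
  derived_dir <- file.path(out_dir, "bseqlab")
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(derived_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, bseqlab_error = function(e) {
      bseq_abort(paste0("[", name, "] ", conditionMessage(e)),
                 class = "stage_failure")
    })
  }
  scheme <- category_scheme(scheme_name)
  tables <- stage("ingest", load_sync_tables(bundle))
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]],
                     file.path(derived_dir, paste0(gsub("/", "_", nm),
                                                   "_sync_minutes.csv")))
  }
  win_all <- stage("features", define_windows(bundle$lab, range_span(tables)))
  windows <- win_all[win_all$id %in% window_ids, , drop = FALSE]
  feats <- stage("features",
                 build_features(tables, windows, scheme,
                                drop_distance = drop_distance))
  feats <- stage("features", apply_exclusions(feats, bundle$experiment))
  readr::write_csv(feats, file.path(derived_dir, "feature_matrix.csv"))

  sel <- stage("multivariate_stats", rf_select(feats, seed = seed))
  emb <- stage("multivariate_stats", ica_embed(feats, sel$selected, seed = seed))
  readr::write_csv(emb, file.path(report_dir, "ica_coordinates.csv"))
  pca <- stage("multivariate_stats", pca_group_test(feats))
  readr::write_csv(pca$scores, file.path(report_dir, "pc1_scores.csv"))

  ml <- NULL
  if (do_ml) {
    ml <- stage("ml_validation",
                permutation_pvalue(feats, kernel = kernel, n_perm = n_perm,
                                   seed = seed, repeats = repeats))
    readr::write_csv(tibble(perm_accuracy = ml$perm_accuracies),
                     file.path(report_dir, "permutation_accuracies.csv"))
  }

  report_file <- file.path(report_dir, "report.md")
  writeLines(render_report(bundle, scheme, windows, feats, sel, emb, pca, ml,
                           seed), report_file)
  invisible(list(features = feats, selection = sel, embedding = emb,
                 pca_test = pca, ml = ml, report_dir = report_dir,
                 derived_dir = derived_dir, report_file = report_file))
}

render_report <- function(bundle, scheme, windows, feats, sel, emb, pca, ml,
                          seed) {
  lines <- c(
    paste0("# Behavior-sequence analysis report - ", bundle$master$proj_name),
    "",
    paste0("Software: ", software_label(), "; seed: ", seed),
    paste0("Categorization: ", scheme$name, " (",
           length(scheme$pooled_levels), " behavior categories)"),
    paste0("Time windows: ", paste(windows$id, collapse = ", ")),
    paste0("Animals x tests analyzed: ", nrow(feats), "; feature columns: ",
           length(feature_cols(feats))),
    "",
    "## PCA first-component group test",
    paste0("- method: ", pca$method),
    sprintf("- PC1 variance explained: %.1f%%", 100 * pca$var_explained[1]),
    sprintf("- Z = %.4g, p = %.4g", pca$Z, pca$p),
    if (!is.na(pca$effect_size_r))
      sprintf("- effect size Z/sqrt(n) = %.3g", pca$effect_size_r) else NULL,
    "",
    "## Double random-forest variable selection",
    paste0("- seed: ", sel$seed, "; trees per forest: ", sel$ntree),
    paste0("- pass 1 retained: ", min(20, nrow(sel$pass1)), " of ",
           nrow(sel$pass1), " variables"),
    paste0("- selected (", length(sel$selected), "): ",
           paste(sel$selected, collapse = ", ")),
    "",
    "## ICA embedding",
    paste0("- components: ", sum(grepl("^IC", names(emb))),
           " (coordinates in ica_coordinates.csv)")
  )
  if (!is.null(ml)) {
    lines <- c(lines, "",
      "## SVM permutation analysis",
      paste0("- kernel: ", ml$kernel, "; validation: ", ml$scheme,
             if (!is.na(ml$repeats)) paste0(" (", ml$repeats, " repeats)") else ""),
      sprintf("- pooled accuracy = %.3f, kappa = %.3f", ml$accuracy, ml$kappa),
      paste0("- permutations: ", ml$n_permutations,
             " (labels permuted in the ", ml$perm_scope, " set)"),
      sprintf("- p = %.4g, p-value range [%.4g, %.4g]",
              ml$p, ml$p_range[1], ml$p_range[2]))
  }
  lines[!vapply(lines, is.null, logical(1))]
}
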