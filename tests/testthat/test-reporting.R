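test_that("hourly summary is exact on constant input and anchored at light-off", {
  # 15 s/min walking everywhere -> every full hour is 25% with zero SD
  mk <- function(animal, group) {
    m <- tibble::tibble(minute_index = 0:1379, WalkLeft = 15, Sleep = 45)
    synchronize(m, list(animal_id = animal, test_id = "T1",
                        recording_start = "2015-03-02 12:00", grp = group),
                test_lab(), group_by = "grp")
  }
  hs <- hourly_summary(list(mk("A1", "g1"), mk("A2", "g1")),
                       category_scheme("berlin"))
  walk <- dplyr::filter(hs, category == "Walk")
  expect_true(all(walk$mean_pct == 25))
  expect_true(all(walk$sd_pct == 0))
  expect_true(all(walk$n == 2))
  # hour bins start exactly at the light-off event
  expect_true(0 %in% walk$hour)
  expect_true(all(walk$hour == floor(walk$hour)))
  # recording starts at -420 min -> first full hour is -7
  expect_equal(min(walk$hour), -7)
})

test_that("hourly summary matches a hand-aggregated two-animal fixture", {
  m1 <- tibble::tibble(minute_index = 0:119, WalkLeft = c(rep(10, 60), rep(30, 60)),
                       Sleep = 50)
  m2 <- tibble::tibble(minute_index = 0:119, WalkLeft = c(rep(20, 60), rep(40, 60)),
                       Sleep = 40)
  mk <- function(m, animal) {
    synchronize(m, list(animal_id = animal, test_id = "T1",
                        recording_start = "2015-03-02 19:00", grp = "g"),
                test_lab(), group_by = "grp")
  }
  hs <- hourly_summary(list(mk(m1, "A1"), mk(m2, "A2")), category_scheme("berlin"))
  walk <- dplyr::filter(hs, category == "Walk")
  # hour 0: A1 10/60, A2 20/60; hour 1: A1 30/90, A2 40/80 (of covered time)
  expect_equal(walk$mean_pct[walk$hour == 0],
               mean(c(100 * 10 / 60, 100 * 20 / 60)))
  expect_equal(walk$sd_pct[walk$hour == 0],
               sd(c(100 * 10 / 60, 100 * 20 / 60)))
  expect_equal(walk$mean_pct[walk$hour == 1],
               mean(c(100 * 30 / 80, 100 * 40 / 80)))
})

test_that("plots are well-formed ggplot objects", {
  m <- gauss_matrix(n_per_group = 6, p = 5, delta = 5, seed = 1)
  ml <- permutation_pvalue(m, n_perm = 12, seed = 1, repeats = 5)
  expect_s3_class(plot_permutation_cloud(ml), "ggplot")
  mk <- function(animal) {
    synchronize(tibble::tibble(minute_index = 0:119, WalkLeft = 15, Sleep = 45),
                list(animal_id = animal, test_id = "T1",
                     recording_start = "2015-03-02 19:00", grp = "g"),
                test_lab(), group_by = "grp")
  }
  hs <- hourly_summary(list(mk("A1"), mk("A2")), category_scheme("berlin"))
  expect_s3_class(plot_hourly(hs, "Walk"), "ggplot")
})

test_that("projects pool by concatenation with ages in months", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_per_group = 2, recording_min = 1380, seed = 31)
  p1 <- simulate_project(cfg, d1)
  # same seed, different registry name: byte-identical data, distinct project
  cfg2 <- sim_config(n_per_group = 2, recording_min = 1380, seed = 31,
                     proj_name = "SYN_copy")
  p2 <- simulate_project(cfg2, d2)
  b1 <- load_project(p1$master_file, p1$project_id)
  b2 <- load_project(p2$master_file, p2$project_id)
  pooled <- pool_projects(list(b1, b2), scheme = category_scheme("berlin"))
  expect_equal(nrow(pooled$table), 8)  # sum of per-project cohort sizes
  expect_equal(nrow(pooled$rejected), 0)
  # 90 days before recording start at 30.44 days/month
  expect_equal(pooled$table$age_months[1], 90 / 30.44, tolerance = 0.05)
  # identical duplicated projects give identical PC1 scores across copies
  tab <- pooled$table[order(pooled$table$project, pooled$table$animal_id), ]
  expect_equal(tab$pc1[tab$project == tab$project[1]],
               tab$pc1[tab$project != tab$project[1]], tolerance = 1e-8)
})

test_that("projects without birth dates are rejected with the reason recorded", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulate_project(sim_config(n_per_group = 2, recording_min = 1380,
                                    seed = 32), d1)
  p2 <- simulate_project(sim_config(n_per_group = 2, recording_min = 1380,
                                    seed = 33, proj_name = "SYN_other"), d2)
  # blank out birth dates in the second project
  b2 <- load_project(p2$master_file, p2$project_id)
  ex <- b2$experiment; ex$birth_date <- ""
  write_project(b2$master, ex, b2$lab, p2$master_file)
  bundles <- list(load_project(p1$master_file, p1$project_id),
                  load_project(p2$master_file, p2$project_id))
  pooled <- pool_projects(bundles, scheme = category_scheme("berlin"))
  expect_equal(nrow(pooled$table), 4)
  expect_equal(pooled$rejected$project, "SYN_other")
  expect_match(pooled$rejected$reason, "birth date")
})

test_that("run_analysis produces a complete, reproducible report bundle", {
  dir <- withr::local_tempdir()
  pr <- simulate_project(sim_config(n_per_group = 4, seed = 41), dir)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  res <- run_analysis(pr$master_file, pr$project_id, out_dir = out1,
                      do_ml = TRUE, n_perm = 20, repeats = 10, seed = 7)
  # versioned report folder, unversioned derived-data folder
  ver <- paste0("bseqlab_", utils::packageVersion("bseqlab"))
  expect_true(dir.exists(file.path(out1, ver)))
  expect_true(dir.exists(file.path(out1, "bseqlab")))
  expect_true(file.exists(file.path(out1, "bseqlab", "feature_matrix.csv")))
  expect_true(file.exists(file.path(out1, ver, "ica_coordinates.csv")))
  rep <- readLines(res$report_file)
  expect_true(any(grepl("p = ", rep)))                   # PCA p-value
  expect_true(any(grepl("selected \\(", rep)))          # RF variable list
  expect_true(any(grepl("permutations: 20", rep)))      # n_perm verbatim
  expect_true(any(grepl("seed: 7", rep)))               # seeds recorded
  # rerun with the same seed reproduces the numbers exactly
  res2 <- run_analysis(pr$master_file, pr$project_id, out_dir = out2,
                       do_ml = TRUE, n_perm = 20, repeats = 10, seed = 7)
  expect_identical(readLines(res$report_file), readLines(res2$report_file))
  expect_equal(res2$pca_test$p, res$pca_test$p)
  # input files are never mutated
  b <- load_project(pr$master_file, pr$project_id)
  expect_equal(nrow(validate_project(b)), 0)
})

test_that("run_analysis attaches the failing stage to propagated errors", {
  dir <- withr::local_tempdir()
  pr <- simulate_project(sim_config(n_per_group = 2, recording_min = 600,
                                    seed = 42), dir)
  # 600-min recordings cannot cover all nine windows
  err <- tryCatch(run_analysis(pr$master_file, pr$project_id,
                               out_dir = file.path(dir, "o")),
                  error = conditionMessage)
  expect_match(err, "\\[features\\]")
})
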