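#' @name metadata
#' @title Project metadata: master, experiment and lab spreadsheets
#' @description
#' A project is described by three linked CSV spreadsheets so that every data
#' file can be located by machine:
#' \itemize{
#'   \item a \strong{master} registry with one row per project (descriptive
#'     fields plus the relative paths to the other files and the data folder),
#'   \item an \strong{experiment} file with one row per test (animal id,
#'     group value(s), recording start, data file and kind, optional
#'     `exclude` flag; extra columns are preserved verbatim),
#'   \item a \strong{lab} file giving the light schedule (`light_off_time`,
#'     `light_on_time`, 24-h `"HH:MM"`).
#' }
#' Dates are ISO-8601; `recording_start` is `"YYYY-MM-DD HH:MM[:SS]"`.
NULL

master_required <- c("identifier", "proj_name", "group_by", "folder_path",
                     "animal_metadata", "lab_metadata")
master_known <- c(master_required,
                  c("title", "creator", "contributors", "creator_email",
                    "publisher", "publication_year", "production_year",
                    "subject_area", "resource", "rights", "rights_holder",
                    "description_comments", "funder", "video_acquisition",
                    "video_analysis", "confound_by", "source_data",
                    "raw_data_folder", "video_folder", "identifier_metadata"))

# header variants like "Proj_name", "Funder information" -> lower snake case
normalize_master_names <- function(x) {
  x <- tolower(gsub("[ .]+", "_", trimws(x)))
  x <- gsub("_+", "_", x)
  x[x == "funder_information"] <- "funder"
  x[x == "indentificator_metadata"] <- "identifier_metadata"  # Table-1 spelling
  x[x == "description_comments_"] <- "description_comments"
  x
}

path_is_unsafe <- function(p) {
  is.na(p) || grepl("^([A-Za-z]:)?[/\\\\]", p) || grepl("(^|[/\\\\])\\.\\.([/\\\\]|$)", p)
}

parse_hhmm <- function(x, field) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", trimws(x)))[[1]]
  if (length(m) == 0) {
    bseq_abort(paste0(field, " is not an HH:MM time: '", x, "'"), "bad_time")
  }
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23 || mi > 59) bseq_abort(paste0(field, " out of range: '", x, "'"), "bad_time")
  h * 60L + mi  # minutes after midnight
}

parse_datetime <- function(x, field) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  if (is.na(out)) {
    bseq_abort(paste0("unparseable ", field, ": '", x, "'"), "bad_datetime")
  }
  out
}

#' Does an exclude-column value mark a test as excluded?
#'
#' Any non-empty value other than `"0"`, `"false"`/`"FALSE"`/`"no"` excludes.
#' @param x character vector (or NULL).
#' @return logical vector.
#' @export
is_excluded <- function(x) {
  if (is.null(x)) return(logical(0))
  x <- trimws(as.character(x))
  !(is.na(x) | x == "" | tolower(x) %in% c("0", "false", "no"))
}

#' Load a project bundle from a master metadata registry
#'
#' Reads the master CSV, selects the row whose `identifier` or `proj_name`
#' equals `project_id`, and loads the linked experiment and lab metadata,
#' resolving their paths against the master file's directory and the
#' project's `folder_path`.
#'
#' @param master_file path to the master metadata CSV (one row per project).
#' @param project_id project `identifier` or `proj_name`.
#' @return a `project_bundle`: list with `master` (named list), `experiment`
#'   (tibble, one row per test, extra columns preserved), `lab` (named list
#'   with `light_off_min`/`light_on_min` minutes after midnight), and
#'   `root` (absolute project folder).
#' @export
load_project <- function(master_file, project_id) {
  if (!file.exists(master_file)) {
    bseq_abort(paste0("master metadata file not found: ", master_file), "missing_file")
  }
  reg <- readr::read_csv(master_file, col_types = readr::cols(.default = "c"),
                         na = character(), show_col_types = FALSE)
  names(reg) <- normalize_master_names(names(reg))
  hit <- which(reg$identifier == project_id | reg$proj_name == project_id)
  if (length(hit) != 1) {
    bseq_abort(paste0("unknown project '", project_id, "' in ", master_file),
               "unknown_project")
  }
  master <- as.list(reg[hit, , drop = FALSE])
  master <- lapply(master, function(v) if (is.na(v)) "" else v)

  for (f in master_required) {
    if (is.null(master[[f]]) || !nzchar(master[[f]])) {
      bseq_abort(paste0("master field '", f, "' is empty"), "invalid_master")
    }
  }
  for (f in c("folder_path", "raw_data_folder", "video_folder",
              "animal_metadata", "lab_metadata")) {
    if (!is.null(master[[f]]) && nzchar(master[[f]]) && path_is_unsafe(master[[f]])) {
      bseq_abort(paste0("master path field '", f, "' must be relative: ",
                        master[[f]]), "invalid_master")
    }
  }
  root <- file.path(dirname(master_file), master$folder_path)

  exp_path <- file.path(root, master$animal_metadata)
  lab_path <- file.path(root, master$lab_metadata)
  for (p in c(exp_path, lab_path)) {
    if (!file.exists(p)) {
      bseq_abort(paste0("linked metadata file missing: ", p), "missing_file")
    }
  }
  experiment <- readr::read_csv(exp_path, col_types = readr::cols(.default = "c"),
                                na = character(), show_col_types = FALSE)
  lab_tab <- readr::read_csv(lab_path, col_types = readr::cols(.default = "c"),
                             na = character(), show_col_types = FALSE)
  lab <- as.list(lab_tab[1, , drop = FALSE])
  lab$light_off_min <- parse_hhmm(lab$light_off_time, "light_off_time")
  lab$light_on_min <- parse_hhmm(lab$light_on_time, "light_on_time")
  if (lab$light_off_min == lab$light_on_min) {
    bseq_abort("degenerate light schedule: light_off_time == light_on_time",
               "bad_schedule")
  }
  if ("recording_start" %in% names(experiment)) {
    for (v in experiment$recording_start) parse_datetime(v, "recording_start")
  }
  structure(list(master = master, experiment = experiment, lab = lab, root = root),
            class = "project_bundle")
}

#' Validate a loaded project bundle
#'
#' Checks every schema invariant and the existence of every linked data
#' file. Problems are report rows, never exceptions; an empty report means
#' the project is fully consistent on disk.
#'
#' @param bundle a [load_project()] result.
#' @return tibble with columns `severity` (`"error"`/`"warning"`), `field`,
#'   `message`.
#' @export
validate_project <- function(bundle) {
  rep <- list()
  add <- function(severity, field, message) {
    rep[[length(rep) + 1]] <<- tibble(severity = severity, field = field,
                                      message = message)
  }
  m <- bundle$master
  ex <- bundle$experiment

  for (f in master_required) {
    if (is.null(m[[f]]) || !nzchar(m[[f]])) add("error", f, "required master field is empty")
  }
  gb <- m$group_by
  if (nzchar(gb %||% "") && !gb %in% names(ex)) {
    add("error", "group_by",
        paste0("group_by column '", gb, "' absent from experiment metadata"))
  }
  cb <- m$confound_by %||% ""
  if (nzchar(cb) && !cb %in% names(ex)) {
    add("error", "confound_by",
        paste0("confound_by column '", cb, "' absent from experiment metadata"))
  }
  need <- c("animal_id", "test_id", "recording_start", "data_file", "data_kind")
  for (f in setdiff(need, names(ex))) {
    add("error", f, "required experiment column missing")
  }
  if (all(c("animal_id", "test_id") %in% names(ex))) {
    key <- paste(ex$animal_id, ex$test_id, sep = "\r")
    if (anyDuplicated(key)) {
      add("error", "animal_id/test_id",
          paste0("duplicated test rows: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
    }
  }
  if ("recording_start" %in% names(ex)) {
    for (i in seq_len(nrow(ex))) {
      ok <- tryCatch({parse_datetime(ex$recording_start[i], "recording_start"); TRUE},
                     bseqlab_error = function(e) FALSE)
      if (!ok) add("error", "recording_start",
                   paste0("row ", i, " (", ex$animal_id[i],
                          "): unparseable '", ex$recording_start[i], "'"))
    }
  }
  if ("data_kind" %in% names(ex)) {
    bad <- !ex$data_kind %in% c("events", "minute_summary", "hour_summary")
    for (i in which(bad)) {
      add("error", "data_kind",
          paste0("row ", i, ": unknown data kind '", ex$data_kind[i], "'"))
    }
  }
  if ("data_file" %in% names(ex)) {
    raw_dir <- file.path(bundle$root, m$raw_data_folder %||% "")
    for (i in seq_len(nrow(ex))) {
      p <- file.path(raw_dir, ex$data_file[i])
      if (path_is_unsafe(ex$data_file[i])) {
        add("error", "data_file", paste0("row ", i, ": path must be relative"))
      } else if (!file.exists(p)) {
        add("error", "data_file",
            paste0("row ", i, " (", ex$animal_id[i], "/", ex$test_id[i],
                   "): data file missing: ", p))
      }
    }
  }
  if (nrow(ex) > 0 && "exclude" %in% names(ex) && all(is_excluded(ex$exclude))) {
    add("warning", "exclude", "every test row is flagged excluded")
  }
  if (length(rep) == 0) {
    tibble(severity = character(), field = character(), message = character())
  } else {
    bind_rows(rep)
  }
}

#' Resolve an experiment row's data file against the project folders
#' @param bundle a [load_project()] result.
#' @param row one experiment row (1-row tibble or named list).
#' @return absolute path.
#' @export
data_file_path <- function(bundle, row) {
  file.path(bundle$root, bundle$master$raw_data_folder %||% "", row$data_file)
}

#' Write a project bundle back to disk
#'
#' Inverse of [load_project()]: writes (or appends to) a master registry and
#' the linked experiment and lab CSVs so that reloading reproduces every
#' field. Used by the synthetic generator and for local project registration.
#'
#' @param master named list/1-row data frame of master fields.
#' @param experiment experiment tibble.
#' @param lab named list with `light_off_time`, `light_on_time` (and free
#'   text fields).
#' @param master_file path of the master CSV to create or append to.
#' @return the master_file path, invisibly.
#' @export
write_project <- function(master, experiment, lab, master_file) {
  master <- as.list(master)
  root <- file.path(dirname(master_file), master$folder_path)
  dir.create(file.path(root, dirname(master$animal_metadata)),
             recursive = TRUE, showWarnings = FALSE)
  keep <- intersect(master_known, names(master))
  row <- as_tibble(master[keep])
  if (file.exists(master_file)) {
    old <- readr::read_csv(master_file, col_types = readr::cols(.default = "c"),
                           na = character(), show_col_types = FALSE)
    names(old) <- normalize_master_names(names(old))
    row <- bind_rows(old[old$identifier != master$identifier, ], row)
  }
  readr::write_csv(row, master_file, na = "")
  readr::write_csv(experiment, file.path(root, master$animal_metadata), na = "")
  lab_keep <- lab[!vapply(lab, is.null, logical(1))]
  lab_keep$light_off_min <- NULL
  lab_keep$light_on_min <- NULL
  readr::write_csv(as_tibble(lab_keep), file.path(root, master$lab_metadata), na = "")
  invisible(master_file)
}
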