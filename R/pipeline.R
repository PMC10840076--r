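# file schema: column name mapping between the on-disk delimited text
# schema (units suffixed) and the internal cohort columns
COHORT_FILE_COLS <- c(
  id = "id", sex = "sex", age = "age",
  height = "height_m", sitting_height = "sitting_height_m",
  weight = "weight_kg", fat_mass = "fat_mass_kg",
  fat_free_mass = "fat_free_mass_kg", bf_pct = "bf_pct",
  wc = "wc_cm", hip = "hip_cm", townsend = "townsend",
  education = "education", smoking = "smoking", alcohol = "alcohol",
  ethnicity = "ethnicity", follow_time = "follow_time_y", event = "event")

COHORT_NUMERIC <- c("age", "height", "sitting_height", "weight", "fat_mass",
                    "fat_free_mass", "bf_pct", "wc", "hip", "townsend",
                    "follow_time")

#' Write a cohort as delimited text
#'
#' Comma-separated, header row, UTF-8, "." decimal; numeric fields are
#' written with 17 significant digits so that [read_cohort()] round-trips
#' them to full double precision.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[names(COHORT_FILE_COLS)]
  names(out) <- unname(COHORT_FILE_COLS)
  for (v in COHORT_FILE_COLS[COHORT_NUMERIC])
    out[[v]] <- formatC(out[[v]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' Reads the documented comma-separated schema back into an internal cohort
#' data frame. Unknown columns are preserved; a missing `bf_pct` column is
#' derived from fat mass and weight (with a message); records with
#' non-positive height or weight are rejected with their ids.
#'
#' @param path CSV file path.
#' @return A `benn_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8",
                         colClasses = c(sex = "character",
                                        id = "character"))
  required <- setdiff(unname(COHORT_FILE_COLS), "bf_pct")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  inv <- stats::setNames(names(COHORT_FILE_COLS), COHORT_FILE_COLS)
  known <- names(raw) %in% names(inv)
  names(raw)[known] <- inv[names(raw)[known]]
  if (!"bf_pct" %in% names(raw)) {
    message("'bf_pct' missing; deriving from fat_mass and weight")
    raw$bf_pct <- 100 * raw$fat_mass / raw$weight
  }
  for (v in COHORT_NUMERIC) {
    raw[[v]] <- as.numeric(raw[[v]])
    if (anyNA(raw[[v]]) && v != "follow_time")
      stop("malformed numeric values in column '", COHORT_FILE_COLS[v],
           "' at line(s): ",
           paste(utils::head(which(is.na(raw[[v]])) + 1L, 10L),
                 collapse = ", "))
  }
  bad <- raw$height <= 0 | raw$weight <= 0
  if (any(bad))
    stop("non-positive height/weight for record(s): ",
         paste(utils::head(raw$id[bad], 10L), collapse = ", "))
  if (anyNA(raw$id) || anyNA(raw$sex)) stop("malformed id/sex values")
  raw$sex <- factor(raw$sex, levels = c("F", "M"))
  for (v in c("education", "smoking", "alcohol", "ethnicity"))
    raw[[v]] <- factor(raw[[v]])
  raw$event <- as.integer(raw$event)
  class(raw) <- c("benn_cohort", "data.frame")
  attr(raw, "provenance") <- path
  raw
}

#' Configuration for a full study run
#'
#' @param mode `"synthetic"` (generate per-sex cohorts) or `"file"` (read a
#'   cohort from `cohort_path`).
#' @param seed Single top-level integer seed; per-stage seeds are spawned
#'   from it deterministically so one number reproduces the whole run.
#' @param n_per_sex Subjects per sex in synthetic mode.
#' @param cohort_path Cohort CSV path in file mode.
#' @param grid [power_grid()] for the exponent scan.
#' @param test_fraction Test share of the sex-stratified split.
#' @param bf_thresholds Per-sex BF% thresholds for the high-fat label.
#' @param old_scheme [category_scheme()] for the conventional index.
#' @param covariates Cox adjustment covariates.
#' @param params_overrides Named list (per sex: `F`, `M`) of
#'   [cohort_params()] overrides for synthetic mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "file"), seed = 1L,
                       n_per_sex = 10000L, cohort_path = NULL,
                       grid = power_grid(-5, 5, 0.01),
                       test_fraction = 0.2,
                       bf_thresholds = c(F = 35, M = 25),
                       old_scheme = category_scheme(),
                       covariates = c("age", "townsend", "education",
                                      "smoking", "alcohol", "ethnicity"),
                       params_overrides = list()) {
  mode <- match.arg(mode)
  if (mode == "file") {
    if (is.null(cohort_path) || !file.exists(cohort_path))
      stop("file mode requires an existing 'cohort_path'")
  }
  structure(list(mode = mode, seed = as.integer(seed),
                 n_per_sex = as.integer(n_per_sex),
                 cohort_path = cohort_path, grid = as_power_grid(grid),
                 test_fraction = test_fraction,
                 bf_thresholds = bf_thresholds, old_scheme = old_scheme,
                 covariates = covariates,
                 params_overrides = params_overrides),
            class = "run_config")
}

# deterministic per-stage seed spawning (kept well below 2^31)
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 1000000007L
}

#' Run the full study flow
#'
#' Per sex: generate (or read and subset) the cohort, fill mortality, split
#' 80/20 stratified by sex, fit the exponent scan on the training set,
#' select the new formula by the height-independency criterion, then
#' evaluate on the test set: screening accuracy with training-derived
#' cutoffs, category reclassification with training-mapped thresholds, and
#' the Cox comparison of old versus new index fifths. All formulas,
#' cutoffs and category thresholds are functions of the training partition
#' only.
#'
#' @param config A [run_config()].
#' @return A list of class `benn_report` with one element per sex (each
#'   holding `criterion_table`, `new_power`, `screening`, `survival`) and a
#'   `manifest` recording seeds, grid and package version.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sexes <- c("F", "M")
  report <- list()
  for (k in seq_along(sexes)) {
    s <- sexes[k]
    if (config$mode == "synthetic") {
      ov <- config$params_overrides[[s]]
      args <- c(list(sex = s, n = config$n_per_sex,
                     seed = stage_seed(config$seed, k)),
                if (is.null(ov)) list() else ov)
      par_s <- do.call(cohort_params, args)
      cohort <- generate_cohort(par_s)
      cohort <- generate_mortality(cohort, par_s)
    } else {
      cohort <- read_cohort(config$cohort_path)
      cohort <- cohort[as.character(cohort$sex) == s, , drop = FALSE]
      if (!nrow(cohort)) stop("no subjects of sex ", s, " in cohort file")
    }
    sp <- split_train_test(cohort, config$test_fraction,
                           seed = stage_seed(config$seed, 10L + k))
    fit <- benn_fit(sp$train, grid = config$grid)
    powers <- c(old = 2, new = fit$power)
    screening <- build_screening_table(sp$train, sp$test, powers,
                                       config$bf_thresholds,
                                       config$old_scheme)
    surv <- compare_formulas_survival(sp$test, powers, config$covariates)
    report[[s]] <- list(
      criterion_table = fit$criterion_table,
      new_power = fit$power,
      n_train = nrow(sp$train), n_test = nrow(sp$test),
      screening = screening, survival = surv)
  }
  report$manifest <- list(
    seed = config$seed,
    stage_seeds = list(
      cohort = stats::setNames(stage_seed(config$seed, 1:2), sexes),
      split = stats::setNames(stage_seed(config$seed, 11:12), sexes)),
    grid = list(p_min = config$grid$p_min, p_max = config$grid$p_max,
                step = config$grid$step),
    mode = config$mode,
    n_per_sex = config$n_per_sex,
    test_fraction = config$test_fraction,
    package_version = as.character(utils::packageVersion("bennscan")))
  class(report) <- "benn_report"
  report
}

#' @export
print.benn_report <- function(x, ...) {
  for (s in setdiff(names(x), "manifest")) {
    cat("==== Sex:", s, "====\n")
    cat(sprintf("train n = %d, test n = %d, selected exponent = %.2f\n",
                x[[s]]$n_train, x[[s]]$n_test, x[[s]]$new_power))
    print(x[[s]]$criterion_table)
    print(x[[s]]$screening)
    print(x[[s]]$survival)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes the machine-readable JSON contract (`report.json`) plus
#' human-readable delimited-text tables per sex. Output is byte-identical
#' across runs with identical configuration and seeds.
#'
#' @param report A [run_full_analysis()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "benn_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(manifest = report$manifest)
  for (s in setdiff(names(report), "manifest")) {
    r <- report[[s]]
    json[[s]] <- list(
      new_power = r$new_power,
      n_train = r$n_train, n_test = r$n_test,
      criterion_table = as.data.frame(r$criterion_table),
      screening = r$screening$screening,
      cutoffs = as.list(r$screening$cutoffs),
      reclassification = r$screening$reclassification,
      hr_fifths = r$survival$hr_fifths,
      aic = as.list(r$survival$aic),
      delta_aic = r$survival$delta_aic)
    utils::write.csv(as.data.frame(r$criterion_table),
                     file.path(dir, paste0("criterion_table_", s, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$screening$screening,
                     file.path(dir, paste0("screening_", s, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$survival$hr_fifths,
                     file.path(dir, paste0("survival_", s, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
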