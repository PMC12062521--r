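#' Read and validate a cohort CSV
#'
#' Reads a subject-level cohort table with columns
#' `subject_id,age_years,sex,snfl_pg_ml` (UTF-8, comma-separated, `.`
#' decimal mark; `#` comment lines are skipped). Rows failing validation —
#' unparsable age or concentration, non-positive concentration, unknown sex
#' code, duplicate subject id, or age outside `age_range` (the recruitment
#' inclusion window, default 18-70 years inclusive) — are rejected with a
#' per-row reason rather than silently dropped. Sex is accepted as
#' `M`/`F`/`male`/`female`, case-insensitively.
#'
#' @param path path to the CSV file.
#' @param age_range inclusive `(min, max)` accepted ages in years.
#' @return an `nfl_cohort` data frame of the accepted rows, carrying a
#'   `validation` attribute: `n_read`, `n_accepted`, and a `rejections`
#'   data frame (`row`, `field`, `reason`). See [validation_report()].
#' @export
read_cohort_csv <- function(path, age_range = c(18, 70)) {
  if (!file.exists(path))
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("subject_id", "age_years", "sex", "snfl_pg_ml")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  n_read <- nrow(raw)
  rej <- list()
  reject <- function(row, field, reason)
    rej[[length(rej) + 1L]] <<- data.frame(row = row, field = field,
                                           reason = reason,
                                           stringsAsFactors = FALSE)
  age <- suppressWarnings(as.numeric(raw$age_years))
  snfl <- suppressWarnings(as.numeric(raw$snfl_pg_ml))
  sex_raw <- toupper(trimws(raw$sex))
  sex <- ifelse(sex_raw %in% c("M", "MALE"), "M",
                ifelse(sex_raw %in% c("F", "FEMALE"), "F", NA_character_))
  ok <- rep(TRUE, n_read)
  for (i in seq_len(n_read)) {
    if (is.na(age[i])) {
      reject(i, "age_years", "unparsable age"); ok[i] <- FALSE
    } else if (age[i] < age_range[1L] || age[i] > age_range[2L]) {
      reject(i, "age_years",
             sprintf("age outside %g-%g", age_range[1L], age_range[2L]))
      ok[i] <- FALSE
    }
    if (is.na(snfl[i])) {
      reject(i, "snfl_pg_ml", "unparsable concentration"); ok[i] <- FALSE
    } else if (snfl[i] <= 0) {
      reject(i, "snfl_pg_ml", "non-positive concentration"); ok[i] <- FALSE
    }
    if (is.na(sex[i])) {
      reject(i, "sex", sprintf("unknown sex code '%s'", raw$sex[i]))
      ok[i] <- FALSE
    }
  }
  dup <- duplicated(raw$subject_id)
  for (i in which(dup & ok)) {
    reject(i, "subject_id", sprintf("duplicate id '%s'", raw$subject_id[i]))
    ok[i] <- FALSE
  }
  cohort <- data.frame(subject_id = raw$subject_id[ok],
                       age_years = age[ok], sex = sex[ok],
                       snfl_pg_ml = snfl[ok], stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L)
    stop(sprintf("no valid rows in %s (%d read, all rejected)", path, n_read),
         call. = FALSE)
  rejections <- if (length(rej) > 0L) do.call(rbind, rej)
                else data.frame(row = integer(), field = character(),
                                reason = character(), stringsAsFactors = FALSE)
  class(cohort) <- c("nfl_cohort", "data.frame")
  attr(cohort, "provenance") <- path
  attr(cohort, "validation") <- list(n_read = n_read,
                                     n_accepted = nrow(cohort),
                                     rejections = rejections)
  cohort
}

#' Validation report of a read cohort
#'
#' @param cohort a cohort returned by [read_cohort_csv()].
#' @return list with `n_read`, `n_accepted` and the `rejections` data frame.
#' @export
validation_report <- function(cohort) {
  attr(cohort, "validation")
}

# "# key=value" metadata header lines for output files
.meta_header <- function(meta) {
  if (is.null(meta) || length(meta) == 0L) return(character())
  sprintf("# %s=%s", names(meta), vapply(meta, format, character(1L)))
}

#' Write a table as CSV with a metadata comment header
#'
#' Writes `# key=value` comment lines (package version plus any caller
#' metadata such as seed and config fingerprint) followed by the CSV body,
#' so downstream parsers can skip the header with `comment.char = "#"`.
#'
#' @param table a data frame.
#' @param path output path.
#' @param meta named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path, meta = list()) {
  meta <- c(list(package = sprintf("nflref %s",
                                   as.character(utils::packageVersion("nflref")))),
            meta)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.meta_header(meta), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort as CSV
#'
#' @param cohort an `nfl_cohort` data frame.
#' @param path output path.
#' @param meta named list of metadata header values.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, meta = list()) {
  write_table_csv(cohort[, c("subject_id", "age_years", "sex", "snfl_pg_ml")],
                  path, meta)
}

# --- model serialization -------------------------------------------------

#' Serialize a fitted model to JSON
#'
#' Stores log10-linear fits, upper-limit formulas, and BCCG centile models
#' (spline knots, boundaries and coefficients) at full double precision so
#' a reloaded model reproduces predictions to better than 1e-12 relative.
#' BCCG models are reloaded without their training data; prediction,
#' centile tables and Z-scoring of new cohorts all work on the reloaded
#' object.
#'
#' @param model an `nfl_loglin`, `upper_limit_formula`, or
#'   `bccg_centile_fit` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <-
    if (inherits(model, "nfl_loglin")) {
      list(type = "loglinear",
           fields = model[c("intercept", "beta_age", "beta_female",
                            "residual_se", "n", "p_age", "p_female")])
    } else if (inherits(model, "upper_limit_formula")) {
      list(type = "upper_limit",
           fields = unclass(model))
    } else if (inherits(model, "bccg_centile_fit")) {
      list(type = "bccg_centiles",
           by_sex = model$by_sex,
           age_domain = model$age_domain,
           edf = as.list(model$edf),
           strata = lapply(model$strata, function(f)
             f[c("spec_mu", "spec_sigma", "spec_nu",
                 "coef_mu", "coef_sigma", "coef_nu",
                 "loglik", "iterations", "converged", "n", "age_range")]))
    } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a model serialized by [write_model_json()]
#'
#' @param path JSON path.
#' @return the reconstructed model object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "loglinear") {
    structure(c(obj$fields, list(lm = NULL)), class = "nfl_loglin")
  } else if (obj$type == "upper_limit") {
    structure(obj$fields, class = "upper_limit_formula")
  } else if (obj$type == "bccg_centiles") {
    strata <- lapply(obj$strata, function(f) {
      f$edf <- c(mu = f$spec_mu$edf, sigma = f$spec_sigma$edf,
                 nu = f$spec_nu$edf)
      f
    })
    structure(list(strata = strata, by_sex = obj$by_sex,
                   age_domain = obj$age_domain,
                   edf = unlist(obj$edf),
                   data = NULL, call = NULL),
              class = "bccg_centile_fit")
  } else stop(sprintf("unknown model type '%s'", obj$type), call. = FALSE)
}

#' Write pipeline outputs
#'
#' Writes each table via [write_table_csv()] and each model via
#' [write_model_json()] into `dir`, attaching the shared metadata header to
#' every CSV.
#'
#' @param tables named list of data frames (names become `<name>.csv`).
#' @param models named list of model objects (names become `<name>.json`).
#' @param dir output directory, created if needed.
#' @param meta named metadata list for the CSV headers (e.g. seed, config
#'   fingerprint).
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(tables = list(), models = list(), dir,
                          meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table_csv(tables[[nm]], p, meta)
    paths[nm] <- p
  }
  for (nm in names(models)) {
    p <- file.path(dir, paste0(nm, ".json"))
    write_model_json(models[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}
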