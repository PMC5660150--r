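# Study-level data model: one row per control-arm comparison (outcome
# summaries + design moderators) and one row per mortality record.

OUTCOME_LEVELS  <- c("IS_AAR", "IS_LV", "EF")
SPECIES_LEVELS  <- c("dog", "pig", "sheep")
STRAIN_LEVELS   <- c("regular_pig", "minipig", "unreported", "not_applicable")
SEX_LEVELS      <- c("male", "female", "both", "unknown")
OCCLUSION_LEVELS <- c("permanent", "temporary", "unknown")
VESSEL_LEVELS   <- c("LAD", "LCX", "LAD_LCX", "RCA", "unknown")
APPROACH_LEVELS <- c("open", "closed", "unknown")
PHASE_LEVELS    <- c("peri", "post")

MODERATOR_COLS <- c("species", "strain", "sex", "occlusion", "vessel",
                    "approach", "comedication", "immunosuppression",
                    "quantification", "follow_up_hours", "ischemia_minutes",
                    "quality_score", "weight_kg", "age_weeks",
                    "vf_excluded_untreated")

ARM_COLS <- c("study_id", "outcome", "mean", "sd", "n_animals", MODERATOR_COLS)

MORTALITY_COLS <- c("study_id", "phase", "deaths", "total",
                    "deaths2", "total2", MODERATOR_COLS)

ARM_NUMERIC <- c("mean", "sd", "n_animals", "follow_up_hours",
                 "ischemia_minutes", "quality_score", "weight_kg", "age_weeks")
MORTALITY_NUMERIC <- c("deaths", "total", "deaths2", "total2",
                       "follow_up_hours", "ischemia_minutes", "quality_score",
                       "weight_kg", "age_weeks")
INTEGER_COLS <- c("n_animals", "quality_score", "deaths", "total",
                  "deaths2", "total2")
LOGICAL_COLS <- c("comedication", "immunosuppression", "vf_excluded_untreated")

#' Assemble a validated study-level dataset
#'
#' Bundles control-arm outcome rows and mortality records into a single
#' container, the unit all analysis functions operate on. Validation is run
#' on construction; invariant violations are reported with row indices.
#'
#' @param arms data frame of control-arm comparisons, one row per
#'   (study, outcome); required columns are given in [arm_columns()].
#' @param mortality optional data frame of mortality records, one row per
#'   (study, phase); see [mortality_columns()]. `deaths2`/`total2` hold an
#'   optional second measurement in the same procedural setting (e.g.
#'   mortality recorded both before and after randomization).
#' @param provenance free-text metadata carried along unmodified.
#' @return An object of class `mi_dataset`: a list with elements `arms`,
#'   `mortality` and `provenance`.
#' @seealso [read_dataset()], [filter_subset()], [generate_dataset()]
#' @export
mi_dataset <- function(arms, mortality = NULL, provenance = "") {
  arms <- as.data.frame(arms)
  if (is.null(mortality)) {
    mortality <- empty_mortality()
  }
  mortality <- as.data.frame(mortality)
  ds <- structure(list(arms = arms, mortality = mortality,
                       provenance = provenance),
                  class = "mi_dataset")
  validate_dataset(ds)
  ds
}

empty_mortality <- function() {
  m <- data.frame(study_id = character(), phase = character(),
                  deaths = integer(), total = integer(),
                  deaths2 = integer(), total2 = integer())
  for (col in MODERATOR_COLS) m[[col]] <- logical()
  m[MORTALITY_COLS]
}

#' Column dictionaries for the CSV interchange format
#'
#' @return Character vector of required column names for the arms table
#'   (`arm_columns`) or the mortality table (`mortality_columns`).
#' @export
arm_columns <- function() ARM_COLS

#' @rdname arm_columns
#' @export
mortality_columns <- function() MORTALITY_COLS

fail_rows <- function(problems) {
  stop("dataset validation failed:\n  ", paste(problems, collapse = "\n  "),
       call. = FALSE)
}

check_enum <- function(x, levels, col, rows, problems) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "row %d: %s '%s' is not one of {%s}", rows[bad], col, x[bad],
      paste(levels, collapse = ", ")))
  }
  problems
}

#' Validate a study-level dataset
#'
#' Checks every invariant of the data model: outcome means are percentages in
#' \[0, 100\], SDs are nonnegative (and strictly positive whenever n > 1),
#' ischemia duration is only present for temporary occlusions, deaths never
#' exceed totals, enumerated fields hold legal levels, and
#' (study, outcome) / (study, phase) keys are unique. Violations are raised
#' as a single error listing each offending row.
#'
#' @param ds an `mi_dataset`.
#' @return `ds`, invisibly, when validation passes.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "mi_dataset"))
  a <- ds$arms
  m <- ds$mortality
  problems <- character()

  missing_a <- setdiff(ARM_COLS, names(a))
  if (length(missing_a)) {
    stop("arms table is missing required column(s): ",
         paste(missing_a, collapse = ", "), call. = FALSE)
  }
  missing_m <- setdiff(MORTALITY_COLS, names(m))
  if (length(missing_m)) {
    stop("mortality table is missing required column(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }

  if (nrow(a)) {
    r <- seq_len(nrow(a))
    problems <- check_enum(a$outcome, OUTCOME_LEVELS, "outcome", r, problems)
    problems <- check_enum(a$species, SPECIES_LEVELS, "species", r, problems)
    problems <- check_enum(a$strain, STRAIN_LEVELS, "strain", r, problems)
    problems <- check_enum(a$sex, SEX_LEVELS, "sex", r, problems)
    problems <- check_enum(a$occlusion, OCCLUSION_LEVELS, "occlusion", r, problems)
    problems <- check_enum(a$vessel, VESSEL_LEVELS, "vessel", r, problems)
    problems <- check_enum(a$approach, APPROACH_LEVELS, "approach", r, problems)

    bad <- which(!is.na(a$mean) & (a$mean < 0 | a$mean > 100))
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: mean %.4g outside [0, 100]", bad, a$mean[bad]))
    bad <- which(!is.na(a$sd) & a$sd < 0)
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: sd %.4g is negative", bad, a$sd[bad]))
    bad <- which(a$n_animals > 1 & !is.na(a$sd) & a$sd <= 0)
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: sd must be > 0 when n_animals > 1", bad))
    bad <- which(is.na(a$n_animals) | a$n_animals < 1 |
                   a$n_animals != round(a$n_animals))
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: n_animals must be a positive integer", bad))
    bad <- which(!is.na(a$ischemia_minutes) & a$occlusion != "temporary")
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: ischemia_minutes present but occlusion is '%s'",
      bad, a$occlusion[bad]))
    bad <- which(!is.na(a$follow_up_hours) & a$follow_up_hours < 0)
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: follow_up_hours is negative", bad))
    key <- paste(a$study_id, a$outcome)
    dup <- which(duplicated(key))
    if (length(dup)) problems <- c(problems, sprintf(
      "row %d: duplicate (study_id, outcome) key '%s'", dup, key[dup]))
  }

  if (nrow(m)) {
    r <- seq_len(nrow(m))
    problems <- check_enum(m$phase, PHASE_LEVELS, "phase", r, problems)
    bad <- which(is.na(m$total) | m$total < 1)
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: total must be a positive integer", bad))
    bad <- which(is.na(m$deaths) | m$deaths < 0 | m$deaths > m$total)
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: deaths must lie in [0, total]", bad))
    has2 <- !is.na(m$total2)
    bad <- which(has2 & (is.na(m$deaths2) | m$deaths2 < 0 | m$deaths2 > m$total2))
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: deaths2 must lie in [0, total2]", bad))
    bad <- which(!has2 & !is.na(m$deaths2))
    if (length(bad)) problems <- c(problems, sprintf(
      "row %d: deaths2 present without total2", bad))
    key <- paste(m$study_id, m$phase)
    dup <- which(duplicated(key))
    if (length(dup)) problems <- c(problems, sprintf(
      "row %d: duplicate (study_id, phase) key '%s'", dup, key[dup]))
  }

  if (length(problems)) fail_rows(problems)
  invisible(ds)
}

coerce_numeric <- function(df, cols, what) {
  for (col in intersect(cols, names(df))) {
    x <- df[[col]]
    if (is.numeric(x)) next
    x <- as.character(x)
    x[!nzchar(trimws(x))] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad)) {
      stop(sprintf("parse error in %s column '%s': non-numeric value '%s' at row %d",
                   what, col, x[bad[1]], bad[1]), call. = FALSE)
    }
    if (col %in% INTEGER_COLS && all(is.na(num) | num == round(num))) {
      num <- as.integer(num)
    }
    df[[col]] <- num
  }
  df
}

coerce_logical <- function(df) {
  for (col in intersect(LOGICAL_COLS, names(df))) {
    x <- df[[col]]
    if (is.logical(x)) next
    x <- tolower(trimws(as.character(x)))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1", "yes")] <- TRUE
    out[x %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(nzchar(x) & !is.na(x) & is.na(out) & x != "na")
    if (length(bad)) {
      stop(sprintf("parse error in logical column '%s': value '%s' at row %d",
                   col, x[bad[1]], bad[1]), call. = FALSE)
    }
    df[[col]] <- out
  }
  df
}

#' Read a study-level dataset from CSV
#'
#' Reads the arms table (and optionally a mortality table) from the package's
#' CSV interchange format: UTF-8, comma-separated, "." decimal, one header
#' row, empty cells for missing optional values (never 0). The result is
#' validated; any invariant violation aborts with row-indexed messages.
#'
#' @param arms_path path to the arms CSV; header must contain every column in
#'   [arm_columns()].
#' @param mortality_path optional path to the mortality CSV
#'   ([mortality_columns()]).
#' @param provenance free-text metadata attached to the dataset.
#' @return An [mi_dataset()].
#' @export
read_dataset <- function(arms_path, mortality_path = NULL, provenance = NULL) {
  if (!file.exists(arms_path)) {
    stop("file not found: ", arms_path, call. = FALSE)
  }
  arms <- read.csv(arms_path, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  missing <- setdiff(ARM_COLS, names(arms))
  if (length(missing)) {
    stop("schema error: arms CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  arms <- coerce_logical(coerce_numeric(arms, ARM_NUMERIC, "arms"))
  if (nrow(arms) == 0L) {
    warning("arms CSV contains a header but no rows", call. = FALSE)
  }
  mortality <- NULL
  if (!is.null(mortality_path)) {
    if (!file.exists(mortality_path)) {
      stop("file not found: ", mortality_path, call. = FALSE)
    }
    mortality <- read.csv(mortality_path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
    missing <- setdiff(MORTALITY_COLS, names(mortality))
    if (length(missing)) {
      stop("schema error: mortality CSV is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    mortality <- coerce_logical(
      coerce_numeric(mortality, MORTALITY_NUMERIC, "mortality"))
  }
  if (is.null(provenance)) provenance <- paste("read from", arms_path)
  mi_dataset(arms, mortality, provenance)
}

#' Write a study-level dataset to CSV
#'
#' Inverse of [read_dataset()]: real values are written with 15 significant
#' digits so that a write/read round trip preserves text and integer fields
#' exactly and reals to at least 12 significant digits.
#'
#' @param ds an `mi_dataset`.
#' @param arms_path destination for the arms CSV.
#' @param mortality_path optional destination for the mortality CSV.
#' @return `ds`, invisibly.
#' @export
write_dataset <- function(ds, arms_path, mortality_path = NULL) {
  stopifnot(inherits(ds, "mi_dataset"))
  fmt <- function(df) {
    for (col in names(df)) {
      if (is.double(df[[col]])) {
        x <- df[[col]]
        df[[col]] <- ifelse(is.na(x), NA_character_, sprintf("%.15g", x))
      }
    }
    df
  }
  write.csv(fmt(ds$arms[ARM_COLS]), arms_path, row.names = FALSE, na = "")
  if (!is.null(mortality_path)) {
    write.csv(fmt(ds$mortality[MORTALITY_COLS]), mortality_path,
              row.names = FALSE, na = "")
  }
  invisible(ds)
}

#' Subset a dataset with a declarative filter
#'
#' Evaluates a filter expression (given as a string, e.g.
#' `"species == 'pig'"` or `"!vf_excluded_untreated"`) against the dataset's
#' columns and keeps the rows where it is `TRUE`. This is the mechanism for
#' sensitivity analyses, e.g. excluding comparisons where animals fibrillating
#' during induction were removed without treatment, or restricting to the pig
#' strains for the minipig/regular-pig comparison. The filter is applied to
#' each table (arms, mortality) in which every referenced field exists; a
#' table lacking one of the fields is left unchanged. Rows where the
#' predicate evaluates to `NA` are dropped. The input dataset is not
#' modified.
#'
#' @param ds an `mi_dataset`.
#' @param where filter expression as a length-1 character string; may
#'   reference any column of the arms or mortality tables.
#' @return A new, validated `mi_dataset` holding the matching rows.
#' @examples
#' ds <- generate_dataset(synthetic_config(k_studies = 30, seed = 1))
#' pigs <- filter_subset(ds, "species == 'pig'")
#' @export
filter_subset <- function(ds, where) {
  stopifnot(inherits(ds, "mi_dataset"))
  if (!is.character(where) || length(where) != 1L) {
    stop("'where' must be a length-1 character string", call. = FALSE)
  }
  expr <- tryCatch(str2lang(where), error = function(e) {
    stop("cannot parse filter expression: ", conditionMessage(e), call. = FALSE)
  })
  vars <- all.vars(expr)
  known <- union(names(ds$arms), names(ds$mortality))
  unknown <- setdiff(vars, known)
  if (length(unknown)) {
    stop("unknown field(s) in filter: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  apply_to <- function(df) {
    if (!all(vars %in% names(df)) || nrow(df) == 0L) return(df)
    keep <- eval(expr, df, baseenv())
    if (is.logical(keep) && length(keep) == 1L) keep <- rep(keep, nrow(df))
    if (!is.logical(keep) || length(keep) != nrow(df)) {
      stop("filter must evaluate to one logical per row", call. = FALSE)
    }
    df[!is.na(keep) & keep, , drop = FALSE]
  }
  out <- ds
  out$arms <- apply_to(ds$arms)
  out$mortality <- apply_to(ds$mortality)
  rownames(out$arms) <- NULL
  rownames(out$mortality) <- NULL
  validate_dataset(out)
  out
}

#' @export
print.mi_dataset <- function(x, ...) {
  cat("<mi_dataset>\n")
  cat("  arms:      ", nrow(x$arms), "control-arm comparisons")
  if (nrow(x$arms)) {
    tab <- table(x$arms$outcome)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n  mortality: ", nrow(x$mortality), "records")
  if (nrow(x$mortality)) {
    tab <- table(x$mortality$phase)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Extract effect records for one outcome
#'
#' Converts the arm rows for a given outcome into the (estimate, sampling
#' variance) form every meta-analytic routine consumes. Raw means are used as
#' effect sizes (percentages are comparable across studies) and the sampling
#' variance is the squared standard error of a mean, `sd^2 / n`.
#'
#' @param ds an `mi_dataset`.
#' @param outcome one of `"IS_AAR"`, `"IS_LV"`, `"EF"`.
#' @return Data frame with columns `study_id`, `yi` (estimate, percent), `vi`
#'   (sampling variance, points squared), `n_animals`, and all moderator
#'   columns.
#' @export
effects_from_arms <- function(ds, outcome = OUTCOME_LEVELS) {
  stopifnot(inherits(ds, "mi_dataset"))
  outcome <- match.arg(outcome)
  a <- ds$arms[ds$arms$outcome == outcome, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop("no arms with outcome '", outcome, "'", call. = FALSE)
  }
  out <- data.frame(study_id = a$study_id, yi = a$mean,
                    vi = a$sd^2 / a$n_animals, n_animals = a$n_animals,
                    stringsAsFactors = FALSE)
  out[MODERATOR_COLS] <- a[MODERATOR_COLS]
  bad <- which(!(out$vi > 0))
  if (length(bad)) {
    stop("nonpositive sampling variance for study ",
         paste(out$study_id[bad], collapse = ", "),
         " (sd must be > 0)", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
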