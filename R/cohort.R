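#' Longitudinal PK cohort
#'
#' A `pk_cohort` holds dosing events, concentration observations and
#' covariates for a set of subjects in the row-oriented layout used by
#' NONMEM and Monolix: one row per dose (`EVID = 1`, `AMT` set) or per
#' observation (`EVID = 0`, `DV` set), with the time scale in hours since
#' the first dose. Albumin (`ALB`, g/dL) and anti-adalimumab antibody
#' status (`AAA`, 0/1) ride along as covariate columns and may be missing
#' on any subset of rows before [impute_covariates()] is applied.
#'
#' @param data Data frame with columns `ID`, `TIME`, `AMT`, `DV`, `EVID`,
#'   `ALB`, `AAA`. Extra columns (e.g. additional covariates, `MDV`) are
#'   kept untouched.
#' @param meta Named list of free-form provenance information (e.g. the
#'   assay quantification range, the generating seed for synthetic data).
#' @param validate Run structural validation (default `TRUE`).
#' @return An object of class `pk_cohort`: a list with elements `data`
#'   (the canonical data frame, sorted by subject and time) and `meta`.
#' @seealso [read_pk_data()], [impute_covariates()], [hold_out_last()]
#' @export
pk_cohort <- function(data, meta = list(), validate = TRUE) {
  stopifnot(is.data.frame(data), is.list(meta))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (validate) {
    .check_columns(data)
    data <- .coerce_columns(data)
    .validate_rows(data)
  }
  ## stable per-subject time sort, subjects kept in first-appearance order
  ord <- order(match(data$ID, unique(data$ID)), data$TIME,
               -data$EVID, method = "radix")
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  if (anyNA(data$AAA) || anyNA(data$ALB)) {
    meta$covariates_complete <- FALSE
  } else {
    meta$covariates_complete <- TRUE
  }
  structure(list(data = data, meta = meta), class = "pk_cohort")
}

.mandatory_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "ALB", "AAA")

.check_columns <- function(data) {
  missing <- setdiff(.mandatory_cols, names(data))
  if (length(missing) > 0L) {
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.coerce_columns <- function(data) {
  num_cols <- c("TIME", "AMT", "DV", "EVID", "ALB", "AAA")
  for (cn in num_cols) {
    x <- data[[cn]]
    if (is.character(x)) x[x == ""] <- NA
    suppressWarnings(data[[cn]] <- as.numeric(x))
  }
  data$ID <- as.character(data$ID)
  data
}

.validate_rows <- function(data) {
  line <- seq_len(nrow(data)) + 1L   # +1 for the header line
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop("validation error: ", what, " (line ",
           paste(line[which(cond)], collapse = ", "), ")", call. = FALSE)
    }
  }
  bad(is.na(data$EVID) | !(data$EVID %in% c(0, 1)),
      "EVID must be 0 (observation) or 1 (dose)")
  bad(is.na(data$TIME) | data$TIME < 0, "TIME must be a number >= 0 hours")
  is_dose <- data$EVID == 1
  bad(is_dose & (is.na(data$AMT) | data$AMT <= 0),
      "dose rows (EVID=1) need AMT > 0 mg")
  bad(is_dose & !is.na(data$DV), "dose rows (EVID=1) must have empty DV")
  bad(!is_dose & is.na(data$DV), "observation rows (EVID=0) need DV set")
  bad(!is_dose & !is.na(data$AMT),
      "observation rows (EVID=0) must have empty AMT")
  bad(!is_dose & data$DV < 0, "DV must be >= 0 mg/L")
  bad(!is.na(data$ALB) & data$ALB <= 0, "ALB must be > 0 g/dL")
  bad(!is.na(data$AAA) & !(data$AAA %in% c(0, 1)), "AAA must be 0 or 1")
  ## a subject contributing observations must have received at least one dose
  has_obs <- tapply(data$EVID == 0, data$ID, any)
  has_dose <- tapply(data$EVID == 1, data$ID, any)
  orphan <- names(has_obs)[has_obs & !has_dose[names(has_obs)]]
  if (length(orphan) > 0L) {
    stop("validation error: subject(s) with observations but no dose: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a PK dataset from a NONMEM/Monolix-style CSV file
#'
#' Comma-separated, period decimal separator, empty string for missing
#' values. The expected header is `ID, TIME, AMT, DV, EVID, ALB, AAA`
#' (`MDV` and extra covariate columns are carried along). Nonstandard
#' column names can be remapped through `columns` or a small JSON/YAML
#' config file with a top-level `columns` map.
#'
#' @param path Path to the CSV file.
#' @param columns Optional named character vector or list mapping
#'   canonical names to the names used in the file, e.g.
#'   `c(ID = "SUBJ", DV = "CONC")`.
#' @param config Optional path to a JSON or YAML file whose `columns`
#'   entry provides the same mapping, and whose optional `time_unit`
#'   entry must be `"hours"` (any other dataset-level time unit is
#'   rejected; the package works in hours throughout).
#' @return A validated [pk_cohort] object.
#' @export
read_pk_data <- function(path, columns = NULL, config = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  if (!is.null(config)) {
    cfg <- .read_config(config)
    if (!is.null(cfg$time_unit) && !identical(tolower(cfg$time_unit), "hours")) {
      stop("format error: dataset time unit must be hours, got '",
           cfg$time_unit, "'", call. = FALSE)
    }
    if (is.null(columns)) columns <- cfg$columns
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", check.names = FALSE)
  if (!is.null(columns)) {
    columns <- unlist(columns)
    for (canon in names(columns)) {
      idx <- match(columns[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  pk_cohort(df, meta = list(source = path))
}

.read_config <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such config: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("\\.json$", path, ignore.case = TRUE) || grepl("^\\s*\\{", txt)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required to read a JSON config", call. = FALSE)
    }
    return(jsonlite::fromJSON(txt))
  }
  ## minimal YAML subset: "key: value" and one level of nesting
  .parse_simple_yaml(txt)
}

.parse_simple_yaml <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list(); current <- NULL
  for (ln in lines) {
    indented <- grepl("^\\s+", ln)
    kv <- sub("^\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    val <- gsub('^"|"$', "", val)
    if (!indented) {
      if (val == "") { current <- key; out[[key]] <- list() }
      else { current <- NULL; out[[key]] <- val }
    } else if (!is.null(current)) {
      out[[current]][[key]] <- val
    }
  }
  out
}

#' Write a PK cohort back to the CSV dialect read by [read_pk_data()]
#'
#' @param cohort A [pk_cohort].
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_pk_data <- function(cohort, path) {
  stopifnot(inherits(cohort, "pk_cohort"))
  ## an id appearing in two separate row blocks means two records were
  ## assembled under the same label
  if (anyDuplicated(rle(cohort$data$ID)$values)) {
    stop("validation error: duplicate subject ids", call. = FALSE)
  }
  out <- cohort$data
  out$HELD <- NULL                      # analysis flag, not part of the dialect
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("I/O error: cannot write to ", path, call. = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Impute missing covariates with per-subject means
#'
#' A subject with at least one observed value of a covariate gets that
#' subject's mean on every row; a subject with no observed value gets the
#' mean of the other subjects' per-subject means. Antibody status is
#' imputed by the same rule and then rounded to 0/1 so it stays a valid
#' binary covariate. Idempotent; never alters non-missing values.
#'
#' @param cohort A [pk_cohort], possibly with missing `ALB`/`AAA` entries.
#' @return A [pk_cohort] with complete covariates.
#' @export
impute_covariates <- function(cohort) {
  stopifnot(inherits(cohort, "pk_cohort"))
  data <- cohort$data
  for (cn in c("ALB", "AAA")) {
    x <- data[[cn]]
    if (!anyNA(x)) next
    subj_mean <- tapply(x, data$ID, function(v) mean(v, na.rm = TRUE))
    subj_mean[is.nan(subj_mean)] <- NA
    if (all(is.na(subj_mean))) {
      stop("validation error: covariate ", cn,
           " missing for every subject; nothing to impute from",
           call. = FALSE)
    }
    grand <- mean(subj_mean, na.rm = TRUE)
    subj_mean[is.na(subj_mean)] <- grand
    fill <- subj_mean[data$ID]
    if (cn == "AAA") fill <- as.numeric(round(fill))
    data[[cn]] <- ifelse(is.na(x), fill, x)
  }
  pk_cohort(data, meta = cohort$meta)
}

#' Flag the last observed trough of every subject as held out
#'
#' Marks, per subject, the chronologically last observation so that
#' downstream empirical Bayes estimation can exclude it and predict it,
#' mimicking prospective use of the model for dose individualization.
#' No rows are removed. Requires at least two observations per subject
#' (the study inclusion criterion).
#'
#' @param cohort A [pk_cohort].
#' @return The cohort with a logical `HELD` column, `TRUE` on exactly one
#'   observation row per subject.
#' @export
hold_out_last <- function(cohort) {
  stopifnot(inherits(cohort, "pk_cohort"))
  data <- cohort$data
  obs <- data$EVID == 0
  n_obs <- tapply(obs, data$ID, sum)
  if (any(n_obs < 2)) {
    stop("validation error: subject(s) with fewer than 2 observations ",
         "(inclusion requires at least two trough concentrations): ",
         paste(names(n_obs)[n_obs < 2], collapse = ", "), call. = FALSE)
  }
  data$HELD <- FALSE
  for (id in unique(data$ID)) {
    rows <- which(data$ID == id & obs)
    last <- rows[which.max(data$TIME[rows])]
    data$HELD[last] <- TRUE
  }
  out <- cohort
  out$data <- data
  out
}

#' @export
print.pk_cohort <- function(x, ...) {
  d <- x$data
  cat("PK cohort:", length(unique(d$ID)), "subjects,",
      sum(d$EVID == 1), "doses,", sum(d$EVID == 0), "observations\n")
  if (!is.null(d$HELD)) {
    cat("  held-out observations:", sum(d$HELD), "\n")
  }
  alb <- tapply(d$ALB, d$ID, function(v) mean(v, na.rm = TRUE))
  if (!all(is.na(alb))) {
    cat(sprintf("  albumin (per-subject mean): median %.2f, range %.2f-%.2f g/dL\n",
                stats::median(alb, na.rm = TRUE), min(alb, na.rm = TRUE),
                max(alb, na.rm = TRUE)))
  }
  invisible(x)
}

#' Number of subjects / observations in a cohort
#' @param cohort A [pk_cohort].
#' @return Integer count.
#' @export
n_subjects <- function(cohort) length(unique(cohort$data$ID))

#' @rdname n_subjects
#' @export
n_observations <- function(cohort) sum(cohort$data$EVID == 0)

#' Split a cohort into per-subject records
#'
#' Returns one `pk_subject` per subject: the dose history, the
#' observation list (with held-out flags if [hold_out_last()] ran), and
#' scalar covariates (per-subject means of `ALB`, rounded `AAA`).
#'
#' @param cohort A [pk_cohort].
#' @return Named list of `pk_subject` objects, in cohort order.
#' @export
cohort_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "pk_cohort"))
  d <- cohort$data
  if (is.null(d$HELD)) d$HELD <- FALSE
  ids <- unique(d$ID)
  out <- lapply(ids, function(id) {
    rows <- d[d$ID == id, , drop = FALSE]
    doses <- rows[rows$EVID == 1, c("TIME", "AMT")]
    obs <- rows[rows$EVID == 0, c("TIME", "DV", "HELD")]
    names(doses) <- c("time", "amt")
    names(obs) <- c("time", "dv", "held_out")
    rownames(doses) <- rownames(obs) <- NULL
    alb <- mean(rows$ALB, na.rm = TRUE)
    aaa <- round(mean(rows$AAA, na.rm = TRUE))
    extra <- setdiff(names(rows), c(.mandatory_cols, "HELD", "MDV"))
    cov <- lapply(rows[extra], function(v) mean(v, na.rm = TRUE))
    structure(list(id = id, doses = doses, obs = obs,
                   alb = alb, aaa = aaa, covariates = cov),
              class = "pk_subject")
  })
  names(out) <- ids
  out
}

#' @export
print.pk_subject <- function(x, ...) {
  cat("Subject", x$id, "-", nrow(x$doses), "doses,", nrow(x$obs),
      sprintf("observations; albumin %.2f g/dL, AAA %d\n", x$alb, x$aaa))
  invisible(x)
}
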