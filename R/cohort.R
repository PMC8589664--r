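#' PANSS item names
#'
#' The 30 items of the Positive and Negative Syndrome Scale in canonical
#' order: positive subscale P1-P7, negative subscale N1-N7, general
#' psychopathology subscale G1-G16. Every symptom matrix in this package
#' uses exactly these column names.
#'
#' @return Character vector of length 30.
#' @export
panss_items <- function() {
  c(paste0("P", 1:7), paste0("N", 1:7), paste0("G", 1:16))
}

# Non-PANSS columns with a fixed meaning; anything else in a cohort table is
# treated as a metabolite measurement.
cohort_reserved_cols <- function() {
  c("patient_id", panss_items(), "age", "sex", "gaf", "sofas",
    "working", "living_independently", "remission", "diagnosis")
}

#' Construct and validate a cohort table
#'
#' A cohort table is a tibble with one row per patient: a `patient_id`,
#' the 30 PANSS item scores (integers 1-7; `NA` allowed but such rows are
#' excluded from stratification), demographics (`age`, `sex`), functional
#' outcomes (`gaf`, `sofas` on 0-100; `working`, `living_independently`,
#' `remission` as logicals; `diagnosis` as a string) and any number of
#' additional numeric columns, which are interpreted as metabolite
#' measurements (micromolar for amino acids and glutathione,
#' umol/min/gHb for enzyme activities). Outcome and metabolite cells may
#' be missing.
#'
#' @param x A data frame with at least `patient_id` and the 30 PANSS
#'   columns named as in [panss_items()].
#' @return A validated tibble of class `cohort_table`.
#' @export
as_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  validate_cohort(x)
  class(x) <- c("cohort_table", class(x))
  x
}

#' @rdname as_cohort
#' @export
validate_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("patient_id", panss_items()), names(x))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- as.character(x$patient_id)
  if (anyDuplicated(ids)) {
    stop("duplicated patient_id values: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bad <- character(0)
  for (item in panss_items()) {
    v <- x[[item]]
    if (!is.numeric(v)) {
      stop("PANSS column ", item, " is not numeric", call. = FALSE)
    }
    ok <- is.na(v) | (v >= 1 & v <= 7 & v == round(v))
    if (!all(ok)) {
      rows <- which(!ok)
      bad <- c(bad, sprintf("patient %s (row %d), item %s = %s",
                            ids[rows], rows, item, format(v[rows])))
    }
  }
  if (length(bad) > 0) {
    stop("PANSS values must be integers in [1, 7]; offending entries:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  if ("age" %in% names(x)) {
    v <- x$age
    if (any(!is.na(v) & v <= 0)) stop("age must be positive", call. = FALSE)
  }
  if ("sex" %in% names(x)) {
    v <- x$sex
    okv <- is.na(v) | v %in% c("male", "female")
    if (!all(okv)) {
      stop("sex must be 'male' or 'female'; found: ",
           paste(unique(v[!okv]), collapse = ", "), call. = FALSE)
    }
  }
  for (col in c("gaf", "sofas")) {
    if (col %in% names(x)) {
      v <- x[[col]]
      if (any(!is.na(v) & (v < 0 | v > 100))) {
        stop(col, " must lie in [0, 100]", call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' Read a cohort table from CSV
#'
#' One row per patient; columns named as in the cohort-table contract
#' (see [as_cohort()]). Missing values are empty cells. An optional
#' `schema` renames file columns to the canonical names before
#' validation, e.g. `c(patient_id = "subject")` if the file calls the
#' identifier column `subject`.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to file column names.
#' @return A `cohort_table` tibble.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      file_col <- schema[[canonical]]
      if (!file_col %in% names(x)) {
        stop("schema names file column '", file_col, "' which is absent",
             call. = FALSE)
      }
      names(x)[names(x) == file_col] <- canonical
    }
  }
  for (col in c("working", "living_independently", "remission")) {
    if (col %in% names(x) && !is.logical(x[[col]])) {
      x[[col]] <- as.logical(x[[col]])
    }
  }
  if ("patient_id" %in% names(x)) x$patient_id <- as.character(x$patient_id)
  as_cohort(x)
}

#' Write a cohort table to CSV
#'
#' Values round-trip exactly: doubles are serialized with
#' shortest-round-trip precision and missing values as empty cells, so
#' `read_cohort(write_cohort(x, f))` reproduces `x`.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(tibble::as_tibble(cohort), path, na = "")
  invisible(path)
}

#' Extract the symptom matrix from a cohort
#'
#' Returns the n x 30 integer matrix of PANSS scores, rows named by
#' `patient_id`. Rows with any missing PANSS item cannot enter the
#' stratification; by default they are dropped with a message.
#'
#' @param cohort A `cohort_table` (or a data frame with the PANSS columns).
#' @param complete_only Drop rows with missing PANSS items (default `TRUE`).
#' @return Numeric matrix with columns [panss_items()].
#' @export
panss_matrix <- function(cohort, complete_only = TRUE) {
  m <- as.matrix(cohort[, panss_items()])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(cohort$patient_id)
  if (complete_only) {
    keep <- stats::complete.cases(m)
    if (!all(keep)) {
      message(sum(!keep), " patient(s) with incomplete PANSS dropped from the symptom matrix")
      m <- m[keep, , drop = FALSE]
    }
  }
  m
}

#' Names of metabolite columns in a cohort table
#'
#' Any column that is not part of the fixed cohort schema is treated as a
#' metabolite measurement.
#'
#' @param cohort A `cohort_table`.
#' @return Character vector (possibly empty).
#' @export
metabolite_names <- function(cohort) {
  setdiff(names(cohort), cohort_reserved_cols())
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table: ", nrow(x), " patients, ",
      length(metabolite_names(x)), " metabolite column(s)\n", sep = "")
  NextMethod()
}
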