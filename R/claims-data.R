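# Linked claims tables: the universal input of the pipeline.

.claims_schema <- list(
  patients = c(patient_id = "character", age = "integer", sex = "character",
               region = "character", diagnoses = "character"),
  practices = c(practice_id = "character", specialty = "character",
                region = "character"),
  encounters = c(encounter_id = "character", patient_id = "character",
                 practice_id = "character", year = "integer",
                 emergency = "logical"),
  prescriptions = c(prescription_id = "character", patient_id = "character",
                    practice_id = "character", encounter_id = "character",
                    year = "integer", drug_class = "character")
)

.coerce_table <- function(df, table) {
  schema <- .claims_schema[[table]]
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema error: table '%s' is missing column(s): %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra) > 0) {
    warning(sprintf("table '%s': ignoring unknown column(s): %s",
                    table, paste(extra, collapse = ", ")), call. = FALSE)
  }
  df <- df[names(schema)]
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = as.character(df[[col]]),
      integer = as.integer(df[[col]]),
      logical = as.logical(df[[col]]))
  }
  id_col <- names(schema)[1]
  df <- df[order(df[[id_col]]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assemble a claims dataset
#'
#' Bundles the four linked claims tables (patients, practices, encounters,
#' prescriptions) into a validated `claims_dataset` object. Columns are
#' coerced to a fixed schema and rows sorted by their id column so that two
#' datasets with the same content are identical object-wise.
#'
#' @param patients data frame with columns `patient_id`, `age`, `sex`,
#'   `region`, `diagnoses` (a `;`-separated set of diagnosis codes).
#' @param practices data frame with columns `practice_id`, `specialty`,
#'   `region`.
#' @param encounters data frame with columns `encounter_id`, `patient_id`,
#'   `practice_id`, `year`, `emergency`.
#' @param prescriptions data frame with columns `prescription_id`,
#'   `patient_id`, `practice_id`, `encounter_id`, `year`, `drug_class`.
#' @param validate check referential integrity and invariants (default TRUE).
#' @return A `claims_dataset`: a list of the four coerced tables.
#' @export
claims_dataset <- function(patients, practices, encounters, prescriptions,
                           validate = TRUE) {
  x <- structure(
    list(patients = .coerce_table(patients, "patients"),
         practices = .coerce_table(practices, "practices"),
         encounters = .coerce_table(encounters, "encounters"),
         prescriptions = .coerce_table(prescriptions, "prescriptions")),
    class = "claims_dataset")
  if (validate) validate_claims(x)
  x
}

#' Validate a claims dataset
#'
#' Checks that every encounter and prescription references an existing
#' patient and practice, that ages are non-negative, and that encounters
#' never cross regions (the patient's and the practice's region agree).
#'
#' @param x a [claims_dataset()].
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_claims <- function(x) {
  stopifnot(inherits(x, "claims_dataset"))
  p <- x$patients; pr <- x$practices; e <- x$encounters; rx <- x$prescriptions
  if (anyDuplicated(p$patient_id)) stop("duplicate patient_id in patients table")
  if (anyDuplicated(pr$practice_id)) stop("duplicate practice_id in practices table")
  if (nrow(p) > 0 && any(p$age < 0, na.rm = TRUE)) stop("negative patient age")
  bad <- setdiff(e$patient_id, p$patient_id)
  if (length(bad) > 0)
    stop("encounters reference unknown patient(s), e.g. ", bad[1])
  bad <- setdiff(e$practice_id, pr$practice_id)
  if (length(bad) > 0)
    stop("encounters reference unknown practice(s), e.g. ", bad[1])
  bad <- setdiff(rx$patient_id, p$patient_id)
  if (length(bad) > 0)
    stop("prescriptions reference unknown patient(s), e.g. ", bad[1])
  bad <- setdiff(rx$practice_id, pr$practice_id)
  if (length(bad) > 0)
    stop("prescriptions reference unknown practice(s), e.g. ", bad[1])
  if (nrow(e) > 0) {
    preg <- setNames(p$region, p$patient_id)
    qreg <- setNames(pr$region, pr$practice_id)
    if (any(preg[e$patient_id] != qreg[e$practice_id]))
      stop("encounter crosses regions: patient and practice region differ")
  }
  invisible(x)
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat(sprintf("  patients:      %d (regions: %s)\n", nrow(x$patients),
              paste(sort(unique(x$patients$region)), collapse = ", ")))
  cat(sprintf("  practices:     %d\n", nrow(x$practices)))
  cat(sprintf("  encounters:    %d\n", nrow(x$encounters)))
  cat(sprintf("  prescriptions: %d\n", nrow(x$prescriptions)))
  invisible(x)
}

#' Write a claims dataset to a directory of CSV tables
#'
#' Emits `patients.csv`, `practices.csv`, `encounters.csv`,
#' `prescriptions.csv` with the documented headers. The round trip through
#' [read_claims()] is lossless.
#'
#' @param x a [claims_dataset()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_claims <- function(x, dir) {
  stopifnot(inherits(x, "claims_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in names(.claims_schema)) {
    write.csv(x[[tab]], file.path(dir, paste0(tab, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a claims dataset from a directory of CSV tables
#'
#' Tolerant reader: unknown extra columns are dropped with a warning; a
#' missing table or missing required column raises a schema error naming the
#' table and column.
#'
#' @param dir directory containing the four CSV tables.
#' @param validate check invariants after reading (default TRUE).
#' @return a [claims_dataset()].
#' @export
read_claims <- function(dir, validate = TRUE) {
  tabs <- list()
  for (tab in names(.claims_schema)) {
    path <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("schema error: table '%s' not found (expected %s)", tab, path),
           call. = FALSE)
    }
    tabs[[tab]] <- read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  claims_dataset(tabs$patients, tabs$practices, tabs$encounters,
                 tabs$prescriptions, validate = validate)
}

#' Test whether ages qualify as senior
#'
#' @param age numeric vector of ages in years.
#' @param cutoff senior age cutoff (default 65).
#' @param comparison `"geq"` (age >= cutoff, default) or `"gt"` (age > cutoff).
#' @return logical vector.
#' @export
is_senior <- function(age, cutoff = 65, comparison = c("geq", "gt")) {
  comparison <- match.arg(comparison)
  if (comparison == "geq") age >= cutoff else age > cutoff
}

# Split a ";"-joined diagnosis string column into a long (id, code) frame.
dx_long <- function(patients) {
  has <- !is.na(patients$diagnoses) & nzchar(patients$diagnoses)
  if (!any(has)) {
    return(data.frame(patient_id = character(), code = character(),
                      stringsAsFactors = FALSE))
  }
  codes <- strsplit(patients$diagnoses[has], ";", fixed = TRUE)
  data.frame(patient_id = rep(patients$patient_id[has], lengths(codes)),
             code = unlist(codes), stringsAsFactors = FALSE)
}

# Restrict a dataset to one region (patients, practices and claims).
subset_region <- function(x, region) {
  stopifnot(inherits(x, "claims_dataset"))
  claims_dataset(
    x$patients[x$patients$region == region, , drop = FALSE],
    x$practices[x$practices$region == region, , drop = FALSE],
    x$encounters[x$encounters$practice_id %in%
                   x$practices$practice_id[x$practices$region == region], ,
                 drop = FALSE],
    x$prescriptions[x$prescriptions$practice_id %in%
                      x$practices$practice_id[x$practices$region == region], ,
                    drop = FALSE],
    validate = FALSE)
}

#' Region labels present in a dataset
#' @param x a [claims_dataset()].
#' @return character vector of region labels in practice-table order.
#' @export
regions <- function(x) unique(x$practices$region)
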