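#' Feature schema for survey cohorts
#'
#' A `feature_schema` is an ordered description of the variables a cohort must
#' supply: the variable name, its kind (`numeric`, `binary`, `ordinal`,
#' `nominal`), measurement units for numeric variables, and the ordered level
#' set for categorical kinds. Binary features are stored with canonical levels
#' `No`/`Yes`; alternate spellings seen in survey exports (`0`/`1`,
#' `Carrier`/`Non-Carrier`) are accepted on read and canonicalised.
#'
#' @param entries a list of entries, each a list with elements `name`, `kind`,
#'   `units` (may be `""`), `levels` (required for binary/ordinal/nominal) and
#'   optionally `aliases`, a named character vector mapping alternate spellings
#'   to canonical levels.
#' @return an object of class `feature_schema`.
#' @seealso [default_schema()] for the 16-variable survey schema.
#' @export
feature_schema <- function(entries) {
  nms <- vapply(entries, function(e) e$name, character(1))
  if (anyDuplicated(nms))
    thal_error("thal_schema_error", "schema feature names must be unique")
  for (e in entries) {
    if (!e$kind %in% c("numeric", "binary", "ordinal", "nominal"))
      thal_error("thal_schema_error",
                 sprintf("unknown kind '%s' for feature '%s'", e$kind, e$name))
    if (e$kind != "numeric" && length(e$levels) < 2L)
      thal_error("thal_schema_error",
                 sprintf("categorical feature '%s' needs >= 2 levels", e$name))
  }
  structure(list(entries = entries), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> with", length(x$entries), "features\n")
  for (e in x$entries) {
    lv <- if (e$kind == "numeric") e$units else paste(e$levels, collapse = "/")
    cat(sprintf("  %-28s %-8s %s\n", e$name, e$kind, lv))
  }
  invisible(x)
}

schema_names <- function(schema) {
  vapply(schema$entries, function(e) e$name, character(1))
}

schema_entry <- function(schema, name) {
  i <- match(name, schema_names(schema))
  if (is.na(i))
    thal_error("thal_schema_error", sprintf("feature '%s' not in schema", name))
  schema$entries[[i]]
}

#' Default 16-feature survey schema
#'
#' The schema used throughout the package: demographic and reproductive
#' variables (Age, BMI, Parity), hereditary flags (family history, genetic
#' marker, known carrier status), socioeconomic context (status, education,
#' residence) and the complete-blood-count indices (Hb g/dL, Hct %, MCV fL,
#' MCH pg, MCHC g/dL, RDW %, RBC million cells/uL).
#'
#' @return a [feature_schema()] with 16 entries.
#' @export
default_schema <- function() {
  yn <- c("No", "Yes")
  yn_alias <- c("0" = "No", "1" = "Yes")
  feature_schema(list(
    list(name = "Age", kind = "numeric", units = "years"),
    list(name = "BMI", kind = "numeric", units = ""),
    list(name = "Hemoglobin_Level", kind = "numeric", units = "g/dL"),
    list(name = "Family_History_Thalassemia", kind = "binary", units = "",
         levels = yn, aliases = yn_alias),
    list(name = "Genetic_Marker_Presence", kind = "binary", units = "",
         levels = yn, aliases = yn_alias),
    list(name = "Socioeconomic_Status", kind = "ordinal", units = "",
         levels = c("Low", "Middle", "High")),
    list(name = "Education_Level", kind = "ordinal", units = "",
         levels = c("No formal education", "Primary", "Secondary",
                    "Higher Secondary", "Graduate")),
    list(name = "Residence", kind = "nominal", units = "",
         levels = c("Urban", "Rural")),
    list(name = "Parity", kind = "numeric", units = "births"),
    list(name = "Carrier_Status", kind = "binary", units = "",
         levels = yn,
         aliases = c(yn_alias, "Non-Carrier" = "No", "Non-Car." = "No",
                     "Carrier" = "Yes")),
    list(name = "Hct", kind = "numeric", units = "%"),
    list(name = "MCV", kind = "numeric", units = "fL"),
    list(name = "MCH", kind = "numeric", units = "pg"),
    list(name = "MCHC", kind = "numeric", units = "g/dL"),
    list(name = "RDW", kind = "numeric", units = "%"),
    list(name = "RBC_count", kind = "numeric", units = "million cells/uL")
  ))
}

is_missing_token <- function(x) {
  is.na(x) | (is.character(x) & (trimws(x) == "" | trimws(x) == "NA"))
}

canonical_level <- function(entry, x, rows = NULL) {
  x <- as.character(x)
  out <- x
  al <- entry$aliases
  if (!is.null(al)) {
    hit <- match(trimws(x), names(al))
    out[!is.na(hit)] <- al[hit[!is.na(hit)]]
  }
  miss <- is_missing_token(out)
  bad <- !miss & !(out %in% entry$levels)
  if (any(bad)) {
    where <- if (is.null(rows)) which(bad)[1] else rows[which(bad)[1]]
    thal_error("thal_level_error",
               sprintf("feature '%s': value '%s' (row %d) not among levels %s",
                       entry$name, x[bad][1], where,
                       paste(entry$levels, collapse = "/")))
  }
  out[miss] <- NA_character_
  out
}

#' Construct a validated cohort
#'
#' A `cohort` binds a record table to a [feature_schema()]. Numeric columns
#' must parse to finite numbers (missing markers become `NA`), categorical
#' columns must draw from the declared levels (alternate spellings are
#' canonicalised). Columns beyond the schema are retained as passthrough
#' metadata.
#'
#' @param data a data.frame with one row per patient.
#' @param schema a [feature_schema()]; defaults to [default_schema()].
#' @param ids optional identifier vector (defaults to a `Patient_ID` column if
#'   present, else `1:n`).
#' @param labels optional per-record diagnosis/carrier label vector.
#' @return an object of class `cohort` with elements `schema`, `data`
#'   (canonicalised schema columns), `ids`, `labels`, `extra` (passthrough
#'   columns).
#' @export
cohort <- function(data, schema = default_schema(), ids = NULL, labels = NULL) {
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols))
    thal_error("thal_schema_error",
               sprintf("required column(s) missing: %s",
                       paste(missing_cols, collapse = ", ")))
  n <- nrow(data)
  out <- data.frame(row.names = seq_len(max(n, 0L)))
  for (e in schema$entries) {
    col <- data[[e$name]]
    if (e$kind == "numeric") {
      if (is.character(col)) {
        raw <- col
        miss <- is_missing_token(raw)
        val <- suppressWarnings(as.numeric(raw))
        bad <- !miss & is.na(val)
        if (any(bad))
          thal_error("thal_parse_error",
                     sprintf("feature '%s': cannot parse '%s' as numeric (row %d)",
                             e$name, raw[bad][1], which(bad)[1]))
        col <- val
      } else {
        col <- as.numeric(col)
      }
      if (any(!is.na(col) & !is.finite(col)))
        thal_error("thal_parse_error",
                   sprintf("feature '%s': non-finite value", e$name))
    } else {
      col <- canonical_level(e, col, rows = seq_len(n))
    }
    out[[e$name]] <- col
  }
  if (is.null(ids)) {
    ids <- if ("Patient_ID" %in% names(data)) data[["Patient_ID"]] else seq_len(n)
  }
  extra <- data[setdiff(names(data), c(nms, "Patient_ID"))]
  structure(list(schema = schema, data = out, ids = ids, labels = labels,
                 extra = extra),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$data), "records x", length(x$schema$entries),
      "features\n")
  invisible(x)
}

#' Number of records in a cohort
#' @param cohort a [cohort()].
#' @return integer record count.
#' @export
n_records <- function(cohort) nrow(cohort$data)

#' Read a cohort from CSV
#'
#' Reads a UTF-8, comma-delimited file with a header row whose names cover the
#' schema (order-insensitive; extra columns are kept as metadata) and validates
#' it via [cohort()].
#'
#' @param path path to a CSV file.
#' @inheritParams cohort
#' @return a [cohort()].
#' @export
read_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path))
    thal_error("thal_io_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  cohort(df, schema = schema)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes ids, schema columns, labels and
#' passthrough columns so that reading the file back reproduces the cohort.
#'
#' @param cohort a [cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cbind(data.frame(Patient_ID = cohort$ids), cohort$data)
  if (!is.null(cohort$labels)) df$Diagnosis <- cohort$labels
  if (ncol(cohort$extra)) df <- cbind(df, cohort$extra)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Per-feature missingness summary
#'
#' Counts missing markers (empty cells, `NA` tokens) per schema feature.
#'
#' @param cohort a [cohort()].
#' @return a `missingness_report`: data.frame with columns `feature`,
#'   `missing`, plus attribute `total` (record count).
#' @export
missingness <- function(cohort) {
  counts <- vapply(cohort$data, function(col) sum(is.na(col)), integer(1))
  out <- data.frame(feature = names(counts), missing = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(cohort$data)
  class(out) <- c("missingness_report", "data.frame")
  out
}

#' Encode a cohort into a numeric matrix
#'
#' Binary features map to 0/1 (level order `No` = 0, `Yes` = 1), ordinal
#' features to consecutive integer codes in level order starting at 0, nominal
#' features to one-hot indicator columns (`feature.level`), numeric features
#' pass through. The level-to-code mapping is recorded so categorical values
#' round-trip exactly via [decode_matrix()].
#'
#' @param cohort a [cohort()].
#' @param max_missing maximum tolerated fraction of missing entries per
#'   feature (default 0: any missing value is an error, mirroring a
#'   complete-case survey pipeline).
#' @return an `encoded_matrix`: list with `values` (samples x features numeric
#'   matrix), `encoding` (per-feature mapping), `schema`.
#' @export
encode_cohort <- function(cohort, max_missing = 0) {
  n <- nrow(cohort$data)
  mats <- list()
  encoding <- list()
  for (e in cohort$schema$entries) {
    col <- cohort$data[[e$name]]
    nmiss <- sum(is.na(col))
    if (n > 0 && nmiss / n > max_missing)
      thal_error("thal_missing_error",
                 sprintf("feature '%s' has %d missing value(s)", e$name, nmiss))
    if (e$kind == "numeric") {
      mats[[e$name]] <- matrix(as.numeric(col), ncol = 1,
                               dimnames = list(NULL, e$name))
      encoding[[e$name]] <- list(kind = "numeric")
    } else if (e$kind %in% c("binary", "ordinal")) {
      codes <- seq_along(e$levels) - 1L
      names(codes) <- e$levels
      mats[[e$name]] <- matrix(as.numeric(codes[col]), ncol = 1,
                               dimnames = list(NULL, e$name))
      encoding[[e$name]] <- list(kind = e$kind, codes = codes)
    } else { # nominal -> one-hot
      cols <- paste(e$name, e$levels, sep = ".")
      m <- matrix(0, nrow = n, ncol = length(e$levels),
                  dimnames = list(NULL, cols))
      for (k in seq_along(e$levels)) m[, k] <- as.numeric(col == e$levels[k])
      mats[[e$name]] <- m
      encoding[[e$name]] <- list(kind = "nominal", levels = e$levels,
                                 columns = cols)
    }
  }
  values <- do.call(cbind, unname(mats))
  if (is.null(values)) values <- matrix(numeric(0), nrow = n, ncol = 0)
  structure(list(values = values, encoding = encoding, schema = cohort$schema),
            class = "encoded_matrix")
}

#' Decode an encoded matrix back to categorical values
#'
#' @param encoded an `encoded_matrix` from [encode_cohort()].
#' @return a data.frame with the original (canonical-level) columns.
#' @export
decode_matrix <- function(encoded) {
  out <- data.frame(row.names = seq_len(nrow(encoded$values)))
  for (e in encoded$schema$entries) {
    enc <- encoded$encoding[[e$name]]
    if (enc$kind == "numeric") {
      out[[e$name]] <- encoded$values[, e$name]
    } else if (enc$kind %in% c("binary", "ordinal")) {
      out[[e$name]] <- names(enc$codes)[match(encoded$values[, e$name],
                                              enc$codes)]
    } else {
      sub <- encoded$values[, enc$columns, drop = FALSE]
      out[[e$name]] <- enc$levels[max.col(sub)]
    }
  }
  out
}

#' Map schema feature names to encoded column names
#'
#' @param encoded an `encoded_matrix`.
#' @param features character vector of schema feature names.
#' @return character vector of matrix column names.
#' @export
encoded_columns <- function(encoded, features) {
  unlist(lapply(features, function(f) {
    enc <- encoded$encoding[[f]]
    if (is.null(enc))
      thal_error("thal_schema_error", sprintf("feature '%s' not encoded", f))
    if (enc$kind == "nominal") enc$columns else f
  }), use.names = FALSE)
}
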