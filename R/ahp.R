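# Analytic Hierarchy Process: reciprocal judgment matrix -> column
# normalization -> row-mean weights -> lambda_max/CI/CR diagnostics.

# Random Index for reciprocal matrices of order n (Saaty's standard table).
AHP_RANDOM_INDEX <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
                      1.51, 1.48, 1.56, 1.57, 1.59)

#' Pairwise judgments on the Saaty scale
#'
#' Holds the upper-triangle expert judgments comparing `n` criteria. Each
#' judgment states how strongly the row criterion is preferred to the column
#' criterion, on the 1-9 fundamental scale (reciprocals encode the inverse
#' preference). The full matrix is reconstructed with exact reciprocals, so a
#' judgment of 3 stores 1/3 at full precision in the mirrored cell.
#'
#' @param criteria ordered character vector of criterion names (n >= 2).
#' @param judgments data.frame with columns `row`, `column`, `value`, one row
#'   per ordered criterion pair (i before j in `criteria`).
#' @return an object of class `pairwise_judgments`.
#' @export
pairwise_judgments <- function(criteria, judgments) {
  n <- length(criteria)
  if (n < 2) thal_error("thal_ahp_error", "need at least 2 criteria")
  if (anyDuplicated(criteria))
    thal_error("thal_ahp_error", "criteria names must be unique")
  need <- c("row", "column", "value")
  if (!all(need %in% names(judgments)))
    thal_error("thal_ahp_error", "judgments need columns row, column, value")
  v <- as.numeric(judgments$value)
  if (any(!is.finite(v) | v <= 0))
    thal_error("thal_scale_error", "judgments must be positive finite numbers")
  if (any(v < 1 / 9 - 1e-9 | v > 9 + 1e-9))
    thal_warn("thal_scale_warning",
              "judgment outside the Saaty [1/9, 9] scale")
  structure(list(criteria = criteria, judgments = judgments),
            class = "pairwise_judgments")
}

#' Read pairwise judgments from CSV
#'
#' Accepts either long form (`row,column,value`, upper triangle) or a full
#' square matrix with criterion names in the header and first column. For a
#' full matrix, the upper triangle is taken as the elicited judgments and
#' exact reciprocals are recomputed (printed roundings such as 0.333 in the
#' lower triangle are discarded).
#'
#' @param path CSV path.
#' @param criteria optional criterion ordering; defaults to first-appearance
#'   order in the file.
#' @return a [pairwise_judgments()].
#' @export
read_judgments <- function(path, criteria = NULL) {
  if (!file.exists(path))
    thal_error("thal_io_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (all(c("row", "column", "value") %in% names(df))) {
    if (is.null(criteria))
      criteria <- unique(c(df$row, df$column))
    return(pairwise_judgments(criteria, df))
  }
  # full-matrix form
  rn <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (is.null(criteria)) criteria <- rn
  long <- do.call(rbind, lapply(seq_along(criteria)[-length(criteria)],
    function(i) {
      j <- seq.int(i + 1, length(criteria))
      data.frame(row = criteria[i], column = criteria[j],
                 value = m[i, j], stringsAsFactors = FALSE)
    }))
  pairwise_judgments(criteria, long)
}

#' The packaged expert judgment fixture
#'
#' Upper-triangle judgments over the ten AHP criteria (Hct, MCHC, BMI, MCH,
#' RDW, RBC count, hemoglobin level, family history, socioeconomic status,
#' MCV), shipped with the package.
#'
#' @return a [pairwise_judgments()].
#' @export
reference_judgments <- function() {
  read_judgments(system.file("extdata", "table7_pairwise.csv",
                             package = "thalrisk", mustWork = TRUE))
}

#' Build the reciprocal comparison matrix
#'
#' Fills an `n x n` matrix from upper-triangle judgments: unit diagonal and
#' exact reciprocals `a_ji = 1/a_ij`.
#'
#' @param judgments a [pairwise_judgments()].
#' @return a `pairwise_matrix`: positive reciprocal numeric matrix with
#'   criterion dimnames.
#' @export
build_matrix <- function(judgments) {
  crit <- judgments$criteria
  n <- length(crit)
  A <- diag(1, n)
  dimnames(A) <- list(crit, crit)
  jd <- judgments$judgments
  for (r in seq_len(nrow(jd))) {
    i <- match(jd$row[r], crit)
    j <- match(jd$column[r], crit)
    if (is.na(i) || is.na(j))
      thal_error("thal_ahp_error",
                 sprintf("judgment references unknown criterion '%s'",
                         if (is.na(i)) jd$row[r] else jd$column[r]))
    v <- as.numeric(jd$value[r])
    if (!is.finite(v) || v <= 0)
      thal_error("thal_scale_error", "non-positive judgment value")
    A[i, j] <- v
    A[j, i] <- 1 / v
  }
  class(A) <- c("pairwise_matrix", class(A))
  A
}

assert_reciprocal <- function(A, tol = 1e-9) {
  if (nrow(A) != ncol(A) || any(abs(diag(A) - 1) > tol) ||
      any(abs(A * t(A) - 1) > tol))
    thal_error("thal_ahp_error", "matrix is not a reciprocal judgment matrix")
  invisible(A)
}

#' Column-normalize a comparison matrix
#'
#' Divides each entry by its column sum, yielding a column-stochastic matrix.
#'
#' @param A a `pairwise_matrix` from [build_matrix()].
#' @return a `normalized_matrix` (columns sum to 1).
#' @export
normalize_matrix <- function(A) {
  assert_reciprocal(unclass(A))
  N <- sweep(A, 2, colSums(A), "/")
  class(N) <- c("normalized_matrix", "matrix", "array")
  N
}

#' Derive criterion weights by row averaging
#'
#' The weight of each criterion is the mean of its row in the
#' column-normalized matrix; the weights sum to 1 by construction.
#'
#' @param N a `normalized_matrix` from [normalize_matrix()].
#' @return named numeric weight vector.
#' @export
compute_weights <- function(N) {
  if (any(abs(colSums(N) - 1) > 1e-9))
    thal_error("thal_ahp_error", "matrix is not column-stochastic")
  rowMeans(N)
}

#' Consistency diagnostics for a judgment matrix
#'
#' Computes the weighted-sum vector `AW`, the maximum-eigenvalue estimate
#' `lambda_max` as the mean of the component ratios `(AW)_i / w_i`, the
#' consistency index `CI = (lambda_max - n) / (n - 1)` and the consistency
#' ratio `CR = CI / RI` using the standard Random Index table. Judgments with
#' `CR < 0.1` are conventionally acceptable. For `n <= 2` a reciprocal matrix
#' is always consistent and `CR = 0`.
#'
#' @param A a `pairwise_matrix`.
#' @param w weight vector (defaults to the row-average weights of `A`).
#' @return a `consistency_report`: list with `aw`, `lambda_max`, `ci`, `ri`,
#'   `cr`, `acceptable`, `n`.
#' @export
consistency <- function(A, w = NULL) {
  assert_reciprocal(unclass(A))
  n <- nrow(A)
  if (is.null(w)) w <- compute_weights(normalize_matrix(A))
  if (length(w) != n)
    thal_error("thal_ahp_error", "weight length does not match matrix order")
  aw <- as.numeric(A %*% w)
  lambda_max <- mean(aw / w)
  if (n <= 2) {
    ci <- 0; ri <- 0; cr <- 0
  } else {
    if (n > length(AHP_RANDOM_INDEX))
      thal_error("thal_ahp_error",
                 sprintf("no Random Index tabulated for n = %d", n))
    ci <- (lambda_max - n) / (n - 1)
    ri <- AHP_RANDOM_INDEX[n]
    cr <- ci / ri
  }
  structure(list(aw = aw, lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
                 acceptable = cr < 0.1, n = n),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> n=%d lambda_max=%.4f CI=%.4f RI=%.2f CR=%.4f (%s)\n",
              x$n, x$lambda_max, x$ci, x$ri, x$cr,
              if (x$acceptable) "acceptable, CR < 0.1" else "NOT acceptable"))
  invisible(x)
}

#' One-call AHP weight derivation with consistency gate
#'
#' Runs build -> normalize -> weights -> consistency. If the consistency
#' ratio is 0.1 or above, a warning is raised, and an error unless
#' `override_cr = TRUE` (the consistency check is treated as a gate).
#'
#' @param judgments a [pairwise_judgments()].
#' @param override_cr proceed despite an unacceptable CR (default `FALSE`).
#' @return list with `matrix`, `normalized`, `weights`, `consistency`.
#' @export
ahp_weights <- function(judgments, override_cr = FALSE) {
  A <- build_matrix(judgments)
  N <- normalize_matrix(A)
  w <- compute_weights(N)
  cons <- consistency(A, w)
  if (!cons$acceptable) {
    thal_warn("thal_cr_warning",
              sprintf("consistency ratio %.4f >= 0.1", cons$cr))
    if (!override_cr)
      thal_error("thal_cr_error",
                 sprintf("judgments inconsistent (CR = %.4f >= 0.1); pass override_cr = TRUE to proceed",
                         cons$cr))
  }
  list(matrix = A, normalized = N, weights = w, consistency = cons)
}
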