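# TOPSIS scoring: min-max normalization, AHP weighting, ideal/anti-ideal
# profiles, Euclidean distances, relative closeness, ranking, and Pareto-style
# risk stratification.

#' Construct a decision matrix
#'
#' A samples-by-criteria numeric matrix together with its normalization state
#' and, once normalized, the per-criterion extremes used for scaling (needed
#' to score new samples against a frozen model without leakage).
#'
#' @param values numeric matrix (samples x criteria) with column names.
#' @param normalized logical; `TRUE` if values are already on the [0,1]
#'   min-max scale (e.g. a published normalized table).
#' @param mins,maxs per-criterion extremes used for scaling (recorded by
#'   [minmax_normalize()]).
#' @param weighted logical; `TRUE` once criterion weights have been applied.
#' @return an object of class `decision_matrix`.
#' @export
decision_matrix <- function(values, normalized = FALSE, mins = NULL,
                            maxs = NULL, weighted = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    thal_error("thal_topsis_error", "decision matrix needs criterion names")
  structure(list(values = values, criteria = colnames(values),
                 normalized = normalized, mins = mins, maxs = maxs,
                 weighted = weighted),
            class = "decision_matrix")
}

#' Min-max normalize a decision matrix
#'
#' Rescales each criterion to [0,1] by `(x - min) / (max - min)` using either
#' the matrix's own extremes or externally supplied ones (training-fold
#' extremes when scoring held-out samples; values are then clipped to [0,1]).
#'
#' @param M a [decision_matrix()].
#' @param mins,maxs optional frozen extremes; defaults to the observed
#'   columnwise min/max.
#' @return a normalized [decision_matrix()] with recorded extremes.
#' @export
minmax_normalize <- function(M, mins = NULL, maxs = NULL) {
  frozen <- !is.null(mins)
  if (is.null(mins)) mins <- apply(M$values, 2, min)
  if (is.null(maxs)) maxs <- apply(M$values, 2, max)
  rng <- maxs - mins
  if (any(rng <= 0)) {
    bad <- M$criteria[which(rng <= 0)[1]]
    thal_error("thal_degenerate_criterion_error",
               sprintf("criterion '%s' has zero range; cannot min-max scale", bad))
  }
  vals <- sweep(sweep(M$values, 2, mins, "-"), 2, rng, "/")
  if (frozen) vals <- pmin(pmax(vals, 0), 1)
  decision_matrix(vals, normalized = TRUE, mins = mins, maxs = maxs)
}

#' Apply criterion weights to a normalized matrix
#'
#' Multiplies each normalized criterion column by its weight (the weighted
#' normalized decision matrix).
#'
#' @param M a normalized [decision_matrix()].
#' @param w named (or positionally aligned) weight vector, one per criterion.
#' @return a weighted [decision_matrix()].
#' @export
apply_weights <- function(M, w) {
  if (!M$normalized)
    thal_error("thal_topsis_error", "matrix must be normalized before weighting")
  if (length(w) != length(M$criteria))
    thal_error("thal_alignment_error",
               "weight count does not match criterion count")
  if (!is.null(names(w))) {
    if (!setequal(names(w), M$criteria))
      thal_error("thal_alignment_error",
                 "weight names do not match criteria")
    w <- w[M$criteria]
  }
  out <- decision_matrix(sweep(M$values, 2, w, "*"), normalized = TRUE,
                         mins = M$mins, maxs = M$maxs, weighted = TRUE)
  attr(out, "weights") <- w
  out
}

#' Ideal and anti-ideal profiles
#'
#' Columnwise maxima (positive ideal) and minima (negative ideal) of the
#' weighted matrix, taken across all samples.
#'
#' @param W a weighted [decision_matrix()].
#' @return an `ideal_pair`: list with `positive` and `negative` named vectors.
#' @export
ideals <- function(W) {
  if (nrow(W$values) < 1)
    thal_error("thal_topsis_error", "need at least one sample")
  structure(list(positive = apply(W$values, 2, max),
                 negative = apply(W$values, 2, min)),
            class = "ideal_pair")
}

#' Relative closeness to the ideal profile
#'
#' Euclidean distances of each sample to the positive (`D+`) and negative
#' (`D-`) ideal, and relative closeness `D- / (D+ + D-)`. A sample at the
#' positive ideal scores 1; at the negative ideal, 0.
#'
#' @param W a weighted [decision_matrix()].
#' @param ip an `ideal_pair` (defaults to [ideals()] of `W` itself).
#' @return a `topsis_result`: data.frame with `d_plus`, `d_minus`,
#'   `closeness`; columns `rank` and `category` are added by [rank_results()]
#'   and [stratify()].
#' @export
closeness <- function(W, ip = ideals(W)) {
  dp <- sqrt(rowSums(sweep(W$values, 2, ip$positive, "-")^2))
  dm <- sqrt(rowSums(sweep(W$values, 2, ip$negative, "-")^2))
  denom <- dp + dm
  if (any(denom == 0))
    thal_error("thal_degenerate_cohort_error",
               "a sample is equidistant-zero from both ideals (all samples identical)")
  out <- data.frame(d_plus = dp, d_minus = dm, closeness = dm / denom)
  attr(out, "ideals") <- ip
  class(out) <- c("topsis_result", "data.frame")
  out
}

#' Rank samples by closeness
#'
#' Rank 1 is the highest closeness; ties receive stable ordinal ranks in
#' input order, so output files are reproducible.
#'
#' @param result a `topsis_result` from [closeness()].
#' @return the result with a `rank` column added.
#' @export
rank_results <- function(result) {
  ord <- order(-result$closeness, seq_len(nrow(result)))
  result$rank <- integer(nrow(result))
  result$rank[ord] <- seq_len(nrow(result))
  result
}

#' Stratification thresholds
#'
#' Closeness at or above `high` is High Risk, below `low` is Low Risk,
#' otherwise Medium Risk. The defaults follow the Pareto-style cutoffs used
#' for risk triage (>= 0.66 High, < 0.33 Low); the `high` boundary belongs to
#' High and the `low` boundary to Medium.
#'
#' @param high upper threshold (default 0.66).
#' @param low lower threshold (default 0.33).
#' @return a `stratification_config`.
#' @export
stratification_config <- function(high = 0.66, low = 0.33) {
  if (!(is.numeric(high) && is.numeric(low) && 0 < low && low < high && high < 1))
    thal_error("thal_config_error", "need 0 < low < high < 1")
  structure(list(high = high, low = low), class = "stratification_config")
}

RISK_LEVELS <- c("Low Risk", "Medium Risk", "High Risk")

#' Assign risk categories from closeness scores
#'
#' @param result a `topsis_result` (or bare numeric closeness vector).
#' @param cfg a [stratification_config()].
#' @return for a `topsis_result`, the result with a `category` factor column
#'   and a `strata_counts` attribute (counts and fractions per category); for
#'   a numeric vector, the factor of categories.
#' @export
stratify <- function(result, cfg = stratification_config()) {
  cl <- if (is.data.frame(result)) result$closeness else as.numeric(result)
  if (any(cl < 0 | cl > 1))
    thal_error("thal_config_error", "closeness values must lie in [0,1]")
  cat_chr <- ifelse(cl >= cfg$high, "High Risk",
                    ifelse(cl < cfg$low, "Low Risk", "Medium Risk"))
  categ <- factor(cat_chr, levels = RISK_LEVELS)
  if (!is.data.frame(result)) return(categ)
  result$category <- categ
  counts <- table(categ)
  attr(result, "strata_counts") <-
    data.frame(category = names(counts), count = as.integer(counts),
               fraction = as.numeric(counts) / max(1L, length(categ)))
  result
}

#' Score a cohort end to end
#'
#' Convenience wrapper: select the criterion columns from an encoded cohort,
#' min-max normalize (optionally with frozen extremes), weight, compute
#' closeness against supplied or self-derived ideals, rank and stratify.
#'
#' @param encoded an `encoded_matrix` from [encode_cohort()].
#' @param w named weight vector over criteria (schema feature names).
#' @param cfg a [stratification_config()].
#' @param mins,maxs optional frozen extremes (training-fold scaling).
#' @param ip optional frozen `ideal_pair`.
#' @return a ranked, stratified `topsis_result`; attributes `mins`, `maxs`,
#'   `ideals` record the scaling actually used.
#' @export
topsis_score <- function(encoded, w, cfg = stratification_config(),
                         mins = NULL, maxs = NULL, ip = NULL) {
  cols <- encoded_columns(encoded, names(w))
  M <- decision_matrix(encoded$values[, cols, drop = FALSE])
  colnames(M$values) <- names(w)
  M$criteria <- names(w)
  N <- minmax_normalize(M, mins = mins, maxs = maxs)
  W <- apply_weights(N, w)
  if (is.null(ip)) ip <- ideals(W)
  res <- stratify(rank_results(closeness(W, ip)), cfg)
  attr(res, "mins") <- N$mins
  attr(res, "maxs") <- N$maxs
  attr(res, "ideals") <- ip
  res
}
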