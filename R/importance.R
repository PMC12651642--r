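# Feature relevance scoring: ensemble impurity importance, univariate
# (ANOVA-style) F scores, and their fusion into a combined importance index.

feature_score_table <- function(method, features, raw) {
  fin <- raw[is.finite(raw)]
  rng <- if (length(fin)) max(fin) - min(fin) else 0
  normalized <- if (rng > 0) {
    (raw - min(fin)) / rng
  } else {
    # constant raw scores carry no ranking information
    rep(0, length(raw))
  }
  normalized[!is.finite(raw)] <- 1  # +Inf flag: maximally separating
  ord <- order(-raw, seq_along(raw))
  rank <- integer(length(raw))
  rank[ord] <- seq_along(raw)
  structure(data.frame(feature = features, method = method, raw = raw,
                       normalized = normalized, rank = rank,
                       stringsAsFactors = FALSE),
            class = c("feature_score_table", "data.frame"))
}

#' Impurity-based feature importance
#'
#' Fits a random-forest ensemble and reports each feature's mean decrease in
#' node impurity (Gini), renormalized so the raw scores sum to 1. The
#' ensemble fit is delegated to \pkg{randomForest}; this function only
#' renormalizes and ranks.
#'
#' @param x numeric feature matrix (samples x features).
#' @param labels class vector (factor or coercible), length `nrow(x)`.
#' @param trees number of trees (default 300).
#' @param seed random seed for the forest.
#' @return a `feature_score_table` (columns `feature`, `method`, `raw`,
#'   `normalized`, `rank`).
#' @export
impurity_importance <- function(x, labels, trees = 300L, seed = 1L) {
  labels <- factor(labels)
  if (length(labels) != nrow(x))
    thal_error("thal_argument_error", "labels length must equal row count")
  if (nlevels(droplevels(labels)) < 2)
    thal_error("thal_degenerate_label_error",
               "need at least two classes to measure importance")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = as.data.frame(x),
                                    y = droplevels(labels),
                                    ntree = trees, importance = FALSE)
  raw <- fit$importance[, "MeanDecreaseGini"]
  total <- sum(raw)
  if (total > 0) raw <- raw / total
  feature_score_table("impurity", colnames(x), as.numeric(raw))
}

#' Univariate F scores per feature
#'
#' Scores each feature's class separability as the ratio of between-class to
#' within-class variation. Three variants:
#' \describe{
#'   \item{`ratio`}{the plain sum-of-squares ratio
#'     `F_j = S_B / S_W` with
#'     `S_B = sum_k n_k (xbar_jk - xbar_j)^2` and
#'     `S_W = sum_k sum_i (x_ij - xbar_jk)^2` (the default).}
#'   \item{`df_adjusted`}{the classical one-way ANOVA F with degrees of
#'     freedom, i.e. `ratio * (n - k) / (k - 1)`; induces the same feature
#'     ranking at fixed `n`, `k`.}
#'   \item{`mutual_information`}{plug-in discrete mutual information between
#'     the (equal-frequency binned) feature and the class.}
#' }
#' A feature with zero within-class variance but nonzero between-class
#' variance scores `+Inf` (flagged, not an error).
#'
#' @param x numeric feature matrix.
#' @param labels class vector.
#' @param variant one of `"ratio"`, `"df_adjusted"`, `"mutual_information"`.
#' @param bins bin count for the mutual-information variant.
#' @return a `feature_score_table`; the variant is recorded in `method`.
#' @export
univariate_f_scores <- function(x, labels,
                                variant = c("ratio", "df_adjusted",
                                            "mutual_information"),
                                bins = 10L) {
  variant <- match.arg(variant)
  labels <- factor(labels)
  if (length(labels) != nrow(x))
    thal_error("thal_argument_error", "labels length must equal row count")
  labels <- droplevels(labels)
  k <- nlevels(labels)
  if (k < 2)
    thal_error("thal_degenerate_label_error", "need at least two classes")
  n <- nrow(x)
  raw <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (variant == "mutual_information") return(binned_mi(v, labels, bins))
    gm <- mean(v)
    sb <- 0; sw <- 0
    for (lev in levels(labels)) {
      vi <- v[labels == lev]
      sb <- sb + length(vi) * (mean(vi) - gm)^2
      sw <- sw + sum((vi - mean(vi))^2)
    }
    f <- if (sw == 0) {
      if (sb == 0) 0 else Inf
    } else sb / sw
    if (variant == "df_adjusted" && is.finite(f)) f * (n - k) / (k - 1) else f
  }, numeric(1))
  feature_score_table(paste0("univariate_", variant), colnames(x), raw)
}

# Plug-in MI between an equal-frequency-binned feature and the class labels.
binned_mi <- function(v, labels, bins) {
  brk <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
  b <- if (length(brk) < 2) factor(rep(1, length(v)))
       else cut(v, breaks = brk, include.lowest = TRUE)
  tab <- table(b, labels)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  mi
}

#' Fuse feature-score tables into a combined importance index
#'
#' Min-max normalizes each table's raw scores to [0,1] (already done in the
#' tables) and averages them per feature; ranks are assigned by descending
#' combined score with ties broken by the feature order of the first table.
#'
#' @param ... two or more `feature_score_table`s over the same feature set
#'   (order-insensitive), or a single list of them.
#' @return a `combined_importance`: data.frame with `feature`, `combined`,
#'   `rank`, plus one normalized-score column per contributing method.
#' @export
combine_importance <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && !is.data.frame(tables[[1]])) tables <- tables[[1]]
  if (length(tables) < 2)
    thal_error("thal_argument_error", "need at least two score tables")
  feats <- tables[[1]]$feature
  scores <- matrix(NA_real_, nrow = length(feats), ncol = length(tables))
  colnames(scores) <- vapply(tables, function(t) t$method[1], character(1))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    if (!setequal(t$feature, feats))
      thal_error("thal_alignment_error", "score tables cover different features")
    scores[, i] <- t$normalized[match(feats, t$feature)]
  }
  combined <- rowMeans(scores)
  ord <- order(-combined, seq_along(feats))
  rank <- integer(length(feats)); rank[ord] <- seq_along(feats)
  out <- data.frame(feature = feats, combined = combined, rank = rank,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores))
  class(out) <- c("combined_importance", "data.frame")
  out
}

#' Top-k features by combined importance
#'
#' @param combined a `combined_importance` from [combine_importance()].
#' @param k how many features (1 <= k <= number of features).
#' @return character vector of the first `k` features in rank order.
#' @export
top_k <- function(combined, k) {
  m <- nrow(combined)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > m)
    thal_error("thal_argument_error",
               sprintf("k must lie in [1, %d]", m))
  combined$feature[order(combined$rank)][seq_len(k)]
}
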