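# Attribution and statistical validation: tree-SHAP global attributions
# (delegated to xgboost's predcontrib), a kernel-weighted local linear
# surrogate for single-instance explanations, and Kruskal-Wallis / pairwise
# Mann-Whitney significance testing of attribution distributions.

#' Global per-sample feature attributions
#'
#' Computes tree-SHAP attribution values for every sample via the boosting
#' backend's native path-dependent algorithm. The additivity identity (base
#' value plus the attribution sum equals the prediction margin) is checked
#' and the maximum deviation recorded.
#'
#' @param model a `thal_model` fitted with the `extreme_gradient_boosting`
#'   backend.
#' @param x numeric matrix with exactly the model's training columns.
#' @param class_label for multiclass models, which class margin to attribute
#'   (default: the first class).
#' @return an `explanation_set`: list with `values` (samples x features
#'   signed attribution matrix), `base` (expected margin), `class_label`,
#'   `additivity_error`.
#' @export
global_attributions <- function(model, x, class_label = NULL) {
  if (model$algorithm != "extreme_gradient_boosting")
    thal_error("thal_model_error",
               "tree-SHAP attributions require the extreme_gradient_boosting backend")
  if (!identical(colnames(x), model$features))
    thal_error("thal_alignment_error",
               "attribution matrix columns must match the model's features")
  dm <- xgboost::xgb.DMatrix(as.matrix(x))
  contrib <- stats::predict(model$handle$fit, dm, predcontrib = TRUE)
  k <- model$handle$k
  if (k == 2) {
    vals <- contrib[, seq_len(ncol(x)), drop = FALSE]
    base <- contrib[1, ncol(x) + 1]
    if (is.null(class_label)) class_label <- model$classes[2]
    margin <- stats::predict(model$handle$fit, dm, outputmargin = TRUE)
  } else {
    if (is.null(class_label)) class_label <- model$classes[1]
    ci <- match(class_label, model$classes)
    if (is.na(ci))
      thal_error("thal_argument_error",
                 sprintf("unknown class '%s'", class_label))
    vals <- contrib[, ci, seq_len(ncol(x)), drop = TRUE]
    vals <- matrix(vals, nrow = nrow(x))
    base <- contrib[1, ci, ncol(x) + 1]
    margin <- stats::predict(model$handle$fit, dm, outputmargin = TRUE)[, ci]
  }
  colnames(vals) <- colnames(x)
  add_err <- max(abs(rowSums(vals) + base - margin))
  structure(list(values = vals, base = base, class_label = class_label,
                 additivity_error = add_err),
            class = "explanation_set")
}

#' Local explanation via a kernel-weighted linear surrogate
#'
#' Explains one prediction by sampling perturbations of the instance
#' (Gaussian noise scaled to per-feature spread of the background data),
#' querying the model's class probability on each, weighting perturbations by
#' an exponential kernel in scaled distance, and fitting a weighted linear
#' surrogate; the coefficients are the local feature weights.
#'
#' @param model a `thal_model`.
#' @param instance named numeric vector over the model's features.
#' @param background numeric matrix used for perturbation scale (training
#'   data).
#' @param n_perturb number of perturbed samples (>= 10).
#' @param seed random seed (the explanation is deterministic under it).
#' @param keep number of top-|weight| features reported.
#' @param kernel_width kernel width; default `0.75 * sqrt(p)` in scaled
#'   units.
#' @param target_class class whose probability is explained (default: the
#'   model's prediction for the instance).
#' @return a `local_explanation`: data.frame with `feature`, `weight`,
#'   `direction` (`supports`/`opposes`), ordered by |weight|; attributes
#'   record the seed, perturbation count and target class.
#' @export
local_explanation <- function(model, instance, background, n_perturb = 500L,
                              seed = 1L, keep = 10L, kernel_width = NULL,
                              target_class = NULL) {
  if (n_perturb < 10)
    thal_error("thal_argument_error", "n_perturb must be at least 10")
  feats <- model$features
  instance <- instance[feats]
  if (anyNA(instance))
    thal_error("thal_alignment_error",
               "instance does not supply every model feature")
  p <- length(feats)
  scale <- apply(background[, feats, drop = FALSE], 2, stats::sd)
  scale[scale == 0] <- 1
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_perturb * p), n_perturb, p)
  pert <- sweep(sweep(z, 2, scale, "*"), 2, instance, "+")
  colnames(pert) <- feats
  pert[1, ] <- instance  # include the instance itself

  prob <- predict_prob(model, pert)
  if (is.null(target_class))
    target_class <- as.character(predict(model, matrix(instance, nrow = 1,
                                                       dimnames = list(NULL, feats))))
  y <- prob[, target_class]
  d2 <- rowSums(z^2)
  wts <- exp(-d2 / kernel_width^2)
  xs <- sweep(sweep(pert, 2, instance, "-"), 2, scale, "/")
  fit <- stats::lm.wfit(cbind(1, xs), y, wts)
  coefs <- fit$coefficients[-1]
  names(coefs) <- feats
  ord <- order(-abs(coefs))[seq_len(min(keep, p))]
  out <- data.frame(feature = feats[ord], weight = unname(coefs[ord]),
                    direction = ifelse(coefs[ord] >= 0, "supports", "opposes"),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "n_perturb") <- n_perturb
  attr(out, "target_class") <- target_class
  class(out) <- c("local_explanation", "data.frame")
  out
}

# Class-probability matrix from any registered backend.
predict_prob <- function(model, x) {
  if (model$algorithm == "extreme_gradient_boosting") {
    p <- stats::predict(model$handle$fit,
                        xgboost::xgb.DMatrix(as.matrix(x)))
    if (model$handle$k == 2) {
      pm <- cbind(1 - p, p)
    } else {
      if (is.null(dim(p))) p <- matrix(p, ncol = model$handle$k, byrow = TRUE)
      pm <- p
    }
  } else if (model$algorithm == "random_forest") {
    pm <- stats::predict(model$handle$fit, as.data.frame(x), type = "prob")
  } else {
    thal_error("thal_model_error",
               sprintf("no probability predictor for backend '%s'",
                       model$algorithm))
  }
  colnames(pm) <- model$classes
  pm
}

#' Kruskal-Wallis tests of attributions across risk classes
#'
#' For each feature, compares the distribution of its attribution values
#' across the class groups with a Kruskal-Wallis rank test.
#'
#' @param explanations an `explanation_set`.
#' @param classes class vector, one per explained sample (>= 2 classes, each
#'   with >= 2 samples).
#' @return a data.frame with `feature`, `statistic` (H), `p`.
#' @export
kruskal_by_class <- function(explanations, classes) {
  classes <- droplevels(factor(classes))
  vals <- explanations$values
  if (length(classes) != nrow(vals))
    thal_error("thal_argument_error", "classes length must match sample count")
  if (nlevels(classes) < 2 || any(table(classes) < 2))
    thal_error("thal_argument_error",
               "need >= 2 classes with >= 2 samples each")
  res <- lapply(seq_len(ncol(vals)), function(j) {
    kt <- stats::kruskal.test(vals[, j], classes)
    data.frame(feature = colnames(vals)[j],
               statistic = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Two-sided Mann-Whitney p-value; exact when both groups are small and
# tie-free, normal approximation with tie correction otherwise.
mwu_p <- function(a, b, exact_max = 8L) {
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1) {
    out <- list(p = 1, tie_flag = TRUE)
    return(out)
  }
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(p = wt$p.value, tie_flag = ties)
}

#' Pairwise Mann-Whitney tests between feature attributions
#'
#' Runs a two-sided Mann-Whitney U test for every pair of features on their
#' per-sample attribution-value distributions, yielding a symmetric p-value
#' matrix with unit diagonal. Attributions are compared signed by default;
#' Benjamini-Hochberg adjustment of the off-diagonal p-values is optional and
#' always recorded in the `correction` attribute.
#'
#' @param explanations an `explanation_set` (>= 2 features, >= 3 samples).
#' @param absolute compare |attribution| instead of signed values.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param alpha significance threshold recorded with the report.
#' @return a `significance_matrix`: symmetric numeric matrix of p-values with
#'   attributes `correction`, `alpha`, `tie_flags`.
#' @export
pairwise_mwu <- function(explanations, absolute = FALSE,
                         adjust = c("none", "BH"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  vals <- explanations$values
  if (ncol(vals) < 2)
    thal_error("thal_argument_error", "need at least two features")
  if (nrow(vals) < 3)
    thal_error("thal_argument_error", "need at least three samples")
  if (absolute) vals <- abs(vals)
  m <- ncol(vals)
  P <- matrix(1, m, m, dimnames = list(colnames(vals), colnames(vals)))
  tie_flags <- matrix(FALSE, m, m, dimnames = dimnames(P))
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      r <- mwu_p(vals[, i], vals[, j])
      P[i, j] <- P[j, i] <- r$p
      tie_flags[i, j] <- tie_flags[j, i] <- r$tie_flag
    }
  }
  if (adjust == "BH") {
    up <- upper.tri(P)
    P[up] <- stats::p.adjust(P[up], method = "BH")
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  structure(P, class = c("significance_matrix", "matrix", "array"),
            correction = adjust, alpha = alpha, tie_flags = tie_flags)
}

#' Shade for a p-value (darker = more significant)
#'
#' Monotone mapping used by [heatmap_export()]: p = 0 maps to black, p = 1 to
#' white.
#'
#' @param p p-values in [0,1].
#' @return gray colour strings.
#' @export
p_shade <- function(p) grDevices::gray(pmin(pmax(p, 0), 1))

#' Export a significance matrix as heatmap and CSV
#'
#' Writes a PNG heatmap (darker cells for lower p-values) and a CSV of the
#' matrix, plus a JSON sidecar recording the correction tag and threshold.
#'
#' @param P a `significance_matrix` from [pairwise_mwu()].
#' @param path output path stem; `.png`, `.csv`, `.json` files are written.
#' @return named character vector of the files written, invisibly.
#' @export
heatmap_export <- function(P, path) {
  png_path <- paste0(path, ".png")
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  m <- ncol(P)
  ok <- tryCatch({
    grDevices::png(png_path, width = 160 + 40 * m, height = 160 + 40 * m)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(8, 8, 2, 2))
    graphics::image(seq_len(m), seq_len(m), t(unclass(P)[m:1, , drop = FALSE]),
                    col = p_shade(seq(0, 1, length.out = 256)),
                    zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "")
    graphics::axis(1, at = seq_len(m), labels = colnames(P), las = 2)
    graphics::axis(2, at = seq_len(m), labels = rev(rownames(P)), las = 2)
    TRUE
  }, error = function(e) {
    thal_error("thal_io_error",
               sprintf("cannot write heatmap to %s: %s", png_path,
                       conditionMessage(e)))
  })
  utils::write.csv(as.data.frame(unclass(P)), csv_path, row.names = TRUE)
  jsonlite::write_json(list(correction = attr(P, "correction"),
                            alpha = attr(P, "alpha")),
                       json_path, auto_unbox = TRUE)
  invisible(c(png = png_path, csv = csv_path, json = json_path))
}
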