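# Leakage-safe stratified cross-validation: every data-dependent quantity
# (feature scores, selected features, min-max extremes, TOPSIS ideals, strata
# labels) is derived inside the training fold; held-out samples are scored
# with the frozen training-fold scaling and ideals.

#' Stratified fold assignment
#'
#' Shuffles indices within each class (seeded) and deals them round-robin to
#' folds, so per-fold class counts differ by at most one from proportionality.
#'
#' @param labels class vector.
#' @param k fold count (default 20).
#' @param seed random seed.
#' @param stratified deal per class (default `TRUE`); otherwise a plain
#'   shuffled partition.
#' @return a `fold_plan`: list with `assignment` (integer fold per sample),
#'   `k`, `seed`, `stratified`.
#' @export
make_folds <- function(labels, k = 20L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (k < 2) thal_error("thal_argument_error", "k must be at least 2")
  labels <- factor(labels)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  assignment <- integer(n)
  if (stratified) {
    for (lev in levels(labels)) {
      idx <- which(labels == lev)
      if (length(idx) < k)
        thal_error("thal_stratification_error",
                   sprintf("class '%s' has %d member(s), fewer than k = %d",
                           lev, length(idx), k))
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    if (n < k)
      thal_error("thal_stratification_error", "fewer samples than folds")
    assignment[sample(n)] <- rep_len(seq_len(k), n)
  }
  structure(list(assignment = assignment, k = as.integer(k),
                 seed = as.integer(seed), stratified = stratified),
            class = "fold_plan")
}

# Feature sets by modelling mode: `diagnostic` uses concurrent hematologic
# manifestations; `etiology` uses antecedent demographic / hereditary /
# socioeconomic context; `all` uses the full schema.
MODE_FEATURES <- list(
  diagnostic = c("Hct", "MCV", "MCH", "MCHC", "RDW", "Hemoglobin_Level",
                 "RBC_count"),
  etiology = c("Age", "BMI", "Family_History_Thalassemia",
               "Genetic_Marker_Presence", "Socioeconomic_Status",
               "Education_Level", "Residence", "Parity", "Carrier_Status")
)

mode_features <- function(mode, schema) {
  switch(mode,
         diagnostic = MODE_FEATURES$diagnostic,
         etiology = MODE_FEATURES$etiology,
         all = schema_names(schema),
         thal_error("thal_argument_error", sprintf("unknown mode '%s'", mode)))
}

#' Benchmark classifiers under leakage-safe cross-validation
#'
#' For every fold: (1) derive AHP weights from the expert judgments (data
#' independent, hence identical across folds); (2) on the training part only,
#' compute min-max extremes over the judgment criteria, run TOPSIS and
#' stratify to construct training risk labels; (3) score held-out samples
#' with the frozen training extremes, ideals and thresholds to obtain
#' held-out labels; (4) again on the training part only, compute impurity and
#' univariate F scores against the training labels, fuse them, and select the
#' top-`select_k` features (restricted to judgment-covered criteria when
#' `condition = "with_mcdm"`); (5) train each model on the selected training
#' columns -- multiplied by their AHP weights under `with_mcdm` -- and
#' evaluate on the held-out fold.
#'
#' Because the risk labels are a deterministic function of the same features,
#' held-out accuracy is expected to be near ceiling; the harness exists to
#' compare models and conditions under identical folds, not to certify
#' clinical validity.
#'
#' @param cohort a [cohort()].
#' @param modelspecs named list of [model_spec()]s (names label the report).
#' @param plan a `fold_plan` over the cohort (built internally from the
#'   full-cohort strata when `NULL`).
#' @param condition `"with_mcdm"` (AHP-weighted features) or
#'   `"without_mcdm"`.
#' @param judgments a [pairwise_judgments()] covering the TOPSIS criteria.
#' @param cfg a [stratification_config()].
#' @param mode `"diagnostic"`, `"etiology"`, or `"all"` -- restricts the
#'   classifier's candidate features.
#' @param select_k number of features kept by in-fold selection (capped at
#'   the number of candidates).
#' @param k,seed fold count and seed used when `plan` is `NULL`.
#' @param average metric averaging mode passed to [compute_metrics()].
#' @return a `benchmark_report`: list with `folds` (per-model, per-fold
#'   metric rows), `fold_details` (per-fold frozen extremes, ideals, selected
#'   features, training indices), `summary` (mean/sd per model and metric),
#'   `condition`, `mode`, `plan`, `weights`.
#' @export
run_cv <- function(cohort, modelspecs, plan = NULL,
                   condition = c("with_mcdm", "without_mcdm"),
                   judgments = reference_judgments(),
                   cfg = stratification_config(),
                   mode = c("all", "diagnostic", "etiology"),
                   select_k = 10L, k = 20L, seed = 1L,
                   average = "macro") {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  if (is.null(names(modelspecs)))
    names(modelspecs) <- vapply(modelspecs, function(s) s$algorithm, character(1))
  ahp <- ahp_weights(judgments)
  w <- ahp$weights
  encoded <- encode_cohort(cohort)

  # fold plan from full-cohort strata when not supplied (stratification needs
  # labels; the labels used for training/evaluation are still per-fold)
  if (is.null(plan)) {
    full <- topsis_score(encoded, w, cfg)
    plan <- make_folds(full$category, k = k, seed = seed)
  }

  cand <- mode_features(mode, cohort$schema)
  if (condition == "with_mcdm") cand <- intersect(cand, names(w))
  if (length(cand) == 0)
    thal_error("thal_argument_error",
               "no candidate features: judgments cover none of the mode's features")

  rows <- list(); details <- list()
  for (f in seq_len(plan$k)) {
    tr <- which(plan$assignment != f)
    te <- which(plan$assignment == f)
    fold_out <- tryCatch({
      # training-fold TOPSIS -> strata labels (frozen extremes + ideals)
      enc_tr <- encoded; enc_tr$values <- encoded$values[tr, , drop = FALSE]
      enc_te <- encoded; enc_te$values <- encoded$values[te, , drop = FALSE]
      res_tr <- topsis_score(enc_tr, w, cfg)
      mins <- attr(res_tr, "mins"); maxs <- attr(res_tr, "maxs")
      ip <- attr(res_tr, "ideals")
      res_te <- topsis_score(enc_te, w, cfg, mins = mins, maxs = maxs, ip = ip)
      y_tr <- droplevels(res_tr$category)
      y_te <- res_te$category
      if (nlevels(y_tr) < 2)
        thal_error("thal_degenerate_label_error",
                   "training fold has a single stratum")

      # in-fold feature scoring and selection
      cand_cols <- encoded_columns(encoded, cand)
      x_tr_all <- encoded$values[tr, cand_cols, drop = FALSE]
      imp <- impurity_importance(x_tr_all, y_tr, trees = 200L, seed = seed + f)
      fsc <- univariate_f_scores(x_tr_all, y_tr)
      comb <- combine_importance(imp, fsc)
      sel_cols <- top_k(comb, min(select_k, nrow(comb)))

      # map selected encoded columns back to schema features for weighting
      col_feature <- rep(cand, times = vapply(cand, function(fn) {
        length(encoded_columns(encoded, fn))
      }, integer(1)))
      names(col_feature) <- cand_cols
      x_tr <- x_tr_all[, sel_cols, drop = FALSE]
      x_te <- encoded$values[te, sel_cols, drop = FALSE]
      if (condition == "with_mcdm") {
        wcol <- w[col_feature[sel_cols]]
        x_tr <- sweep(x_tr, 2, wcol, "*")
        x_te <- sweep(x_te, 2, wcol, "*")
      }

      fold_rows <- lapply(names(modelspecs), function(mname) {
        fit <- train_model(modelspecs[[mname]], x_tr, y_tr)
        pred <- predict(fit, x_te)
        m <- compute_metrics(confusion_counts(y_te, pred), average = average)
        data.frame(model = mname, condition = condition, fold = f,
                   n_train = length(tr), n_test = length(te),
                   accuracy = m$accuracy, precision = m$precision,
                   recall = m$recall, f1 = m$f1, mcc = m$mcc,
                   failed = FALSE, stringsAsFactors = FALSE)
      })
      list(rows = do.call(rbind, fold_rows),
           detail = list(fold = f, train_idx = tr, test_idx = te,
                         mins = mins, maxs = maxs, ideals = ip,
                         selected = sel_cols, weights = w, failed = FALSE))
    }, thal_error = function(e) {
      list(rows = data.frame(model = names(modelspecs), condition = condition,
                             fold = f, n_train = length(tr),
                             n_test = length(te), accuracy = NA_real_,
                             precision = NA_real_, recall = NA_real_,
                             f1 = NA_real_, mcc = NA_real_, failed = TRUE,
                             stringsAsFactors = FALSE),
           detail = list(fold = f, train_idx = tr, test_idx = te,
                         failed = TRUE, message = conditionMessage(e)))
    })
    rows[[f]] <- fold_out$rows
    details[[f]] <- fold_out$detail
  }
  folds <- do.call(rbind, rows)
  ok <- folds[!folds$failed, , drop = FALSE]
  summary <- do.call(rbind, lapply(split(ok, ok$model), function(d) {
    data.frame(model = d$model[1], condition = condition,
               folds_used = nrow(d),
               accuracy = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               precision = mean(d$precision), recall = mean(d$recall),
               f1 = mean(d$f1), mcc = mean(d$mcc),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(folds = folds, fold_details = details, summary = summary,
                 condition = condition, mode = mode, plan = plan,
                 weights = w, cfg = cfg, select_k = select_k,
                 candidates = cand),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>", x$condition, "mode:", x$mode, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Recompute a fold's frozen quantities from its training indices
#'
#' Audit helper: re-derives the min-max extremes, TOPSIS ideals, and selected
#' feature list for one fold of a [run_cv()] report using only the recorded
#' training indices, so a test can assert that nothing outside the training
#' fold influenced them.
#'
#' @param cohort the cohort passed to [run_cv()].
#' @param report the `benchmark_report`.
#' @param fold fold number.
#' @return list with `mins`, `maxs`, `ideals`, `selected` recomputed from
#'   scratch.
#' @export
audit_fold <- function(cohort, report, fold) {
  det <- report$fold_details[[fold]]
  if (isTRUE(det$failed)) return(NULL)
  tr <- det$train_idx
  encoded <- encode_cohort(cohort)
  enc_tr <- encoded; enc_tr$values <- encoded$values[tr, , drop = FALSE]
  res_tr <- topsis_score(enc_tr, report$weights, report$cfg)
  y_tr <- droplevels(res_tr$category)
  cand_cols <- encoded_columns(encoded, report$candidates)
  x_tr_all <- encoded$values[tr, cand_cols, drop = FALSE]
  imp <- impurity_importance(x_tr_all, y_tr, trees = 200L,
                             seed = report$plan$seed + fold)
  fsc <- univariate_f_scores(x_tr_all, y_tr)
  comb <- combine_importance(imp, fsc)
  list(mins = attr(res_tr, "mins"), maxs = attr(res_tr, "maxs"),
       ideals = attr(res_tr, "ideals"),
       selected = top_k(comb, min(report$select_k, nrow(comb))))
}

#' Inner-CV grid search over a hyperparameter grid
#'
#' Expands the spec's grid, evaluates each candidate by stratified inner
#' cross-validation mean accuracy, and returns the spec fixed to the best
#' point (ties broken by grid order).
#'
#' @param x numeric feature matrix.
#' @param labels class vector.
#' @param spec a [model_spec()] with a non-empty `grid`.
#' @param inner_k inner fold count (>= 2).
#' @return the winning `model_spec` with `params` set and `grid` cleared.
#' @export
grid_search <- function(x, labels, spec, inner_k = 3L) {
  if (inner_k < 2) thal_error("thal_argument_error", "inner_k must be >= 2")
  if (length(spec$grid) == 0) return(spec)
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  plan <- make_folds(labels, k = inner_k, seed = spec$seed)
  best_acc <- -Inf; best_row <- 1L
  for (g in seq_len(nrow(grid))) {
    cand <- spec
    cand$params <- utils::modifyList(spec$params, as.list(grid[g, , drop = FALSE]))
    accs <- vapply(seq_len(inner_k), function(f) {
      tr <- plan$assignment != f; te <- !tr
      fit <- train_model(cand, x[tr, , drop = FALSE], labels[tr])
      pred <- predict(fit, x[te, , drop = FALSE])
      mean(pred == labels[te])
    }, numeric(1))
    if (mean(accs) > best_acc) { best_acc <- mean(accs); best_row <- g }
  }
  out <- spec
  out$params <- utils::modifyList(spec$params,
                                  as.list(grid[best_row, , drop = FALSE]))
  out$grid <- list()
  attr(out, "inner_cv_accuracy") <- best_acc
  out
}
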