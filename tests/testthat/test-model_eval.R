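test_that("stratified folds partition samples proportionally", {
  labels <- factor(rep(c("High", "Medium", "Low"), times = c(240, 720, 240)))
  plan <- make_folds(labels, k = 20, seed = 1)
  expect_equal(length(plan$assignment), 1200)
  expect_equal(unname(table(plan$assignment)), rep(60L, 20), ignore_attr = TRUE)
  # per-fold class counts within one of proportionality
  for (lev in levels(labels)) {
    per_fold <- table(plan$assignment[labels == lev])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  plan2 <- make_folds(labels, k = 20, seed = 1)
  expect_identical(plan$assignment, plan2$assignment)
  plan3 <- make_folds(labels, k = 20, seed = 2)
  expect_false(identical(plan$assignment, plan3$assignment))

  tiny <- make_folds(factor(c("A", "A", "B", "B")), k = 2, seed = 1)
  for (f in 1:2) {
    expect_equal(sum(tiny$assignment == f &
                       factor(c("A", "A", "B", "B")) == "A"), 1)
  }
  expect_error(make_folds(factor(c("A", "A", "B")), k = 2, seed = 1),
               class = "thal_stratification_error")
  expect_error(make_folds(labels, k = 1), class = "thal_argument_error")
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  perfect <- confusion_counts(factor(c("a", "b", "a")), factor(c("a", "b", "a")))
  m <- compute_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$mcc, 1)

  # binary TP=50 TN=40 FP=5 FN=5
  truth <- factor(c(rep("pos", 55), rep("neg", 45)), levels = c("pos", "neg"))
  pred <- factor(c(rep("pos", 50), rep("neg", 5), rep("pos", 5), rep("neg", 40)),
                 levels = c("pos", "neg"))
  cc <- confusion_counts(truth, pred)
  m <- compute_metrics(cc)
  expect_equal(m$accuracy, 0.9)
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$precision, 50 / 55)
  expect_equal(pos$recall, 50 / 55)
  expect_equal(pos$f1, 50 / 55)
  expect_equal(pos$mcc, (50 * 40 - 5 * 5) / sqrt(55 * 55 * 45 * 45))
  # binary overall MCC equals the per-class value
  expect_equal(m$mcc, pos$mcc)

  # all predictions one class: MCC 0 by convention, flagged
  mono <- compute_metrics(confusion_counts(truth, factor(rep("pos", 100),
                                                         levels = c("pos", "neg"))))
  expect_equal(mono$mcc, 0)
  expect_true(mono$zero_denominator)
  expect_error(compute_metrics(confusion_counts(factor(), factor())),
               class = "thal_argument_error")
})

test_that("metrics agree with a straight-line oracle on random tables", {
  set.seed(6)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(k * k, 8), k, k,
                  dimnames = list(letters[1:k], letters[1:k]))
    truth <- rep(rep(letters[1:k], each = k), times = as.vector(t(tab)))
    pred <- rep(rep(letters[1:k], times = k), times = as.vector(t(tab)))
    if (length(truth) == 0) next
    cc <- confusion_counts(factor(truth, levels = letters[1:k]),
                           factor(pred, levels = letters[1:k]))
    expect_equal(unclass(cc$table), tab, ignore_attr = TRUE)
    m <- compute_metrics(cc)
    orc <- oracle_metrics(cc$table)
    expect_equal(m$per_class$precision, unname(orc[, "precision"]),
                 tolerance = 1e-12)
    expect_equal(m$per_class$recall, unname(orc[, "recall"]), tolerance = 1e-12)
    expect_equal(m$per_class$f1, unname(orc[, "f1"]), tolerance = 1e-12)
    expect_equal(m$per_class$mcc, unname(orc[, "mcc"]), tolerance = 1e-12)
    expect_equal(m$accuracy, sum(diag(cc$table)) / sum(cc$table),
                 tolerance = 1e-12)
  }
})

test_that("run_cv produces a populated fold record per model and fold", {
  ch <- generate_cohort(default_cohort_spec(n = 400, seed = 2))
  specs <- list(forest = model_spec("random_forest", params = list(ntree = 100)),
                boost = model_spec("extreme_gradient_boosting",
                                   params = list(nrounds = 30)))
  rep <- run_cv(ch, specs, condition = "with_mcdm", k = 5, seed = 3)
  expect_equal(nrow(rep$folds), 10)  # 5 folds x 2 models
  ok <- rep$folds[!rep$folds$failed, ]
  expect_true(all(is.finite(ok$accuracy)))
  expect_true(all(is.finite(ok$mcc)))
  expect_true(all(ok$accuracy >= 0 & ok$accuracy <= 1))
  # AHP weights identical across folds: they depend only on the judgments
  ws <- lapply(rep$fold_details, function(d) d$weights)
  for (w in ws[-1]) expect_identical(w, ws[[1]])
})

test_that("toggling the condition changes weighting but not fold assignment", {
  ch <- generate_cohort(default_cohort_spec(n = 300, seed = 4))
  spec <- list(boost = model_spec("extreme_gradient_boosting",
                                  params = list(nrounds = 20)))
  r1 <- run_cv(ch, spec, condition = "with_mcdm", k = 4, seed = 5)
  r2 <- run_cv(ch, spec, condition = "without_mcdm", k = 4, seed = 5)
  expect_identical(r1$plan$assignment, r2$plan$assignment)
  expect_equal(r1$condition, "with_mcdm")
  expect_equal(r2$condition, "without_mcdm")
})

test_that("per-fold frozen quantities are recomputable from training rows only", {
  ch <- generate_cohort(default_cohort_spec(n = 300, seed = 6))
  spec <- list(boost = model_spec("extreme_gradient_boosting",
                                  params = list(nrounds = 20)))
  rep <- run_cv(ch, spec, condition = "with_mcdm", k = 3, seed = 7)
  for (f in 1:3) {
    audit <- audit_fold(ch, rep, f)
    det <- rep$fold_details[[f]]
    if (isTRUE(det$failed)) next
    expect_equal(audit$mins, det$mins)
    expect_equal(audit$maxs, det$maxs)
    expect_equal(audit$ideals$positive, det$ideals$positive)
    expect_equal(audit$ideals$negative, det$ideals$negative)
    expect_identical(audit$selected, det$selected)
  }
})

test_that("an unavailable boosting variant fails with a clear message", {
  err <- expect_error(model_spec("ordered_boosting"),
                      class = "thal_model_error")
  expect_match(conditionMessage(err), "register_model_backend")
  expect_true(all(c("random_forest", "extreme_gradient_boosting") %in%
                    list_model_backends()))
})

test_that("grid search picks the stronger configuration deterministically", {
  set.seed(12)
  x <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("f1", "f2")))
  # xor-style target: a single depth-1 round cannot learn it, a real
  # boosting configuration can
  y <- factor(ifelse(xor(x[, 1] > 0, x[, 2] > 0), "a", "b"))

  single <- model_spec("extreme_gradient_boosting",
                       grid = list(nrounds = 25L), seed = 1)
  out <- grid_search(x, y, single, inner_k = 2)
  expect_equal(out$params$nrounds, 25L)

  spec <- model_spec("extreme_gradient_boosting",
                     grid = list(nrounds = c(1L, 60L), max_depth = c(1L, 4L)),
                     seed = 1)
  best <- grid_search(x, y, spec, inner_k = 3)
  expect_equal(best$params$nrounds, 60L)
  best2 <- grid_search(x, y, spec, inner_k = 3)
  expect_equal(best$params, best2$params)
  expect_error(grid_search(x, y, spec, inner_k = 1),
               class = "thal_argument_error")
})
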