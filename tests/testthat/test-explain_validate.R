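# Shared fitted model: three informative-feature strengths, binary target
# dominated by feature "dom".
make_explained <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(31)
    n <- 400
    x <- cbind(dom = rnorm(n), weak = rnorm(n), const = rep(1, n))
    y <- factor(ifelse(x[, "dom"] + 0.2 * x[, "weak"] + 0.3 * rnorm(n) > 0,
                       "hi", "lo"))
    fit <- thalrisk:::train_model(model_spec("extreme_gradient_boosting",
                                             params = list(nrounds = 40)),
                                  x, y)
    cache <<- list(x = x, y = y, fit = fit)
    cache
  }
})

test_that("tree attributions satisfy additivity and zero out constants", {
  d <- make_explained()
  expl <- global_attributions(d$fit, d$x)
  expect_equal(dim(expl$values), dim(d$x))
  expect_lt(expl$additivity_error, 1e-4)
  expect_lt(max(abs(expl$values[, "const"])), 1e-8)
  imp <- colMeans(abs(expl$values))
  expect_equal(names(which.max(imp)), "dom")
  expect_error(global_attributions(d$fit, d$x[, c(2, 1, 3)]),
               class = "thal_alignment_error")
  rf <- thalrisk:::train_model(model_spec("random_forest",
                                          params = list(ntree = 50)),
                               d$x, d$y)
  expect_error(global_attributions(rf, d$x), class = "thal_model_error")
})

test_that("local surrogate weights are seeded, bounded and faithful", {
  d <- make_explained()
  inst <- d$x[1, ]
  e1 <- local_explanation(d$fit, inst, d$x, n_perturb = 300, seed = 9, keep = 2)
  e2 <- local_explanation(d$fit, inst, d$x, n_perturb = 300, seed = 9, keep = 2)
  expect_equal(e1$weight, e2$weight)
  expect_lte(nrow(e1), 2)
  e_all <- local_explanation(d$fit, inst, d$x, n_perturb = 500, seed = 9,
                             keep = 3)
  expect_equal(e_all$feature[1], "dom")
  expect_true(all(e_all$direction %in% c("supports", "opposes")))
  expect_error(local_explanation(d$fit, inst, d$x, n_perturb = 5),
               class = "thal_argument_error")
})

test_that("Kruskal-Wallis separates shifted attribution groups only", {
  set.seed(13)
  base <- rnorm(200)
  # the same values in both classes: H ~ 0, p ~ 1
  classes <- factor(rep(c("A", "B"), each = 100))
  same <- structure(list(values = matrix(c(base[1:100], base[1:100]), ncol = 1,
                                         dimnames = list(NULL, "f"))),
                    class = "explanation_set")
  kw_same <- kruskal_by_class(same, classes)
  expect_gt(kw_same$p, 0.05)
  expect_lt(kw_same$statistic, 1)

  shifted <- matrix(c(rnorm(100), rnorm(100) + 2), ncol = 1,
                    dimnames = list(NULL, "f"))
  kw_shift <- kruskal_by_class(structure(list(values = shifted),
                                         class = "explanation_set"), classes)
  expect_lt(kw_shift$p, 0.05)

  # permuting class labels destroys significance most of the time
  hits <- 0
  for (i in 1:50) {
    kw <- kruskal_by_class(structure(list(values = shifted),
                                     class = "explanation_set"),
                           sample(classes))
    hits <- hits + (kw$p < 0.05)
  }
  expect_lte(hits, 10)
  expect_error(kruskal_by_class(structure(list(values = shifted),
                                          class = "explanation_set"),
                                factor(rep("A", 200))),
               class = "thal_argument_error")
})

test_that("Kruskal-Wallis matches the rank-sum decision for two balanced groups", {
  set.seed(14)
  agree <- 0
  for (i in 1:200) {
    a <- rnorm(30)
    b <- rnorm(30) + sample(c(0, 0.8), 1)
    kw <- stats::kruskal.test(list(a, b))$p.value < 0.05
    es <- structure(list(values = cbind(f1 = a, f2 = b)),
                    class = "explanation_set")
    mw <- pairwise_mwu(es)["f1", "f2"] < 0.05
    agree <- agree + (kw == mw)
  }
  expect_gt(agree / 200, 0.95)
})

test_that("pairwise rank tests form a symmetric unit-diagonal p matrix", {
  set.seed(15)
  vals <- cbind(low = rnorm(100), high = rnorm(100) + 5, mid = rnorm(100) + 1)
  es <- structure(list(values = vals), class = "explanation_set")
  P <- pairwise_mwu(es)
  expect_equal(unclass(P), t(unclass(P)))
  expect_equal(unname(diag(P)), rep(1, 3))
  expect_true(all(P >= 0 & P <= 1))
  expect_lt(P["low", "high"], 0.05)

  # identical columns: p = 1 against itself by construction of the diagonal
  const <- structure(list(values = cbind(a = rep(1, 10), b = rep(1, 10))),
                     class = "explanation_set")
  Pc <- pairwise_mwu(const)
  expect_equal(Pc["a", "b"], 1)
  expect_true(attr(Pc, "tie_flags")["a", "b"])

  Pbh <- pairwise_mwu(es, adjust = "BH")
  expect_equal(attr(Pbh, "correction"), "BH")
  expect_true(all(Pbh >= P - 1e-12))
  expect_error(pairwise_mwu(structure(list(values = vals[1:2, ]),
                                      class = "explanation_set")),
               class = "thal_argument_error")
})

test_that("small-sample rank tests agree with exact enumeration", {
  set.seed(16)
  for (i in 1:20) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    a <- rnorm(m); b <- rnorm(n) + sample(c(0, 1.5), 1)
    p_impl <- thalrisk:::mwu_p(a, b)$p
    p_orc <- oracle_mwu_exact(a, b)
    expect_equal(p_impl, p_orc, tolerance = 1e-12)
  }
})

test_that("heatmap export writes image, round-trippable CSV and sidecar", {
  set.seed(17)
  vals <- cbind(f1 = rnorm(30), f2 = rnorm(30) + 1, f3 = rnorm(30) - 1)
  P <- pairwise_mwu(structure(list(values = vals), class = "explanation_set"))
  stem <- file.path(withr::local_tempdir(), "sig")
  files <- heatmap_export(P, stem)
  expect_true(all(file.exists(files)))
  back <- as.matrix(utils::read.csv(files["csv"], row.names = 1))
  expect_equal(unname(back), unname(unclass(P)), tolerance = 1e-12,
               ignore_attr = TRUE)
  meta <- jsonlite::read_json(files["json"])
  expect_equal(meta$alpha, 0.05)
  # shade mapping is monotone: lower p, darker cell
  g <- grDevices::col2rgb(p_shade(c(0, 0.2, 0.5, 0.9, 1)))[1, ]
  expect_true(all(diff(g) > 0))
})
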