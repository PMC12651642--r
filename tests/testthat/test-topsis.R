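dm <- function(values, ...) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(NULL, "c1"))
  decision_matrix(values, ...)
}

test_that("min-max scaling maps extremes to 0/1 and is idempotent", {
  M <- dm(c(2, 4, 6))
  N <- minmax_normalize(M)
  expect_equal(unname(N$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(N$mins), 2)
  expect_equal(unname(N$maxs), 6)
  N2 <- minmax_normalize(N)
  expect_equal(N2$values, N$values)

  err <- expect_error(minmax_normalize(dm(c(3, 3, 3))),
                      class = "thal_degenerate_criterion_error")
  expect_match(conditionMessage(err), "c1")
})

test_that("frozen extremes are honoured and out-of-range values clipped", {
  M <- dm(c(1, 9))
  N <- minmax_normalize(M, mins = c(c1 = 2), maxs = c(c1 = 6))
  expect_equal(unname(N$values[, 1]), c(0, 1))  # clipped at both ends
})

test_that("weighting multiplies criterion columns by their weights", {
  vals <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2,
                 dimnames = list(NULL, c("x", "y")))
  N <- decision_matrix(vals, normalized = TRUE)
  W <- apply_weights(N, c(x = 0.5, y = 0.5))
  expect_equal(W$values, vals / 2)
  Wz <- apply_weights(N, c(x = 0, y = 1))
  expect_equal(unname(Wz$values[, "x"]), c(0, 0))
  expect_error(apply_weights(N, c(0.5, 0.3, 0.2)),
               class = "thal_alignment_error")
  expect_error(apply_weights(dm(c(1, 5)), 1), class = "thal_topsis_error")
  # published worked example: first-entry Hct cell times its weight
  t10 <- table10_matrix(); w9 <- table9_weight_vector()
  Wt <- apply_weights(decision_matrix(t10, normalized = TRUE), w9)
  expect_equal(unname(Wt$values[1, "Hct"]), 0.8889 * 0.2989,
               tolerance = 1e-12)
})

test_that("ideal profiles are the columnwise extremes", {
  W <- decision_matrix(matrix(c(0.1, 0.3, 0.4, 0.2), 2, 2,
                              dimnames = list(NULL, c("x", "y"))),
                       normalized = TRUE, weighted = TRUE)
  ip <- ideals(W)
  expect_equal(unname(ip$positive), c(0.3, 0.4))
  expect_equal(unname(ip$negative), c(0.1, 0.2))
  single <- decision_matrix(matrix(c(0.2, 0.5), 1, 2,
                                   dimnames = list(NULL, c("x", "y"))),
                            normalized = TRUE, weighted = TRUE)
  ips <- ideals(single)
  expect_equal(ips$positive, ips$negative)
  # on full-cohort min-max data with weights w, ideals are (w_j, 0)
  t10 <- table10_matrix(); w9 <- table9_weight_vector()
  Wt <- apply_weights(minmax_normalize(decision_matrix(t10)), w9)
  ipt <- ideals(Wt)
  expect_equal(unname(ipt$negative), rep(0, 10))
})

test_that("closeness is 1 at the ideal, 0 at the anti-ideal, 0.5 midway", {
  vals <- matrix(c(1, 0, 0.5, 1, 0, 0.5), 3, 2,
                 dimnames = list(NULL, c("x", "y")))
  W <- apply_weights(decision_matrix(vals, normalized = TRUE), c(x = .5, y = .5))
  res <- closeness(W)
  expect_equal(res$closeness, c(1, 0, 0.5))
  expect_equal(res$d_plus[1], 0)
  expect_equal(res$d_minus[2], 0)
  same <- decision_matrix(matrix(0.3, 3, 2, dimnames = list(NULL, c("x", "y"))),
                          normalized = TRUE, weighted = TRUE)
  expect_error(closeness(same), class = "thal_degenerate_cohort_error")
})

test_that("closeness on the published normalized table matches the oracle", {
  t10 <- table10_matrix(); w9 <- table9_weight_vector()
  W <- apply_weights(decision_matrix(t10, normalized = TRUE), w9)
  ip <- structure(list(positive = w9, negative = stats::setNames(rep(0, 10),
                                                                 names(w9))),
                  class = "ideal_pair")
  res <- closeness(W, ip)
  orc <- oracle_topsis(W$values, ip$positive, ip$negative)
  expect_equal(res$d_plus, orc$d_plus, tolerance = 1e-12)
  expect_equal(res$d_minus, orc$d_minus, tolerance = 1e-12)
  expect_equal(res$closeness, orc$closeness, tolerance = 1e-12)
})

test_that("ranking is stable-descending in closeness", {
  res <- structure(data.frame(closeness = c(0.9, 0.1, 0.5)),
                   class = c("topsis_result", "data.frame"))
  expect_equal(rank_results(res)$rank, c(1, 3, 2))
  tied <- structure(data.frame(closeness = rep(0.4, 4)),
                    class = c("topsis_result", "data.frame"))
  expect_equal(rank_results(tied)$rank, 1:4)
  set.seed(2)
  rnd <- structure(data.frame(closeness = runif(50)),
                   class = c("topsis_result", "data.frame"))
  rr <- rank_results(rnd)
  expect_equal(rr$closeness[rr$rank == 1], max(rr$closeness))
})

test_that("stratification reproduces the published category assignments", {
  expect_equal(as.character(stratify(0.7064)), "High Risk")
  expect_equal(as.character(stratify(0.2414)), "Low Risk")
  expect_equal(as.character(stratify(c(0.3414, 0.6082))),
               rep("Medium Risk", 2))
  # boundary ownership: 0.66 -> High, 0.33 -> Medium
  expect_equal(as.character(stratify(c(0.66, 0.33))),
               c("High Risk", "Medium Risk"))
  t11 <- utils::read.csv(fixture_path("table11_closeness.csv"))
  cats <- stratify(t11$closeness)
  expect_equal(as.character(cats), t11$category)
  expect_equal(unname(table(cats)["High Risk"]), 2, ignore_attr = TRUE)
  expect_equal(sum(cats == "Medium Risk"), 4)
  expect_equal(sum(cats == "Low Risk"), 4)
  expect_error(stratification_config(high = 0.3, low = 0.6),
               class = "thal_config_error")
})

test_that("raising a criterion value never lowers closeness at fixed ideals", {
  set.seed(8)
  vals <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("c", 1:4)))
  w <- c(c1 = 0.4, c2 = 0.3, c3 = 0.2, c4 = 0.1)
  W <- apply_weights(decision_matrix(vals, normalized = TRUE), w)
  ip <- structure(list(positive = w, negative = stats::setNames(rep(0, 4),
                                                                names(w))),
                  class = "ideal_pair")
  base <- closeness(W, ip)
  for (j in 1:4) {
    vals2 <- vals
    vals2[3, j] <- min(1, vals2[3, j] + 0.2)
    W2 <- apply_weights(decision_matrix(vals2, normalized = TRUE), w)
    expect_gte(closeness(W2, ip)$closeness[3], base$closeness[3] - 1e-12)
  }
})

test_that("sample permutation and weight rescaling act as expected", {
  set.seed(10)
  vals <- matrix(runif(30), 10, 3, dimnames = list(NULL, paste0("c", 1:3)))
  w <- c(c1 = 0.5, c2 = 0.3, c3 = 0.2)
  res <- stratify(rank_results(closeness(
    apply_weights(decision_matrix(vals, normalized = TRUE), w))))
  perm <- sample(10)
  resp <- stratify(rank_results(closeness(
    apply_weights(decision_matrix(vals[perm, ], normalized = TRUE), w))))
  expect_equal(resp$closeness, res$closeness[perm])
  expect_equal(resp$rank, res$rank[perm])
  expect_equal(as.character(resp$category), as.character(res$category)[perm])
  # doubling all weights leaves the closeness ratio unchanged
  res2 <- closeness(apply_weights(decision_matrix(vals, normalized = TRUE),
                                  2 * w))
  expect_equal(res2$closeness, res$closeness, tolerance = 1e-12)
})
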