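make_truth <- function(p, edges) {
  A <- matrix(0L, p, p)
  for (e in edges) { A[e[1], e[2]] <- A[e[2], e[1]] <- 1L }
  A
}

test_that("error rates count the upper triangle exactly", {
  A <- make_truth(4, list(c(1, 2), c(3, 4)))
  P1 <- matrix(1, 4, 4)
  er <- error_rates(P1, A, 0.05)
  expect_equal(er$type_I, 0)
  expect_equal(er$type_II, 1)

  # indicator-perfect p-values: reject exactly the true edges
  P2 <- 1 - A
  er2 <- error_rates(P2, A, 0.05)
  expect_equal(er2$type_I, 0)
  expect_equal(er2$type_II, 0)

  # seeded case vs direct count
  set.seed(1)
  P3 <- matrix(runif(16), 4, 4); P3 <- (P3 + t(P3)) / 2
  er3 <- error_rates(P3, A, 0.3)
  up <- upper.tri(A)
  expect_equal(er3$type_I, mean(P3[up & A == 0] < 0.3))
  expect_equal(er3$type_II, mean(P3[up & A == 1] >= 0.3))

  # empty alternative set: rate is an explicit NA marker, not zero
  empty <- matrix(0L, 4, 4)
  expect_true(is.na(error_rates(P3, empty, 0.3)$type_II))
  full <- make_truth(4, combn(4, 2, c, simplify = FALSE))
  expect_true(is.na(error_rates(P3, full, 0.3)$type_I))
})

test_that("CI coverage separates the zero and non-zero pair sets", {
  model <- ggm_graph("band", p = 6, seed = 1)
  fake <- function(lo, hi) {
    structure(list(estimate = (lo + hi) / 2, ci_low = lo, ci_high = hi),
              class = "ggm_inference")
  }
  wide <- fake(matrix(-Inf, 6, 6), matrix(Inf, 6, 6))
  cw <- ci_coverage(wide, model)
  expect_equal(cw$coverage_nonzero, 1)
  expect_equal(cw$coverage_zero, 1)

  narrow <- fake(matrix(100, 6, 6), matrix(101, 6, 6))
  cn <- ci_coverage(narrow, model)
  expect_equal(cn$coverage_nonzero, 0)
  expect_equal(cn$coverage_zero, 0)
})

test_that("MCC follows the contingency table with safe degenerate cases", {
  A <- make_truth(5, list(c(1, 2), c(2, 3), c(4, 5)))
  expect_equal(mcc(A, A), 1)
  comp <- 1L - A; diag(comp) <- 0L
  expect_equal(mcc(comp, A), -1)
  expect_equal(mcc(matrix(0L, 5, 5), A), 0)  # zero factor convention

  set.seed(2)
  D <- make_truth(5, list(c(1, 2), c(1, 3), c(4, 5)))
  up <- upper.tri(A)
  tp <- sum(D[up] & A[up]); tn <- sum(!D[up] & !A[up])
  fp <- sum(D[up] & !A[up]); fn <- sum(!D[up] & A[up])
  want <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mcc(D, A), want)
  # transpose-augmented input changes nothing (upper triangle only)
  expect_equal(mcc(D + t(D) > 0, A), mcc(D, A))
})

test_that("degree diagnostic recovers known distributions", {
  # star on 11 nodes: one degree-10 hub, ten degree-1 leaves
  star <- matrix(0L, 11, 11)
  star[1, 2:11] <- star[2:11, 1] <- 1L
  dd <- degree_diagnostic(star)
  expect_setequal(dd$m, c(1, 10))
  expect_equal(dd$prob[dd$m == 1], 10 / 11)
  expect_equal(sum(dd$prob), 1)

  # synthetic power law: a union of disjoint cliques, sized so the number
  # of degree-m nodes is proportional to m^-2; slope should be ~ -2
  ms <- c(1, 2, 4)
  n_nodes <- 720 / ms^2              # 720, 180, 45: exactly prop. to m^-2
  n_cliques <- n_nodes / (ms + 1)    # 360, 60, 9: all integral
  blocks <- unlist(lapply(seq_along(ms), function(k)
    rep(ms[k] + 1, n_cliques[k])))
  P <- sum(blocks)
  adj <- matrix(0L, P, P)
  at <- 1
  for (b in blocks) {
    idx <- at:(at + b - 1)
    adj[idx, idx] <- 1L
    at <- at + b
  }
  diag(adj) <- 0L
  ddp <- degree_diagnostic(adj)
  expect_equal(ddp$slope, -2, tolerance = 1e-8)
  # and the function's slope matches lm on a real adjacency: ring graph
  ring <- matrix(0L, 8, 8)
  for (i in 1:8) { j <- i %% 8 + 1; ring[i, j] <- ring[j, i] <- 1L }
  ddr <- degree_diagnostic(ring)
  expect_true(is.na(ddr$slope))     # single-point distribution
  expect_equal(ddr$m, 2)

  dd0 <- degree_diagnostic(matrix(0L, 5, 5))
  expect_true(dd0$empty)
  expect_true(is.na(dd0$slope))
})

test_that("the diagnostic slope matches a direct regression", {
  g <- ggm_graph("scale_free", p = 120, seed = 5)
  dd <- degree_diagnostic(g$adjacency)
  pos <- dd$m >= 1
  want <- unname(coef(lm(log2(dd$prob[pos]) ~ log2(dd$m[pos])))[2])
  expect_equal(dd$slope, want, tolerance = 1e-10)
  expect_lt(dd$slope, 0)  # decreasing degree distribution
})

test_that("metric_report flattens all metrics consistently", {
  model <- ggm_graph("band", p = 15, seed = 6)
  x <- preprocess(sample_mvn(model, n = 200, seed = 7))
  fit <- b_nw_sl(x)
  g <- globalize(fit$z_score, alphas = 0.1)
  rep <- metric_report("B_NW_SL", "band", 7, model, result = fit,
                       decisions = g$decisions[[1]])
  expect_s3_class(rep, "data.frame")
  expect_equal(nrow(rep), 1)
  expect_true(all(c("type_I", "coverage_zero", "mcc", "fdp", "power")
                  %in% names(rep)))
  expect_equal(rep$mcc, mcc(g$decisions[[1]], model$adjacency))
})
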