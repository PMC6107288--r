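test_that("nodewise fits satisfy the residual identity and recover scales", {
  model <- ggm_graph("band", p = 10, seed = 1)
  x <- preprocess(sample_mvn(model, n = 120, seed = 2))
  fits <- fit_all_nodewise(x, "scaled_lasso")
  # residuals are exactly x_i - X beta_i
  expect_equal(fits$residuals, x - x %*% fits$beta, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_true(all(diag(fits$beta) == 0))
  expect_true(all(fits$sigma_hat > 0))

  # independent columns, n >> p: coefficients shrink to ~0 and the noise
  # scale estimates the column SD
  m0 <- ggm_graph("er", p = 6, seed = 3, prob = 1e-12)
  x0 <- preprocess(sample_mvn(m0, n = 2000, seed = 4))
  f0 <- fit_all_nodewise(x0, "scaled_lasso")
  expect_lt(max(abs(f0$beta)), 0.1)
  expect_equal(f0$sigma_hat,
               unname(apply(x0, 2, function(v) sqrt(mean(v^2)))),
               tolerance = 0.05)
})

test_that("collinear genes trigger a degenerate-response error", {
  set.seed(5)
  v <- rnorm(50)
  x <- preprocess(cbind(g1 = v, g2 = v))
  expect_error(fit_all_nodewise(x, "scaled_lasso", lambda = 1e-10),
               "degenerate")
})

test_that("residual moments match the dense computation", {
  model <- ggm_graph("hub", p = 12, seed = 6, g = 4)
  x <- preprocess(sample_mvn(model, n = 80, seed = 7))
  fits <- fit_all_nodewise(x, "scaled_lasso")
  R <- residual_moments(fits)
  expect_equal(R, crossprod(fits$residuals) / 80, tolerance = 1e-12)
  expect_true(all(diag(R) > 0))

  # with a dominating penalty all beta = 0 and the moments are the sample
  # covariance of the centered data
  fits0 <- fit_all_nodewise(x, "lasso", lambda = 100)
  expect_true(all(fits0$beta == 0))
  expect_equal(residual_moments(fits0), crossprod(x) / 80, tolerance = 1e-12)
})

test_that("bias correction is exact at the population values", {
  # fixed 3x3 precision matrix; plug in the population quantities
  Omega <- matrix(c(2, 0.5, 0, 0.5, 1.5, -0.4, 0, -0.4, 1), 3, 3)
  d <- 1 / diag(Omega)                          # population r_ii
  Rpop <- Omega / outer(diag(Omega), diag(Omega))  # population r_ij
  diag(Rpop) <- d
  Bpop <- matrix(0, 3, 3)
  for (j in 1:3) for (i in 1:3) if (i != j)
    Bpop[i, j] <- -Omega[i, j] / Omega[j, j]    # beta_{i,j}
  fake <- structure(list(beta = Bpop, n = 100,
                         gene_names = paste0("g", 1:3)),
                    class = "ggm_nodewise")
  bc <- bias_corrected_estimates(Rpop, fake)
  expect_equal(unname(bc$omega), Omega, tolerance = 1e-12)
  # and rtilde reproduces the population residual moments off-diagonal
  expect_equal(unname(bc$rtilde[1, 2]), Rpop[1, 2], tolerance = 1e-12)
})

test_that("with all beta zero the correction reduces to the raw moments", {
  model <- ggm_graph("band", p = 6, seed = 8)
  x <- preprocess(sample_mvn(model, n = 60, seed = 9))
  fits <- fit_all_nodewise(x, "lasso", lambda = 100)
  R <- residual_moments(fits)
  bc <- bias_corrected_estimates(R, fits)
  d <- diag(R)
  expected <- -R / outer(d, d)
  diag(expected) <- 1 / d
  expect_equal(unname(bc$omega), unname(expected), tolerance = 1e-12)
})

test_that("with no penalty and n > p all methods reduce to the MLE", {
  model <- ggm_graph("band", p = 15, seed = 10)
  x <- preprocess(sample_mvn(model, n = 150, seed = 11))
  S <- crossprod(x) / nrow(x)
  target <- solve(S)
  for (f in list(function() b_nw_sl(x, lambda0 = 1e-11),
                 function() ds_nw_sl(x, lambda0 = 1e-11))) {
    r <- f()
    full <- r$estimate
    diag(full) <- r$diag_precision
    expect_equal(full, target, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("inference surfaces obey their structural invariants", {
  model <- ggm_graph("er", p = 20, seed = 12, prob = 0.15)
  x <- preprocess(sample_mvn(model, n = 100, seed = 13))
  for (r in list(b_nw_sl(x), ds_nw_sl(x))) {
    expect_equal(r$estimate, t(r$estimate))
    expect_true(all(diag(r$estimate) == 0))
    expect_true(all(diag(r$p_value) == 0))
    expect_true(all(r$p_value >= 0 & r$p_value <= 1))
    expect_true(all(r$ci_low <= r$estimate + 1e-12 &
                      r$estimate <= r$ci_high + 1e-12))
    # monotone evidence: larger |z| means smaller p-value
    z <- abs(upper_vals(r$z_score)); pv <- upper_vals(r$p_value)
    o <- order(z)
    expect_true(all(diff(pv[o]) <= 1e-12))
  }
})

test_that("GFC statistics reduce correctly and share the estimate's sign", {
  model <- ggm_graph("band", p = 8, seed = 14)
  x <- preprocess(sample_mvn(model, n = 90, seed = 15))
  # all-zero beta reduction
  fits0 <- fit_all_nodewise(x, "lasso", lambda = 100)
  R <- residual_moments(fits0)
  st0 <- gfc_statistics(x, "lasso", lambda = 100)
  d <- diag(R)
  expected <- -sqrt(90) * R / sqrt(outer(d, d))
  diag(expected) <- 0
  expect_equal(unname(st0$T), unname(expected), tolerance = 1e-10)

  # shared numerator: sign(T) == sign(omega_check)
  st <- gfc_statistics(x, "scaled_lasso")
  fits <- fit_all_nodewise(x, "scaled_lasso")
  bc <- bias_corrected_estimates(residual_moments(fits), fits)
  off <- upper.tri(st$T)
  expect_true(all(sign(st$T[off]) == sign(bc$omega[off])))
})

test_that("GFC statistics are calibrated against the asymptotic null", {
  # identity precision: off-diagonal statistics should be ~N(0, 1)
  m0 <- ggm_graph("er", p = 50, seed = 16, prob = 1e-12)
  x0 <- preprocess(sample_mvn(m0, n = 200, seed = 17))
  st <- gfc_statistics(x0, "scaled_lasso")
  tv <- upper_vals(st$T)
  expect_lt(abs(mean(tv)), 3 / sqrt(length(tv)) + 0.02)
  expect_equal(sd(tv), 1, tolerance = 0.08)
})

test_that("estimation error on true edges shrinks as n grows", {
  errs <- sapply(c(150, 600), function(n) {
    e <- numeric(4)
    for (s in 1:4) {
      model <- ggm_graph("band", p = 40, seed = 100 + s)
      x <- preprocess(sample_mvn(model, n = n, seed = 200 + s))
      r <- b_nw_sl(x)
      edge <- model$adjacency == 1 & upper.tri(model$adjacency)
      e[s] <- mean(abs(r$estimate[edge] - model$Omega[edge]))
    }
    mean(e)
  })
  expect_lt(errs[2], errs[1])
})
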