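test_that("lasso_cd solves the univariate and fully-shrunk limits exactly", {
  # p = 1, y = 2x, no penalty: OLS slope 2
  x <- matrix(seq(-2, 2, length.out = 20), ncol = 1)
  y <- 2 * x[, 1]
  pb <- gram_problem(x, y)
  expect_equal(as.numeric(lasso_cd(pb$gram, pb$xty, 0)), 2, tolerance = 1e-10)

  # lambda at or above max |xty| shrinks everything to zero
  set.seed(11)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- rnorm(40)
  pb <- gram_problem(X, y)
  b <- lasso_cd(pb$gram, pb$xty, max(abs(pb$xty)))
  expect_identical(as.numeric(b), rep(0, 4))
})

test_that("lasso_cd agrees with an independent convex-QP oracle and KKT", {
  set.seed(101)
  for (rep in 1:3) {
    X <- matrix(rnorm(50 * 5), 50, 5)
    y <- X %*% c(1.5, -2, 0, 0, 0.7) + rnorm(50)
    pb <- gram_problem(X, y)
    lam <- c(0.05, 0.15, 0.4)[rep]
    b <- as.numeric(lasso_cd(pb$gram, pb$xty, lam))
    expect_equal(b, lasso_oracle(pb$gram, pb$xty, lam), tolerance = 1e-6)
    # KKT: active coordinates at +-lambda, inactive within lambda
    grad <- drop(pb$gram %*% b - pb$xty)
    act <- b != 0
    if (any(act))
      expect_lt(max(abs(grad[act] + lam * sign(b[act]))), 1e-5)
    if (any(!act))
      expect_lt(max(abs(grad[!act])), lam + 1e-5)
  }
})

test_that("warm and cold starts reach the same solution", {
  set.seed(21)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- X %*% rnorm(8) + rnorm(60)
  pb <- gram_problem(X, y)
  cold <- lasso_cd(pb$gram, pb$xty, 0.2)
  warm <- lasso_cd(pb$gram, pb$xty, 0.2,
                   beta_init = as.numeric(cold) + rnorm(8, sd = 0.3))
  expect_equal(as.numeric(warm), as.numeric(cold), tolerance = 1e-5)
})

test_that("orthogonal designs reproduce soft-thresholding along a path", {
  # gram = I: the lasso solution is soft(xty, lambda) coordinatewise
  xty <- c(1.2, -0.8, 0.3, -0.05, 2)
  G <- diag(5)
  sizes <- integer(0)
  for (lam in c(1.5, 1.0, 0.5, 0.1, 0.01)) {
    b <- as.numeric(lasso_cd(G, xty, lam))
    expect_equal(b, sign(xty) * pmax(abs(xty) - lam, 0), tolerance = 1e-9)
    sizes <- c(sizes, sum(b != 0))
  }
  expect_true(all(diff(sizes) >= 0))  # active set grows as lambda decreases
})

test_that("scaled lasso returns the noise scale as a fixed point", {
  # pure-noise response with a dominating penalty: beta = 0 and
  # sigma = ||y|| / sqrt(n) exactly
  set.seed(31)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- rnorm(80)
  pb <- gram_problem(X, y)
  fit <- scaled_lasso(pb$gram, pb$xty, pb$yty, lambda0 = 10)
  expect_identical(fit$beta, rep(0, 6))
  expect_equal(fit$sigma_hat, sqrt(sum(y^2) / 80), tolerance = 1e-12)

  # generic converged fit: sigma equals the RMS residual of returned beta
  fit2 <- scaled_lasso(pb$gram, pb$xty, pb$yty, lambda0 = 0.2)
  rms <- sqrt(pb$yty - 2 * sum(fit2$beta * pb$xty) +
                drop(crossprod(fit2$beta, pb$gram %*% fit2$beta)))
  expect_equal(fit2$sigma_hat, rms, tolerance = 1e-6)
})

test_that("the scaled-lasso joint objective is non-increasing over updates", {
  set.seed(41)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- X %*% c(rep(1, 3), rep(0, 7)) + rnorm(50)
  pb <- gram_problem(X, y)
  lambda0 <- 0.3
  obj <- function(b, s) {
    rss <- pb$yty - 2 * sum(b * pb$xty) + drop(crossprod(b, pb$gram %*% b))
    rss / (2 * s) + s / 2 + lambda0 * sum(abs(b))
  }
  # replay the alternating algorithm, tracking the objective each step
  b <- rep(0, 10); s <- sqrt(pb$yty)
  objs <- obj(b, s)
  for (k in 1:20) {
    b <- as.numeric(lasso_cd(pb$gram, pb$xty, lambda0 * s, beta_init = b))
    s <- sqrt(max(pb$yty - 2 * sum(b * pb$xty) +
                    drop(crossprod(b, pb$gram %*% b)), 0))
    objs <- c(objs, obj(b, s))
  }
  expect_true(all(diff(objs) <= 1e-10))
  # and the packaged solver lands at the same fixed point
  fit <- scaled_lasso(pb$gram, pb$xty, pb$yty, lambda0 = lambda0)
  expect_equal(fit$beta, b, tolerance = 1e-4)
})

test_that("scaled lasso flags a degenerate (perfectly predictable) response", {
  x1 <- rnorm(30)
  X <- cbind(x1)
  y <- 3 * x1  # exactly in the span
  pb <- gram_problem(X, y)
  expect_error(scaled_lasso(pb$gram, pb$xty, pb$yty, lambda0 = 1e-6),
               "degenerate")
})

test_that("graphical lasso hits its closed-form limits", {
  # fully decoupling penalty: diagonal inverse
  S <- random_pd(6, seed = 51)
  lam <- max(abs(S[upper.tri(S)])) + 0.01
  Om <- graphical_lasso(S, lam)
  expect_equal(unclass(Om), diag(1 / diag(S)), tolerance = 1e-7,
               ignore_attr = TRUE)

  # p = 2, lambda = 0: the exact 2x2 inverse
  S2 <- matrix(c(2, 0.6, 0.6, 1), 2, 2)
  det2 <- 2 * 1 - 0.6^2
  inv2 <- matrix(c(1, -0.6, -0.6, 2), 2, 2) / det2
  expect_equal(unclass(graphical_lasso(S2, 0)), inv2, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("graphical lasso attains a small duality gap and stays PD", {
  S <- random_pd(10, seed = 61)
  Om <- graphical_lasso(S, 0.1)
  # recompute the gap from the returned estimate
  gap <- sum(S * Om) - 10 + 0.1 * (sum(abs(Om)) - sum(abs(diag(Om))))
  expect_lt(abs(gap), 1e-6)
  expect_lt(max(abs(Om - t(Om))), 1e-12)
  expect_gt(min(eigen(unclass(Om), symmetric = TRUE)$values), 0)
})

test_that("sparse_quadform equals the dense triple product", {
  p <- 50
  Sg <- random_pd(p, seed = 71)
  expect_equal(sparse_quadform(matrix(0, p, p), Sg), matrix(0, p, p))

  Thd <- diag(runif(p, 0.5, 2))
  expect_equal(sparse_quadform(Thd, Sg), t(Thd) %*% Sg %*% Thd,
               tolerance = 1e-12)

  set.seed(72)
  Th <- matrix(0, p, p)
  nz <- sample(p * p, round(0.05 * p * p))
  Th[nz] <- rnorm(length(nz))
  expect_equal(sparse_quadform(Th, Sg), t(Th) %*% Sg %*% Th,
               tolerance = 1e-10)
  expect_error(sparse_quadform(Th[, 1:3, drop = FALSE][1:3, ], Sg),
               "shape")
})

test_that("sparse_quadform operation count scales with the non-zeros", {
  p <- 50
  Sg <- random_pd(p, seed = 81)
  set.seed(82)
  Th <- matrix(0, p, p)
  nz <- sample(p * p, round(0.05 * p * p))
  Th[nz] <- rnorm(length(nz))
  ops <- ggminfer:::sparse_quadform_opcount(Th, Sg)
  expect_equal(ops, length(nz) * 2 * p)   # s*p^2-type, not p^3
  expect_lt(ops, 0.2 * p^3)
})
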