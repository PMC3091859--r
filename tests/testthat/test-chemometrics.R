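test_that("autoscaling standardizes the training matrix exactly", {
  set.seed(30)
  X <- matrix(rnorm(20 * 6, 5, 3), 20, 6)
  prm <- autoscale_fit(X)
  Xs <- autoscale_apply(X, prm)
  expect_lt(max(abs(colMeans(Xs))), 1e-12)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-12)
})

test_that("autoscaling the 2x2 instance matches the hand computation", {
  X <- rbind(c(0, 10), c(2, 30))
  Xs <- autoscale_apply(X, autoscale_fit(X))
  a <- 1 / sqrt(2)  # (0 - 1)/sd(c(0,2)) = -1/sqrt(2), same for column 2
  expect_equal(Xs, rbind(c(-a, -a), c(a, a)), tolerance = 1e-12)
})

test_that("new data is scaled with training parameters, not its own", {
  set.seed(31)
  X <- matrix(rnorm(10 * 3), 10, 3)
  prm <- autoscale_fit(X)
  Xnew <- matrix(rnorm(4 * 3, 10, 5), 4, 3)
  Xs <- autoscale_apply(Xnew, prm)
  expect_equal(Xs, sweep(sweep(Xnew, 2, prm$mean), 2, prm$sd, "/"),
               tolerance = 1e-12)
  expect_gt(abs(mean(Xs)), 1)  # far from zero because params are training's
})

test_that("a constant column is a degenerate-column error naming the band", {
  X <- cbind(`450` = rnorm(5), `505` = rep(2, 5))
  expect_error(autoscale_fit(X), "505")
})

test_that("PLS fits an exact linear relation to numerical zero", {
  set.seed(32)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3, 1)) + 4
  m <- plsr_fit(X, y, ncomp = 6)
  expect_lt(max(abs(m$fitted - y)), 1e-8)
})

test_that("full-component PLS equals ordinary least squares", {
  for (s in 1:20) {
    inst <- random_instance(n = 12 + s %% 6, p = 3 + s %% 4, seed = 300 + s)
    Xnew <- matrix(rnorm(5 * ncol(inst$X)), 5)
    m <- plsr_fit(inst$X, inst$y, ncomp = ncol(inst$X))
    expect_equal(predict(m, Xnew), ols_predict(inst$X, inst$y, Xnew),
                 tolerance = 1e-10)
  }
})

test_that("single-column PLS reduces to simple linear regression", {
  set.seed(33)
  x <- rnorm(15, 2, 1)
  y <- 3 * x - 1 + rnorm(15, sd = 0.2)
  m <- plsr_fit(matrix(x, ncol = 1), y, ncomp = 1)
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  xg <- c(-1, 0, 2.5)
  expect_equal(predict(m, matrix(xg, ncol = 1)), slope * xg + intercept,
               tolerance = 1e-10)
})

test_that("predicting the training mean spectrum returns the mean response", {
  inst <- random_instance(20, 5, seed = 34)
  m <- plsr_fit(inst$X, inst$y, ncomp = 3)
  expect_equal(predict(m, colMeans(inst$X)), mean(inst$y), tolerance = 1e-10)
})

test_that("regression-vector and loadings-path predictions coincide", {
  inst <- random_instance(18, 6, seed = 35)
  m <- plsr_fit(inst$X, inst$y, ncomp = 4)
  Xnew <- matrix(rnorm(7 * 6), 7, 6)
  Xs <- autoscale_apply(Xnew, m$autoscale)
  scores <- Xs %*% m$W %*% solve(crossprod(m$P, m$W))
  path <- m$y_mean + drop(scores %*% m$q) * m$y_sd
  expect_equal(predict(m, Xnew), path, tolerance = 1e-10)
})

test_that("PLS prediction is affine in the input spectrum", {
  inst <- random_instance(16, 5, seed = 36)
  m <- plsr_fit(inst$X, inst$y, ncomp = 3)
  x1 <- rnorm(5); x2 <- rnorm(5)
  lhs <- predict(m, 0.3 * x1 + 0.7 * x2)
  rhs <- 0.3 * predict(m, x1) + 0.7 * predict(m, x2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("PLS rejects invalid component counts and degenerate responses", {
  inst <- random_instance(10, 4, seed = 37)
  expect_error(plsr_fit(inst$X, inst$y, ncomp = 0), "domain error")
  expect_error(plsr_fit(inst$X, inst$y, ncomp = 5), "domain error")
  expect_error(plsr_fit(inst$X, rep(2, 10), ncomp = 2), "degenerate")
  m <- plsr_fit(inst$X, inst$y, ncomp = 2)
  expect_error(predict(m, matrix(1, 2, 3)), "shape error")
})

test_that("LOOCV equals the brute-force refit oracle", {
  for (s in 1:5) {
    inst <- random_instance(n = 10 + s, p = 4, noise = 0.3, seed = 400 + s)
    cv <- loocv_select(inst$X, inst$y, a_max = 4)
    expect_equal(unname(cv$rmsecv), loocv_oracle(inst$X, inst$y, 4),
                 tolerance = 1e-10)
    expect_identical(unname(cv$ncomp), unname(which.min(cv$rmsecv)))
  }
})

test_that("LOOCV finds a one-factor structure at one component", {
  set.seed(38)
  t <- rnorm(15)
  X <- outer(t, c(1, 0.5, -0.3, 2)) # rank-1, noiseless
  y <- 2 * t + 1
  cv <- loocv_select(X, y, a_max = 3)
  expect_identical(unname(cv$ncomp), 1L)
  expect_lt(cv$rmsecv[1], 1e-8)
})

test_that("LOOCV caps unreachable component counts with a warning", {
  inst <- random_instance(6, 10, seed = 39)
  expect_warning(cv <- loocv_select(inst$X, inst$y, a_max = 9), "capped")
  expect_length(cv$rmsecv, 4)  # min(p, n - 2)
})

test_that("prediction metrics match hand-computed values", {
  m <- prediction_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmsep, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(m$r2, 0.5, tolerance = 1e-12)
  perfect <- prediction_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$r2, 1)
  null <- prediction_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(null$r2, 0)
  expect_error(prediction_metrics(c(1, 1), c(1, 2)), "zero variance")
  expect_error(prediction_metrics(1, 1), "lengths")
})

test_that("outlier screening is calibrated under the null", {
  set.seed(41)
  frac <- replicate(100, {
    X <- matrix(rnorm(200 * 5), 200, 5)
    length(screen_outliers(X)$flagged) / 200
  })
  expect_lt(abs(mean(frac) - 0.025), 0.01)
})

test_that("a gross outlier is flagged and flagging ignores column order", {
  set.seed(40)
  X <- matrix(rnorm(50 * 6), 50, 6)
  X[7, ] <- X[7, ] + 10
  out <- screen_outliers(X)
  expect_true(7 %in% out$flagged)
  perm <- X[, c(4, 1, 6, 2, 5, 3)]
  expect_identical(screen_outliers(perm)$flagged, out$flagged)
  expect_identical(ncol(out$scores), 2L)
})
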