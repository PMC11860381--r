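test_that("detrend removes exact polynomials and matches the least-squares oracle", {
  p <- 20
  ramp <- matrix(3 + 2 * seq_len(p), 1)
  expect_equal(max(abs(detrend(ramp, 1))), 0, tolerance = 1e-12)
  quad <- matrix(1 - 0.5 * seq_len(p) + 0.1 * seq_len(p)^2, 1)
  expect_equal(max(abs(detrend(quad, 2))), 0, tolerance = 1e-9)

  set.seed(11)
  X <- matrix(rnorm(3 * p), 3)
  out <- detrend(X, 1)
  # normal-equations oracle, one row at a time
  idx <- seq_len(p)
  for (i in 1:3) {
    fit <- stats::lm.fit(cbind(1, idx), X[i, ])
    expect_equal(out[i, ], unname(fit$residuals), tolerance = 1e-8)
  }
  # idempotent at fixed order; shape preserved
  expect_equal(detrend(out, 1), out, tolerance = 1e-10)
  expect_equal(dim(out), dim(X))
  expect_error(detrend(X, p), "n_points")
})

test_that("snv standardizes each row and rejects constant scans", {
  expect_equal(as.vector(snv(matrix(1:3, 1))), c(-1, 0, 1))
  set.seed(2)
  X <- matrix(rnorm(50), 5)
  out <- snv(X)
  expect_equal(rowMeans(out), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(out, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_equal(snv(out), out, tolerance = 1e-12)  # idempotent
  expect_error(snv(rbind(X, 7)), "row 6")
})

test_that("msc inverts affine scatter and matches the 2x2 normal-equations oracle", {
  set.seed(4)
  ref <- as.vector(smooth_ref <- cumsum(rnorm(30)))
  expect_equal(as.vector(msc(matrix(ref, 1), ref)), ref, tolerance = 1e-10)
  distorted <- matrix(2 * ref + 3, 1)
  expect_equal(as.vector(msc(distorted, ref)), ref, tolerance = 1e-10)

  X <- matrix(rnorm(60), 2)
  out <- msc(X, ref)
  for (i in 1:2) {
    cf <- solve(rbind(c(30, sum(ref)), c(sum(ref), sum(ref^2))),
                c(sum(X[i, ]), sum(X[i, ] * ref)))  # (b, a)
    expect_equal(out[i, ], (X[i, ] - cf[1]) / cf[2], tolerance = 1e-8)
  }
  expect_error(msc(X, rep(1, 30)), "zero variance")
  expect_error(msc(matrix(0, 1, 30), ref), "row 1")
})

test_that("emsc removes polynomial baselines and reduces to msc at order 0", {
  set.seed(5)
  p <- 40
  ref <- exp(-0.5 * ((seq_len(p) - 20) / 5)^2)
  baseline <- 0.4 - 0.02 * seq_len(p) + 0.003 * seq_len(p)^2
  expect_equal(as.vector(emsc(matrix(ref + baseline, 1), ref, 2)), ref,
               tolerance = 1e-9)

  X <- matrix(rnorm(2 * p), 2)
  expect_equal(emsc(X, ref, 0), msc(X, ref), tolerance = 1e-8)

  # residual of the fit is orthogonal to [reference, polynomial basis]
  out <- emsc(X, ref, 2)
  D <- cbind(ref, outer(seq_len(p) - (p + 1) / 2, 0:2, `^`))
  cf <- t(qr.coef(qr(D), t(X)))
  resid <- X - cf %*% t(D)
  expect_lt(max(abs(resid %*% D)), 1e-8)
  expect_error(emsc(X, D[, 3] * 2, 1), "collinear")
})

test_that("savgol derivatives of polynomials match analytic values on interior points", {
  p <- 60
  i <- seq_len(p)
  q <- 2 + 0.3 * i - 0.05 * i^2
  interior <- 8:(p - 7)
  d1 <- savgol(matrix(q, 1), 15, 2, 1)
  expect_equal(d1[1, interior], 0.3 - 0.1 * i[interior], tolerance = 1e-9)
  d2 <- savgol(matrix(q, 1), 15, 2, 2)
  expect_equal(d2[1, interior], rep(-0.1, length(interior)), tolerance = 1e-9)
  expect_equal(max(abs(savgol(matrix(5, 1, p), 15, 2, 1))), 0)
  # deriv 0 leaves degree <= polyorder polynomials fixed on the interior
  sm <- savgol(matrix(q, 1), 15, 2, 0)
  expect_equal(sm[1, interior], q[interior], tolerance = 1e-9)
  # shrink-window edges reproduce a local polynomial fit at the boundary
  set.seed(6)
  x <- rnorm(p)
  out <- savgol(matrix(x, 1), 15, 2, 1)
  off <- -1:7  # window at point 2: points 1..9
  fit <- stats::lm.fit(outer(off, 0:2, `^`), x[1:9])
  expect_equal(out[1, 2], unname(fit$coefficients[2]), tolerance = 1e-9)
  expect_error(savgol(matrix(x, 1), 14, 2, 1), "odd")
  expect_error(savgol(matrix(x, 1), 3, 4, 1), "exceed")
  expect_error(savgol(matrix(x, 1), 61, 2, 1), "n_points")
})

test_that("savgol interior agrees with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(9)
  x <- cumsum(rnorm(80))
  ours <- savgol(matrix(x, 1), 15, 2, 0)[1, ]
  theirs <- as.vector(signal::sgolayfilt(x, p = 2, n = 15, m = 0))
  expect_equal(ours[8:73], theirs[8:73], tolerance = 1e-9)
})

test_that("mean centering uses calibration means, never the new data's own", {
  set.seed(10)
  Xcal <- matrix(rnorm(40), 4)
  mu <- mean_center_fit(Xcal)
  centered <- mean_center_apply(Xcal, mu)
  expect_equal(colMeans(centered), rep(0, 10), tolerance = 1e-12)
  # idempotence: re-centering already-centered data with its own means
  expect_equal(mean_center_apply(centered, mean_center_fit(centered)),
               centered, tolerance = 1e-12)
  expect_equal(as.vector(mean_center_apply(matrix(0, 1, 10), mu)), -mu)
  expect_error(mean_center_apply(Xcal, mu[-1]), "length")
})

test_that("pipelines fit state on calibration only and apply it unchanged", {
  set.seed(12)
  Xcal <- matrix(rnorm(200), 10)
  Xval <- matrix(rnorm(100), 5)

  fitted <- fit_pipeline(cultivar_chain(), Xcal)
  out_val <- predict(fitted, Xval)
  # manual replay: MSC reference and means must come from the cal chain
  s1 <- detrend(Xcal, 1)
  ref <- colMeans(s1)
  s2 <- msc(s1, ref)
  s3 <- savgol(s2, 15, 2, 2)
  mu <- colMeans(s3)
  v <- mean_center_apply(savgol(msc(detrend(Xval, 1), ref), 15, 2, 2), mu)
  expect_equal(out_val, v, tolerance = 1e-10)

  # empty pipeline is the identity
  id <- fit_pipeline(preprocess_pipeline(), Xcal)
  expect_equal(predict(id, Xval), Xval)

  # endophyte chain ends in mean centering over the calibration data
  fe <- fit_pipeline(endophyte_chain(), Xcal)
  expect_equal(colMeans(fe$cal_transformed), rep(0, 20), tolerance = 1e-12)

  expect_error(predict(endophyte_chain(), Xval), "fitted")
})

test_that("row-local operators commute with scan permutation", {
  set.seed(13)
  X <- matrix(rnorm(80), 8)
  perm <- sample(8)
  for (f in list(function(m) detrend(m, 1), snv,
                 function(m) savgol(m, 7, 2, 1))) {
    expect_equal(f(X)[perm, ], f(X[perm, ]))
  }
  # msc with a fixed reference is also row-local
  ref <- colMeans(X)
  expect_equal(msc(X, ref)[perm, ], msc(X[perm, ], ref))
})
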