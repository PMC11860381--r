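test_that("full-rank PLS reproduces the least-squares fit", {
  set.seed(31)
  X <- matrix(rnorm(20 * 10), 20)
  y <- rep(c("A", "B"), 10)
  m <- plsda(X, y, n_lv = 10, positive = "A", threshold_method = "zero")
  ynum <- ifelse(y == "A", 1, -1)
  ols <- stats::lm.fit(cbind(1, X), ynum)
  expect_equal(fitted(m), unname(ols$fitted.values), tolerance = 1e-8)
})

test_that("rank-1 X with proportional y is fit exactly by one LV", {
  set.seed(32)
  t1 <- c(rnorm(6, 2, 0.3), rnorm(6, -2, 0.3))  # clear one-factor margin
  X <- outer(t1, rnorm(6))
  y <- ifelse(t1 > 0, "hi", "lo")
  m <- plsda(X, y, n_lv = 1, positive = "hi")
  expect_equal(as.character(predict(m, X, type = "class")),
               ifelse(t1 > 0, "hi", "lo"))
  # exact reproduction when y IS the single factor direction
  yprop <- ifelse(t1 > median(t1), 1, -1)
  Xp <- outer(yprop - mean(yprop), rnorm(6))
  mp <- plsda(Xp, ifelse(yprop > 0, "P", "N"), n_lv = 1, positive = "P",
              threshold_method = "zero")
  expect_equal(fitted(mp), as.vector(yprop), tolerance = 1e-10)
})

test_that("calibration score vectors are pairwise orthogonal", {
  set.seed(33)
  X <- matrix(rnorm(30 * 12), 30)
  y <- rep(c("A", "B"), 15)
  m <- plsda(X, y, n_lv = 5, positive = "A")
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("degenerate fits are rejected with the attained rank", {
  X <- matrix(rnorm(40), 10)
  expect_error(plsda(X, rep("A", 10), n_lv = 1), "single class")
  expect_error(plsda(X, rep(c("A", "B"), 5), n_lv = 7), "rank")
})

test_that("decision thresholds match closed forms and the root-finding oracle", {
  set.seed(34)
  # symmetric, equal spread -> 0
  p1 <- rnorm(200, 1, 0.3)
  is1 <- rep(c(TRUE, FALSE), each = 200)
  thr <- decision_threshold(c(p1, -p1), is1, "gaussian")
  expect_equal(thr, 0, tolerance = 1e-12)
  # equal sds, unequal means -> midpoint
  p2 <- p1 - 3.7  # identical spread by construction
  expect_equal(decision_threshold(c(p1, p2), is1, "gaussian"),
               (mean(p1) + mean(p2)) / 2, tolerance = 1e-10)
  # unequal sds: crossing matches numerical density-equality root
  m1 <- -1; s1 <- 0.1; m2 <- 1; s2 <- 0.4
  q1 <- rnorm(500); q1 <- m1 + s1 * (q1 - mean(q1)) / sd(q1)
  q2 <- rnorm(500); q2 <- m2 + s2 * (q2 - mean(q2)) / sd(q2)
  thr <- decision_threshold(c(q1, q2), rep(c(TRUE, FALSE), each = 500),
                            "gaussian")
  root <- uniroot(function(x) dnorm(x, m1, s1) - dnorm(x, m2, s2),
                  c(m1, m2), tol = 1e-12)$root
  expect_equal(thr, root, tolerance = 1e-6)
  # degenerate class -> midpoint with warning
  expect_warning(
    thr2 <- decision_threshold(c(0.5, -1, -2, -3), c(TRUE, FALSE, FALSE, FALSE)),
    "midpoint")
  expect_equal(thr2, (0.5 + mean(c(-1, -2, -3))) / 2)
})

test_that("classification is deterministic, ties go to class 1", {
  sep <- make_separable()
  m <- plsda(sep$X, sep$y, n_lv = 2, positive = "A")
  expect_equal(as.character(predict(m, sep$X, type = "class")), sep$y)
  # force a tie: set the threshold to an exact prediction value
  r <- predict(m, sep$X[5, , drop = FALSE], type = "response")
  m$threshold <- r
  expect_equal(as.character(predict(m, sep$X[5, , drop = FALSE],
                                    type = "class")), "A")
})

test_that("random labels on noise give chance-level cross-validation error", {
  errs <- sapply(1:8, function(seed) {
    set.seed(seed + 100)
    X <- matrix(rnorm(60 * 10), 60)
    y <- rep(c("A", "B"), 30)
    cross_validate(X, y, venetian_blinds(60, 6), NULL, n_lv = 1,
                   positive = "A")$report$class_error
  })
  expect_gt(mean(errs), 0.3)
  expect_lt(mean(errs), 0.7)
})

test_that("class error equals 1 - (sensitivity + specificity)/2 (printed-row check)", {
  # sensitivity 1.00 with specificity 51/53 = 0.962 gives class error 1.9%
  truth <- c(rep("pos", 12), rep("neg", 53))
  pred <- c(rep("pos", 12), rep("pos", 2), rep("neg", 51))
  rep <- evaluate(truth, pred, positive = "pos", context = "prediction")
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 51 / 53)
  expect_equal(round(100 * rep$class_error, 1), 1.9)
  expect_equal(rep$overall_accuracy, 1 - rep$class_error)

  perfect <- evaluate(truth, truth, positive = "pos")
  expect_equal(perfect$class_error, 0)
  expect_equal(perfect$overall_accuracy, 1)

  all_pos <- evaluate(c("pos", "pos", "neg", "neg"), rep("pos", 4), "pos")
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$class_error, 0.5)
})

test_that("class error is symmetric under swapping class roles", {
  set.seed(36)
  truth <- sample(c("A", "B"), 40, replace = TRUE)
  pred <- sample(c("A", "B"), 40, replace = TRUE)
  ra <- evaluate(truth, pred, positive = "A")
  rb <- evaluate(truth, pred, positive = "B")
  expect_equal(ra$class_error, rb$class_error)
  expect_equal(ra$sensitivity, rb$specificity)
  expect_equal(ra$specificity, rb$sensitivity)
})

test_that("cross-validation predicts every scan exactly once and beats calibration rarely", {
  sep <- make_separable(n_per_class = 15, gap = 8)
  folds <- venetian_blinds(30, 5)
  cv <- cross_validate(sep$X, sep$y, folds, NULL, n_lv = 2, positive = "A")
  expect_false(any(is.na(cv$predicted)))
  expect_equal(cv$report$class_error, 0)  # noiseless separable
  expect_equal(sum(cv$report$confusion), 30)

  # CV error >= calibration error on average over noisy repetitions
  diffs <- sapply(1:20, function(seed) {
    set.seed(seed + 200)
    X <- matrix(rnorm(40 * 8), 40)
    y <- rep(c("A", "B"), 20)
    X[y == "A", 1] <- X[y == "A", 1] + 1.2
    m <- plsda(X, y, n_lv = 3, positive = "A")
    cal_err <- evaluate(y, predict(m, X, type = "class"), "A")$class_error
    cv_err <- cross_validate(X, y, venetian_blinds(40, 5), NULL, 3,
                             positive = "A")$report$class_error
    cv_err - cal_err
  })
  expect_gte(mean(diffs), 0)
})

test_that("latent-variable selection minimizes CV error with parsimony ties", {
  set.seed(37)
  # signal spans 3 orthogonal directions
  n <- 48
  S <- matrix(rnorm(n * 3), n)
  y <- ifelse(S %*% c(1, 1, 1) > 0, "A", "B")
  X <- S %*% matrix(rnorm(3 * 12), 3) + matrix(rnorm(n * 12, sd = 0.05), n)
  sel <- select_lv(X, y, venetian_blinds(n, 6), NULL, max_lv = 8,
                   positive = "A")
  expect_lte(sel$n_lv, 4)
  expect_lte(sel$cv_class_error[sel$n_lv], sel$cv_class_error[8])
  expect_equal(sel$n_lv, which.min(sel$cv_class_error))  # first minimum
  sel1 <- select_lv(X, y, venetian_blinds(n, 6), NULL, max_lv = 1,
                    positive = "A")
  expect_equal(sel1$n_lv, 1)
})

test_that("nested sequences eliminate classes in order with shrinking pools", {
  set.seed(38)
  d <- toy_design(n_bags_per_class = 3, cultivars = c("Alto", "Bronsyn", "Trojan"))
  s <- generate_spectra(d, spectral_effect_params(seed = 38))
  nested <- fit_nested(s$absorbance, s$metadata$cultivar,
                       order = c("Bronsyn", "Alto", "Trojan"),
                       pipeline = cultivar_chain(), n_splits = 6, max_lv = 4)
  expect_length(nested$steps, 2)
  expect_equal(nested$steps[[1]]$target, "Bronsyn")
  expect_setequal(nested$steps[[1]]$pool, c("Alto", "Trojan"))
  expect_equal(nested$steps[[2]]$pool, "Trojan")
  expect_equal(nested$elimination_order, c("Bronsyn", "Alto", "Trojan"))
  expect_error(fit_nested(s$absorbance, s$metadata$cultivar,
                          order = c("Alto", "Bronsyn"),
                          pipeline = cultivar_chain()), "permutation")

  # two classes -> a single plain binary model
  d2 <- toy_design(n_bags_per_class = 3)
  s2 <- generate_spectra(d2, spectral_effect_params(seed = 39))
  n2 <- fit_nested(s2$absorbance, s2$metadata$cultivar,
                   order = c("Alto", "Trojan"),
                   pipeline = cultivar_chain(), n_splits = 6, max_lv = 3)
  expect_length(n2$steps, 1)
  expect_s3_class(n2$steps[[1]]$model, "plsda")
})

test_that("automatic ordering matches exhaustive per-step lowest-CV-error search", {
  set.seed(40)
  d <- toy_design(n_bags_per_class = 3,
                  cultivars = c("Alto", "Bronsyn", "Trojan"))
  s <- generate_spectra(d, spectral_effect_params(seed = 40))
  X <- s$absorbance; y <- s$metadata$cultivar
  auto <- fit_nested(X, y, order = "auto", pipeline = cultivar_chain(),
                     n_splits = 6, max_lv = 3)
  # oracle: enumerate candidate first targets, pick lowest one-vs-rest CV error
  errs <- sapply(sort(unique(y)), function(target) {
    sel <- select_lv(X, y, venetian_blinds(nrow(X), 6),
                     cultivar_chain(), max_lv = 3, positive = target)
    sel$cv_class_error[sel$n_lv]
  })
  expect_equal(auto$steps[[1]]$target, names(which.min(errs)))
})

test_that("four-cultivar nesting uses the default elimination order", {
  set.seed(41)
  d <- toy_design(n_bags_per_class = 3,
                  cultivars = c("Alto", "Bronsyn", "Maxsyn", "Trojan"))
  s <- generate_spectra(d, spectral_effect_params(seed = 41))
  nested <- fit_nested(s$absorbance, s$metadata$cultivar,
                       pipeline = cultivar_chain(), n_splits = 6, max_lv = 3)
  expect_length(nested$steps, 3)
  expect_equal(nested$elimination_order,
               c("Maxsyn", "Alto", "Bronsyn", "Trojan"))
  pools <- sapply(nested$steps, function(st) length(st$pool) + 1)
  expect_equal(pools, c(4, 3, 2))  # working classes shrink 4 -> 3 -> 2
})
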