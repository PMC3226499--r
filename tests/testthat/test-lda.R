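gauss_case <- function(seed, n = 50, delta = 5) {
  set.seed(seed)
  X <- matrix(c(rnorm(n, 0), rnorm(n, delta)), ncol = 1)
  list(X = X, y = rep(c(0, 1), each = n))
}

test_that("well-separated Gaussians are almost perfectly classified", {
  d <- gauss_case(101)
  fit <- lda_fit(d$X, d$y)
  acc <- mean(predict(fit, d$X, type = "class") == d$y)
  expect_true(acc >= 0.98)   # Bayes error at delta = 5 sigma is ~0.006
})

test_that("identical class means carry no signal", {
  set.seed(102)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y <- rep(c(0, 1), 100)
  fit <- lda_fit(X[1:120, ], y[1:120])
  expect_true(sqrt(sum(fit$coefficients^2)) < 1)   # near-null direction
  held <- predict(fit, X[121:200, ], type = "class")
  cc <- table(factor(held, c(0, 1)), factor(y[121:200], c(0, 1)))
  ba <- balanced_accuracy(cc[2, 2], cc[2, 1], cc[1, 1], cc[1, 2])
  expect_true(abs(ba - 0.5) < 0.2)
})

test_that("coefficients match a direct matrix-inverse computation", {
  set.seed(103)
  for (rep in 1:10) {
    X <- matrix(rnorm(80), 40, 2)
    y <- rep(c(0, 1), 20)
    X[y == 1, ] <- X[y == 1, ] + c(1.5, -1)
    fit <- lda_fit(X, y, ridge = 1e-6)
    X0 <- X[y == 0, ]; X1 <- X[y == 1, ]
    S <- ((nrow(X0) - 1) * cov(X0) + (nrow(X1) - 1) * cov(X1)) /
      (nrow(X) - 2) + diag(1e-6, 2)
    det_S <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    inv_S <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det_S
    w <- inv_S %*% (colMeans(X1) - colMeans(X0))
    expect_equal(unname(fit$coefficients), as.numeric(w), tolerance = 1e-10)
  }
})

test_that("the discriminant direction agrees with an established LDA", {
  set.seed(104)
  X <- matrix(rnorm(200), 100, 2)
  y <- rep(c(0, 1), 50)
  X[y == 1, ] <- X[y == 1, ] + c(2, 1)
  fit <- lda_fit(X, y)
  ref <- MASS::lda(X, grouping = y)
  # directions proportional: projections perfectly correlated
  expect_equal(as.numeric(abs(cor(X %*% fit$coefficients, X %*% ref$scaling))),
               1, tolerance = 1e-6)
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(lda_fit(X, rep(1, 10)), "both classes")
  expect_error(lda_fit(matrix(rnorm(12), 3, 4), c(0, 1, 1)),
               "more samples")
  # perfectly collinear features defeat even the ridge at zero ridge
  Xc <- cbind(1:10, 1:10)
  expect_error(lda_fit(Xc, rep(c(0, 1), 5), ridge = 0), "singular")
})

test_that("balanced accuracy is the sensitivity/specificity average", {
  expect_equal(balanced_accuracy(10, 0, 10, 0), 1)
  expect_equal(balanced_accuracy(9, 3, 7, 1), (0.9 + 0.7) / 2)  # 0.8
  expect_equal(balanced_accuracy(10, 10, 0, 0), 0.5)  # all-positive predictor
  expect_error(balanced_accuracy(0, 0, 0, 0), "both classes")
  expect_error(balanced_accuracy(-1, 0, 1, 1), "nonnegative")
})

test_that("AUC is the Mann-Whitney statistic with ties credited 0.5", {
  expect_equal(auc_score(c(1, 2, 3, 11, 12, 13), rep(c(0, 1), each = 3)), 1)
  expect_equal(auc_score(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(105)
  for (rep in 1:10) {
    s <- sample(1:8, 30, replace = TRUE)   # heavy ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- 0; wins <- 0
    for (i in which(y == 1)) for (j in which(y == 0)) {
      pairs <- pairs + 1
      wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    expect_equal(auc_score(s, y), wins / pairs)
    expect_equal(auc_score(s, y), as.numeric(pROC::auc(y, s, quiet = TRUE,
                                                       direction = "<")))
  }
})

planted_case <- function(seed, signal = TRUE, n = 60, p = 20) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(0, 1), each = n / 2)
  if (signal) X[, 5] <- y * 4 + rnorm(n, sd = 0.3)
  list(X = X, y = y)
}

test_that("stepwise selection finds a perfectly separating feature first", {
  d <- planted_case(7)
  mod <- stepwise_select(d$X, d$y, folds = 5, seed = 7)
  expect_equal(mod$features[1], "V5")
  expect_true(mod$cv_stats$test_ba >= 0.95)
  expect_true(mod$cv_stats$auc >= 0.95)
})

test_that("pure-noise features yield a small chance-level model", {
  d <- planted_case(7, signal = FALSE)
  mod <- stepwise_select(d$X, d$y, folds = 5, seed = 7)
  expect_true(length(mod$features) <= 2)
  expect_true(mod$cv_stats$test_ba >= 0.3 && mod$cv_stats$test_ba <= 0.7)
})

test_that("a duplicated informative feature is selected exactly once", {
  d <- planted_case(7)
  X2 <- cbind(d$X, d$X[, 5])
  colnames(X2) <- c(paste0("V", 1:20), "V5_copy")
  mod <- stepwise_select(X2, d$y, folds = 5, seed = 7)
  expect_equal(sum(mod$features %in% c("V5", "V5_copy")), 1)
  expect_equal(mod$features[1], "V5")   # lowest index wins the tie
})

test_that("selection requires enough members per class", {
  d <- planted_case(7)
  expect_error(stepwise_select(d$X[c(1:3, 31:40), ], d$y[c(1:3, 31:40)],
                               folds = 5), "at least")
})

test_that("predictions are invariant to affine feature rescaling", {
  d <- planted_case(9)
  mod <- stepwise_select(d$X, d$y, folds = 5, seed = 9, max_features = 3)
  Xs <- d$X
  Xs[, 5] <- Xs[, 5] * 1000 + 7
  fit_a <- lda_fit(d$X[, 1:6], d$y)
  fit_b <- lda_fit(Xs[, 1:6], d$y)
  expect_equal(predict(fit_a, d$X[, 1:6], type = "class"),
               predict(fit_b, Xs[, 1:6], type = "class"))
  expect_true(length(mod$features) >= 1)
})

test_that("fixed-seed repetition is bit-identical; reseeding stays stable", {
  d <- planted_case(12)
  chk <- stability_check(d$X, d$y, repeats = 5, seed = 12)
  expect_true(chk$identical)
  expect_equal(chk$dispersion, 0)
  chk2 <- stability_check(d$X, d$y, repeats = 5, seed = 12,
                          vary_seeds = TRUE)
  expect_true(chk2$dispersion < 0.1)
  # degenerate n: graceful NA report, no crash
  tiny <- planted_case(13, signal = FALSE, n = 10, p = 3)
  chk3 <- stability_check(tiny$X, tiny$y, repeats = 2, folds = 8)
  expect_true(all(is.na(chk3$test_ba)))
})

test_that("the feature matrix is unit-scaled with undefined pathway scores as 0", {
  set.seed(106)
  m <- random_pm(6, 8, hit_rate = 0.4)
  ann <- round_robin_annotations(colnames(m), "x")
  ann$gene_symbol <- paste0("g", 1:8)
  pw <- pathway_set(c("few", "many"),
                    list(paste0("g", 1:2), paste0("g", 1:8)))
  X <- build_feature_matrix(m, ann, pathways = pw, min_targets = 5)
  expect_equal(dim(X), c(6, 10))
  expect_true(all(X >= 0 & X <= 1))
  expect_false(anyNA(X))
  # the two-gene pathway can never reach five active targets
  expect_true(all(X[, "pathway:few"] == 0))
  expect_equal(unname(X[, 1:8]),
               unname(matrix(assay_unit_score(unclass(m)), 6, 8)))
})
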