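test_that("feature matrix columns match a hand overlap table", {
  sites <- mk_sites("chr1", c(0, 100, 200, 300, 400),
                    c(50, 150, 250, 350, 450))
  same <- sites
  shifted <- mk_sites("chr1", c(40, 500), c(90, 600))
  disjoint <- mk_sites("chr2", 0, 1000)
  ft <- build_feature_matrix(sites,
                             binary_sets = list(same = same, part = shifted,
                                                none = disjoint),
                             continuous = list(sig = c(1, 2, 3, 4, 5)))
  expect_equal(unname(ft$X[, "same"]), rep(1, 5))
  expect_equal(unname(ft$X[, "part"]), c(1, 0, 0, 0, 0))
  expect_equal(unname(ft$X[, "none"]), rep(0, 5))
  expect_equal(mean(ft$X[, "sig"]), 0)
  expect_equal(stats::sd(ft$X[, "sig"]), 1)
  expect_warning(
    build_feature_matrix(sites, continuous = list(flat = rep(2, 5),
                                                  ok = 1:5)),
    "zero-variance")
})

test_that("k-means recovers well-separated planted clusters", {
  km1 <- kmeans_cluster(matrix(rnorm(50), 25, 2), k = 1, seed = 1)
  expect_true(all(km1$cluster == 1))
  expect_error(kmeans_cluster(matrix(0, 5, 2), k = 0), "k must be")
  expect_error(kmeans_cluster(matrix(0, 5, 2), k = 6), "exceeds")

  set.seed(99)
  cl <- sample(1:3, 240, replace = TRUE)
  X <- matrix(rnorm(240 * 4), 240, 4) + 5 * cbind(cl == 1, cl == 2, cl == 3, 0)
  km <- kmeans_cluster(X, k = 3, seed = 5)
  expect_gte(adjusted_rand(km$cluster, cl), 0.95)
  # duplicated rows land in the same cluster; determinism under the seed
  X2 <- rbind(X, X[1, , drop = FALSE])
  km2 <- kmeans_cluster(X2, k = 3, seed = 5)
  expect_equal(km2$cluster[241], km2$cluster[1])
  expect_identical(km, kmeans_cluster(X, k = 3, seed = 5))
})

test_that("chromosome-held-out splits are disjoint and balanced", {
  chrom <- paste0("chr", rep(1:4, times = c(10, 11, 12, 13)))
  sp <- make_split(chrom, "chr4", folds = 5, seed = 2)
  expect_equal(sum(sp$test), 13)
  expect_true(all(is.na(sp$fold[sp$test])))
  sizes <- table(sp$fold)
  expect_lte(diff(range(sizes)), 1)
  expect_identical(sp, make_split(chrom, "chr4", folds = 5, seed = 2))
  expect_error(make_split(chrom, "chr9"), "no rows")
  expect_error(make_split(rep("chr1", 5), "chr1"), "training set is empty")
})

test_that("SMOTE balances classes inside the minority geometry", {
  set.seed(3)
  X <- cbind(cont = rnorm(60), bin = rbinom(60, 1, 0.4))
  y <- c(rep(1, 10), rep(0, 50))
  out <- smote_oversample(X, y, k_neighbors = 5, seed = 4,
                          binary_cols = "bin")
  expect_equal(sum(out$y == 1), sum(out$y == 0))
  expect_equal(out$n_synthetic, 40)
  synth <- out$X[61:100, ]
  rng <- range(X[y == 1, "cont"])
  expect_true(all(synth[, "cont"] >= rng[1] & synth[, "cont"] <= rng[2]))
  expect_true(all(synth[, "bin"] %in% c(0, 1)))

  # k = 1 with two minority points: synthetics lie on the segment
  X2 <- cbind(a = c(0, 1, rnorm(20, 10)), b = c(0, 2, rnorm(20, 10)))
  y2 <- c(1, 1, rep(0, 20))
  o2 <- smote_oversample(X2, y2, k_neighbors = 1, seed = 1)
  s2 <- o2$X[-(1:22), ]
  # collinearity: b = 2a on the segment from (0,0) to (1,2)
  expect_lt(max(abs(s2[, "b"] - 2 * s2[, "a"])), 1e-12)
  expect_error(smote_oversample(X, y, k_neighbors = 10), "k_neighbors")
  expect_error(smote_oversample(X2[1:21, ], c(1, rep(0, 20)), 1), "minority")
})

test_that("logistic model follows the stated probability form", {
  # all coefficients zero -> P = 0.5; intercept ln 3 -> P = 0.75
  m0 <- structure(list(intercept = 0,
                       coefficients = c(f1 = 0, f2 = 0),
                       feature_names = c("f1", "f2")),
                  class = "logistic_model")
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(predict_logistic(m0, X), rep(0.5, 5))
  m1 <- m0; m1$intercept <- log(3)
  expect_equal(predict_logistic(m1, X), rep(0.75, 5))

  # affine rescaling of a feature with a matching coefficient rescale
  # leaves predictions unchanged
  mf <- structure(list(intercept = 0.3,
                       coefficients = c(f1 = 1.2, f2 = -0.7),
                       feature_names = c("f1", "f2")),
                  class = "logistic_model")
  p1 <- predict_logistic(mf, X)
  Xs <- X; Xs[, "f1"] <- X[, "f1"] * 10
  ms <- mf; ms$coefficients["f1"] <- mf$coefficients["f1"] / 10
  expect_equal(predict_logistic(ms, Xs), p1)

  expect_error(train_logistic(X, rep(1, 5)), "single class")
  expect_error(predict_logistic(mf, matrix(0, 2, 2)), "feature names")
})

test_that("classifier evaluation equals the rank-statistic identity", {
  prob <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.1)
  y <- c(1, 1, 0, 1, 0, 0)
  ev <- evaluate_classifier(prob, y)
  # brute-force pair counting with half credit for ties
  pos <- prob[y == 1]; neg <- prob[y == 0]
  auc_brute <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(ev$auroc, auc_brute)
  expect_equal(evaluate_classifier(c(1, 1, 0, 0), c(1, 1, 0, 0))$auroc, 1)
  expect_equal(evaluate_classifier(rep(0.4, 6), y)$auroc, 0.5)
  expect_true(is.na(evaluate_classifier(prob, rep(1, 6))$auroc))
})

test_that("importance ranks planted informative features first", {
  fm <- simulate_feature_matrix(n_sites = 1500, n_features = 50,
                                n_informative = 10, effect_size = 2,
                                minority_fraction = 0.1, seed = 2)
  m <- train_logistic(fm$X, fm$y_class, penalty = "none")
  imp <- feature_importance(m)
  expect_equal(imp$rank, seq_len(nrow(imp)))
  top10 <- imp$feature[1:10]
  expect_gte(sum(top10 %in% colnames(fm$X)[fm$informative_idx]), 8)
})

test_that("elastic net satisfies optimality and the OLS limit", {
  fm <- simulate_feature_matrix(n_sites = 600, n_features = 40,
                                k_nonzero = 4, snr = 3, seed = 3)
  en <- elastic_net_select(fm$X, fm$y_linear, alpha = 0.5, seed = 3)
  expect_lt(en$kkt_residual, 1e-8)
  truenz <- colnames(fm$X)[fm$beta != 0]
  expect_true(all(truenz %in% en$survivors))
  # univariate follow-up defined exactly on the survivors
  expect_equal(en$univariate$feature, en$survivors)
  # univariate slope equals lm() on each survivor
  f <- en$survivors[1]
  expect_equal(en$univariate$b[1],
               unname(stats::coef(stats::lm(fm$y_linear ~ fm$X[, f]))[2]))

  # lambda = 0 reduces to ordinary least squares
  en0 <- elastic_net_select(fm$X[, 1:10], fm$y_linear, lambda = 0)
  ols <- stats::coef(stats::lm(fm$y_linear ~ fm$X[, 1:10]))
  expect_lt(max(abs(c(en0$intercept, en0$beta) - unname(ols))), 1e-6)

  # huge lambda shrinks everything to zero
  expect_warning(
    enL <- elastic_net_select(fm$X, fm$y_linear, lambda = 1e4),
    "zero")
  expect_length(enL$survivors, 0)
})

test_that("cross-cell-type prediction enriches for experimental calls", {
  fm <- simulate_feature_matrix(n_sites = 1200, n_features = 30,
                                n_informative = 8, effect_size = 2,
                                minority_fraction = 0.15, seed = 4)
  half <- seq_len(600)
  shared <- colnames(fm$X)[1:25]
  out <- predict_cross(fm$X[half, ], fm$y_class[half],
                       fm$X[-half, ], shared,
                       experimental = fm$y_class[-half], seed = 4)
  expect_lt(out$overlap_test$p, 0.01)
  # label permutation kills the enrichment (median over a few permutations)
  set.seed(9)
  pperm <- replicate(15, {
    yp <- sample(fm$y_class[-half])
    k <- sum(out$predicted == 1 & yp == 1)
    hypergeom_overlap(k, sum(yp), sum(out$predicted == 1),
                      length(yp))$p
  })
  expect_gt(stats::median(pperm), 0.1)
  expect_error(predict_cross(fm$X[half, ], fm$y_class[half], fm$X[-half, ],
                             c("nope"), fm$y_class[-half]),
               "missing")
  expect_error(predict_cross(fm$X[half, ], fm$y_class[half], fm$X[-half, ],
                             character(0), fm$y_class[-half]), "empty")
})
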