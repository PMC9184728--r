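# Feature-matrix construction and the ML layer: k-means clustering, SMOTE
# over-sampling, logistic classification with chromosome-held-out splits,
# feature importance, elastic-net selection and cross-cell-type prediction.

#' Build a sites x features matrix
#'
#' Binary columns mark >= 1 bp co-localization of each interval dataset with
#' each site; continuous per-site signals are z-scored. The normalization
#' constants are recorded so a second cell type can be scored identically.
#'
#' @param sites Site table (rows of the matrix, in order).
#' @param binary_sets Named list of interval tables (one 0/1 column each).
#' @param continuous Named list of numeric per-site vectors (one z-scored
#'   column each); zero-variance columns are dropped with a warning.
#' @return List of class \code{feature_table}: \code{X} (matrix, rownames =
#'   site names), \code{chrom}, \code{binary_cols}, \code{scaling}
#'   (per-column mean/sd of the continuous features).
#' @export
build_feature_matrix <- function(sites, binary_sets = list(),
                                 continuous = list()) {
  gr <- sites_granges(sites)
  cols <- list()
  for (nm in names(binary_sets)) {
    cols[[nm]] <- as.numeric(suppressWarnings(IRanges::overlapsAny(
      gr, sites_granges(binary_sets[[nm]]), ignore.strand = TRUE)))
  }
  scaling <- list()
  for (nm in names(continuous)) {
    v <- continuous[[nm]]
    stopifnot(length(v) == nrow(sites))
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("dropping zero-variance continuous feature '", nm, "'")
      next
    }
    scaling[[nm]] <- c(mean = mean(v), sd = s)
    cols[[nm]] <- (v - mean(v)) / s
  }
  if (length(cols) == 0L) stop("no features supplied")
  X <- do.call(cbind, cols)
  rownames(X) <- sites$name
  structure(list(X = X, chrom = sites$chrom,
                 binary_cols = names(binary_sets), scaling = scaling),
            class = "feature_table")
}

#' k-means clustering of the feature matrix
#'
#' Deterministic given the seed; the best of \code{restarts} random starts
#' (by within-cluster sum of squares) is kept. Per-cluster feature means are
#' returned as the substrate of cluster heatmaps.
#'
#' @param X Numeric matrix (rows = sites).
#' @param k Number of clusters (default 10).
#' @param seed Integer seed.
#' @param restarts Random restarts (default 10).
#' @return List: \code{cluster} (assignment), \code{centers},
#'   \code{cluster_means} (k x features), \code{tot_withinss}.
#' @export
kmeans_cluster <- function(X, k = 10L, seed = 1L, restarts = 10L) {
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(X)) stop("k exceeds the number of rows")
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = restarts,
                                      iter.max = 50L))
  means <- km$centers
  rownames(means) <- paste0("cluster_", seq_len(k))
  list(cluster = km$cluster, centers = km$centers, cluster_means = means,
       tot_withinss = km$tot.withinss)
}

#' Chromosome-held-out split with CV folds
#'
#' All rows on the test chromosomes form the test set; the remaining rows
#' are assigned to \code{folds} cross-validation folds of near-equal size
#' (sizes differ by at most 1), deterministically given the seed.
#'
#' @param chrom Chromosome label per row.
#' @param test_chroms Chromosomes reserved for testing.
#' @param folds Number of CV folds on the remainder.
#' @param seed Integer seed.
#' @return List: \code{test} (logical per row), \code{fold} (integer per
#'   row, NA on test rows).
#' @export
make_split <- function(chrom, test_chroms, folds = 5L, seed = 1L) {
  test <- chrom %in% test_chroms
  if (!any(test)) stop("no rows on the requested test chromosomes")
  n_train <- sum(!test)
  if (n_train == 0L) stop("training set is empty: all rows on test chromosomes")
  fold <- rep(NA_integer_, length(chrom))
  fold[!test] <- with_seed(derive_seed(seed, "split"),
                           sample(rep_len(seq_len(folds), n_train)))
  list(test = test, fold = fold)
}

#' SMOTE over-sampling of the minority class
#'
#' Synthesizes minority rows by interpolating between each sampled minority
#' point and one of its \code{k_neighbors} nearest minority neighbours
#' (Euclidean): \code{x_new = x_i + u (x_nn - x_i)}, \code{u ~ U(0,1)}.
#' Classes are balanced to exactly equal counts; binary columns of synthetic
#' rows are rounded to \{0,1\}.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param k_neighbors Neighbourhood size (must be < minority count).
#' @param seed Integer seed.
#' @param binary_cols Names or indices of binary columns to round.
#' @return List: \code{X}, \code{y} (augmented), \code{n_synthetic}.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L,
                             binary_cols = NULL) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  minority <- if (n1 <= n0) 1 else 0
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min < 2L) stop("minority class needs at least 2 members")
  if (k_neighbors >= n_min) stop("k_neighbors must be < minority count")
  need <- n_maj - n_min
  if (need == 0L) return(list(X = X, y = y, n_synthetic = 0L))
  Xm <- X[y == minority, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn_idx <- matrix(apply(D, 1, function(d) order(d)[seq_len(k_neighbors)]),
                   ncol = k_neighbors, byrow = TRUE)
  synth <- with_seed(derive_seed(seed, "smote"), {
    i <- sample(nrow(Xm), need, replace = TRUE)
    j <- nn_idx[cbind(i, sample(k_neighbors, need, replace = TRUE))]
    u <- stats::runif(need)
    Xm[i, , drop = FALSE] + u * (Xm[j, , drop = FALSE] - Xm[i, , drop = FALSE])
  })
  if (!is.null(binary_cols)) {
    synth[, binary_cols] <- round(synth[, binary_cols])
  }
  rownames(synth) <- sprintf("synthetic_%05d", seq_len(need))
  list(X = rbind(X, synth), y = c(y, rep(minority, need)),
       n_synthetic = need)
}

#' Train a logistic classifier
#'
#' Fits P(Y=1|X) = 1/(1+exp(-(b0 + sum_j b_j X_j))), unpenalized via
#' \code{glm} or L1/L2-penalized via \code{glmnet} (lambda by CV when not
#' given).
#'
#' @param X Feature matrix (no missing values).
#' @param y 0/1 labels, both classes present.
#' @param penalty \code{"none"} (default), \code{"l1"} or \code{"l2"}.
#' @param lambda Penalty strength; NULL selects by 5-fold CV.
#' @param seed Seed for the CV fold assignment.
#' @return List of class \code{logistic_model}: \code{intercept},
#'   \code{coefficients} (named), \code{penalty}, \code{lambda},
#'   \code{feature_names}.
#' @export
train_logistic <- function(X, y, penalty = c("none", "l1", "l2"),
                           lambda = NULL, seed = 1L) {
  penalty <- match.arg(penalty)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (penalty == "none") {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                           family = stats::binomial()))
    b <- fit$coefficients
    intercept <- b[1]; coefs <- b[-1]
  } else {
    alpha <- if (penalty == "l1") 1 else 0
    if (is.null(lambda)) {
      cv <- with_seed(seed, glmnet::cv.glmnet(X, y, family = "binomial",
                                              alpha = alpha, nfolds = 5L))
      lambda <- cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                            lambda = lambda)
    }
    cf <- as.matrix(stats::coef(fit, s = lambda))
    intercept <- cf[1, 1]; coefs <- cf[-1, 1]
  }
  names(coefs) <- colnames(X)
  structure(list(intercept = unname(intercept), coefficients = coefs,
                 penalty = penalty, lambda = lambda,
                 feature_names = colnames(X)),
            class = "logistic_model")
}

#' Predict class-1 probabilities from a logistic model
#'
#' @param model A \code{logistic_model}.
#' @param X Feature matrix with the model's feature columns (matched by
#'   name; a mismatch is an error, never silently subset).
#' @return Probabilities in (0, 1).
#' @export
predict_logistic <- function(model, X) {
  if (is.null(colnames(X)) ||
      !identical(sort(colnames(X)), sort(model$feature_names))) {
    stop("feature names of X do not match the model")
  }
  X <- X[, model$feature_names, drop = FALSE]
  eta <- model$intercept + as.vector(X %*% model$coefficients)
  1 / (1 + exp(-eta))
}

#' Evaluate a binary classifier
#'
#' AUROC via the rank statistic (ties averaged; the Mann-Whitney identity
#' U/(n1 n0)), average precision, and the confusion matrix at threshold 0.5.
#'
#' @param prob Predicted class-1 probabilities.
#' @param y True 0/1 labels.
#' @return List: \code{auroc} (NA if one class), \code{average_precision},
#'   \code{confusion} (2x2 table at 0.5).
#' @export
evaluate_classifier <- function(prob, y) {
  stopifnot(length(prob) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auroc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(prob)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  ap <- if (n1 == 0) NA_real_ else {
    ord <- order(prob, decreasing = TRUE)
    ys <- y[ord]
    prec <- cumsum(ys) / seq_along(ys)
    mean(prec[ys == 1])
  }
  pred <- factor(as.integer(prob > 0.5), levels = c(0, 1))
  confusion <- table(predicted = pred, truth = factor(y, levels = c(0, 1)))
  list(auroc = auroc, average_precision = ap, confusion = confusion)
}

#' Signed feature importance of a trained model
#'
#' With features standardized (or binary) at build time, coefficients are
#' comparable across features; importance is the signed coefficient ranked
#' by magnitude.
#'
#' @param model A \code{logistic_model} (or any list with
#'   \code{coefficients}).
#' @return \code{data.frame(feature, coefficient, importance, rank)} sorted
#'   by decreasing |coefficient|.
#' @export
feature_importance <- function(model) {
  cf <- model$coefficients
  out <- data.frame(feature = names(cf), coefficient = unname(cf),
                    importance = abs(unname(cf)), stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# elastic-net subgradient residual of (RSS/(2n) + lambda*((1-a)/2 b^2 + a|b|))
enet_kkt_residual <- function(X, y, b0, beta, lambda, alpha) {
  n <- nrow(X)
  r <- y - b0 - as.vector(X %*% beta)
  g <- -as.vector(crossprod(X, r)) / n + lambda * (1 - alpha) * beta
  viol <- ifelse(beta != 0,
                 abs(g + lambda * alpha * sign(beta)),
                 pmax(abs(g) - lambda * alpha, 0))
  max(c(viol, abs(mean(r))))
}

# cycle coordinate descent until the KKT residual drops below tol
enet_polish <- function(X, y, b0, beta, lambda, alpha, tol = 1e-9,
                        max_sweeps = 2000L) {
  n <- nrow(X)
  xs <- colSums(X^2) / n
  r <- y - b0 - as.vector(X %*% beta)
  for (s in seq_len(max_sweeps)) {
    b0_new <- b0 + mean(r)
    r <- r - (b0_new - b0)
    b0 <- b0_new
    for (j in seq_len(ncol(X))) {
      z <- sum(X[, j] * r) / n + xs[j] * beta[j]
      bj <- sign(z) * max(abs(z) - lambda * alpha, 0) /
        (xs[j] + lambda * (1 - alpha))
      if (bj != beta[j]) {
        r <- r - X[, j] * (bj - beta[j])
        beta[j] <- bj
      }
    }
    if (enet_kkt_residual(X, y, b0, beta, lambda, alpha) < tol) break
  }
  list(b0 = b0, beta = beta)
}

#' Elastic-net feature selection with univariate follow-up
#'
#' Minimizes RSS/(2n) + lambda ((1-alpha)/2 sum b^2 + alpha sum |b|) over a
#' lambda grid, picking lambda by cross-validation — by default the largest
#' lambda within one standard error of the minimum CV error (the standard
#' parsimony convention for selection; \code{lambda_choice = "min"} takes
#' the CV-error minimizer instead). Survivors are the features with nonzero
#' coefficients. The returned solution is
#' polished by coordinate descent until the subgradient optimality residual
#' is below \code{tol}. For each survivor an ordinary least-squares
#' univariate fit Y = a + bX is reported.
#'
#' @param X Feature matrix (continuous columns already standardized).
#' @param y Continuous response (e.g. the normalized M value).
#' @param alpha L1/L2 mix in [0,1] (default 0.5).
#' @param lambda Optional fixed lambda (skips CV); \code{lambda = 0} gives
#'   the ordinary least-squares solution.
#' @param nfolds CV folds for the lambda search.
#' @param lambda_choice \code{"1se"} (default) or \code{"min"}.
#' @param seed Seed for CV fold assignment.
#' @param tol Subgradient optimality tolerance of the polished solution.
#' @return List of class \code{enet_model}: \code{intercept}, \code{beta},
#'   \code{lambda}, \code{alpha}, \code{survivors} (feature names),
#'   \code{kkt_residual}, \code{univariate}
#'   (\code{data.frame(feature, a, b)}).
#' @export
elastic_net_select <- function(X, y, alpha = 0.5, lambda = NULL, nfolds = 5L,
                               lambda_choice = c("1se", "min"),
                               seed = 1L, tol = 1e-8) {
  lambda_choice <- match.arg(lambda_choice)
  stopifnot(alpha >= 0, alpha <= 1, all(is.finite(y)), nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(lambda)) {
    cv <- with_seed(seed, glmnet::cv.glmnet(X, y, alpha = alpha,
                                            nfolds = nfolds,
                                            standardize = FALSE))
    lambda <- if (lambda_choice == "1se") cv$lambda.1se else cv$lambda.min
    cf <- as.matrix(stats::coef(cv, s = lambda))
  } else if (lambda > 0) {
    fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                          standardize = FALSE, thresh = 1e-12)
    cf <- as.matrix(stats::coef(fit, s = lambda))
  } else {
    cf <- matrix(0, ncol(X) + 1L, 1L)  # polish from zero: plain least squares
  }
  pol <- enet_polish(X, y, cf[1, 1], cf[-1, 1], lambda, alpha, tol = tol)
  beta <- stats::setNames(pol$beta, colnames(X))
  survivors <- names(beta)[beta != 0]
  if (length(survivors) == 0L) {
    warning("elastic net shrank every coefficient to zero")
  }
  uni <- do.call(rbind, lapply(survivors, function(f) {
    co <- stats::coef(stats::lm(y ~ X[, f]))
    data.frame(feature = f, a = unname(co[1]), b = unname(co[2]),
               stringsAsFactors = FALSE)
  }))
  structure(list(intercept = pol$b0, beta = beta, lambda = lambda,
                 alpha = alpha, survivors = survivors,
                 kkt_residual = enet_kkt_residual(X, y, pol$b0, pol$beta,
                                                  lambda, alpha),
                 univariate = uni),
            class = "enet_model")
}

#' Cross-cell-type DIC prediction
#'
#' Refits an L1-penalized logistic model on the shared-feature subset of
#' cell type 1, predicts DIC labels for cell type 2, and tests the overlap
#' of predicted and experimental calls with an upper-tail hypergeometric
#' test. Feature names must match exactly in both tables.
#'
#' @param X1,y1 Training features and 0/1 labels (cell type 1).
#' @param X2 Features of cell type 2 (same shared columns, identically
#'   normalized).
#' @param shared_features Feature names available in both cell types.
#' @param experimental 0/1 experimental DIC calls for the rows of X2.
#' @param threshold Probability cutoff for a predicted DIC (default 0.5).
#' @param seed Seed for the penalized fit's CV.
#' @return List: \code{model}, \code{prob}, \code{predicted} (0/1),
#'   \code{overlap_test} (hypergeometric \code{StatResult}).
#' @export
predict_cross <- function(X1, y1, X2, shared_features, experimental,
                          threshold = 0.5, seed = 1L) {
  if (length(shared_features) == 0L) stop("shared feature set is empty")
  if (!all(shared_features %in% colnames(X1)) ||
      !all(shared_features %in% colnames(X2))) {
    stop("shared features missing from one of the tables")
  }
  model <- train_logistic(X1[, shared_features, drop = FALSE], y1,
                          penalty = "l1", seed = seed)
  prob <- predict_logistic(model, X2[, shared_features, drop = FALSE])
  predicted <- as.integer(prob > threshold)
  k <- sum(predicted == 1 & experimental == 1)
  test <- hypergeom_overlap(k, K = sum(experimental == 1),
                            n = sum(predicted == 1), N = length(predicted))
  list(model = model, prob = prob, predicted = predicted,
       overlap_test = test)
}
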