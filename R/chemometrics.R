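# Multivariate discrimination: PCA for overview, from-scratch NIPALS
# PLS1-DA, 10-fold Venetian-blind cross-validation with repeats, Q2/RMSCV,
# and variable-importance-in-projection feature ranking.

#' Principal component analysis by singular value decomposition
#'
#' @param X numeric matrix (samples x features); centred internally, the
#'   centring vector is stored.
#' @param k number of components (default `min(dim) - 1` capped at 10).
#' @return object of class `pca_model` with `scores` (samples x k),
#'   `loadings` (features x k, orthonormal, sign-fixed so each loading's
#'   largest-magnitude entry is positive) and
#'   `explained_variance_fraction`.
#' @export
fit_pca <- function(X, k = min(10L, min(dim(X)) - 1L)) {
  gm_assert(is.matrix(X) && is.numeric(X), "X must be a numeric matrix")
  gm_assert(is_count(k) && k >= 1 && k <= min(dim(X)),
            "k must be a positive integer <= min(dim(X))")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = k, nv = k)
  # sign convention: largest-|entry| of each loading positive
  for (j in seq_len(k)) {
    s <- sign(sv$v[which.max(abs(sv$v[, j])), j])
    if (s < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  d <- sv$d[seq_len(k)]
  structure(list(scores = sweep(sv$u, 2, d, `*`),
                 loadings = sv$v,
                 explained_variance_fraction = d^2 / sum(sv$d^2),
                 center = ctr),
            class = "pca_model")
}

coerce_class_labels <- function(y) {
  if (is.factor(y)) {
    gm_assert(nlevels(droplevels(y)) == 2, "y must have exactly two classes")
    y <- as.integer(y == levels(droplevels(y))[2])
  }
  y <- as.numeric(y)
  gm_assert(all(y %in% c(0, 1)), "y must be 0/1-codable class labels")
  gm_assert(length(unique(y)) == 2,
            "both classes must be present in y")
  y
}

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' NIPALS partial least squares on column-centred `X` against the
#' 0/1-coded class vector, with successive deflation of `X`; weight
#' vectors are unit-norm. Class coding: 0 = normoalbuminuric,
#' 1 = microalbuminuric (decision threshold 0.5).
#'
#' @param X numeric matrix, samples x features.
#' @param y two-class labels (0/1, logical, or 2-level factor).
#' @param k number of latent components (1 <= k <= rank(X)).
#' @return object of class `plsda_model` with `x_weights`, `x_loadings`,
#'   `y_loadings`, `scores`, `coefficients`, centring vectors and `k`.
#' @export
fit_plsda <- function(X, y, k = 2L) {
  gm_assert(is.matrix(X) && is.numeric(X), "X must be a numeric matrix")
  y <- coerce_class_labels(y)
  gm_assert(length(y) == nrow(X), "X rows and y length must match")
  gm_assert(is_count(k) && k >= 1, "k must be a positive integer")
  gm_assert(k <= min(dim(X)), "k exceeds the dimensions of X")
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_center
  p <- ncol(X)
  W <- P <- matrix(0, p, k)
  Tt <- matrix(0, nrow(X), k)
  q <- numeric(k)
  for (a in seq_len(k)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      gm_stop(sprintf("k = %d exceeds the predictive rank of X", k))
    }
    w <- w / nw
    tt <- drop(E %*% w)
    tsq <- sum(tt^2)
    pp <- drop(crossprod(E, tt)) / tsq
    qq <- sum(f * tt) / tsq
    E <- E - tcrossprod(tt, pp)
    W[, a] <- w; P[, a] <- pp; Tt[, a] <- tt; q[a] <- qq
  }
  B <- W %*% solve(crossprod(P, W), q)
  structure(list(k = k, x_weights = W, x_loadings = P, y_loadings = q,
                 scores = Tt, coefficients = drop(B),
                 x_center = x_center, y_center = y_center,
                 class_coding = c(normo = 0, malb = 1)),
            class = "plsda_model")
}

#' Predict continuous class scores from a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return numeric vector of predicted class scores (threshold at 0.5 for
#'   a hard call).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  gm_assert(ncol(newdata) == length(object$x_center),
            "newdata has the wrong number of features")
  drop(sweep(newdata, 2, object$x_center) %*% object$coefficients) +
    object$y_center
}

#' Cross-validation plan
#'
#' Venetian-blind assignment: sample `i` goes to fold
#' `((i - 1 + rotation) mod n_folds) + 1`; each repeat uses a different
#' seeded rotation so the repeats are non-identical but keep the blind
#' structure. Folds partition the samples and differ in size by at most 1.
#'
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats of the whole process (default 10).
#' @return object of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10L, n_repeats = 10L) {
  gm_assert(is_count(n_folds) && n_folds >= 2, "n_folds must be >= 2")
  gm_assert(is_count(n_repeats) && n_repeats >= 1, "n_repeats must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 scheme = "venetian_blind"),
            class = "cv_plan")
}

#' Cross-validate a PLS-DA model
#'
#' For each repeat, every fold is predicted from a model fitted on the
#' remaining samples. `q2` is the averaged Pearson correlation between the
#' labels and the out-of-fold predictions across repeats (the convention
#' used in the chemometric literature for R2CV); `q2_press`
#' (1 - PRESS/TSS) is also reported for comparability. `rmscv` is the root
#' mean squared out-of-fold error averaged across repeats.
#'
#' @param X samples x features matrix.
#' @param y two-class labels.
#' @param plan a [cv_plan()].
#' @param k latent components.
#' @param seed seed for the per-repeat fold rotations.
#' @return list with `q2`, `q2_press`, `rmscv`, `k`, and a `per_repeat`
#'   data.frame.
#' @export
cross_validate <- function(X, y, plan = cv_plan(), k = 2L, seed = 1) {
  y <- coerce_class_labels(y)
  n <- nrow(X)
  gm_assert(n >= plan$n_folds,
            sprintf("need at least %d samples for %d folds (have %d)",
                    plan$n_folds, plan$n_folds, n))
  rotations <- with_seed(seed, {
    sample(0:(plan$n_folds - 1L), plan$n_repeats,
           replace = plan$n_repeats > plan$n_folds)
  })
  per <- lapply(seq_len(plan$n_repeats), function(r) {
    fold <- ((seq_len(n) - 1L + rotations[r]) %% plan$n_folds) + 1L
    yhat <- numeric(n)
    for (fd in seq_len(plan$n_folds)) {
      tr <- fold != fd
      gm_assert(length(unique(y[tr])) == 2,
                "a training split contains a single class")
      m <- fit_plsda(X[tr, , drop = FALSE], y[tr], k)
      yhat[!tr] <- predict(m, X[!tr, , drop = FALSE])
    }
    c(q2 = stats::cor(y, yhat),
      q2_press = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
      rmscv = sqrt(mean((y - yhat)^2)))
  })
  per <- as.data.frame(do.call(rbind, per))
  per$repeat_id <- seq_len(nrow(per))
  list(q2 = mean(per$q2), q2_press = mean(per$q2_press),
       rmscv = mean(per$rmscv), k = k, per_repeat = per)
}

#' Choose the number of PLS components by cross-validated Q2
#'
#' @param X,y,plan,seed as in [cross_validate()].
#' @param k_max largest component count tried (default 5).
#' @return list with the chosen `k` and the per-k Q2 values.
#' @export
select_ncomp <- function(X, y, plan = cv_plan(), k_max = 5L, seed = 1) {
  ks <- seq_len(min(k_max, min(dim(X)) - 1L))
  q2s <- vapply(ks, function(k) {
    cross_validate(X, y, plan, k, seed)$q2
  }, 0)
  list(k = ks[which.max(q2s)], q2_by_k = stats::setNames(q2s, ks))
}

#' Rank features by variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a ssy_a * w_ja^2 / sum_a ssy_a)` with
#' `ssy_a = q_a^2 * t_a't_a` the y-variance explained by component `a`.
#' The mean squared VIP over features is 1 by construction.
#'
#' @param model a `plsda_model`.
#' @return data.frame ordered by decreasing VIP with columns `feature`,
#'   `rank`, `vip`.
#' @export
rank_features <- function(model) {
  gm_assert(inherits(model, "plsda_model"), "model must be a plsda_model")
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  p <- nrow(model$x_weights)
  vip <- sqrt(p * drop(model$x_weights^2 %*% ssy) / sum(ssy))
  feats <- rownames(model$x_weights)
  if (is.null(feats)) feats <- names(model$x_center)
  if (is.null(feats)) feats <- sprintf("V%d", seq_len(p))
  out <- data.frame(feature = feats, vip = vip)
  out <- out[order(-out$vip), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("feature", "rank", "vip")]
}
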