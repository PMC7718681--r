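#' One backward-elimination run on a random subsample
#'
#' Draws a fraction of the rows at random (stratified by `group` when given,
#' so both classes appear in every run), fits a linear model of the response
#' on all current features, and repeatedly removes the feature with the
#' largest partial p-value above `alpha` until every remaining feature is
#' significant at `alpha`. The partial p-value is the nested-model F-test of
#' dropping one feature (equivalently the coefficient t-test). If the
#' subsample has fewer rows than features, a marginal-correlation prefilter
#' reduces the candidate set to `rows - 2` features first. A singular design
#' triggers a ridge-stabilised refit for the p-values (logged via message).
#'
#' @param X numeric matrix, subjects x features (named columns).
#' @param y numeric response (e.g. upper-limb SARA sum).
#' @param alpha elimination threshold (default 0.05).
#' @param group optional factor for stratified subsampling.
#' @param subsampleFraction fraction of rows drawn (default 0.9).
#' @return Character vector of surviving feature names (possibly empty);
#'   attribute `"partialF"` holds the survivors' partial F statistics.
#' @export
fbeOnce <- function(X, y, alpha = 0.05, group = NULL,
                    subsampleFraction = 0.9) {
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (!is.null(group)) group <- group[keep]
  n <- nrow(X)
  idx <- if (is.null(group)) {
    sample(n, max(2L, round(subsampleFraction * n)))
  } else {
    unlist(lapply(split(seq_len(n), group), function(ii)
      sample(ii, max(1L, round(subsampleFraction * length(ii))))))
  }
  Xs <- X[idx, , drop = FALSE]; ys <- y[idx]
  feats <- colnames(Xs)[apply(Xs, 2, stats::sd) > 0]
  maxp <- nrow(Xs) - 2L
  if (length(feats) > maxp) {
    sc <- abs(apply(Xs[, feats, drop = FALSE], 2,
                    function(v) suppressWarnings(stats::cor(v, ys))))
    sc[is.na(sc)] <- 0
    feats <- feats[order(-sc)][seq_len(maxp)]
  }
  repeat {
    if (!length(feats)) break
    pv <- .partial_stats(Xs[, feats, drop = FALSE], ys)
    worst <- which.max(pv$p)
    if (pv$p[worst] > alpha) {
      feats <- feats[-worst]
    } else break
  }
  out <- feats
  attr(out, "partialF") <- if (length(feats)) {
    st <- .partial_stats(Xs[, feats, drop = FALSE], ys)
    stats::setNames(st$t^2, feats)
  } else stats::setNames(numeric(0), character(0))
  out
}

# Coefficient t statistics and p-values; falls back to a ridge-stabilised
# solve when the design is singular.
.partial_stats <- function(Xs, ys) {
  df <- data.frame(..y = ys, Xs, check.names = FALSE)
  fit <- stats::lm(..y ~ ., data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    message("singular design: ridge-stabilised refit")
    Xc <- cbind(1, as.matrix(Xs))
    p <- ncol(Xc); n <- nrow(Xc)
    XtX <- crossprod(Xc)
    lam <- 1e-8 * mean(diag(XtX))
    A <- XtX + diag(lam, p)
    Ai <- solve(A)
    beta <- Ai %*% crossprod(Xc, ys)
    res <- ys - Xc %*% beta
    dof <- max(1, n - sum(diag(Xc %*% Ai %*% t(Xc))))
    s2 <- sum(res^2) / dof
    covb <- s2 * Ai   # ridge covariance: unidentifiable directions blow up
    tval <- (beta / sqrt(pmax(diag(covb), .Machine$double.eps)))[-1]
    pv <- 2 * stats::pt(-abs(tval), dof)
    return(list(p = as.numeric(pv), t = as.numeric(tval)))
  }
  sm <- summary(fit)$coefficients
  rows <- rownames(sm) != "(Intercept)"
  list(p = sm[rows, "Pr(>|t|)"], t = sm[rows, "t value"])
}

#' Selection frequency over repeated backward-elimination runs
#'
#' Repeats [fbeOnce] `nIter` times on fresh 90% subsamples and reports, per
#' feature, the fraction of runs in which it survived -- the selection
#' frequency used to rank features for the downstream models. Deterministic
#' given `seed`.
#'
#' @inheritParams fbeOnce
#' @param nIter number of runs (default 100).
#' @param seed RNG seed (default 1).
#' @return A [SelectionReport-class] including the FBE ranking (frequency
#'   descending, ties broken by mean partial F, then name).
#' @export
selectionFrequency <- function(X, y, nIter = 100, alpha = 0.05,
                               group = NULL, subsampleFraction = 0.9,
                               seed = 1) {
  set.seed(seed)
  feats <- colnames(X)
  count <- stats::setNames(numeric(length(feats)), feats)
  fsum <- count; fn <- count
  for (i in seq_len(nIter)) {
    surv <- fbeOnce(X, y, alpha = alpha, group = group,
                    subsampleFraction = subsampleFraction)
    count[surv] <- count[surv] + 1
    pf <- attr(surv, "partialF")
    fsum[names(pf)] <- fsum[names(pf)] + pf
    fn[names(pf)] <- fn[names(pf)] + 1
  }
  freq <- count / nIter
  mpf <- ifelse(fn > 0, fsum / pmax(fn, 1), 0)
  ord <- order(-freq, -mpf, feats)
  new("SelectionReport", frequency = freq, meanPartialF = mpf,
      alpha = alpha, nIter = nIter, subsampleFraction = subsampleFraction,
      rankings = list(FBE = feats[ord]))
}

#' @describeIn selectionFrequency Accessor for the per-feature frequencies.
#' @param report a [SelectionReport-class].
#' @export
selectionFrequencies <- function(report) report@frequency

.relieff <- function(X, labels, k = 10) {
  labels <- as.factor(labels)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  D <- as.matrix(stats::dist(Xn))
  W <- stats::setNames(numeric(p), colnames(X))
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    diffc <- which(labels != labels[i])
    kh <- same[order(D[i, same])][seq_len(min(k, length(same)))]
    km <- diffc[order(D[i, diffc])][seq_len(min(k, length(diffc)))]
    if (!length(kh) || !length(km)) next
    hits <- colMeans(abs(Xn[kh, , drop = FALSE] -
                         matrix(Xn[i, ], length(kh), p, byrow = TRUE)))
    miss <- colMeans(abs(Xn[km, , drop = FALSE] -
                         matrix(Xn[i, ], length(km), p, byrow = TRUE)))
    W <- W + (miss - hits) / n
  }
  W
}

#' Rank features by one of four methods
#'
#' \itemize{
#'   \item `"FBE"`: selection frequency over resampled backward elimination
#'     (requires `y`; uses `report` when supplied).
#'   \item `"RF"`: random-forest permutation importance (mean decrease in
#'     accuracy) on the class labels.
#'   \item `"RELIEF"`: ReliefF weights (k nearest hits/misses on min-max
#'     scaled features).
#'   \item `"LASSO"`: order of coefficient activation along the glmnet
#'     regularisation path of a binomial lasso (earlier activation ranks
#'     higher).
#' }
#'
#' @param method one of "FBE", "RF", "RELIEF", "LASSO".
#' @param X subjects x features matrix with column names.
#' @param y continuous response for FBE (upper-limb SARA sum).
#' @param labels class labels ("control"/"ataxic") for RF/RELIEF/LASSO.
#' @param report optional precomputed [SelectionReport-class] for FBE.
#' @param seed RNG seed for the stochastic methods.
#' @param ... passed on to [selectionFrequency] for FBE.
#' @return Character vector of feature names, best first.
#' @export
rankFeatures <- function(method, X, y = NULL, labels = NULL, report = NULL,
                         seed = 1, ...) {
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (!is.null(y)) y <- y[keep]
  if (!is.null(labels)) labels <- labels[keep]
  switch(method,
    FBE = {
      if (is.null(report)) {
        stopifnot(!is.null(y))
        report <- selectionFrequency(X, y, seed = seed, ...)
      }
      report@rankings$FBE
    },
    RF = {
      stopifnot(!is.null(labels))
      set.seed(seed)
      fit <- randomForest::randomForest(x = X, y = as.factor(labels),
                                        importance = TRUE)
      imp <- randomForest::importance(fit, type = 1)[, 1]
      names(imp)[order(-imp, names(imp))]
    },
    RELIEF = {
      stopifnot(!is.null(labels))
      W <- .relieff(X, labels)
      names(W)[order(-W, names(W))]
    },
    LASSO = {
      stopifnot(!is.null(labels))
      yy <- as.integer(as.factor(labels)) - 1L
      fit <- glmnet::glmnet(X, yy, family = "binomial", nlambda = 100)
      B <- as.matrix(fit$beta)
      firstAct <- apply(B, 1, function(r) {
        nz <- which(abs(r) > 0)
        if (length(nz)) nz[1] else ncol(B) + 1L
      })
      lastAbs <- abs(B[, ncol(B)])
      rownames(B)[order(firstAct, -lastAbs, rownames(B))]
    },
    stop("unknown ranking method: ", method))
}
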