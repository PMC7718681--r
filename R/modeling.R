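#' Classification metrics from a 2 x 2 confusion matrix
#'
#' Standard definitions with "ataxic" as the positive class: accuracy,
#' recall (sensitivity), precision, F1, and the Matthews correlation
#' coefficient via the 2 x 2 covariance formula
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (defined as 0 when
#' the denominator vanishes, with a message). When held-out scores and
#' labels are supplied, AUC is added as the rank statistic (ties get average
#' ranks).
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @param scores optional numeric held-out scores (larger = more positive).
#' @param labels optional logical/character vector, positive class "ataxic"
#'   or TRUE, aligned with `scores`.
#' @return Named numeric: acc, recall, precision, f1, mcc (and auc if
#'   scores were given), all as fractions.
#' @export
metricsFromConfusion <- function(TP, FP, TN, FN, scores = NULL,
                                 labels = NULL) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  acc <- (TP + TN) / (TP + FP + TN + FN)
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den == 0) { message("MCC denominator 0; reporting 0"); 0 }
         else (TP * TN - FP * FN) / den
  out <- c(acc = acc, recall = recall, precision = precision, f1 = f1,
           mcc = mcc)
  if (!is.null(scores)) {
    pos <- if (is.logical(labels)) labels else labels == "ataxic"
    out["auc"] <- .auc(scores, pos)
  }
  out
}

.auc <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Regularised quadratic discriminant: class-wise Gaussians with covariance
# shrinkage toward the diagonal so small folds with p close to n stay
# invertible.
.qdaFit <- function(X, labels, shrink = 1e-3) {
  classes <- sort(unique(labels))
  fit <- lapply(classes, function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    S <- stats::cov(Xi)
    S <- (1 - shrink) * S + shrink * diag(diag(S), ncol(X))
    diag(S) <- pmax(diag(S), 1e-12)
    ch <- tryCatch(chol(S), error = function(e)
      chol(S + diag(1e-6 * mean(diag(S)), ncol(S))))
    list(mu = colMeans(Xi), chol = ch,
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  names(fit) <- classes
  fit
}

.qdaLogLik <- function(fit, x) {
  vapply(fit, function(f) {
    z <- backsolve(f$chol, x - f$mu, transpose = TRUE)
    -0.5 * f$logdet - 0.5 * sum(z^2) + f$logprior
  }, numeric(1))
}

.fitPredict <- function(model, Xtr, ytr, xte, k = 5, shrink = 1e-3) {
  if (model == "QDA") {
    f <- .qdaFit(Xtr, ytr, shrink)
    ll <- .qdaLogLik(f, xte)
    score <- ll["ataxic"] - ll["control"]
    pred <- names(ll)[which.max(ll)]
  } else if (model == "LD") {
    f <- MASS::lda(Xtr, grouping = factor(ytr))
    pr <- stats::predict(f, matrix(xte, 1, dimnames = list(NULL, colnames(Xtr))))
    score <- pr$posterior[1, "ataxic"]
    pred <- as.character(pr$class)
  } else if (model == "SVM") {
    d <- stats::dist(Xtr)
    sigma <- stats::median(d[d > 0])
    f <- e1071::svm(Xtr, factor(ytr), kernel = "radial",
                    gamma = 1 / (2 * sigma^2), scale = FALSE)
    pr <- stats::predict(f, matrix(xte, 1), decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- if (grepl("^ataxic", colnames(dv)[1])) dv[1] else -dv[1]
    pred <- as.character(pr[1])
  } else if (model == "KNN") {
    pr <- class::knn(Xtr, matrix(xte, 1), cl = factor(ytr), k = k,
                     prob = TRUE)
    p <- attr(pr, "prob")
    pred <- as.character(pr)
    score <- if (pred == "ataxic") p else 1 - p
  } else stop("unknown model: ", model)
  list(pred = pred, score = unname(score))
}

.standardize <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       te = sweep(sweep(Xte, 2, mu, check.margin = FALSE), 2, sdv, "/"))
}

#' Leave-one-out classification of ataxic vs control
#'
#' For every subject in turn: standardise the features on the remaining
#' subjects only, fit the chosen classifier (regularised QDA, linear
#' discriminant, radial SVM with median-heuristic bandwidth, or k-nearest
#' neighbours), and predict the held-out subject. Metrics come from the
#' pooled confusion counts; AUC from the pooled held-out scores. Subjects
#' with any missing feature are excluded (logged via message).
#'
#' @param X subjects x features numeric matrix (row names = subject ids).
#' @param labels character vector, "control"/"ataxic".
#' @param model one of "QDA", "LD", "SVM", "KNN".
#' @param k neighbours for KNN.
#' @param shrink diagonal shrinkage weight for QDA covariances.
#' @return List with `confusion` (TP/FP/TN/FN), `metrics` (incl. auc),
#'   `scores`, `predicted`, `subjects` (ids used).
#' @export
looClassify <- function(X, labels, model = c("QDA", "LD", "SVM", "KNN"),
                        k = 5, shrink = 1e-3) {
  model <- match.arg(model)
  keep <- stats::complete.cases(X)
  if (any(!keep))
    message(sum(!keep), " subject(s) with missing features excluded")
  X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  stopifnot(sum(labels == "ataxic") >= 2, sum(labels == "control") >= 2)
  n <- nrow(X)
  preds <- character(n); scores <- numeric(n)
  for (i in seq_len(n)) {
    st <- .standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    r <- .fitPredict(model, st$tr, labels[-i], as.numeric(st$te),
                     k = k, shrink = shrink)
    preds[i] <- r$pred; scores[i] <- r$score
  }
  TP <- sum(preds == "ataxic" & labels == "ataxic")
  FP <- sum(preds == "ataxic" & labels == "control")
  TN <- sum(preds == "control" & labels == "control")
  FN <- sum(preds == "control" & labels == "ataxic")
  met <- metricsFromConfusion(TP, FP, TN, FN, scores = scores,
                              labels = labels)
  list(confusion = c(TP = TP, FP = FP, TN = TN, FN = FN), metrics = met,
       scores = stats::setNames(scores, rownames(X)),
       predicted = stats::setNames(preds, rownames(X)),
       subjects = rownames(X))
}

# Exact LOO mean squared error of ridge regression (unpenalised intercept
# handled by centring) via the hat-matrix identity.
.ridgeLooMse <- function(Xc, yc, lambda) {
  A <- crossprod(Xc) + diag(lambda, ncol(Xc))
  Ai <- solve(A)
  H <- Xc %*% Ai %*% t(Xc)
  h <- diag(H) + 1 / nrow(Xc)
  yhat <- H %*% yc
  e <- (yc - yhat) / pmax(1 - h, 1e-8)
  mean(e^2)
}

.ridgeFit <- function(X, y, lambda) {
  mu <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mu); yc <- y - my
  beta <- solve(crossprod(Xc) + diag(lambda, ncol(Xc)), crossprod(Xc, yc))
  list(beta = beta, mu = mu, my = my)
}

.ridgePredict <- function(fit, x) fit$my + sum((x - fit$mu) * fit$beta)

#' Leave-one-out ridge severity regression
#'
#' Predicts each subject's upper-limb SARA sum from the feature matrix with
#' ridge regression, the held-out subject never touching the fit: features
#' are standardised on the training fold, the ridge penalty is chosen by
#' exact inner leave-one-out over a log-spaced grid within each outer fold,
#' and the held-out prediction `ps` is recorded. Reports the Spearman
#' correlation between `ps` and the observed response.
#'
#' @param X subjects x features matrix.
#' @param y upper-limb SARA sum (0-15 scale).
#' @param lambdas penalty grid (default `10^(-3:3)`).
#' @return List with `ps` (named), `rho`, `subjects`.
#' @export
looSeverity <- function(X, y, lambdas = 10^(-3:3)) {
  keep <- stats::complete.cases(X, y)
  if (any(!keep))
    message(sum(!keep), " subject(s) with missing features excluded")
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (stats::sd(y) == 0) stop("zero-variance response")
  n <- nrow(X)
  ps <- numeric(n)
  for (i in seq_len(n)) {
    st <- .standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    ytr <- y[-i]
    Xc <- sweep(st$tr, 2, colMeans(st$tr))
    yc <- ytr - mean(ytr)
    mses <- vapply(lambdas, function(l) .ridgeLooMse(Xc, yc, l), numeric(1))
    lam <- lambdas[which.min(mses)]
    fit <- .ridgeFit(st$tr, ytr, lam)
    ps[i] <- .ridgePredict(fit, as.numeric(st$te))
  }
  rho <- spearmanValidity(ps, y)$rho
  list(ps = stats::setNames(ps, rownames(X)), rho = rho,
       subjects = rownames(X))
}

#' Bucket a predicted severity score into the 4-level scale
#'
#' `ps < 4` is level 0 (normal), `4 <= ps < 7` level 1 (mild),
#' `7 <= ps < 10` level 2 (moderate), `ps >= 10` level 3 (severe) -- the
#' instrumented counterpart of the rounded upper-limb SARA levels.
#'
#' @param ps numeric vector of predicted (or observed) severity scores on
#'   the 0-15 upper-limb SARA sum scale.
#' @return Integer vector of levels 0-3.
#' @export
bucketSeverity <- function(ps) {
  stopifnot(all(is.finite(ps)))
  findInterval(ps, c(4, 7, 10))
}

.agreementMatrix <- function(trueLevel, predLevel) {
  m <- table(factor(trueLevel, levels = 0:3),
             factor(predLevel, levels = 0:3))
  m <- unclass(m)
  dimnames(m) <- list(true = 0:3, predicted = 0:3)
  m
}

#' Full evaluation: diagnosis plus severity on selected features
#'
#' Restricts the feature table to the top `topk` features of a ranking
#' (computing the backward-elimination selection frequencies if no report is
#' given), then runs leave-one-out classification and leave-one-out ridge
#' severity regression, and assembles an [EvaluationReport-class] including
#' the 4-level agreement matrix (true level = bucketed observed SARA-UL
#' sum).
#'
#' @param ft an [AtaxiaFeatureTable-class].
#' @param topk number of top-ranked features to use (default 22).
#' @param model classifier (default "QDA").
#' @param report optional [SelectionReport-class]; computed when NULL.
#' @param nIter,alpha,seed selection parameters when `report` is NULL.
#' @param ... passed to [looClassify].
#' @return An [EvaluationReport-class].
#' @export
evaluateCohort <- function(ft, topk = 22, model = "QDA", report = NULL,
                           nIter = 100, alpha = 0.05, seed = 1, ...) {
  X <- featureMatrix(ft)
  sdat <- subjectData(ft)
  if (is.null(report))
    report <- selectionFrequency(X, sdat$sara_ul_sum, nIter = nIter,
                                 alpha = alpha, group = sdat$group,
                                 seed = seed)
  sel <- utils::head(report@rankings$FBE, topk)
  Xs <- X[, sel, drop = FALSE]
  cl <- looClassify(Xs, sdat$group, model = model, ...)
  sv <- looSeverity(Xs, sdat$sara_ul_sum)
  common <- intersect(cl$subjects, sv$subjects)
  ps <- sv$ps[common]
  lev <- bucketSeverity(ps)
  trueLev <- bucketSeverity(sdat[common, "sara_ul_sum"])
  new("EvaluationReport",
      confusion = cl$confusion, metrics = cl$metrics,
      scores = cl$scores, predictedClass = cl$predicted,
      ps = ps, level = as.numeric(lev), trueLevel = as.numeric(trueLev),
      rho = sv$rho, agreement = .agreementMatrix(trueLev, lev),
      model = model)
}

#' STAR-domain composition of a feature set
#'
#' @param ft an [AtaxiaFeatureTable-class].
#' @param features character vector of feature names.
#' @return Named numeric percentages over Stability/Timing/Accuracy/
#'   Rhythmicity, summing to 100.
#' @export
starComposition <- function(ft, features) {
  info <- featureInfo(ft)
  tags <- info$star[match(features, info$name)]
  tab <- table(factor(tags, levels = STAR))
  stats::setNames(100 * as.numeric(tab) / sum(tab), STAR)
}

#' Evaluate combinations of bedside tests
#'
#' Reruns selection, leave-one-out classification and severity regression on
#' the feature subsets of each test combination: G1 = FCT+FTT, G2 = FCT+FNT,
#' G3 = FCT+DDKT, G4 = FCT+FNT+DDKT, G5 = FCT+FTT+DDKT, G6 = FCT+FTT+FNT,
#' and all four tests.
#'
#' @param ft an [AtaxiaFeatureTable-class].
#' @param groups named list of test-name vectors; default G1-G6 plus "all".
#' @param topk features kept per group (capped at the group's catalog size).
#' @param model classifier (default "QDA").
#' @param nIter selection iterations per group.
#' @param seed RNG seed.
#' @return data.frame with one row per group: acc, auc, recall, precision,
#'   f1, mcc, rho, n_features.
#' @export
evaluateTestGroups <- function(ft, groups = NULL, topk = 22, model = "QDA",
                               nIter = 100, seed = 1) {
  if (is.null(groups))
    groups <- list(G1 = c("FCT", "FTT"), G2 = c("FCT", "FNT"),
                   G3 = c("FCT", "DDKT"), G4 = c("FCT", "FNT", "DDKT"),
                   G5 = c("FCT", "FTT", "DDKT"),
                   G6 = c("FCT", "FTT", "FNT"), all = TESTS)
  info <- featureInfo(ft)
  rows <- lapply(names(groups), function(g) {
    feats <- info$name[info$test %in% groups[[g]]]
    if (!length(feats)) stop("group '", g, "' has no features")
    sub <- ft[feats, ]
    rep_ <- evaluateCohort(new("AtaxiaFeatureTable", sub),
                           topk = min(topk, length(feats)),
                           model = model, nIter = nIter, seed = seed)
    data.frame(group = g, acc = rep_@metrics[["acc"]],
               auc = rep_@metrics[["auc"]],
               recall = rep_@metrics[["recall"]],
               precision = rep_@metrics[["precision"]],
               f1 = rep_@metrics[["f1"]], mcc = rep_@metrics[["mcc"]],
               rho = rep_@rho, n_features = length(feats),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
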