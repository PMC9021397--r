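# NIPALS PLS1 on pre-centered data. Lean on purpose: called thousands of
# times by loocv()/balanced_ensemble(). Returns weights W (unit columns),
# loadings P, score norms tt, y-loadings q, and the regression vector b.
pls_core <- function(Xc, yc, A) {
  p <- ncol(Xc)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  q <- numeric(A); tt <- numeric(A)
  Tm <- matrix(0, nrow(Xc), A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12)
      stopf("PLS deflation exhausted at component %d (rank deficiency)", a)
    w <- w / nw
    t <- Xc %*% w
    ss <- sum(t * t)
    if (ss < 1e-12)
      stopf("PLS deflation exhausted at component %d (zero scores)", a)
    pa <- crossprod(Xc, t) / ss
    qa <- sum(yc * t) / ss
    Xc <- Xc - tcrossprod(t, pa)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; tt[a] <- ss; Tm[, a] <- t
  }
  b <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, q = q, tt = tt, scores = Tm, b = b)
}

# Map a two-class label vector to the -1/+1 coding used throughout
# (+1 = positive class, default "deceased").
encode_classes <- function(y, positive = "deceased") {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(-1, 1)) || length(u) < 2)
      stopf("numeric y must contain both -1 and +1")
    return(list(code = as.numeric(y), classes = c("survivor", "deceased")))
  }
  y <- as.character(y)
  u <- unique(y)
  if (length(u) != 2)
    stopf("y must contain exactly 2 classes (got %d)", length(u))
  if (!positive %in% u)
    stopf("positive class '%s' absent from y", positive)
  neg <- setdiff(u, positive)
  list(code = ifelse(y == positive, 1, -1), classes = c(neg, positive))
}

#' Fit a PLS-DA model
#'
#' Partial least squares regression of a two-class code (-1/+1) on a
#' fingerprint matrix, by sequential NIPALS deflation. Data are
#' mean-centered only (no unit-variance scaling), preserving the intensity
#' weighting of the spectrum. Classification uses the sign of the predicted
#' score (threshold at the class-code midpoint, 0).
#'
#' @param X Samples x variables numeric matrix (or `binned_matrix`).
#' @param y Class labels: a two-level factor/character vector, or a -1/+1
#'   numeric code.
#' @param n_components Number of PLS components (default 7).
#' @param positive Label coded +1 (default `"deceased"`).
#' @return An object of class `pls_model` with elements `x_weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `score_ss` (per-component score
#'   sums of squares), `coefficient_vector`, `x_mean`, `y_mean`, `classes`,
#'   `n_components`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 10), 40)
#' y <- rep(c("survivor", "deceased"), each = 20)
#' X[y == "deceased", 1] <- X[y == "deceased", 1] + 3
#' fit <- fit_pls(X, y, n_components = 2)
#' table(predict(fit, X, type = "class"), y)
#' @export
fit_pls <- function(X, y, n_components = 7, positive = "deceased") {
  if (inherits(X, "binned_matrix")) X <- X$values
  X <- as.matrix(X)
  if (n_components < 1) stopf("n_components must be >= 1")
  enc <- encode_classes(y, positive)
  if (length(enc$code) != nrow(X))
    stopf("length(y) != nrow(X)")
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components > kmax)
    stopf("n_components (%d) exceeds the rank bound min(n - 1, p) = %d",
          n_components, kmax)
  x_mean <- colMeans(X)
  y_mean <- mean(enc$code)
  core <- pls_core(sweep(X, 2, x_mean), enc$code - y_mean, n_components)
  structure(list(n_components = n_components,
                 x_weights = core$W, x_loadings = core$P,
                 y_loadings = core$q, scores = core$scores,
                 score_ss = core$tt,
                 coefficient_vector = as.numeric(core$b),
                 x_mean = x_mean, y_mean = y_mean,
                 classes = enc$classes,
                 var_names = colnames(X)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d variables; classes %s (-1) vs %s (+1)\n",
              x$n_components, length(x$x_mean), x$classes[1], x$classes[2]))
  invisible(x)
}

#' @export
coef.pls_model <- function(object, ...) {
  stats::setNames(object$coefficient_vector,
                  object$var_names %||%
                    paste0("V", seq_along(object$coefficient_vector)))
}

#' Predict from a PLS-DA model
#'
#' Continuous score `(X - x_mean) %*% b + y_mean`; class label is the
#' positive class iff the score exceeds 0 (the -1/+1 midpoint).
#'
#' @param object A `pls_model`.
#' @param newdata Matrix (or `binned_matrix`) with the training columns.
#' @param type `"score"` (default), `"class"`, or `"both"`.
#' @param ... Unused.
#' @return Numeric scores, character labels, or a data frame of both.
#' @export
predict.pls_model <- function(object, newdata, type = c("score", "class", "both"),
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "binned_matrix")) newdata <- newdata$values
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  p <- length(object$x_mean)
  if (!is.matrix(newdata)) {
    if (length(newdata) != p)
      stopf("newdata has %d values; model expects %d columns",
            length(newdata), p)
    newdata <- matrix(newdata, 1)
  }
  if (ncol(newdata) != p)
    stopf("newdata has %d columns; model expects %d", ncol(newdata), p)
  storage.mode(newdata) <- "double"
  score <- as.numeric(sweep(newdata, 2, object$x_mean) %*%
                        object$coefficient_vector) + object$y_mean
  if (type == "score") return(score)
  cls <- ifelse(score > 0, object$classes[2], object$classes[1])
  if (type == "class") cls else data.frame(score = score, class = cls,
                                           stringsAsFactors = FALSE)
}

#' Variable importance in projection (VIP)
#'
#' For variable j over components a: `VIP_j = sqrt(p * sum_a SS_a w_ja^2 /
#' sum_a SS_a)` where `SS_a = q_a^2 * t_a't_a` is the response variance
#' captured by component a and the weight columns are unit-normalized. By
#' construction the mean squared VIP equals 1; variables with VIP > 1 are
#' conventionally deemed important.
#'
#' @param model A fitted `pls_model`.
#' @param threshold Selection cutoff (strict `>`), default 1.
#' @return Data frame: `variable`, `vip`, `selected`, sorted as the model's
#'   columns.
#' @export
vip_scores <- function(model, threshold = 1) {
  stopifnot(inherits(model, "pls_model"))
  ss <- model$y_loadings^2 * model$score_ss
  if (sum(ss) <= 0) stopf("VIP undefined: model explains no response variance")
  p <- nrow(model$x_weights)
  vip <- sqrt(p * as.numeric(model$x_weights^2 %*% ss) / sum(ss))
  data.frame(variable = model$var_names %||% paste0("V", seq_len(p)),
             vip = vip, selected = vip > threshold,
             stringsAsFactors = FALSE)
}

#' Confusion metrics for a two-class prediction
#'
#' Standard definitions with the deceased (high-risk) class as positive:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/(TP+TN+FP+FN).
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive Positive-class label.
#' @return Object of class `confusion_metrics`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(predicted, truth, positive = "deceased") {
  if (length(predicted) == 0) stopf("empty input")
  if (length(predicted) != length(truth))
    stopf("predicted and truth lengths differ")
  predicted <- as.character(predicted); truth <- as.character(truth)
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  tn <- sum(predicted != positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / length(predicted)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Reconstruct an integer confusion matrix from printed percentages
#'
#' Given class sizes and sensitivity/specificity/accuracy printed to a fixed
#' number of decimals (percent scale), enumerates all integer confusion
#' matrices consistent with the printed values. Useful to recover exact
#' counts from a published performance summary.
#'
#' @param sensitivity,specificity,accuracy Printed percentages (e.g. 76.9).
#' @param n_pos,n_neg Class sizes (positives, negatives).
#' @param tol Half-width of the printed-rounding band (default 0.05, i.e.
#'   one decimal).
#' @return Data frame of consistent `(tp, fn, tn, fp)` rows (usually one).
#' @export
reconstruct_confusion <- function(sensitivity, specificity, accuracy,
                                  n_pos, n_neg, tol = 0.05) {
  grid <- expand.grid(tp = 0:n_pos, tn = 0:n_neg)
  sens <- 100 * grid$tp / n_pos
  spec <- 100 * grid$tn / n_neg
  acc <- 100 * (grid$tp + grid$tn) / (n_pos + n_neg)
  ok <- abs(sens - sensitivity) <= tol + 1e-9 &
    abs(spec - specificity) <= tol + 1e-9 &
    abs(acc - accuracy) <= tol + 1e-9
  out <- grid[ok, , drop = FALSE]
  data.frame(tp = out$tp, fn = n_pos - out$tp, tn = out$tn,
             fp = n_neg - out$tn, row.names = NULL)
}

#' Leave-one-out cross-validation of a PLS-DA model
#'
#' Fits n models, each excluding one sample, and records the held-out
#' prediction; metrics are computed on held-out labels only.
#'
#' @inheritParams fit_pls
#' @return List of class `pls_loocv`: `predicted` (labels), `scores`,
#'   `truth`, `metrics` (a [confusion_metrics()] object).
#' @export
loocv <- function(X, y, n_components = 7, positive = "deceased") {
  if (inherits(X, "binned_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stopf("LOOCV needs n >= 3")
  enc <- encode_classes(y, positive)
  if (min(table(enc$code)) < 2)
    stopf("each class needs >= 2 members for LOOCV")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- enc$code[-i]
    if (length(unique(yi)) < 2)
      stopf("LOOCV fold %d lost an entire class", i)
    xm <- colMeans(Xi); ym <- mean(yi)
    core <- pls_core(sweep(Xi, 2, xm), yi - ym, n_components)
    scores[i] <- sum((X[i, ] - xm) * core$b) + ym
  }
  predicted <- ifelse(scores > 0, enc$classes[2], enc$classes[1])
  truth <- ifelse(enc$code > 0, enc$classes[2], enc$classes[1])
  structure(list(predicted = predicted, scores = scores, truth = truth,
                 metrics = confusion_metrics(predicted, truth,
                                             positive = enc$classes[2])),
            class = "pls_loocv")
}

#' @export
print.pls_loocv <- function(x, ...) {
  cat(sprintf("<pls_loocv> %d held-out predictions\n", length(x$predicted)))
  print(x$metrics)
  invisible(x)
}
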