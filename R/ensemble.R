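#' Majority vote with a gray-zone margin
#'
#' Converts per-sample vote counts into a predicted class, a margin
#' `|vote_share - 0.5|`, and a gray-zone flag (`margin < gray_threshold`,
#' strict). An exact 50/50 tie is resolved to the survivor (lower-risk)
#' class and always flagged gray.
#'
#' @param votes_deceased Votes for the deceased class, per sample.
#' @param votes_total Total votes per sample (> 0).
#' @param gray_threshold Gray-zone margin cutoff (default 0.10).
#' @param sample_id Optional labels.
#' @return Data frame of class `ensemble_vote`: `sample_id`,
#'   `votes_deceased`, `votes_total`, `vote_share`, `predicted_class`,
#'   `margin`, `gray_zone`.
#' @examples
#' majority_vote(c(60, 55, 50), c(100, 100, 100))
#' @export
majority_vote <- function(votes_deceased, votes_total, gray_threshold = 0.10,
                          sample_id = NULL) {
  if (any(votes_total <= 0)) stopf("votes_total must be > 0")
  if (any(votes_deceased < 0 | votes_deceased > votes_total))
    stopf("votes_deceased must lie in [0, votes_total]")
  share <- votes_deceased / votes_total
  # computed from integer counts so a margin exactly at the threshold is
  # never pushed into the gray zone by floating-point error
  margin <- abs(2 * votes_deceased - votes_total) / (2 * votes_total)
  gray <- abs(2 * votes_deceased - votes_total) <
    2 * gray_threshold * votes_total - 1e-9
  tie <- votes_deceased * 2 == votes_total
  out <- data.frame(
    sample_id = sample_id %||% sprintf("S%d", seq_along(share)),
    votes_deceased = votes_deceased,
    votes_total = votes_total,
    vote_share = share,
    predicted_class = ifelse(share > 0.5, "deceased", "survivor"),
    margin = margin,
    gray_zone = gray | tie,
    stringsAsFactors = FALSE)
  class(out) <- c("ensemble_vote", "data.frame")
  attr(out, "gray_threshold") <- gray_threshold
  out
}

#' Balanced-resampling PLS-DA ensemble classifier
#'
#' Handles class imbalance by repeatedly drawing a balanced subsample
#' (`per_class` patients from each class, without replacement), fitting a
#' PLS-DA model on it, and voting: subsample members receive their held-out
#' LOOCV prediction, all remaining patients the fitted model's prediction.
#' Every patient therefore accrues exactly `n_iter` votes; final classes
#' come from [majority_vote()], with patients decided by a margin below
#' `gray_threshold` flagged as gray-zone (ambiguous).
#'
#' Iteration k draws its subsample from its own seed substream, so
#' increasing `n_iter` extends the ensemble without reshuffling earlier
#' iterations.
#'
#' @inheritParams fit_pls
#' @param n_iter Number of resampling iterations (default 100).
#' @param per_class Patients drawn per class each iteration (default 25).
#' @param gray_threshold Gray-zone margin (default 0.10).
#' @param seed Integer master seed.
#' @return Object of class `plsda_ensemble`: `votes` (an `ensemble_vote`
#'   data frame), `iteration_metrics` (per-iteration LOOCV accuracy,
#'   sensitivity, specificity), `truth`, `metrics` (ensemble-level
#'   [confusion_metrics()]), and the call parameters.
#' @export
balanced_ensemble <- function(X, y, n_iter = 100, per_class = 25,
                              n_components = 7, gray_threshold = 0.10,
                              seed = 1L, positive = "deceased") {
  if (inherits(X, "binned_matrix")) X <- X$values
  X <- as.matrix(X)
  sample_ids <- rownames(X) %||% sprintf("S%d", seq_len(nrow(X)))
  enc <- encode_classes(y, positive)
  idx_pos <- which(enc$code > 0)
  idx_neg <- which(enc$code < 0)
  small <- min(length(idx_pos), length(idx_neg))
  if (per_class > small)
    stopf(paste0("per_class (%d) exceeds the minority class size (%d); ",
                 "reduce per_class to at most %d"),
          per_class, small, small)
  if (per_class < 2) stopf("per_class must be >= 2")
  n <- nrow(X)
  votes_dec <- integer(n)
  iter_metrics <- matrix(NA_real_, n_iter, 3,
                         dimnames = list(NULL, c("accuracy", "sensitivity",
                                                 "specificity")))
  for (k in seq_len(n_iter)) {
    sub <- with_seed(derive_seed(seed, 11L, k),
                     c(sample(idx_neg, per_class), sample(idx_pos, per_class)))
    ysub <- enc$code[sub]
    Xsub <- X[sub, , drop = FALSE]
    # held-out LOOCV votes for subsample members
    held_scores <- numeric(length(sub))
    for (j in seq_along(sub)) {
      Xj <- Xsub[-j, , drop = FALSE]; yj <- ysub[-j]
      xm <- colMeans(Xj); ym <- mean(yj)
      core <- pls_core(sweep(Xj, 2, xm), yj - ym, n_components)
      held_scores[j] <- sum((Xsub[j, ] - xm) * core$b) + ym
    }
    votes_dec[sub] <- votes_dec[sub] + (held_scores > 0)
    hm <- confusion_metrics(ifelse(held_scores > 0, "pos", "neg"),
                            ifelse(ysub > 0, "pos", "neg"), positive = "pos")
    iter_metrics[k, ] <- c(hm$accuracy, hm$sensitivity, hm$specificity)
    # whole-model votes for everyone outside the subsample
    out_idx <- setdiff(seq_len(n), sub)
    if (length(out_idx)) {
      xm <- colMeans(Xsub); ym <- mean(ysub)
      core <- pls_core(sweep(Xsub, 2, xm), ysub - ym, n_components)
      sc <- sweep(X[out_idx, , drop = FALSE], 2, xm) %*% core$b + ym
      votes_dec[out_idx] <- votes_dec[out_idx] + (as.numeric(sc) > 0)
    }
  }
  votes <- majority_vote(votes_dec, rep(n_iter, n),
                         gray_threshold = gray_threshold,
                         sample_id = sample_ids)
  truth <- ifelse(enc$code > 0, enc$classes[2], enc$classes[1])
  # ensemble predictions are in survivor/deceased vocabulary; map truth too
  truth_sd <- ifelse(enc$code > 0, "deceased", "survivor")
  structure(list(votes = votes,
                 iteration_metrics = as.data.frame(iter_metrics),
                 truth = truth, truth_sd = truth_sd,
                 metrics = confusion_metrics(votes$predicted_class, truth_sd,
                                             positive = "deceased"),
                 n_iter = n_iter, per_class = per_class,
                 n_components = n_components,
                 gray_threshold = gray_threshold, seed = seed,
                 classes = enc$classes),
            class = "plsda_ensemble")
}

#' @export
print.plsda_ensemble <- function(x, ...) {
  cat(sprintf("<plsda_ensemble> %d iterations, %d per class, %d components\n",
              x$n_iter, x$per_class, x$n_components))
  cat(sprintf("  %d/%d samples in the gray zone (margin < %g)\n",
              sum(x$votes$gray_zone), nrow(x$votes), x$gray_threshold))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.plsda_ensemble <- function(object, ...) {
  im <- colMeans(object$iteration_metrics)
  cat("Balanced PLS-DA ensemble\n")
  cat(sprintf("  iterations: %d (%d + %d per draw), components: %d, seed: %d\n",
              object$n_iter, object$per_class, object$per_class,
              object$n_components, object$seed))
  cat(sprintf("  mean per-iteration LOOCV: accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              im[1], im[2], im[3]))
  cat("  ensemble majority vote:\n")
  print(object$metrics)
  ng <- !object$votes$gray_zone
  if (any(ng) && !all(ng)) {
    m2 <- confusion_metrics(object$votes$predicted_class[ng],
                            object$truth_sd[ng], positive = "deceased")
    cat(sprintf("  excluding %d gray-zone samples:\n",
                sum(object$votes$gray_zone)))
    print(m2)
  }
  invisible(object)
}

#' @export
predict.plsda_ensemble <- function(object, ...) {
  stats::setNames(object$votes$predicted_class, object$votes$sample_id)
}
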