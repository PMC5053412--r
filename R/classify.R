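# Two-class linear discriminant on the (T, S) feature pair, leave-one-out
# cross-validation, and the two-region fusion rule.

#' Fit a two-class linear discriminant on (T, S)
#'
#' Pooled-covariance linear discriminant analysis with equal priors and a
#' symmetric (0/1) loss. Features are z-scored with training statistics
#' before fitting, since T is of order 1 while S can reach hundreds. If the
#' pooled covariance is singular (e.g. one sample per class), a ridge of
#' \code{ridge_factor * trace} is added to its diagonal.
#'
#' @param x numeric matrix or data frame with columns \code{T} and \code{S}.
#' @param labels factor or character vector with exactly two classes.
#' @param positive name of the positive (disease) class, default
#'   \code{"aprop"}.
#' @param standardize z-score the features with training statistics.
#' @param ridge_factor ridge multiplier applied to the covariance trace
#'   when regularization is needed.
#' @return object of class \code{rop_lda} with components \code{classes},
#'   \code{means} (per class, standardized space), \code{cov} (pooled),
#'   \code{w} and \code{cutoff} (the boundary is where the projection of x
#'   onto \code{w} equals \code{cutoff}),
#'   \code{center}, \code{scale}, \code{ridge_used}.
#' @examples
#' set.seed(1)
#' x <- rbind(cbind(rnorm(20, 1.05, 0.02), rnorm(20, 30, 5)),
#'            cbind(rnorm(20, 1.30, 0.02), rnorm(20, 80, 5)))
#' colnames(x) <- c("T", "S")
#' fit <- rop_lda(x, rep(c("healthy", "aprop"), each = 20))
#' table(predict(fit, x), rep(c("healthy", "aprop"), each = 20))
#' @export
rop_lda <- function(x, labels, positive = "aprop", standardize = TRUE,
                    ridge_factor = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing feature values; exclude incomplete images ",
                     "before fitting", call. = FALSE)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L)
    stop("need exactly two classes, got: ", paste(cls, collapse = ", "),
         call. = FALSE)
  # order classes as (negative, positive)
  if (positive %in% cls) cls <- c(setdiff(cls, positive), positive)
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  if (!standardize) {
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  z <- sweep(sweep(x, 2L, center), 2L, scl, `/`)
  mu <- t(vapply(cls, function(k) colMeans(z[labels == k, , drop = FALSE]),
                 numeric(ncol(z))))
  n_k <- table(factor(labels, levels = cls))
  pool <- matrix(0, ncol(z), ncol(z))
  df <- sum(n_k) - 2L
  for (k in cls) {
    zk <- z[labels == k, , drop = FALSE]
    if (nrow(zk) > 1L)
      pool <- pool + crossprod(sweep(zk, 2L, colMeans(zk)))
  }
  pool <- if (df > 0L) pool / df else pool
  ridge_used <- FALSE
  inv <- tryCatch(solve(pool), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv)) ||
      rcond(pool) < .Machine$double.eps * 1e3) {
    eps <- ridge_factor * max(sum(diag(pool)), 1)
    pool <- pool + diag(eps, ncol(z))
    inv <- solve(pool)
    ridge_used <- TRUE
  }
  w <- drop(inv %*% (mu[2L, ] - mu[1L, ]))      # positive-class direction
  cutoff <- sum(w * (mu[1L, ] + mu[2L, ])) / 2  # equal priors
  structure(list(classes = cls, positive = cls[2L], means = mu, cov = pool,
                 w = w, cutoff = cutoff, center = center, scale = scl,
                 n = as.vector(n_k), features = colnames(x),
                 ridge_used = ridge_used),
            class = "rop_lda")
}

#' @export
print.rop_lda <- function(x, ...) {
  cat("Two-class linear discriminant (equal priors)\n")
  cat(sprintf("  classes: %s (n=%d) vs %s (n=%d)%s\n",
              x$classes[1L], x$n[1L], x$classes[2L], x$n[2L],
              if (x$ridge_used) " [ridge-regularized]" else ""))
  cf <- coef(x)
  cat("  boundary: ",
      paste(sprintf("%+.4g*%s", cf[-1L], names(cf)[-1L]), collapse = " "),
      sprintf(" %+.4g = 0\n", cf[1L]))
  invisible(x)
}

#' Boundary coefficients in the original feature space
#'
#' Returns the intercept and feature weights of the decision boundary: a
#' raw (unstandardized) feature vector is predicted positive when its
#' weighted sum plus the intercept exceeds zero.
#'
#' @param object a [rop_lda()] fit.
#' @param ... unused.
#' @export
coef.rop_lda <- function(object, ...) {
  w0 <- object$w / object$scale
  i0 <- -object$cutoff - sum(object$w * object$center / object$scale)
  stats::setNames(c(i0, w0),
                  c("(Intercept)",
                    object$features %||% paste0("x", seq_along(w0))))
}

#' Predict class labels or discriminant scores
#'
#' @param object a [rop_lda()] fit.
#' @param newdata matrix or data frame with the same feature columns.
#' @param type \code{"class"} or \code{"score"} (signed distance along the
#'   discriminant; positive means the positive class).
#' @param ... unused.
#' @export
predict.rop_lda <- function(object, newdata,
                            type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  z <- sweep(sweep(x, 2L, object$center), 2L, object$scale, `/`)
  s <- drop(z %*% object$w) - object$cutoff
  if (type == "score") return(s)
  ifelse(s > 0, object$classes[2L], object$classes[1L])
}

#' Plot a fitted discriminant with its decision boundary
#'
#' Scatter of the training or supplied feature pairs with the linear
#' decision boundary overlaid.
#'
#' @param x a [rop_lda()] fit.
#' @param data matrix/data frame of features to plot.
#' @param labels class labels for coloring.
#' @param ... passed to \code{plot}.
#' @export
plot.rop_lda <- function(x, data, labels, ...) {
  d <- as.matrix(data)
  cols <- ifelse(as.character(labels) == x$positive, "firebrick",
                 "steelblue")
  graphics::plot(d[, 1L], d[, 2L], col = cols, pch = 19,
                 xlab = x$features[1L] %||% "T",
                 ylab = x$features[2L] %||% "S", ...)
  cf <- coef(x)
  if (abs(cf[3L]) > 1e-12) {
    graphics::abline(a = -cf[1L] / cf[3L], b = -cf[2L] / cf[3L], lty = 2)
  } else {
    graphics::abline(v = -cf[1L] / cf[2L], lty = 2)
  }
  graphics::legend("topleft", legend = x$classes, col =
                   c("steelblue", "firebrick"), pch = 19, bty = "n")
  invisible(x)
}

#' Leave-one-out cross-validation of the discriminant
#'
#' Fits the discriminant n times, each time holding out one sample and
#' predicting it. Folds whose training set degenerates to a single class
#' are counted as misclassified (the fold's prediction is recorded as
#' \code{NA}). The confusion matrix treats the positive class (APROP) as
#' positive: recall = TP/(TP+FN), precision = TP/(TP+FP), both in percent.
#'
#' @param x feature matrix (columns \code{T}, \code{S}).
#' @param labels two-class label vector.
#' @param positive positive class name.
#' @param ... passed to [rop_lda()].
#' @return object of class \code{rop_cv}: \code{predictions}, counts
#'   \code{TP FP TN FN}, \code{recall}, \code{precision}, \code{accuracy}.
#' @export
loocv <- function(x, labels, positive = "aprop", ...) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples for LOOCV", call. = FALSE)
  preds <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (length(unique(tr_lab)) < 2L) next       # degenerate fold
    fit <- rop_lda(x[-i, , drop = FALSE], tr_lab, positive = positive, ...)
    preds[i] <- predict(fit, x[i, , drop = FALSE])
  }
  confusion_stats(preds, labels, positive = positive)
}

#' Confusion counts, recall and precision
#'
#' \code{NA} predictions count as misclassifications of their true class.
#'
#' @param predicted,truth label vectors.
#' @param positive positive class name.
#' @return object of class \code{rop_cv}.
#' @export
confusion_stats <- function(predicted, truth, positive = "aprop") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  pos <- truth == positive
  hit <- !is.na(predicted) & predicted == truth
  tp <- sum(pos & hit); fn <- sum(pos & !hit)
  tn <- sum(!pos & hit); fp <- sum(!pos & !hit)
  structure(list(predictions = predicted, positive = positive,
                 TP = tp, FP = fp, TN = tn, FN = fn,
                 recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
                 precision = if (tp + fp > 0) 100 * tp / (tp + fp)
                             else NA_real_,
                 accuracy = 100 * (tp + tn) / length(truth),
                 n = length(truth)),
            class = "rop_cv")
}

#' @export
print.rop_cv <- function(x, ...) {
  cat(sprintf("LOOCV (%d samples, positive = %s):\n", x$n, x$positive))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  recall %.2f%%  precision %.2f%%  accuracy %.2f%%\n",
              x$recall, x$precision, x$accuracy))
  invisible(x)
}

#' Fuse the two diagnostic-region decisions
#'
#' An eye is called clinically healthy only if both the DR1 and the EDR1
#' classifier call it healthy; any APROP call (or a missing region label)
#' yields APROP. The asymmetry deliberately trades false positives for zero
#' false negatives, since a missed APROP case progresses within days.
#'
#' @param label_dr1,label_edr1 per-image label vectors
#'   (\code{"healthy"}/\code{"aprop"}, \code{NA} allowed).
#' @return character vector of fused labels.
#' @export
fuse_regions <- function(label_dr1, label_edr1) {
  ok <- !is.na(label_dr1) & label_dr1 == "healthy" &
        !is.na(label_edr1) & label_edr1 == "healthy"
  ifelse(ok, "healthy", "aprop")
}
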