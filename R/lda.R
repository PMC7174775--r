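#' Regularized linear discriminant classifier
#'
#' Linear discriminant analysis with class means, a pooled within-class
#' covariance shrunk toward a scaled identity (Ledoit-Wolf-style analytic
#' shrinkage), and per-feature standardization using training-set statistics.
#' Shrinkage keeps the classifier well defined when the feature count (4
#' features x 64 channels = 256) approaches or exceeds the training-set
#' size, where the unregularized pooled covariance is singular.
#'
#' @param x Numeric matrix (samples x features) or data frame of features.
#' @param y Class labels (coerced to factor).
#' @param lambda Shrinkage intensity in `[0, 1]`, or `"auto"` (default) for
#'   the analytic estimate.
#' @param standardize Z-score features with training statistics (default
#'   `TRUE`).
#' @return An `hdemg_lda` model with `predict()`, [tidy()] and [glance()]
#'   methods.
#' @export
train_lda <- function(x, y, lambda = "auto", standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  counts <- table(y)
  if (length(counts) < 2) {
    abort("LDA needs at least two classes", class = "hdemg_training_error")
  }
  if (any(counts < 2)) {
    abort(sprintf("class `%s` has fewer than 2 training samples",
                  names(counts)[which(counts < 2)[1]]),
          class = "hdemg_training_error")
  }
  n <- nrow(x)
  p <- ncol(x)

  center <- colMeans(x)
  scale_ <- rep(1, p)
  if (standardize) {
    scale_ <- apply(x, 2, sd)
    scale_[scale_ == 0] <- 1
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  means <- rowsum(xs, y) / as.vector(counts)
  resid <- xs - means[as.integer(y), , drop = FALSE]
  s_pool <- crossprod(resid) / (n - length(counts))

  if (identical(lambda, "auto")) {
    lambda <- lw_shrinkage(resid, s_pool)
  }
  check_number(lambda, "lambda", 0, 1)
  mu <- sum(diag(s_pool)) / p
  sigma <- (1 - lambda) * s_pool
  diag(sigma) <- diag(sigma) + lambda * mu
  # linear discriminant: delta_k(z) = z' W_k - 0.5 mu_k' W_k + log prior_k
  w <- solve(sigma, t(means))
  intercept <- -0.5 * colSums(t(means) * w) + log(as.vector(counts) / n)

  structure(
    list(levels = levels(y), means = means, weights = w,
         intercept = intercept, lambda = lambda,
         center = center, scale = scale_, n = n, p = p,
         counts = as.vector(counts)),
    class = "hdemg_lda"
  )
}

# Ledoit-Wolf analytic shrinkage intensity toward (tr(S)/p) I, computed on
# the class-centered residuals.
lw_shrinkage <- function(resid, s_pool) {
  n <- nrow(resid)
  p <- ncol(resid)
  mu <- sum(diag(s_pool)) / p
  d2 <- sum((s_pool - diag(mu, p))^2) / p
  if (d2 <= .Machine$double.eps) return(0)
  xs2 <- rowSums(resid^2)
  # mean squared Frobenius distance of rank-1 terms from S
  b_bar <- (sum(xs2^2) - 2 * sum((resid %*% s_pool) * resid) +
              n * sum(s_pool^2)) / n^2 / p
  min(1, max(0, min(b_bar, d2) / d2))
}

#' @export
predict.hdemg_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  scores <- xs %*% object$weights +
    matrix(object$intercept, nrow(xs), length(object$levels), byrow = TRUE)
  colnames(scores) <- object$levels
  if (type == "score") return(scores)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.hdemg_lda <- function(x, ...) {
  cat(sprintf("<hdemg_lda> %d classes, %d features, n = %d, shrinkage %.3g\n",
              length(x$levels), x$p, x$n, x$lambda))
  invisible(x)
}

#' @export
tidy.hdemg_lda <- function(x, ...) {
  m <- x$means
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  tibble::as_tibble(m, rownames = "class")
}

#' @export
glance.hdemg_lda <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = x$p, n_classes = length(x$levels),
                 lambda = x$lambda)
}
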