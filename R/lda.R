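#' Fit a two-class linear discriminant
#'
#' Closed-form Fisher / equal-covariance Gaussian discriminant for the
#' signal-versus-noise window classification: weight vector
#' `pooled-covariance^-1 (mean_signal - mean_noise)`, bias from the class
#' means and (by default empirical) class priors. The decision score of a
#' feature vector `x` is `w'x + b`; positive scores classify as `"signal"`.
#'
#' @param x Numeric matrix (observations x dimensions), e.g. LPP-projected
#'   time-series features or subband powers.
#' @param labels Vector with levels `"signal"` and `"noise"`; both classes
#'   must be present.
#' @param priors `"empirical"` (training class proportions) or `"equal"`.
#' @param shrinkage Relative diagonal shrinkage added to the pooled
#'   covariance (default 0; increase for near-singular feature sets).
#' @return An `lda_model` with `weights`, `bias`, `means`, `pooled_cov`,
#'   `priors`.
#' @export
fit_lda <- function(x, labels, priors = c("empirical", "equal"),
                    shrinkage = 0) {
  priors <- match.arg(priors)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  labels <- as.character(labels)
  keep <- labels %in% c("signal", "noise")
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  n_s <- sum(labels == "signal")
  n_n <- sum(labels == "noise")
  if (n_s == 0 || n_n == 0) {
    stop("both 'signal' and 'noise' classes must be present", call. = FALSE)
  }
  xs <- x[labels == "signal", , drop = FALSE]
  xn <- x[labels == "noise", , drop = FALSE]
  mu_s <- colMeans(xs)
  mu_n <- colMeans(xn)
  sc <- function(z, mu) crossprod(sweep(z, 2, mu))
  pooled <- (sc(xs, mu_s) + sc(xn, mu_n)) / (n_s + n_n - 2)
  if (shrinkage > 0) {
    pooled <- pooled + diag(shrinkage * mean(diag(pooled)), ncol(x))
  }
  pr <- if (priors == "empirical") {
    c(signal = n_s, noise = n_n) / (n_s + n_n)
  } else {
    c(signal = 0.5, noise = 0.5)
  }
  w <- tryCatch(solve(pooled, mu_s - mu_n),
                error = function(e) stop("degenerate data: pooled covariance is singular",
                                         call. = FALSE))
  bias <- -sum(w * (mu_s + mu_n)) / 2 + log(pr["signal"] / pr["noise"])
  structure(list(weights = as.numeric(w), bias = unname(bias),
                 means = rbind(signal = mu_s, noise = mu_n),
                 pooled_cov = pooled, priors = pr, prior_mode = priors),
            class = "lda_model")
}

#' Predict with a linear discriminant
#'
#' @param object An `lda_model`.
#' @param x Feature vector or matrix.
#' @param type `"label"` for `"signal"`/`"noise"` factors, `"score"` for the
#'   raw discriminant score.
#' @param ... Unused.
#' @return Factor of labels, or numeric scores.
#' @export
predict.lda_model <- function(object, x, type = c("label", "score"), ...) {
  type <- match.arg(type)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(object$weights)) {
    stop("expected ", length(object$weights), " feature columns", call. = FALSE)
  }
  s <- as.numeric(x %*% object$weights + object$bias)
  if (!all(is.finite(s))) {
    stop("degenerate data: non-finite discriminant scores", call. = FALSE)
  }
  if (type == "score") return(s)
  factor(ifelse(s > 0, "signal", "noise"), levels = c("signal", "noise"))
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, priors %s (signal %.3f), |w| = %.3g\n",
              length(x$weights), x$prior_mode, x$priors["signal"],
              sqrt(sum(x$weights^2))))
  invisible(x)
}

#' Tidy an LDA model
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return A tibble of discriminant coefficients (the bias as term
#'   `"(bias)"`).
#' @export
tidy.lda_model <- function(x, ...) {
  tibble::tibble(term = c(paste0("x", seq_along(x$weights)), "(bias)"),
                 estimate = c(x$weights, x$bias))
}

#' Glance at an LDA model
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return One-row tibble with feature count and class priors.
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$weights),
                 prior_signal = unname(x$priors["signal"]),
                 prior_mode = x$prior_mode)
}
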