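#' Fit a Locality Preserving Projection
#'
#' Learns the linear map that best preserves the local neighbourhood
#' structure of the feature cloud: a k-nearest-neighbour adjacency with
#' heat-kernel weights `W` gives the degree matrix `D` and graph Laplacian
#' `L = D - W`; the projection directions solve the generalized eigenproblem
#' `X L X' a = lambda X D X' a` and the `m` eigenvectors of smallest
#' eigenvalue are kept. Rank deficiency (more dimensions than informative
#' directions) is handled by an energy-preserving SVD pre-projection before
#' the eigenproblem.
#'
#' @param x Numeric matrix (observations x dimensions) or a `feature_set`.
#' @param m Output dimensionality (default 10).
#' @param k Neighbourhood size of the adjacency graph (default 5).
#' @param kernel_width Heat-kernel width (squared-distance scale); default is
#'   the mean squared pairwise distance of the (pre-projected) data.
#' @param var_keep Fraction of signal energy retained by the pre-projection
#'   (default 0.99). The map stays purely linear: no centring is applied, so
#'   projections scale homogeneously with their input.
#' @param ridge Relative ridge added to `X D X'` before factorization.
#' @return An `lpp_model` with elements `pre` (pre-projection),
#'   `proj` (LPP directions in pre-projected space), `eigenvalues`, and the
#'   graph hyperparameters.
#' @export
fit_lpp <- function(x, m = 10, k = 5, kernel_width = NULL,
                    var_keep = 0.99, ridge = 1e-8) {
  if (inherits(x, "feature_set")) x <- x$x
  stopifnot(is.matrix(x))
  n <- nrow(x)
  d <- ncol(x)
  if (n <= k) stop("need more than k = ", k, " observations", call. = FALSE)
  if (m > d) stop("output dimension m must not exceed input dimension",
                  call. = FALSE)
  sv <- svd(x)
  if (max(sv$d) <= 0 || !any(sv$d > max(sv$d) * 1e-10)) {
    stop("degenerate data: features carry no energy", call. = FALSE)
  }
  varfrac <- cumsum(sv$d^2) / sum(sv$d^2)
  q <- max(which(varfrac >= var_keep)[1], m)
  q <- min(q, sum(sv$d > max(sv$d) * 1e-10))
  if (q < m) {
    stop("degenerate data: rank ", q, " is below the requested dimension ",
         m, call. = FALSE)
  }
  pre <- sv$v[, seq_len(q), drop = FALSE]
  y <- x %*% pre

  dv <- stats::dist(y)
  if (is.null(kernel_width)) kernel_width <- mean(dv^2)
  if (!is.finite(kernel_width) || kernel_width <= 0) {
    stop("degenerate data: all observations coincide", call. = FALSE)
  }
  dm <- as.matrix(dv)
  w <- lpp_heat_graph(dm, k, kernel_width)
  deg <- rowSums(w)
  b <- crossprod(y, deg * y)
  a <- b - crossprod(y, w %*% y)
  b_reg <- b + diag(ridge * mean(diag(b)), q)
  r <- tryCatch(chol(b_reg),
                error = function(e) stop("degenerate data: X D X' is not positive definite",
                                         call. = FALSE))
  ri <- backsolve(r, diag(q))
  msym <- crossprod(ri, a) %*% ri
  msym <- (msym + t(msym)) / 2
  es <- eigen(msym, symmetric = TRUE)
  sel <- seq(q, q - m + 1L)           # eigen() sorts decreasing; take smallest
  proj <- ri %*% es$vectors[, sel, drop = FALSE]
  structure(list(pre = pre, proj = proj,
                 eigenvalues = es$values[sel], m = m, k = k,
                 kernel_width = kernel_width, d = d, q = q),
            class = "lpp_model")
}

# symmetrized kNN heat-kernel adjacency from a dense distance matrix
lpp_heat_graph <- function(dm, k, kernel_width) {
  n <- nrow(dm)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dm[i, ])[2:(k + 1L)]   # skip self
    w[i, nb] <- exp(-dm[i, nb]^2 / kernel_width)
  }
  w <- pmax(w, t(w))                   # edge if either endpoint is a neighbour
  diag(w) <- 0
  w
}

#' Project features through a fitted LPP
#'
#' @param model An `lpp_model`.
#' @param x Numeric vector of length `d`, or a matrix/`feature_set` with `d`
#'   columns.
#' @return A projected vector of length `m`, or a matrix with `m` columns.
#' @export
project_lpp <- function(model, x) {
  if (inherits(x, "feature_set")) x <- x$x
  if (is.vector(x)) {
    if (length(x) != model$d) {
      stop("expected a vector of length ", model$d, call. = FALSE)
    }
    return(as.numeric(x %*% model$pre %*% model$proj))
  }
  if (ncol(x) != model$d) {
    stop("expected ", model$d, " columns", call. = FALSE)
  }
  x %*% model$pre %*% model$proj
}

#' @export
print.lpp_model <- function(x, ...) {
  cat(sprintf("<lpp_model> %d -> %d dims (pre-projection rank %d), k = %d, kernel width = %.3g\n",
              x$d, x$m, x$q, x$k, x$kernel_width))
  invisible(x)
}

#' Tidy an LPP model
#'
#' @param x An `lpp_model`.
#' @param ... Unused.
#' @return A tibble with one row per retained component and its generalized
#'   eigenvalue (smaller = more locality-preserving).
#' @export
tidy.lpp_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$m), eigenvalue = x$eigenvalues)
}

#' Glance at an LPP model
#'
#' @param x An `lpp_model`.
#' @param ... Unused.
#' @return A one-row tibble of model dimensions and hyperparameters.
#' @export
glance.lpp_model <- function(x, ...) {
  tibble::tibble(d = x$d, rank = x$q, m = x$m, k = x$k,
                 kernel_width = x$kernel_width)
}
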