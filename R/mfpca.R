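#' Trapezoidal quadrature weights
#'
#' Weights discretising an integral over the frame grid; they are
#' positive and sum to the total duration, and are exact for piecewise
#' linear integrands.
#'
#' @param times Strictly increasing numeric grid.
#' @return Numeric weight vector of the same length.
#' @export
trapezoid_weights <- function(times) {
  n <- length(times)
  stopifnot(n >= 2L, all(diff(times) > 0))
  h <- diff(times)
  c(h[1L] / 2, (h[-1L] + h[-(n - 1L)]) / 2, h[n - 1L] / 2)
}

#' Centre a functional sample
#'
#' Subtracts the pointwise (per time point) mean across subjects.
#'
#' @param X Numeric matrix, subjects x time points (P >= 2).
#' @return Matrix of the same shape with zero column means.
#' @export
center_sample <- function(X) {
  if (nrow(X) < 2L) stop("need at least two subjects", call. = FALSE)
  sweep(X, 2L, colMeans(X))
}

#' Univariate functional principal component analysis
#'
#' Eigenanalysis of the empirical covariance operator of a sample of
#' curves, discretised with quadrature weights `w`: with centred data
#' `X` (P x T) and `W = diag(w)`, the eigenproblem of
#' `W^{1/2} (X'X / (P-1)) W^{1/2}` yields eigenfunctions
#' `phi_k = W^{-1/2} u_k` with unit norm under the weighted inner
#' product, and scores `xi_ik = sum_t w_t phi_k(t) X_i(t)` (the
#' quadrature form of the integral inner product).  The variance of the
#' k-th score equals the k-th eigenvalue.
#'
#' @param X Subjects x time points matrix.
#' @param times Frame times (defaults to a unit grid).
#' @param M Number of components (must satisfy `M <= min(P - 1, T)`).
#' @param weights Quadrature weights; default trapezoidal on `times`.
#' @param center Centre the sample first (default `TRUE`).
#' @return Object of class `ufpca`: list with `eigenfunctions` (T x M),
#'   `eigenvalues` (all `min(P-1, T)` of them), `scores` (P x M),
#'   `mean`, `times`, `weights`.
#' @export
univariate_fpca <- function(X, times = seq_len(ncol(X)) - 1, M = 5L,
                            weights = NULL, center = TRUE) {
  P <- nrow(X); Tn <- ncol(X)
  if (M > min(P - 1L, Tn))
    stop(sprintf("M = %d exceeds min(P - 1, T) = %d", M, min(P - 1L, Tn)),
         call. = FALSE)
  if (is.null(weights)) weights <- trapezoid_weights(times)
  stopifnot(length(weights) == Tn, all(weights > 0))
  mu <- colMeans(X)
  Xc <- if (center) sweep(X, 2L, mu) else X
  sw <- sqrt(weights)
  A <- crossprod(Xc %*% diag(sw, Tn)) / (P - 1L)   # T x T, symmetric
  eg <- eigen(A, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  k <- seq_len(M)
  phi <- eg$vectors[, k, drop = FALSE] / sw        # W^{-1/2} u
  scores <- Xc %*% (weights * phi)
  structure(list(eigenfunctions = phi, eigenvalues = lambda,
                 scores = scores, mean = mu, times = times,
                 weights = weights, M = M),
            class = "ufpca")
}

#' Cumulative explained variance of a univariate FPCA
#'
#' @param fit A `ufpca` object.
#' @param k Number of leading components (default the fitted `M`).
#' @return Fraction in `[0, 1]`.
#' @export
explained_variance <- function(fit, k = fit$M) {
  tot <- sum(fit$eigenvalues)
  if (tot <= 0) return(1)
  sum(fit$eigenvalues[seq_len(k)]) / tot
}

#' Stack univariate scores into the joint score matrix
#'
#' Row i is `(xi_i1^(1), ..., xi_iM^(1), ..., xi_i1^(D), ...,
#' xi_iM^(D))`: the per-element score blocks in element order.
#'
#' @param results List of `ufpca` fits, one per descriptor element.
#' @return Matrix P x sum(M) with attribute `block` mapping columns to
#'   elements.
#' @export
assemble_scores <- function(results) {
  P <- vapply(results, function(r) nrow(r$scores), integer(1L))
  if (length(unique(P)) != 1L)
    stop("inconsistent number of subjects across elements", call. = FALSE)
  Xi <- do.call(cbind, lapply(results, function(r) r$scores))
  attr(Xi, "block") <- rep(seq_along(results),
                           vapply(results, function(r) ncol(r$scores),
                                  integer(1L)))
  Xi
}

#' First-mode scores of the joint score matrix
#'
#' Projects the (column-centred) joint score matrix onto the leading
#' eigenvector of its covariance matrix.  The eigenvector sign is fixed
#' so that the scores correlate non-negatively with the row sums of the
#' matrix, making results reproducible.
#'
#' @param Xi Joint score matrix (P x sum(M)).
#' @return List with `scores` (length P, zero mean), `explained_var`
#'   (leading eigenvalue over total) and `loading` (the eigenvector).
#' @export
first_mode_scores <- function(Xi) {
  if (nrow(Xi) < 2L) stop("need at least two subjects", call. = FALSE)
  Xc <- sweep(Xi, 2L, colMeans(Xi))
  cv <- stats::cov(Xc)
  tot <- sum(diag(cv))
  if (tot <= .Machine$double.eps)
    stop("degenerate joint score matrix: zero covariance", call. = FALSE)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  s <- as.numeric(Xc %*% v)
  if (sum(s * rowSums(Xc)) < 0) { v <- -v; s <- -s }
  list(scores = s, explained_var = eg$values[1L] / tot, loading = v)
}

#' Multivariate functional principal component analysis
#'
#' Reduces a multivariate descriptor trajectory (D features observed
#' over T time points for P subjects) to one score per subject in four
#' steps: (1) centre each feature's curves, (2) univariate FPCA with M
#' components per feature, (3) stack the per-feature scores into a
#' joint `P x (D*M)` matrix, (4) eigenanalysis of the joint covariance,
#' keeping the first mode of variation.
#'
#' @param x Either a 3D array (P subjects x T time points x D features)
#'   or a list of D matrices of dimension P x T.
#' @param times Frame times (minutes); default unit-spaced.
#' @param M Components per feature (default 5).  When the sample cannot
#'   support 5 (`M > min(P-1, T)`), an error is raised; see
#'   `reduce_scores()` for the pipeline behaviour.
#' @param weights Quadrature weights (default trapezoidal).
#' @return Object of class `mfpca` with elements `scores` (first-mode
#'   score per subject), `explained_var`, `loading`, `univariate`
#'   (list of `ufpca` fits), `Xi`, `times`, `M`.
#' @examples
#' set.seed(1)
#' traj <- array(rnorm(20 * 10 * 3), c(20, 10, 3))
#' fit <- mfpca(traj, M = 3)
#' head(scores(fit))
#' @export
mfpca <- function(x, times = NULL, M = 5L, weights = NULL) {
  if (is.array(x) && length(dim(x)) == 3L)
    x <- lapply(seq_len(dim(x)[3L]), function(j) x[, , j])
  stopifnot(is.list(x), length(x) >= 1L)
  Tn <- ncol(x[[1L]])
  if (is.null(times)) times <- seq_len(Tn) - 1
  fits <- lapply(x, univariate_fpca, times = times, M = M,
                 weights = weights, center = TRUE)
  Xi <- assemble_scores(fits)
  fm <- first_mode_scores(Xi)
  structure(list(scores = fm$scores, explained_var = fm$explained_var,
                 loading = fm$loading, univariate = fits, Xi = Xi,
                 times = times, M = M, call = match.call()),
            class = "mfpca")
}

#' Extract scores from a fitted object
#' @param object A fitted object.
#' @param ... Unused.
#' @export
scores <- function(object, ...) UseMethod("scores")

#' @rdname scores
#' @export
scores.mfpca <- function(object, ...) object$scores

#' @export
print.mfpca <- function(x, ...) {
  cat(sprintf("Multivariate FPCA: %d subjects, %d elements, M = %d\n",
              length(x$scores), length(x$univariate), x$M))
  cat(sprintf("First joint mode explains %.1f%% of score variance\n",
              100 * x$explained_var))
  invisible(x)
}

#' @export
summary.mfpca <- function(object, ...) {
  uev <- vapply(object$univariate, explained_variance, numeric(1L))
  out <- list(n_subjects = length(object$scores),
              n_elements = length(object$univariate),
              M = object$M,
              joint_explained = object$explained_var,
              univariate_explained = uev,
              score_summary = summary(object$scores))
  class(out) <- "summary.mfpca"
  out
}

#' @export
print.summary.mfpca <- function(x, ...) {
  cat(sprintf("Multivariate FPCA of %d elements, %d subjects (M = %d)\n",
              x$n_elements, x$n_subjects, x$M))
  cat(sprintf("Univariate variance explained by M components: %.1f%% (min) to %.1f%% (max)\n",
              100 * min(x$univariate_explained),
              100 * max(x$univariate_explained)))
  cat(sprintf("Joint first mode explains %.1f%% of stacked-score variance\n",
              100 * x$joint_explained))
  cat("First-mode scores:\n"); print(x$score_summary)
  invisible(x)
}

#' Project new trajectories onto a fitted MFPCA
#'
#' Centres new curves with the training means, computes their
#' univariate scores against the fitted eigenfunctions, and projects
#' the stacked scores onto the fitted first joint mode.
#'
#' @param object A fitted `mfpca`.
#' @param newdata 3D array (n x T x D) or list of D matrices (n x T).
#' @param ... Unused.
#' @return Numeric vector of first-mode scores.
#' @export
predict.mfpca <- function(object, newdata, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3L)
    newdata <- lapply(seq_len(dim(newdata)[3L]), function(j) newdata[, , j])
  stopifnot(length(newdata) == length(object$univariate))
  blocks <- lapply(seq_along(newdata), function(j) {
    f <- object$univariate[[j]]
    Xc <- sweep(as.matrix(newdata[[j]]), 2L, f$mean)
    Xc %*% (f$weights * f$eigenfunctions)
  })
  Xi_new <- do.call(cbind, blocks)
  Xi_new <- sweep(Xi_new, 2L, colMeans(object$Xi))
  as.numeric(Xi_new %*% object$loading)
}

#' @export
plot.mfpca <- function(x, element = 1L, ...) {
  f <- x$univariate[[element]]
  graphics::matplot(f$times, f$eigenfunctions, type = "l", lty = 1,
                    xlab = "time", ylab = "eigenfunction",
                    main = sprintf("Element %d eigenfunctions (M = %d)",
                                   element, x$M), ...)
  invisible(x)
}
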