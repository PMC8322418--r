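#' Radial basis function kernel of one gene's expression profile
#'
#' Computes the \eqn{n \times n} Gaussian kernel of a single expression
#' vector, \eqn{K_{iu} = \exp(-(v_i - v_u)^2 / \gamma)}.  The RBF kernel is
#' the inner product of an infinite polynomial feature expansion of the
#' input, which is what lets kernel PCA regression approximate an arbitrary
#' continuous regulator-to-target relationship.
#'
#' @param v numeric vector of length \eqn{n \ge 2}; one gene's expression
#'   across samples (typically standardized).
#' @param gamma positive kernel width. Larger values make the kernel flatter
#'   (closer to linear behaviour); the package default used by [kboost()] is
#'   60.
#' @return A symmetric \eqn{n \times n} matrix with unit diagonal and
#'   entries in \eqn{(0, 1]}.
#' @seealso [center_kernel()], [kernel_pca()]
#' @examples
#' K <- rbf_kernel(c(0, 1, 2), gamma = 60)
#' diag(K)  # exactly 1
#' @export
rbf_kernel <- function(v, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop_kpcboost("invalid_parameter_error", "'gamma' must be a single positive number")
  v <- as.numeric(v)
  if (length(v) < 2L)
    stop_kpcboost("invalid_input_error", "'v' must contain at least 2 observations")
  if (any(!is.finite(v)))
    stop_kpcboost("invalid_input_error", "'v' contains non-finite values")
  d <- outer(v, v, "-")
  exp(-(d * d) / gamma)
}

#' Double-center a kernel matrix in feature space
#'
#' Implicitly centers the (possibly infinite-dimensional) feature vectors
#' underlying a kernel matrix:
#' \eqn{\bar K = K - 1_{nn} K - K 1_{nn} + 1_{nn} K 1_{nn}}, where
#' \eqn{1_{nn}} is the matrix with every entry \eqn{1/n}.  Every row and
#' column of the result sums to zero, and the operation is idempotent.
#'
#' @param K square symmetric kernel matrix.
#' @return The centered kernel matrix, same dimension as `K`.
#' @export
center_kernel <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop_kpcboost("shape_error", "'K' must be a square matrix; got ",
                  nrow(K), " x ", ncol(K))
  rm <- rowMeans(K)
  cm <- colMeans(K)
  sweep(sweep(K, 1L, rm, "-"), 2L, cm, "-") + mean(K)
}

#' Kernel principal components of a centered kernel matrix
#'
#' Solves the symmetric eigenproblem \eqn{\bar K \alpha = \alpha \lambda},
#' retains components whose eigenvalues satisfy
#' \eqn{\lambda_i \ge} `eig_threshold` \eqn{\cdot \lambda_1} (and are
#' strictly positive after clipping tiny numerical negatives in
#' \eqn{[-10^{-10}, 0)} to zero), and returns the projections
#' \eqn{\bar K \alpha} rescaled to unit Euclidean norm.  Column signs are
#' fixed so the largest-magnitude entry of each component is positive,
#' making results reproducible; regression fits are sign-invariant.
#'
#' @param K_centered centered kernel matrix (see [center_kernel()]),
#'   positive semi-definite up to numerical tolerance.
#' @param eig_threshold nonnegative relative retention threshold; a
#'   component is kept when its eigenvalue is at least `eig_threshold` times
#'   the leading eigenvalue. Default `1e-6`.
#' @return A list with `kpcs`, an \eqn{n \times z} matrix of orthonormal
#'   kernel principal components, and `eigenvalues`, the corresponding
#'   \eqn{z} positive eigenvalues in descending order.
#' @export
kernel_pca <- function(K_centered, eig_threshold = 1e-6) {
  if (!is.matrix(K_centered) || nrow(K_centered) != ncol(K_centered))
    stop_kpcboost("shape_error", "'K_centered' must be a square matrix")
  if (!is.numeric(eig_threshold) || length(eig_threshold) != 1L || eig_threshold < 0)
    stop_kpcboost("invalid_parameter_error", "'eig_threshold' must be a nonnegative number")
  eg <- eigen(K_centered, symmetric = TRUE)
  lam <- eg$values
  lam[lam < 0 & lam >= -1e-10] <- 0       # PSD guard for floating-point negatives
  if (lam[1L] <= 0)
    stop_kpcboost("degenerate_tf_error", "kernel has no positive variance to decompose")
  keep <- lam > 0 & lam >= eig_threshold * lam[1L]
  if (!any(keep))
    stop_kpcboost("degenerate_tf_error", "all eigenvalues fall below the retention threshold")
  lam <- lam[keep]
  g <- K_centered %*% eg$vectors[, keep, drop = FALSE]
  g <- sweep(g, 2L, sqrt(colSums(g * g)), "/")
  for (k in seq_len(ncol(g))) {
    i <- which.max(abs(g[, k]))
    if (g[i, k] < 0) g[, k] <- -g[, k]
  }
  list(kpcs = g, eigenvalues = lam)
}

#' Build the per-TF kernel principal component library
#'
#' Runs kernel computation, implicit centering and kernel PCA for each
#' transcription factor in turn.  Only the component blocks are kept; the
#' \eqn{n \times n} kernels are transient, so peak additional working memory
#' is one kernel, not one per TF.  TFs whose centered kernel carries no
#' variance (e.g. constant expression) are recorded as excluded and receive
#' zero posterior probability everywhere downstream.
#'
#' @param X standardized expression matrix, genes in rows (see
#'   [standardize_expression()]).
#' @param tf_ids TF gene identifiers or row indices into `X`.
#' @param gamma positive RBF kernel width (default 60).
#' @param eig_threshold relative eigenvalue retention threshold (default
#'   `1e-6`); see [kernel_pca()].
#' @return An object of class `"kpc_library"`: a list with per-TF component
#'   blocks (`kpcs`, `eigenvalues`; `NULL` for excluded TFs), the TF row
#'   `tf_indices` and identifiers `tf_ids`, a logical `excluded` vector, and
#'   the kernel parameters.
#' @export
build_feature_library <- function(X, tf_ids, gamma = 60, eig_threshold = 1e-6) {
  X <- as_expression_matrix(X)
  idx <- resolve_tf_index(X, tf_ids)
  P <- length(idx)
  kpcs <- vector("list", P)
  eigenvalues <- vector("list", P)
  excluded <- logical(P)
  for (p in seq_len(P)) {
    K <- rbf_kernel(X[idx[p], ], gamma)
    Kc <- center_kernel(K)
    res <- tryCatch(kernel_pca(Kc, eig_threshold), degenerate_tf_error = function(e) NULL)
    if (is.null(res)) {
      excluded[p] <- TRUE
    } else {
      kpcs[[p]] <- res$kpcs
      eigenvalues[[p]] <- res$eigenvalues
    }
  }
  structure(list(kpcs = kpcs,
                 eigenvalues = eigenvalues,
                 tf_indices = idx,
                 tf_ids = rownames(X)[idx],
                 excluded = excluded,
                 gamma = gamma,
                 eig_threshold = eig_threshold),
            class = "kpc_library")
}
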