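#' Standardize gene expression rows
#'
#' Centers each gene to sample mean 0 and scales it to sample variance 1
#' (denominator \eqn{n - 1}).  Genes with zero variance cannot be
#' standardized; their rows are set to all zeros and their identifiers are
#' recorded in the `"constant_genes"` attribute of the result.
#'
#' @param X numeric genes-by-samples matrix.
#' @return The standardized matrix with a `"constant_genes"` character
#'   attribute listing flagged genes.
#' @export
standardize_expression <- function(X) {
  X <- as_expression_matrix(X)
  m <- rowMeans(X)
  s <- sqrt(apply(X, 1L, stats::var))
  const <- s == 0 | !is.finite(s)
  out <- (X - m) / ifelse(const, 1, s)
  out[const, ] <- 0
  attr(out, "constant_genes") <- rownames(X)[const]
  out
}

#' Default shrinkage for the boosting coefficients
#'
#' The marginal likelihood scales exponentially with \eqn{(n-1)/2}, so with
#' many samples the posterior would concentrate on a handful of TFs per
#' gene.  The default shrinkage counteracts this sample-size effect:
#' \eqn{\nu = 10/n} when \eqn{n > 10}, else \eqn{\nu = 0.5}.
#'
#' @param n number of samples, at least 2.
#' @return The shrinkage value in \eqn{(0, 1]}.
#' @examples
#' default_shrinkage(24)  # 10/24
#' default_shrinkage(10)  # 0.5
#' @export
default_shrinkage <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2)
    stop_kpcboost("invalid_parameter_error", "'n' must be a single integer >= 2")
  if (n > 10) 10 / n else 0.5
}

#' Log marginal likelihood of one TF-subset regression model
#'
#' Under a Jeffreys prior on the noise variance (and treating the fitted
#' regression function as fixed), the noise variance integrates out
#' analytically and the marginal likelihood of a model is proportional to
#' \eqn{\mathrm{RSS}^{-(n-1)/2}}.  This function returns its logarithm,
#' \eqn{-\frac{n-1}{2}\log(\mathrm{RSS})}.  A residual sum of squares at or
#' below the numerical floor `1e-12 * n` is clamped to the floor rather than
#' producing an infinite value.
#'
#' @param rss residual sum of squares (positive).
#' @param n number of samples.
#' @return The log marginal likelihood (up to an additive constant shared
#'   by all models for the same gene).
#' @export
log_marginal_likelihood <- function(rss, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop_kpcboost("invalid_parameter_error", "'n' must be a single integer >= 2")
  rss <- max(rss, 1e-12 * n)
  -((n - 1) / 2) * log(rss)
}

#' Log prior probability of a TF subset under independent binomial weights
#'
#' The prior of a model is a product over all \eqn{P} candidate TFs:
#' weight \eqn{w_p} if TF \eqn{p} is a member and \eqn{1 - w_p} otherwise.
#' Membership is set-valued: a TF selected several times during boosting
#' counts once.
#'
#' @param members integer vector of TF positions (into `w_row`) in the
#'   model; repeats allowed.
#' @param w_row numeric vector of \eqn{P} prior edge weights, all strictly
#'   inside \eqn{(0, 1)}.
#' @return The log prior.
#' @export
log_model_prior <- function(members, w_row) {
  if (any(w_row <= 0 | w_row >= 1))
    stop_kpcboost("invalid_parameter_error", "prior weights must lie strictly in (0, 1)")
  inset <- logical(length(w_row))
  inset[unique(members)] <- TRUE
  sum(log(w_row[inset])) + sum(log(1 - w_row[!inset]))
}

#' Fit one shrunken kernel-PC regression component
#'
#' For orthonormal regressors the least-squares coefficients are simply
#' \eqn{g^T \varepsilon}; boosting damps them by the shrinkage \eqn{\nu},
#' giving \eqn{\beta = \nu\, g^T \varepsilon} and prediction \eqn{g\beta}.
#'
#' @param kpcs \eqn{n \times z} matrix with orthonormal columns (one TF's
#'   kernel principal components).
#' @param residual length-\eqn{n} numeric vector of current boosting
#'   residuals.
#' @param nu shrinkage in \eqn{(0, 1]}.
#' @return A list with `beta` (length \eqn{z}) and `prediction`
#'   (length \eqn{n}).
#' @export
fit_component <- function(kpcs, residual, nu) {
  if (!is.matrix(kpcs) || nrow(kpcs) != length(residual))
    stop_kpcboost("shape_error", "'kpcs' rows (", nrow(kpcs),
                  ") must match residual length (", length(residual), ")")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1)
    stop_kpcboost("invalid_parameter_error", "'nu' must lie in (0, 1]")
  beta <- nu * drop(crossprod(kpcs, residual))
  list(beta = beta, prediction = drop(kpcs %*% beta))
}

#' Configuration for the boosting search
#'
#' @param gamma positive RBF kernel width (default 60).
#' @param nu shrinkage in \eqn{(0, 1]}; `NULL` means apply
#'   [default_shrinkage()] to the sample count at fit time.
#' @param iterations number of boosting iterations; this is also the
#'   maximum number of TFs a single gene model may contain (default 3).
#' @param eig_threshold relative eigenvalue retention threshold (default
#'   `1e-6`).
#' @return A list of class `"kboost_config"`.
#' @export
kboost_config <- function(gamma = 60, nu = NULL, iterations = 3, eig_threshold = 1e-6) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop_kpcboost("invalid_parameter_error", "'gamma' must be positive")
  if (!is.null(nu) && (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1))
    stop_kpcboost("invalid_parameter_error", "'nu' must lie in (0, 1]")
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1)
    stop_kpcboost("invalid_parameter_error", "'iterations' must be a positive integer")
  if (!is.numeric(eig_threshold) || length(eig_threshold) != 1L || eig_threshold < 0)
    stop_kpcboost("invalid_parameter_error", "'eig_threshold' must be nonnegative")
  structure(list(gamma = gamma, nu = nu, iterations = as.integer(iterations),
                 eig_threshold = eig_threshold),
            class = "kboost_config")
}

#' Greedy boosting search over TF subsets for one gene
#'
#' Iteration 1 evaluates every candidate TF (every library TF except the
#' gene itself and excluded TFs) as a singleton model.  The TF with the
#' highest unnormalized log posterior (log marginal likelihood + log prior)
#' is selected; ties go to the lowest TF position.  Each later iteration
#' evaluates, for every candidate TF, the model consisting of the selected
#' prefix plus that TF, fit on the current residuals, then selects the best
#' and updates the cumulative prediction with the shrunken component.  A TF
#' may be selected more than once.  Every evaluated model is recorded; the
#' returned list is the explored model set over which Bayesian model
#' averaging runs.
#'
#' @param j row index of the target gene in the expression matrix the
#'   library was built from.
#' @param lib a `"kpc_library"` from [build_feature_library()].
#' @param x_j the gene's standardized expression (length \eqn{n}).
#' @param w_row length-\eqn{P} vector of prior edge weights for this gene.
#' @param cfg a [kboost_config()] with a concrete `nu`.
#' @return A list of model records, each with elements `gene`, `members`
#'   (TF positions, with multiplicity), `rss`, `log_ml`, `log_prior`.
#'   Empty when the gene has no candidate TFs.
#' @export
boost_gene <- function(j, lib, x_j, w_row, cfg) {
  P <- length(lib$tf_indices)
  n <- length(x_j)
  if (length(w_row) != P)
    stop_kpcboost("shape_error", "'w_row' length (", length(w_row),
                  ") must equal the number of TFs (", P, ")")
  cand <- which(!lib$excluded & lib$tf_indices != j)
  records <- vector("list", length(cand) * cfg$iterations)
  if (!length(cand)) return(list())
  residual <- as.numeric(x_j)
  prefix <- integer(0)
  rss_floor <- 1e-12 * n
  d <- 0L
  for (t in seq_len(cfg$iterations)) {
    best_lp <- -Inf
    best_pred <- NULL
    best_p <- NA_integer_
    for (p in cand) {
      fc <- fit_component(lib$kpcs[[p]], residual, cfg$nu)
      r <- residual - fc$prediction
      rss <- max(sum(r * r), rss_floor)
      members <- c(prefix, p)
      lml <- log_marginal_likelihood(rss, n)
      lpr <- log_model_prior(members, w_row)
      d <- d + 1L
      records[[d]] <- list(gene = j, members = members, rss = rss,
                           log_ml = lml, log_prior = lpr)
      if (lml + lpr > best_lp) {   # strict ">": lowest candidate wins ties
        best_lp <- lml + lpr
        best_pred <- fc$prediction
        best_p <- p
      }
    }
    residual <- residual - best_pred
    prefix <- c(prefix, best_p)
  }
  records
}

#' Bayesian model averaging over the explored models of one gene
#'
#' Each explored model gets weight proportional to
#' \eqn{\exp(\log\mathrm{ML} + \log\mathrm{prior})}, normalized over the
#' explored set via log-sum-exp.  The posterior probability of an edge from
#' TF \eqn{p} is the total weight of explored models containing \eqn{p}.
#'
#' @param records list of model records from [boost_gene()].
#' @param P number of candidate TFs.
#' @return Numeric vector of length `P` with entries in \eqn{[0, 1]}; all
#'   zeros when `records` is empty.
#' @export
bma_posterior <- function(records, P) {
  out <- numeric(P)
  if (!length(records)) return(out)
  lp <- vapply(records, function(r) r$log_ml + r$log_prior, numeric(1))
  m <- max(lp)
  w <- exp(lp - (m + log(sum(exp(lp - m)))))
  for (d in seq_along(records)) {
    mem <- unique(records[[d]]$members)
    out[mem] <- out[mem] + w[d]
  }
  pmin(pmax(out, 0), 1)
}

#' Column-variance scaling of a posterior matrix
#'
#' Multiplies each TF column of the posterior matrix by its own sample
#' variance (denominator \eqn{G - 1}).  TFs whose posterior profile is
#' nearly uniform across genes are damped, preserving the sparse outdegree
#' distribution typical of biological regulatory networks.  The ranking
#' within each column is unchanged.
#'
#' @param raw genes-by-TFs matrix of posterior probabilities in
#'   \eqn{[0, 1]}.
#' @return The scaled matrix; entries lie in \eqn{[0, 0.25]} because the
#'   variance of values in \eqn{[0, 1]} is at most \eqn{1/4}.
#' @export
variance_scaling <- function(raw) {
  if (!is.matrix(raw))
    stop_kpcboost("shape_error", "'raw' must be a matrix")
  v <- apply(raw, 2L, stats::var)
  sweep(raw, 2L, v, "*")
}

check_prior <- function(prior, G, P, gene_ids, tf_labels) {
  if (is.null(prior))
    return(matrix(0.5, G, P, dimnames = list(gene_ids, tf_labels)))
  if (is.data.frame(prior)) prior <- as.matrix(prior)
  if (!is.matrix(prior) || nrow(prior) != G || ncol(prior) != P)
    stop_kpcboost("shape_error", "prior matrix must be ", G, " x ", P,
                  " (genes x TFs); got ", nrow(prior), " x ", ncol(prior))
  if (any(!is.finite(prior)) || any(prior <= 0 | prior >= 1))
    stop_kpcboost("invalid_parameter_error", "prior weights must lie strictly in (0, 1)")
  dimnames(prior) <- list(gene_ids, tf_labels)
  prior
}

#' Infer a gene regulatory network by kernel-PC regression boosting
#'
#' Fits, for every gene, an ensemble of kernel principal-component
#' regressions on transcription-factor expression via a greedy boosting
#' search, and converts the explored models into posterior edge
#' probabilities by Bayesian model averaging.  The procedure is fully
#' deterministic: the same inputs always produce the same network.
#'
#' The steps are: (1) standardize every gene to mean 0, sample variance 1;
#' (2) compute each TF's RBF kernel, center it in feature space and keep
#' the leading kernel principal components; (3) for every target gene, run
#' `iterations` rounds of greedy boosting, each round scoring all candidate
#' TFs on the current residuals by their Jeffreys-marginalized likelihood
#' times a binomial edge prior; (4) average all explored models to get the
#' posterior probability that each TF regulates each gene; (5) additionally
#' report a column-variance-scaled matrix that damps promiscuous TFs.
#' A gene never appears as its own regulator.
#'
#' @param X numeric genes-by-samples expression matrix (microarray or
#'   RNA-seq, any real-valued scale), gene identifiers as row names. At
#'   least 3 samples.
#' @param tf_ids the transcription factors: gene identifiers or row
#'   indices into `X`.
#' @param prior optional genes-by-TFs matrix of prior edge probabilities,
#'   entries strictly in \eqn{(0, 1)} (for instance 0.6 for edges supported
#'   by ChIP-seq and 0.4 otherwise). `NULL` means the noninformative 0.5
#'   everywhere, under which priors cancel in the model average.
#' @param gamma RBF kernel width; default 60.
#' @param nu shrinkage in \eqn{(0, 1]}; default `NULL` applies the rule
#'   \eqn{\nu = 10/n} for \eqn{n > 10}, else 0.5 (see
#'   [default_shrinkage()]).
#' @param iterations boosting iterations, also the maximum number of TFs
#'   per gene model; default 3.
#' @param eig_threshold relative eigenvalue retention threshold for the
#'   kernel PCA; default `1e-6`.
#' @return An object of class `"kboost"`: a list with
#'   \describe{
#'     \item{raw}{genes \eqn{\times} TFs matrix of posterior edge
#'       probabilities in \eqn{[0, 1]}; self-loop entries are 0.}
#'     \item{scaled}{the column-variance-scaled matrix (entries in
#'       \eqn{[0, 0.25]}).}
#'     \item{gene_ids, tf_ids}{row and column identifiers.}
#'     \item{excluded_tfs}{TFs skipped because their kernel carried no
#'       variance (e.g. constant expression).}
#'     \item{constant_genes}{genes with zero expression variance (their
#'       rows are all zero).}
#'     \item{config}{the parameters used, including the resolved `nu`.}
#'   }
#' @references The method combines kernel PCA regression, greedy gradient
#'   boosting and Occam's-window-style Bayesian model averaging; see the
#'   package vignette for the full model.
#' @examples
#' spec <- simulation_spec(n_genes = 15, n_tfs = 4, n_samples = 30, seed = 7)
#' gold <- simulate_network(spec)
#' X <- simulate_expression(gold, spec)
#' fit <- kboost(X, tf_ids = gold$tf_ids)
#' fit
#' head(as.data.frame(fit))
#' auroc(fit, gold)
#' @export
kboost <- function(X, tf_ids, prior = NULL, gamma = 60, nu = NULL,
                   iterations = 3, eig_threshold = 1e-6) {
  cl <- match.call()
  X <- as_expression_matrix(X)
  n <- ncol(X)
  G <- nrow(X)
  if (n < 3L)
    stop_kpcboost("invalid_input_error", "need at least 3 samples, got ", n)
  idx <- resolve_tf_index(X, tf_ids)
  P <- length(idx)
  tf_labels <- rownames(X)[idx]
  cfg <- kboost_config(gamma, nu, iterations, eig_threshold)
  if (is.null(cfg$nu)) cfg$nu <- default_shrinkage(n)
  W <- check_prior(prior, G, P, rownames(X), tf_labels)
  Xs <- standardize_expression(X)
  const <- attr(Xs, "constant_genes")
  lib <- build_feature_library(Xs, idx, gamma = cfg$gamma,
                               eig_threshold = cfg$eig_threshold)
  raw <- matrix(0, G, P, dimnames = list(rownames(X), tf_labels))
  for (j in seq_len(G)) {
    if (rownames(X)[j] %in% const) next
    recs <- boost_gene(j, lib, Xs[j, ], W[j, ], cfg)
    raw[j, ] <- bma_posterior(recs, P)
  }
  structure(list(raw = raw,
                 scaled = variance_scaling(raw),
                 gene_ids = rownames(X),
                 tf_ids = tf_labels,
                 tf_indices = idx,
                 excluded_tfs = lib$tf_ids[lib$excluded],
                 constant_genes = const,
                 config = cfg,
                 call = cl),
            class = "kboost")
}

#' @export
print.kboost <- function(x, ...) {
  cat("Gene regulatory network inferred by kernel-PC regression boosting\n")
  cat(sprintf("  %d genes, %d TFs (%d excluded), parameters: gamma = %g, nu = %g, iterations = %d\n",
              length(x$gene_ids), length(x$tf_ids), length(x$excluded_tfs),
              x$config$gamma, x$config$nu, x$config$iterations))
  top <- utils::head(ranked_edges(x), 5L)
  if (nrow(top)) {
    cat("  Top edges (posterior probability):\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s -> %s  %.3f\n", top$tf[i], top$target[i], top$score[i]))
  }
  invisible(x)
}

#' @export
summary.kboost <- function(object, tau = 0.2, ...) {
  raw <- object$raw
  n_pairs <- sum(object$raw >= 0) - length(object$tf_ids)  # exclude self pairs
  hubs <- sort(colSums(raw > tau), decreasing = TRUE)
  out <- list(n_genes = length(object$gene_ids),
              n_tfs = length(object$tf_ids),
              excluded_tfs = object$excluded_tfs,
              constant_genes = object$constant_genes,
              tau = tau,
              n_edges = sum(raw > tau),
              density = sum(raw > tau) / n_pairs,
              top_hubs = utils::head(hubs, 5L),
              config = object$config)
  class(out) <- "summary.kboost"
  out
}

#' @export
print.summary.kboost <- function(x, ...) {
  cat(sprintf("kboost network: %d genes x %d TFs\n", x$n_genes, x$n_tfs))
  cat(sprintf("  edges with posterior > %.2g: %d (density %.4f)\n",
              x$tau, x$n_edges, x$density))
  if (length(x$excluded_tfs))
    cat("  excluded TFs:", paste(x$excluded_tfs, collapse = ", "), "\n")
  if (length(x$constant_genes))
    cat("  constant genes:", paste(x$constant_genes, collapse = ", "), "\n")
  cat("  top hub TFs (outdegree):",
      paste(sprintf("%s=%d", names(x$top_hubs), x$top_hubs), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the posterior edge-probability matrix
#'
#' @param object a fitted `"kboost"` object.
#' @param type `"raw"` for posterior probabilities, `"scaled"` for the
#'   column-variance-scaled matrix.
#' @param ... unused.
#' @return A genes-by-TFs numeric matrix.
#' @export
coef.kboost <- function(object, type = c("raw", "scaled"), ...) {
  type <- match.arg(type)
  object[[type]]
}

#' Ranked edge list of a fitted network
#'
#' @param fit a `"kboost"` object.
#' @param use_scaled use the variance-scaled matrix instead of the raw
#'   posterior.
#' @return A data frame with columns `tf`, `target`, `score`, sorted by
#'   score descending, ties broken by (tf, target) lexicographically.
#'   Self pairs are omitted.
#' @export
ranked_edges <- function(fit, use_scaled = FALSE) {
  mat <- if (use_scaled) fit$scaled else fit$raw
  tf <- rep(colnames(mat), each = nrow(mat))
  target <- rep(rownames(mat), times = ncol(mat))
  df <- data.frame(tf = tf, target = target, score = as.vector(mat),
                   stringsAsFactors = FALSE)
  df <- df[df$tf != df$target, , drop = FALSE]
  df <- df[order(-df$score, df$tf, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
as.data.frame.kboost <- function(x, ..., use_scaled = FALSE) {
  ranked_edges(x, use_scaled = use_scaled)
}

#' Plot method for fitted networks
#'
#' Draws the distribution of posterior edge probabilities (self pairs
#' omitted) and the TF outdegree profile at a probability threshold.
#'
#' @param x a `"kboost"` object.
#' @param tau probability threshold for the outdegree panel (default 0.2).
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.kboost <- function(x, tau = 0.2, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  e <- ranked_edges(x)
  graphics::hist(e$score, breaks = 30, main = "Posterior edge probabilities",
                 xlab = "P(edge | data)", col = "grey80", border = "white", ...)
  deg <- sort(colSums(x$raw > tau), decreasing = TRUE)
  graphics::barplot(deg, las = 2, main = sprintf("TF outdegree (> %.2g)", tau),
                    ylab = "targets", cex.names = 0.7)
  invisible(x)
}
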