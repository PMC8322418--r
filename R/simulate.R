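#' Specification of a simulated regulatory system
#'
#' Bundles the parameters of the synthetic benchmark generator: a sparse
#' directed acyclic TF-to-gene network and steady-state multifactorial
#' expression in which each regulated gene is a sum of (optionally
#' nonlinear) functions of its regulators plus Gaussian noise.  The
#' defaults describe the standard recovery benchmark used throughout the
#' package's tests: 50 genes of which 10 are TFs, average TF outdegree 3,
#' 100 samples, noise standard deviation 0.25 and linear links.
#'
#' @param n_genes total number of genes \eqn{G}.
#' @param n_tfs number of transcription factors \eqn{P \le G}; the first
#'   `n_tfs` genes in the generated system are the TFs.
#' @param avg_outdegree expected number of targets per TF; must be below
#'   `n_genes`. Zero gives an empty network.
#' @param n_samples number of steady-state samples \eqn{n \ge 3}.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   regulated genes.
#' @param link_function regulator-to-target link: `"linear"` (identity),
#'   `"tanh"` (saturating), or `"quadratic"`.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return A list of class `"sim_spec"`.
#' @export
simulation_spec <- function(n_genes = 50, n_tfs = 10, avg_outdegree = 3,
                            n_samples = 100, noise_sd = 0.25,
                            link_function = c("linear", "tanh", "quadratic"),
                            seed = 1L) {
  link_function <- match.arg(link_function)
  if (n_tfs < 1 || n_tfs > n_genes)
    stop_kpcboost("invalid_parameter_error", "'n_tfs' must lie in [1, n_genes]")
  if (n_genes < 2)
    stop_kpcboost("invalid_parameter_error", "'n_genes' must be at least 2")
  if (!is.numeric(avg_outdegree) || avg_outdegree < 0 || avg_outdegree >= n_genes)
    stop_kpcboost("invalid_parameter_error",
                  "'avg_outdegree' must lie in [0, n_genes)")
  if (n_samples < 3)
    stop_kpcboost("invalid_parameter_error", "'n_samples' must be at least 3")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_kpcboost("invalid_parameter_error", "'noise_sd' must be nonnegative")
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 avg_outdegree = avg_outdegree, n_samples = as.integer(n_samples),
                 noise_sd = noise_sd, link_function = link_function,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a sparse acyclic TF-to-gene gold-standard network
#'
#' Genes are laid out in a fixed topological order with the TFs first; a TF
#' may regulate any gene later in the order, which guarantees acyclicity
#' and excludes self-loops by construction.  Per-TF edge propensities are
#' drawn from an exponential distribution, so a few TFs act as hubs
#' (heavy-ish outdegree tail) while the expected mean outdegree matches
#' `avg_outdegree`.  The returned gold standard labels every TF-to-gene
#' pair (full universe: positives and negatives).
#'
#' @param spec a [simulation_spec()].
#' @return A [gold_standard()] covering all \eqn{G \cdot P - P} ordered
#'   pairs.
#' @export
simulate_network <- function(spec) {
  if (!inherits(spec, "sim_spec"))
    stop_kpcboost("invalid_parameter_error", "'spec' must be a simulation_spec()")
  G <- spec$n_genes
  P <- spec$n_tfs
  ids <- paste0("G", seq_len(G))
  lab <- with_seed(spec$seed, {
    u <- stats::rexp(P)
    w <- u / sum(u)
    out <- vector("list", P)
    for (p in seq_len(P)) {
      targets <- setdiff(seq_len(G), seq_len(p))   # only downstream of p
      q <- if (length(targets))
        min(1, spec$avg_outdegree * P * w[p] / length(targets)) else 0
      hit <- if (length(targets)) stats::runif(length(targets)) < q else logical(0)
      pos <- targets[hit]
      all_t <- setdiff(seq_len(G), p)
      out[[p]] <- data.frame(tf = ids[p], target = ids[all_t],
                             label = as.integer(all_t %in% pos),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  gold_standard(lab, tf_ids = ids[seq_len(P)], gene_ids = ids)
}

link_fun <- function(name) {
  switch(name,
         linear = identity,
         tanh = tanh,
         quadratic = function(x) x^2,
         stop_kpcboost("invalid_parameter_error", "unknown link function: ", name))
}

#' Simulate steady-state expression from a gold-standard network
#'
#' Emulates a multifactorial steady-state experiment: genes without
#' regulators (root TFs and orphan targets) are drawn i.i.d. standard
#' normal per sample; every regulated gene is
#' \eqn{x_j = \sum_{p \in \mathrm{reg}(j)} c_{p,j}\, f(x_p) + \varepsilon},
#' with per-edge coefficients \eqn{c_{p,j}} drawn once as
#' \eqn{\pm U(0.5, 1.5)}, \eqn{f} the spec's link function and
#' \eqn{\varepsilon \sim N(0, \sigma^2)}.  Genes are evaluated in a
#' topological order of the network, so the generation is exact (no fixed
#' points to solve); cyclic input is rejected.  Expression draws are seeded
#' by `spec$seed + 1`, keeping topology and expression reproducible from
#' the single spec seed.
#'
#' @param gold a [gold_standard()] whose positive edges form a DAG.
#' @param spec the [simulation_spec()] providing sample count, noise level,
#'   link function and seed.
#' @return A genes-by-samples numeric matrix with gene and sample
#'   identifiers.
#' @export
simulate_expression <- function(gold, spec) {
  if (!inherits(gold, "grn_gold"))
    stop_kpcboost("invalid_parameter_error", "'gold' must be a gold_standard()")
  if (!inherits(spec, "sim_spec"))
    stop_kpcboost("invalid_parameter_error", "'spec' must be a simulation_spec()")
  ids <- gold$gene_ids
  G <- length(ids)
  n <- spec$n_samples
  pos <- gold$edges[gold$edges$label == 1L, , drop = FALSE]
  g <- igraph::graph_from_data_frame(pos[, c("tf", "target")], directed = TRUE,
                                     vertices = data.frame(name = ids))
  if (!igraph::is_dag(g))
    stop_kpcboost("cycle_error", "gold-standard network contains a directed cycle")
  topo <- names(igraph::topo_sort(g, mode = "out"))
  f <- link_fun(spec$link_function)
  with_seed(spec$seed + 1L, {
    coef <- sample(c(-1, 1), nrow(pos), replace = TRUE) *
      stats::runif(nrow(pos), 0.5, 1.5)
    X <- matrix(0, G, n, dimnames = list(ids, paste0("S", seq_len(n))))
    for (gene in topo) {
      inc <- which(pos$target == gene)
      if (!length(inc)) {
        X[gene, ] <- stats::rnorm(n)
      } else {
        sig <- rep(0, n)
        for (e in inc) sig <- sig + coef[e] * f(X[pos$tf[e], ])
        X[gene, ] <- sig + stats::rnorm(n, 0, spec$noise_sd)
      }
    }
    X
  })
}

#' Noisy informative prior from a gold standard
#'
#' Emulates prior knowledge (e.g. from ChIP-seq) of varying quality: a
#' fraction of the gold standard's edges is corrupted — statuses flipped,
#' balanced between deletions of true edges and additions of false ones
#' where availability allows — and the perturbed network is encoded as a
#' prior matrix giving weight `w_in` to its present edges and `w_out` to
#' absent pairs.  The number of flips is
#' \eqn{\lfloor \mathrm{flip\_fraction} \cdot N \rfloor} with \eqn{N} the
#' number of labeled gold pairs, so `flip_fraction = 1` encodes the exact
#' complement of the gold network and `flip_fraction = 0` encodes the gold
#' standard itself.
#'
#' @param gold a [gold_standard()] with a full labeled universe.
#' @param flip_fraction fraction of gold edges to corrupt, in
#'   \eqn{[0, 1]}.
#' @param w_in prior weight of edges present in the (perturbed) network;
#'   default 0.6.
#' @param w_out prior weight of absent pairs; default 0.4.  Requires
#'   \eqn{0 < w_{out} < w_{in} < 1}.
#' @param seed integer seed for the flip sampling.
#' @return A genes-by-TFs prior matrix with entries in \eqn{(0, 1)}
#'   (self pairs get the noninformative 0.5; they are never scored).
#' @export
perturb_prior <- function(gold, flip_fraction, w_in = 0.6, w_out = 0.4, seed = 1L) {
  if (!inherits(gold, "grn_gold"))
    stop_kpcboost("invalid_parameter_error", "'gold' must be a gold_standard()")
  if (!is.numeric(flip_fraction) || flip_fraction < 0 || flip_fraction > 1)
    stop_kpcboost("invalid_parameter_error", "'flip_fraction' must lie in [0, 1]")
  if (!is.numeric(w_in) || !is.numeric(w_out) ||
      w_out <= 0 || w_in >= 1 || w_in <= w_out)
    stop_kpcboost("invalid_parameter_error", "need 0 < w_out < w_in < 1")
  ed <- gold$edges
  status <- ed$label
  pos <- which(status == 1L)
  neg <- which(status == 0L)
  n_flip <- floor(flip_fraction * nrow(ed))
  n_del <- min(floor(n_flip / 2), length(pos))
  n_add <- min(n_flip - n_del, length(neg))
  # if negatives run out, push the remainder back into deletions
  n_del <- min(n_del + (n_flip - n_del - n_add), length(pos))
  with_seed(seed, {
    del <- pos[sample.int(length(pos), n_del)]
    add <- neg[sample.int(length(neg), n_add)]
    status[del] <- 0L
    status[add] <- 1L
  })
  W <- matrix(0.5, length(gold$gene_ids), length(gold$tf_ids),
              dimnames = list(gold$gene_ids, gold$tf_ids))
  W[cbind(match(ed$target, gold$gene_ids), match(ed$tf, gold$tf_ids))] <-
    ifelse(status == 1L, w_in, w_out)
  W
}
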