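test_that("standardize_expression centers, scales and flags constant genes", {
  X <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-4, 0, 10))
  Z <- standardize_expression(X)
  expect_lt(max(abs(rowMeans(Z[c("a", "c"), ]))), 1e-10)
  expect_equal(apply(Z[c("a", "c"), ], 1, var), c(a = 1, c = 1), tolerance = 1e-10)
  expect_identical(unname(Z["b", ]), c(0, 0, 0))
  expect_identical(attr(Z, "constant_genes"), "b")
  expect_equal(unname(standardize_expression(Z)), unname(Z), tolerance = 1e-10)
})

test_that("default_shrinkage follows the 10/n rule with a strict n > 10 cut", {
  expect_identical(default_shrinkage(24), 10 / 24)
  expect_identical(default_shrinkage(100), 0.1)
  expect_identical(default_shrinkage(10), 0.5)
  expect_identical(default_shrinkage(3), 0.5)
  expect_error(default_shrinkage(1), class = "invalid_parameter_error")
})

test_that("log marginal likelihood is -((n-1)/2) log(RSS) with a floor", {
  expect_identical(log_marginal_likelihood(1, 50), 0)
  expect_equal(log_marginal_likelihood(exp(1), 25), -12)
  # halving the RSS at n = 21 raises the log-ML by 10 log 2
  expect_equal(log_marginal_likelihood(0.7, 21) - log_marginal_likelihood(1.4, 21),
               10 * log(2))
  expect_true(is.finite(log_marginal_likelihood(0, 30)))
  expect_true(is.finite(log_marginal_likelihood(-1, 30)))
})

test_that("binomial model prior has set semantics over distinct members", {
  w <- rep(0.5, 6)
  expect_equal(log_model_prior(c(2L, 4L), w), 6 * log(0.5))
  expect_equal(log_model_prior(integer(0), w), 6 * log(0.5))
  expect_equal(log_model_prior(1L, 0.6) - log_model_prior(integer(0), 0.6),
               log(1.5))
  w2 <- c(0.6, 0.4, 0.3)
  expect_identical(log_model_prior(c(1L, 1L), w2), log_model_prior(1L, w2))
  expect_error(log_model_prior(1L, c(0.5, 1)), class = "invalid_parameter_error")
  expect_error(log_model_prior(1L, c(0, 0.5)), class = "invalid_parameter_error")
})

test_that("fit_component is the shrunken projection onto orthonormal columns", {
  set.seed(9)
  g <- qr.Q(qr(matrix(rnorm(8 * 3), 8)))[, 1:3]
  # residual orthogonal to the components: nothing to fit
  r_perp <- residuals(lm(rnorm(8) ~ g - 1))
  fc <- fit_component(g, r_perp, 0.7)
  expect_equal(fc$beta, rep(0, 3), tolerance = 1e-12)
  expect_equal(fc$prediction, rep(0, 8), tolerance = 1e-12)
  # exact fit at nu = 1 when the residual lies in the span
  g1 <- g[, 1, drop = FALSE]
  fc2 <- fit_component(g1, 2 * g1[, 1], 1)
  expect_equal(fc2$prediction, 2 * g1[, 1])
  expect_equal(sum((2 * g1[, 1] - fc2$prediction)^2), 0)
  # nu = 1 reproduces the generic least-squares RSS
  y <- rnorm(8)
  fc3 <- fit_component(g, y, 1)
  rss_ls <- sum(residuals(lm(y ~ g - 1))^2)
  expect_equal(sum((y - fc3$prediction)^2), rss_ls, tolerance = 1e-8)
  expect_error(fit_component(g, rnorm(5), 1), class = "shape_error")
  expect_error(fit_component(g, y, 0), class = "invalid_parameter_error")
})

test_that("boost_gene explores iterations x candidates models without self-loops", {
  X <- standardize_expression(random_expression(6, 12, seed = 21))
  lib <- build_feature_library(X, 1:4)
  cfg <- kboost_config(nu = 0.5)
  recs <- boost_gene(2L, lib, X[2, ], rep(0.5, 4), cfg)
  expect_length(recs, 3 * 3)            # gene 2 is a TF: 3 candidates, 3 iterations
  expect_false(any(vapply(recs, function(r) 2L %in% r$members, TRUE)))
  recs5 <- boost_gene(5L, lib, X[5, ], rep(0.5, 4), cfg)
  expect_length(recs5, 3 * 4)           # non-TF gene: all 4 TFs are candidates
  sizes <- vapply(recs5, function(r) length(r$members), 1L)
  expect_identical(sort(unique(sizes)), 1:3)
  expect_true(all(vapply(recs5, function(r) r$rss > 0, TRUE)))
})

test_that("boost_gene selects the generating TF first for a planted edge", {
  X <- standardize_expression(planted_edge_expression())
  lib <- build_feature_library(X, 1:2)
  cfg <- kboost_config(nu = 1)
  recs <- boost_gene(3L, lib, X[3, ], rep(0.5, 2), cfg)
  first_iter <- recs[1:2]
  lp <- vapply(first_iter, function(r) r$log_ml + r$log_prior, 1)
  expect_identical(first_iter[[which.max(lp)]]$members, 1L)
})

test_that("bma_posterior normalizes explored-model weights", {
  # hand-derived: log posteriors {0, -log 2, -log 2} over {1}, {2}, {1,2}
  recs <- list(list(members = 1L, log_ml = 0, log_prior = 0),
               list(members = 2L, log_ml = -log(2), log_prior = 0),
               list(members = c(1L, 2L), log_ml = 0, log_prior = -log(2)))
  expect_equal(bma_posterior(recs, 2), c(0.75, 0.5))
  # symmetric singletons
  recs2 <- list(list(members = 1L, log_ml = -3, log_prior = -1),
                list(members = 2L, log_ml = -3, log_prior = -1))
  expect_equal(bma_posterior(recs2, 3), c(0.5, 0.5, 0))
  expect_identical(bma_posterior(list(), 4), rep(0, 4))
  # no underflow at large n scales of log-likelihood
  recs3 <- list(list(members = 1L, log_ml = -4e4, log_prior = 0),
                list(members = 2L, log_ml = -4e4 - 2, log_prior = 0))
  p <- bma_posterior(recs3, 2)
  expect_equal(sum(p), 1, tolerance = 1e-10)
  expect_gt(p[1], p[2])
})

test_that("uniform priors cancel: shifting all log-priors leaves the average unchanged", {
  X <- standardize_expression(random_expression(7, 14, seed = 31))
  lib <- build_feature_library(X, 1:3)
  recs <- boost_gene(6L, lib, X[6, ], rep(0.5, 3), kboost_config(nu = 0.5))
  shifted <- lapply(recs, function(r) {
    r$log_prior <- r$log_prior + 7.3
    r
  })
  expect_equal(bma_posterior(shifted, 3), bma_posterior(recs, 3), tolerance = 1e-12)
})

test_that("raising one prior weight never lowers that TF's posterior (fixed models)", {
  X <- standardize_expression(random_expression(8, 12, seed = 41))
  lib <- build_feature_library(X, 1:4)
  recs <- boost_gene(7L, lib, X[7, ], rep(0.5, 4), kboost_config(nu = 0.5))
  rescore <- function(w_row) {
    r2 <- lapply(recs, function(r) {
      r$log_prior <- log_model_prior(r$members, w_row)
      r
    })
    bma_posterior(r2, 4)
  }
  w <- rep(0.5, 4)
  prev <- rescore(w)[2]
  for (wp in c(0.6, 0.75, 0.9, 0.99)) {
    w[2] <- wp
    cur <- rescore(w)[2]
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("shrinkage toward zero flattens singleton fits toward the raw RSS", {
  X <- standardize_expression(planted_edge_expression(noise = 0.2))
  lib <- build_feature_library(X, 1:2)
  x <- X[3, ]
  rss_at <- function(nu) {
    fc <- fit_component(lib$kpcs[[1]], x, nu)
    sum((x - fc$prediction)^2)
  }
  expect_lt(rss_at(1), rss_at(0.5))
  expect_lt(rss_at(0.5), rss_at(0.05))
  expect_equal(rss_at(1e-9), sum(x^2), tolerance = 1e-6)
})

test_that("variance_scaling multiplies columns by their sample variance", {
  raw <- cbind(a = c(0, 1), b = c(0.3, 0.3))
  sc <- variance_scaling(raw)
  expect_equal(sc[, "a"], c(0, 0.5), ignore_attr = TRUE)  # var(c(0,1)) = 0.5
  expect_equal(sc[, "b"], c(0, 0), ignore_attr = TRUE)
  set.seed(2)
  R <- matrix(runif(40), 10, 4)
  S <- variance_scaling(R)
  for (k in 1:4) expect_identical(order(S[, k]), order(R[, k]))
  expect_true(all(variance_scaling(matrix(runif(60), 20, 3)) <= 0.25))
})

test_that("kboost is deterministic, self-loop free, and handles degenerate rows", {
  X <- random_expression(12, 15, seed = 51)
  X[4, ] <- 2                      # constant gene (and TF)
  f1 <- kboost(X, tf_ids = 1:5)
  f2 <- kboost(X, tf_ids = 1:5)
  expect_identical(f1$raw, f2$raw)
  expect_identical(f1$scaled, f2$scaled)
  for (tf in f1$tf_ids) expect_identical(f1$raw[tf, tf], 0)
  expect_identical(f1$excluded_tfs, "G4")
  expect_identical(unname(f1$raw["G4", ]), rep(0, 5))  # constant gene row
  expect_identical(unname(f1$raw[, "G4"]), rep(0, 12)) # excluded TF column
  expect_true(all(f1$raw >= 0 & f1$raw <= 1))
  expect_true(all(f1$scaled >= 0 & f1$scaled <= 0.25))
  expect_equal(f1$config$nu, 10 / 15)
})

test_that("kboost rejects malformed priors and tiny sample counts", {
  X <- random_expression(6, 10, seed = 61)
  expect_error(kboost(X[, 1:2], tf_ids = 1:2), class = "invalid_input_error")
  expect_error(kboost(X, tf_ids = 1:2, prior = matrix(0.5, 3, 2)),
               class = "shape_error")
  expect_error(kboost(X, tf_ids = 1:2, prior = matrix(1.2, 6, 2)),
               class = "invalid_parameter_error")
  expect_error(kboost(X, tf_ids = c(1, 1)), class = "invalid_parameter_error")
})

test_that("optimized fit equals the naive straight-from-the-equations reference", {
  for (seed in c(101, 202)) {
    set.seed(seed)
    G <- sample(6:9, 1)
    n <- sample(10:14, 1)
    P <- sample(2:4, 1)
    X <- random_expression(G, n, seed = seed)
    W <- matrix(runif(G * P, 0.3, 0.7), G, P)
    fit <- kboost(X, tf_ids = seq_len(P), prior = W, iterations = 2)
    ref <- naive_kboost(X, seq_len(P), W = W, iterations = 2)
    expect_lt(max(abs(unname(fit$raw) - ref$raw)), 1e-8)
    expect_lt(max(abs(unname(fit$scaled) - ref$scaled)), 1e-8)
  }
})

test_that("fit object methods expose ranked edges and matrices coherently", {
  spec <- simulation_spec(n_genes = 12, n_tfs = 3, n_samples = 20, seed = 5)
  gold <- simulate_network(spec)
  fit <- kboost(simulate_expression(gold, spec), tf_ids = gold$tf_ids)
  expect_output(print(fit), "kernel-PC regression boosting")
  s <- summary(fit)
  expect_s3_class(s, "summary.kboost")
  expect_output(print(s), "edges with posterior")
  expect_identical(coef(fit), fit$raw)
  expect_identical(coef(fit, "scaled"), fit$scaled)
  re <- as.data.frame(fit)
  expect_identical(names(re), c("tf", "target", "score"))
  expect_identical(nrow(re), 12L * 3L - 3L)
  expect_true(all(diff(re$score) <= 0))
  expect_false(any(re$tf == re$target))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
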