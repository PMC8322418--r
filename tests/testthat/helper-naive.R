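# Deliberately naive reference implementation of the whole inference,
# written straight from the model equations with explicit loops, no
# precomputation and kernels recomputed from scratch for every gene and
# iteration.  It shares no code with the package internals and serves as
# the independent oracle for the optimized path.

naive_kboost <- function(X, tf_rows, W = NULL, gamma = 60, nu = NULL,
                         iterations = 3, eig_threshold = 1e-6) {
  G <- nrow(X)
  n <- ncol(X)
  P <- length(tf_rows)
  if (is.null(nu)) nu <- if (n > 10) 10 / n else 0.5
  if (is.null(W)) W <- matrix(0.5, G, P)

  # standardize each gene row (sample variance, n-1 denominator)
  Z <- X
  for (j in 1:G) {
    mu <- sum(X[j, ]) / n
    v <- sum((X[j, ] - mu)^2) / (n - 1)
    Z[j, ] <- if (v == 0) rep(0, n) else (X[j, ] - mu) / sqrt(v)
  }

  kpcs_of_tf <- function(p) {
    K <- matrix(0, n, n)
    for (i in 1:n) for (u in 1:n)
      K[i, u] <- exp(-(Z[p, i] - Z[p, u])^2 / gamma)
    ones <- matrix(1 / n, n, n)
    Kc <- K - ones %*% K - K %*% ones + ones %*% K %*% ones
    eg <- eigen(Kc, symmetric = TRUE)
    lam <- eg$values
    lam[lam < 0 & lam >= -1e-10] <- 0
    if (lam[1] <= 0) return(NULL)
    keep <- which(lam > 0 & lam >= eig_threshold * lam[1])
    if (!length(keep)) return(NULL)
    g <- Kc %*% eg$vectors[, keep, drop = FALSE]
    for (k in seq_along(keep)) g[, k] <- g[, k] / sqrt(sum(g[, k]^2))
    g
  }

  model_log_prior <- function(members, w) {
    s <- 0
    for (p in 1:P)
      s <- s + if (p %in% members) log(w[p]) else log(1 - w[p])
    s
  }

  raw <- matrix(0, G, P)
  for (j in 1:G) {
    if (all(Z[j, ] == 0)) next
    cand <- integer(0)
    for (p in 1:P)
      if (tf_rows[p] != j && !is.null(kpcs_of_tf(tf_rows[p]))) cand <- c(cand, p)
    if (!length(cand)) next
    residual <- Z[j, ]
    prefix <- integer(0)
    rec_members <- list()
    rec_lp <- numeric(0)
    for (t in 1:iterations) {
      best_lp <- -Inf
      best_p <- NA
      best_pred <- NULL
      for (p in cand) {
        g <- kpcs_of_tf(tf_rows[p])       # recomputed every time, on purpose
        beta <- nu * (t(g) %*% residual)
        pred <- as.numeric(g %*% beta)
        rss <- sum((residual - pred)^2)
        if (rss < 1e-12 * n) rss <- 1e-12 * n
        members <- c(prefix, p)
        lp <- -((n - 1) / 2) * log(rss) + model_log_prior(members, W[j, ])
        rec_members[[length(rec_members) + 1]] <- members
        rec_lp <- c(rec_lp, lp)
        if (lp > best_lp) {
          best_lp <- lp
          best_p <- p
          best_pred <- pred
        }
      }
      residual <- residual - best_pred
      prefix <- c(prefix, best_p)
    }
    m <- max(rec_lp)
    w_d <- exp(rec_lp - m) / sum(exp(rec_lp - m))
    for (d in seq_along(rec_members))
      for (p in unique(rec_members[[d]]))
        raw[j, p] <- raw[j, p] + w_d[d]
  }
  raw[raw > 1] <- 1
  # column-variance heuristic
  scaled <- raw
  for (p in 1:P) {
    mu <- mean(raw[, p])
    v <- sum((raw[, p] - mu)^2) / (G - 1)
    scaled[, p] <- raw[, p] * v
  }
  list(raw = raw, scaled = scaled)
}

# Brute-force metric oracles by explicit threshold enumeration.
brute_auroc <- function(s, y) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

brute_aupr <- function(s, y) {
  npos <- sum(y == 1)
  thr <- sort(unique(s), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    keep <- s >= t               # everything at or above this distinct value
    tp <- sum(y[keep] == 1)
    prec <- tp / sum(keep)
    rec <- tp / npos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}
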