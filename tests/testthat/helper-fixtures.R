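# Small in-code fixtures shared across test files.

random_expression <- function(G, n, seed) {
  set.seed(seed)
  matrix(rnorm(G * n), G, n,
         dimnames = list(paste0("G", seq_len(G)), paste0("S", seq_len(n))))
}

# A tiny system where TF G1 drives G3 almost noiselessly and G2 is an
# independent decoy TF.
planted_edge_expression <- function(n = 20, seed = 42, noise = 1e-3) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  x3 <- 1.2 * x1 + rnorm(n, 0, noise)
  rbind(G1 = x1, G2 = x2, G3 = x3)
}

# Gold standard over an explicit small pair table.
tiny_gold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ids <- paste0("T", seq_along(scores))
  list(gold = gold_standard(data.frame(tf = "TF1", target = ids, label = labels)),
       scores = data.frame(tf = "TF1", target = ids, score = scores))
}
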