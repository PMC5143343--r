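# Independent brute-force reference implementations used as oracles.
# Deliberately naive (triple loops, exhaustive enumeration) and kept free of
# any code path shared with the package internals.

oracle_fw <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_lengths <- function(W, binary) {
  L <- matrix(Inf, nrow(W), ncol(W))
  L[W > 0] <- if (binary) 1 else 1 / W[W > 0]
  diag(L) <- 0
  L
}

oracle_global_eff <- function(W, binary) {
  n <- nrow(W)
  if (n < 2) return(0)
  d <- oracle_fw(oracle_lengths(W, binary))
  acc <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && is.finite(d[i, j]) && d[i, j] > 0)
        acc <- acc + 1 / d[i, j]
  acc / (n * (n - 1))
}

oracle_local_eff <- function(W, binary) {
  n <- nrow(W)
  if (n == 0) return(0)
  acc <- 0
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    acc <- acc + oracle_global_eff(W[nb, nb, drop = FALSE], binary)
  }
  acc / n
}

# binary clustering by exhaustive triangle enumeration
oracle_clustering_bin <- function(W) {
  A <- W > 0
  n <- nrow(A)
  if (n == 0) return(0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]]) tri <- tri + 1
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

# Onnela geometric-mean triangle intensity, max-weight rescaled
oracle_clustering_onnela <- function(W) {
  n <- nrow(W)
  if (n == 0 || max(W) == 0) return(0)
  Wh <- W / max(W)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        s <- s + (Wh[i, nb[a]] * Wh[i, nb[b]] * Wh[nb[a], nb[b]])^(1 / 3)
    ci[i] <- 2 * s / (k * (k - 1))
  }
  mean(ci)
}

oracle_degree <- function(W) mean(colSums(W > 0))
oracle_strength <- function(W) mean(colSums(W))

# random symmetric weight matrix (weighted or 0/1), zero diagonal
rand_weights <- function(n, density = 0.4, weighted = TRUE, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  m <- sum(ut)
  present <- runif(m) < density
  w <- numeric(m)
  w[present] <- if (weighted) runif(sum(present), 0.05, 0.95) else 1
  W[ut] <- w
  W + t(W)
}

rand_connectome <- function(n, density = 0.4, weighted = TRUE, seed = 1) {
  W <- rand_weights(n, density, weighted, seed)
  connectome(W, variant = if (weighted) "fa_weighted" else "binary")
}

triplet_from_weights <- function(W) {
  faw <- connectome(W, variant = "fa_weighted")
  list(binary = connectome((W > 0) * 1, variant = "binary"),
       fa_weighted = faw,
       fa_normalized = normalize_total_strength(faw))
}
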