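# Shared fixtures and independent oracles, built in code at test time.

# A small cohort cached per (n, prevalence, effect, seed) to keep the suite fast.
tiny_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 300, prevalence = 0.35, effect = 1, seed = 42) {
    key <- paste(n, prevalence, effect, seed, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(n, prevalence, effect, seed)
    }
    cache[[key]]
  }
})

# Random probability rows (valid distributions) for property sweeps.
random_prob_rows <- function(n, C = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * C), nrow = n)
  m / rowSums(m)
}

# Independent straight-line recomputation of the distillation chain
# (temperature -> weights -> clip -> aggregate -> filter), written with
# explicit loops so it shares no code path with the package.
oracle_chain <- function(prob_list, accuracies, temperature, cap, tau,
                         epsilon = 1e-12) {
  n <- nrow(prob_list[[1]])
  C <- ncol(prob_list[[1]])
  N <- length(prob_list)

  scaled <- lapply(prob_list, function(P) {
    out <- matrix(0, n, C)
    for (r in seq_len(n)) {
      z <- log(P[r, ] + epsilon) / temperature
      e <- exp(z - max(z))
      out[r, ] <- e / sum(e)
    }
    out
  })

  w <- accuracies / sum(accuracies)
  while (max(w) > cap + 1e-15) {
    over <- w > cap + 1e-15
    excess <- sum(w[over] - cap)
    w[over] <- cap
    free <- !over & w > 0
    w[free] <- w[free] + excess * w[free] / sum(w[free])
  }
  w <- w / sum(w)

  glob <- matrix(0, n, C)
  for (i in seq_len(N)) glob <- glob + w[i] * scaled[[i]]
  glob <- glob / rowSums(glob)

  accepted <- logical(n)
  labels <- rep(NA_integer_, n)
  for (r in seq_len(n)) {
    if (max(glob[r, ]) >= tau) {
      accepted[r] <- TRUE
      labels[r] <- which(glob[r, ] == max(glob[r, ]))[1] - 1L
    }
  }
  list(weights = w, global = glob, accepted = accepted, labels = labels)
}

# Loop-based local-outlier-factor oracle (independent of the package's
# vectorised implementation).
oracle_lof <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    ds <- sort(D[i, ])
    kdist[i] <- ds[k]
    nbrs[[i]] <- which(D[i, ] <= kdist[i] + 1e-12)
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in nbrs[[i]]) s <- s + max(kdist[j], D[i, j])
    lrd[i] <- length(nbrs[[i]]) / s
  }
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- mean(lrd[nbrs[[i]]]) / lrd[i]
  out
}
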