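# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration / brute force) kept separate from the package
# code paths it checks.

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1+n2, n1) assignments of the observed values to group 1.
exactMWPValue <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- uOf(seq_len(n1))
  mu <- n1 * length(b) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2L, uOf)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Exact permutation distribution of the Spearman rho of (x, y): two-sided
# p-value over all length(y)! permutations (keep n tiny).
exactSpearmanPValue <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  obs <- cor(x, y, method = "spearman")
  rhos <- vapply(perms(y), function(p) cor(x, p, method = "spearman"),
                 numeric(1))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# All maximal cliques of an undirected graph by exhaustive bitmask dynamic
# programming over the 2^n vertex subsets (n <= 15).
bruteForceMaximalCliques <- function(adj, minSize = 1L) {
  n <- nrow(adj)
  stopifnot(n <= 15L)
  vnames <- rownames(adj)
  adjMask <- vapply(seq_len(n), function(v)
    sum(bitwShiftL(1L, which(adj[v, ] != 0) - 1L)), numeric(1))
  nMask <- bitwShiftL(1L, n)
  isClique <- logical(nMask)
  isClique[1L] <- TRUE  # empty set
  masks <- seq_len(nMask - 1L)
  low <- bitwAnd(masks, -masks)             # lowest set bit
  lowV <- as.integer(round(log2(low))) + 1L # its vertex index
  for (m in masks) {
    rest <- bitwAnd(m, m - 1L)  # m without its lowest bit
    isClique[m + 1L] <- isClique[rest + 1L] &&
      bitwAnd(adjMask[lowV[m]], rest) == rest
  }
  cliques <- masks[isClique[masks + 1L]]
  # maximal: no outside vertex adjacent to every member
  maximal <- vapply(cliques, function(m) {
    for (v in seq_len(n)) {
      vb <- bitwShiftL(1L, v - 1L)
      if (bitwAnd(m, vb) == 0L && bitwAnd(adjMask[v], m) == m)
        return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- lapply(cliques[maximal], function(m)
    sort(vnames[which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)]))
  out <- out[lengths(out) >= minSize]
  key <- vapply(out, paste, character(1), collapse = "|")
  out[order(-lengths(out), key)]
}

# Edge list of a random Erdos-Renyi graph plus its adjacency matrix.
randomGraph <- function(n, p) {
  vnames <- sprintf("v%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(vnames, vnames))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  list(adj = adj,
       edges = data.frame(a = vnames[idx[, 1L]], b = vnames[idx[, 2L]]))
}
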