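# Independent oracles used across the suite.  These are deliberately
# naive re-derivations (explicit loops, exhaustive search) kept separate
# from the package's implementations.

# literal double-loop evaluation of the activity update: for each target i,
# gather upregulation from positive incoming weights, inhibition from the
# magnitudes of negative ones, subtract the flat per-outgoing-edge use
# cost, clamp to [0, 1]
naive_step <- function(W, p, use_coef) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    up <- 0
    down <- 0
    for (j in seq_len(n)) {
      w <- W[j, i]
      if (w > 0) up <- up + w * p[j]
      if (w < 0) down <- down + abs(w) * p[j]
    }
    n_out <- 0
    for (j in seq_len(n)) if (W[i, j] != 0) n_out <- n_out + 1
    x <- p[i] + (1 - p[i]) * up - p[i] * down - use_coef * n_out
    out[i] <- min(max(x, 0), 1)
  }
  out
}

resample_ids <- function(x) x[sample.int(length(x), 1)]

# random legal weight matrix: 1 = detector, n = effector, rest signaling
random_small_W <- function(n, p_edge = 0.5) {
  W <- matrix(ifelse(runif(n^2) < p_edge, runif(n^2, -1, 1), 0), n, n)
  W[1, n] <- 0
  W
}

random_small_net <- function(n, p_edge = 0.5, lineage_id = 1L) {
  stopifnot(n >= 3)
  immune_network(seq_len(n),
                 c("detector", rep("signaling", n - 2), "effector"),
                 random_small_W(n, p_edge), lineage_id = lineage_id)
}

# exhaustive maximum set of detector->effector paths with pairwise
# disjoint interiors: enumerate all simple paths, reduce interiors to
# bitmasks over signaling nodes, then exact DFS over disjoint mask sets
brute_force_distinct_paths <- function(net) {
  n <- length(net$ids)
  d <- which(net$roles == "detector")
  e <- which(net$roles == "effector")
  adj <- net$W != 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  paths <- igraph::all_simple_paths(g, from = d, to = e, mode = "out")
  if (length(paths) == 0) return(0L)
  sig <- setdiff(seq_len(n), c(d, e))
  masks <- unique(vapply(paths, function(p) {
    interior <- setdiff(as.integer(p), c(d, e))
    sum(2^(match(interior, sig) - 1))
  }, numeric(1)))
  best_from <- function(used, remaining) {
    if (length(remaining) == 0) return(0L)
    best <- 0L
    for (k in seq_along(remaining)) {
      m <- remaining[k]
      if (bitwAnd(used, m) == 0) {
        cand <- 1L + best_from(bitwOr(used, m), remaining[-seq_len(k)])
        if (cand > best) best <- cand
      }
    }
    best
  }
  best_from(0L, as.integer(sort(masks)))
}
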