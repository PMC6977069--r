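# Independent brute-force oracles. Each recomputes a quantity by a route
# disjoint from the implementation: Bernoulli convolution for binomial
# tails, adjacency-matrix powers for distances/components, shortest-path
# counts for betweenness.

# binomial distribution by convolving n Bernoulli(p) variables
oracle_binom_tail <- function(k, n, p) {
  dist <- 1
  for (i in seq_len(n)) {
    dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  }
  if (k <= 0) 1 else sum(dist[(k + 1):(n + 1)])
}

oracle_adjacency <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# all-pairs shortest path lengths via matrix powers; Inf if unreachable
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- diag(n)
  for (d in seq_len(n)) {
    P <- P %*% A
    newly <- P > 0 & !is.finite(D)
    D[newly] <- d
  }
  D
}

oracle_components <- function(g) {
  A <- oracle_adjacency(g)
  deg <- rowSums(A)
  keep <- deg > 0
  if (!any(keep)) return(0L)
  A <- A[keep, keep, drop = FALSE]
  D <- oracle_distances(A)
  n <- nrow(D)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (i in seq_len(n)) {
    if (!seen[i]) {
      comps <- comps + 1L
      seen[is.finite(D[i, ])] <- TRUE
    }
  }
  comps
}

oracle_diameter <- function(g) {
  A <- oracle_adjacency(g)
  if (nrow(A) == 0) return(0L)
  D <- oracle_distances(A)
  # largest component = the reachability set with most members
  sizes <- rowSums(is.finite(D))
  members <- which(is.finite(D[which.max(sizes), ]))
  if (length(members) <= 1) return(0L)
  max(D[members, members])
}

# betweenness via shortest-path counts: sigma_st = (A^d)[s,t] counts the
# walks of minimal length, which are exactly the geodesics
oracle_betweenness <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  if (n == 0) return(numeric(0))
  D <- oracle_distances(A)
  pow <- vector("list", n + 1)
  pow[[1]] <- diag(n)
  for (d in seq_len(n)) pow[[d + 1]] <- pow[[d]] %*% A
  sigma <- function(i, j) {
    d <- D[i, j]
    if (!is.finite(d)) return(0)
    pow[[d + 1]][i, j]
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || D[s, t] == 0) next
      st <- sigma(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          b[v] <- b[v] + sigma(s, v) * sigma(v, t) / st
        }
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

oracle_density <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  sum(A) / (n * (n - 1))
}

oracle_centralization <- function(g) {
  A <- oracle_adjacency(g)
  d <- rowSums(A)
  n <- length(d)
  sum(max(d) - d) / ((n - 1) * (n - 2))
}
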