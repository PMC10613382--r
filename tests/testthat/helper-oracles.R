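# Independent brute-force oracles for the graph measures, kept deliberately
# naive: BFS distances, full shortest-path enumeration for betweenness, and
# a dense eigendecomposition for eigenvector centrality.

bf_adjacency <- function(g) {
  m <- as.matrix(igraph::as_adjacency_matrix(g))
  m[m > 0] <- 1
  m
}

bf_dist <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; visited <- s; d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- setdiff(which(colSums(adj[frontier, , drop = FALSE]) > 0), visited)
      if (length(nxt) == 0) break
      D[s, nxt] <- d
      visited <- c(visited, nxt)
      frontier <- nxt
    }
  }
  D
}

bf_degree <- function(adj) rowSums(adj)

bf_density <- function(adj) sum(adj) / (nrow(adj) * (nrow(adj) - 1))

bf_mean_distance <- function(adj) {
  D <- bf_dist(adj)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0) NA_real_ else mean(v)
}

# all shortest paths between s and t as vertex sequences
bf_shortest_paths <- function(adj, D, s, t) {
  recurse <- function(cur) {
    if (cur == t) return(list(t))
    nb <- which(adj[cur, ] == 1 & D[, t] == D[cur, t] - 1)
    out <- list()
    for (v in nb) {
      for (p in recurse(v)) out[[length(out) + 1L]] <- c(cur, p)
    }
    out
  }
  recurse(s)
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- bf_dist(adj)
  bet <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] < 2) next
    paths <- bf_shortest_paths(adj, D, s, t)
    nst <- length(paths)
    for (p in paths) {
      interior <- p[-c(1, length(p))]
      bet[interior] <- bet[interior] + 1 / nst
    }
  }
  bet
}

bf_eigenvector <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  if (n == 0 || sum(adj) == 0) return(out)
  D <- bf_dist(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1L
      comp[is.finite(D[v, ])] <- cid
    }
  }
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  first_vertex <- vapply(big, function(cc) min(which(comp == cc)), numeric(1))
  cc <- big[which.min(first_vertex)]
  idx <- which(comp == cc)
  if (sum(adj[idx, idx]) == 0) return(out)
  ev <- eigen(adj[idx, idx, drop = FALSE], symmetric = TRUE)
  v1 <- abs(ev$vectors[, 1])
  out[idx] <- v1 / max(v1)
  out
}

# named random graph for oracle comparisons
rand_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# brute-force shared-patient counts from an encounters table
bf_shared_counts <- function(encounters, practice_ids) {
  n <- length(practice_ids)
  cnt <- matrix(0, n, n, dimnames = list(practice_ids, practice_ids))
  pats <- lapply(practice_ids, function(pr)
    unique(encounters$patient_id[encounters$practice_id == pr]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cnt[i, j] <- cnt[j, i] <- length(intersect(pats[[i]], pats[[j]]))
  }
  cnt
}
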