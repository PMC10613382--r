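# Node-level centralities, network-level summaries, random-graph baseline
# and specialty-tie composition. All measures are computed on the binary
# (unweighted) projection: each tied practice is weighted equally.

as_graph <- function(net) {
  g <- if (inherits(net, "practice_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a practice_network or igraph object")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

#' Degree centrality
#'
#' Number of distinct practices tied to each practice (unweighted).
#'
#' @param net a `practice_network` (or igraph graph).
#' @return named integer vector, one entry per practice.
#' @export
degree_centrality <- function(net) {
  g <- as_graph(net)
  d <- igraph::degree(g, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Betweenness centrality
#'
#' Standard unnormalized shortest-path betweenness: for every unordered pair
#' (s, t), an intermediate practice v accrues the fraction of shortest s--t
#' paths passing through it; pairs with no connecting path contribute
#' nothing.
#'
#' @param net a `practice_network` (or igraph graph).
#' @return named non-negative numeric vector.
#' @export
betweenness_centrality <- function(net) {
  g <- as_graph(net)
  igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the binary adjacency matrix, rescaled so the
#' maximum value is 1. Eigenvector centrality is ill-defined on a
#' disconnected graph, so it is computed on the largest connected component
#' (ties broken towards the component containing the first practice id) and
#' practices outside that component are assigned 0; component sizes are
#' reported via a message when this happens.
#'
#' @param net a `practice_network` (or igraph graph).
#' @return named numeric vector in `[0, 1]`.
#' @export
eigenvector_centrality <- function(net) {
  g <- as_graph(net)
  n <- igraph::vcount(g)
  out <- setNames(numeric(n), igraph::V(g)$name)
  if (n == 0) return(out)
  if (igraph::ecount(g) == 0) {
    warning("network has no ties: eigenvector centrality set to 0 everywhere")
    return(out)
  }
  comp <- igraph::components(g)
  if (comp$no > 1) {
    biggest <- which(comp$csize == max(comp$csize))
    # tie-break: component containing the earliest vertex
    cid <- biggest[which.min(vapply(biggest, function(b)
      min(which(comp$membership == b)), numeric(1)))]
    message(sprintf(
      "eigenvector centrality computed on the largest component (%d of %d nodes; %d components)",
      max(comp$csize), n, comp$no))
    sub <- igraph::induced_subgraph(g, which(comp$membership == cid))
  } else {
    sub <- g
  }
  if (igraph::ecount(sub) == 0) return(out)
  ev <- power_iteration(igraph::as_adjacency_matrix(sub, sparse = TRUE))
  out[names(ev)] <- ev
  out
}

# Leading eigenvector of a binary symmetric adjacency matrix by power
# iteration on A + I (the shift keeps bipartite spectra from oscillating);
# deterministic uniform start, rescaled to unit maximum.
power_iteration <- function(adj, tol = 1e-10, max_iter = 100000L) {
  adj <- methods::as(Matrix::Matrix(adj, sparse = TRUE), "generalMatrix")
  adj@x[adj@x != 0] <- 1
  n <- nrow(adj)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    x_new <- as.numeric(adj %*% x) + x
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(x_new - x)) < tol) {
      x_new <- abs(x_new)
      return(setNames(x_new / max(x_new), rownames(adj)))
    }
    x <- x_new
  }
  stop(sprintf(
    "eigenvector centrality did not converge to %.1e after %d iterations",
    tol, max_iter))
}

#' Centrality table for a practice network
#'
#' @param net a `practice_network`.
#' @return data frame with columns `practice_id`, `degree`, `betweenness`,
#'   `eigenvector`.
#' @export
centrality_table <- function(net) {
  d <- degree_centrality(net)
  data.frame(practice_id = names(d),
             degree = as.integer(d),
             betweenness = unname(betweenness_centrality(net)[names(d)]),
             eigenvector = unname(eigenvector_centrality(net)[names(d)]),
             stringsAsFactors = FALSE)
}

#' Network density
#'
#' Realized ties over all possible ties, `2 m / (n (n - 1))`.
#'
#' @param net a `practice_network` (or igraph graph).
#' @return density in `[0, 1]`; error for fewer than two nodes.
#' @export
net_density <- function(net) {
  g <- as_graph(net)
  if (igraph::vcount(g) < 2) stop("density is undefined for fewer than 2 nodes")
  igraph::edge_density(g, loops = FALSE)
}

#' Average shortest-path length
#'
#' Mean of the unweighted shortest-path lengths over all unordered pairs of
#' practices that are connected by some path; disconnected pairs are
#' excluded (the usual mean-distance convention). With
#' `largest_component = TRUE` the mean is instead taken within the largest
#' connected component only.
#'
#' @param net a `practice_network` (or igraph graph).
#' @param largest_component restrict to the largest component (default
#'   FALSE).
#' @return mean distance (>= 1), or NA with a warning when no pair is
#'   connected; error for fewer than two nodes.
#' @export
net_mean_distance <- function(net, largest_component = FALSE) {
  g <- as_graph(net)
  if (igraph::vcount(g) < 2)
    stop("mean distance is undefined for fewer than 2 nodes")
  if (largest_component) {
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    if (igraph::vcount(g) < 2) {
      warning("largest component has fewer than 2 nodes: mean distance is NA")
      return(NA_real_)
    }
  }
  if (igraph::ecount(g) == 0) {
    warning("no connected pair of nodes: mean distance is NA")
    return(NA_real_)
  }
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE, weights = NA)
}

#' Random-graph baseline for the average path length
#'
#' Generates `reps` uniform random graphs with exactly the observed number
#' of nodes and edges (G(n, m); a G(n, p) variant matches the expected edge
#' count instead) and summarises their mean distances
#' (connected-pairs convention). Used to compare an observed network's
#' connectivity with random wiring at the same size.
#'
#' @param n_nodes,n_edges size of the graphs.
#' @param reps number of random graphs (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param model `"gnm"` (fixed edge count, default) or `"gnp"`.
#' @return list with `mean`, `sd` of the per-graph mean distances, and the
#'   vector `values`.
#' @export
random_graph_baseline <- function(n_nodes, n_edges, reps = 1000, seed = NULL,
                                  model = c("gnm", "gnp")) {
  model <- match.arg(model)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < 0 || n_edges > max_edges)
    stop(sprintf("infeasible edge count: %d not in [0, %d]", n_edges, max_edges))
  if (reps < 1) stop("reps must be >= 1")
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      g <- if (model == "gnm") {
        igraph::sample_gnm(n_nodes, n_edges)
      } else {
        igraph::sample_gnp(n_nodes, if (max_edges > 0) n_edges / max_edges else 0)
      }
      if (igraph::ecount(g) == 0) return(NA_real_)
      igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    }, numeric(1))
  })
  list(mean = mean(vals, na.rm = TRUE),
       sd = stats::sd(vals, na.rm = TRUE),
       values = vals)
}

#' Specialty composition of network ties
#'
#' First statistic: percentage of ties whose two endpoint practices share a
#' specialty code. Second: among those same-specialty ties, the percentage
#' whose shared specialty is a primary-care specialty. Both are reported as
#' percentages in `[0, 100]`; with no ties (or no same-specialty tie for the
#' second), the statistic is undefined and reported as NA.
#'
#' @param net a `practice_network` with node specialty attributes.
#' @param primary_care specialty codes counted as primary care.
#' @return list with `pct_same_specialty` and `pct_same_specialty_pcp`.
#' @export
specialty_tie_stats <- function(net, primary_care = pcp_specialties()) {
  g <- as_graph(net)
  if (is.null(igraph::V(g)$specialty))
    stop("network has no node specialty attribute")
  if (igraph::ecount(g) == 0) {
    warning("network has no ties: specialty tie statistics undefined")
    return(list(pct_same_specialty = NA_real_, pct_same_specialty_pcp = NA_real_))
  }
  ends <- igraph::as_edgelist(g, names = FALSE)
  spec <- igraph::V(g)$specialty
  same <- spec[ends[, 1]] == spec[ends[, 2]]
  pct_same <- 100 * mean(same)
  if (!any(same)) {
    return(list(pct_same_specialty = 0, pct_same_specialty_pcp = NA_real_))
  }
  shared <- spec[ends[same, 1]]
  list(pct_same_specialty = pct_same,
       pct_same_specialty_pcp = 100 * mean(shared %in% primary_care))
}

#' Network-level summary
#'
#' One row of network-level measures: node and tie counts, density, mean
#' distance, the random-graph baseline of the mean distance, and the
#' specialty-tie percentages.
#'
#' @param net a `practice_network`.
#' @param baseline_reps random graphs for the baseline (default 1000).
#' @param seed seed for the baseline.
#' @return one-row data frame.
#' @export
network_summary <- function(net, baseline_reps = 1000, seed = NULL) {
  g <- as_graph(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  base <- random_graph_baseline(n, m, reps = baseline_reps, seed = seed)
  ties <- specialty_tie_stats(net)
  data.frame(region = net$region %||% NA_character_,
             n_nodes = n, n_edges = m,
             density = net_density(net),
             mean_distance = net_mean_distance(net),
             random_baseline_mean_distance = base$mean,
             random_baseline_sd = base$sd,
             pct_same_specialty_ties = ties$pct_same_specialty,
             pct_same_specialty_ties_primary_care = ties$pct_same_specialty_pcp,
             stringsAsFactors = FALSE)
}
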