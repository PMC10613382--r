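# Patient-sharing practice network: bipartite incidence -> weighted
# one-mode projection with a shared-patient tie threshold.

#' Shared-patient counts between practices
#'
#' Entry (i, j) is the number of distinct patients with at least one
#' encounter at practice i and at least one at practice j; repeat encounters
#' by the same patient do not add weight. Computed as the cross-product of
#' the sparse patient-by-practice incidence matrix. The dataset should
#' already be restricted to a single region and year (see
#' [filter_for_network()]); an error is raised if practices from several
#' regions are present.
#'
#' @param x a [claims_dataset()].
#' @return sparse symmetric matrix (class `dsCMatrix`) over all practices in
#'   the dataset, zero diagonal.
#' @export
shared_patient_counts <- function(x) {
  stopifnot(inherits(x, "claims_dataset"))
  if (length(unique(x$practices$region)) > 1) {
    stop("shared_patient_counts expects a single-region dataset; ",
         "split by region first")
  }
  practice_ids <- sort(x$practices$practice_id)
  pp <- unique(x$encounters[c("patient_id", "practice_id")])
  patient_ids <- sort(unique(pp$patient_id))
  if (nrow(pp) == 0) {
    n <- length(practice_ids)
    counts <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                   dims = c(n, n), symmetric = TRUE)
    dimnames(counts) <- list(practice_ids, practice_ids)
    return(counts)
  }
  inc <- Matrix::sparseMatrix(
    i = match(pp$patient_id, patient_ids),
    j = match(pp$practice_id, practice_ids),
    x = 1,
    dims = c(length(patient_ids), length(practice_ids)),
    dimnames = list(patient_ids, practice_ids))
  counts <- Matrix::crossprod(inc)
  diag(counts) <- 0
  Matrix::forceSymmetric(Matrix::drop0(counts))
}

#' Project shared-patient counts into a practice network
#'
#' Keeps an edge between two practices when their shared-patient count meets
#' the tie threshold (inclusive `>=` by default); isolated practices remain
#' in the node set. Edge weights carry the raw shared-patient counts, but all
#' downstream centrality and distance computations treat the network as
#' binary (each tied practice weighted equally).
#'
#' @param counts symmetric shared-patient count matrix
#'   (from [shared_patient_counts()]).
#' @param threshold minimum shared patients for a tie (default 8; at least 1).
#' @param node_attrs optional data frame with `practice_id`, `specialty`,
#'   `region` used to attach node attributes (typically the practices table).
#' @param comparison `"geq"` (count >= threshold, default) or `"gt"`.
#' @param region optional region label stored on the network.
#' @return a `practice_network` object.
#' @export
project_network <- function(counts, threshold = 8, node_attrs = NULL,
                            comparison = c("geq", "gt"), region = NULL) {
  comparison <- match.arg(comparison)
  if (threshold < 1) stop("tie threshold must be >= 1")
  adj <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  keep <- if (comparison == "geq") adj@x >= threshold else adj@x > threshold
  adj@x[!keep] <- 0
  adj <- Matrix::drop0(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(node_attrs)) {
    idx <- match(igraph::V(g)$name, node_attrs$practice_id)
    igraph::V(g)$specialty <- node_attrs$specialty[idx]
    igraph::V(g)$region <- node_attrs$region[idx]
    igraph::V(g)$pcp <- as.integer(node_attrs$specialty[idx] %in% pcp_specialties())
    if (is.null(region) && nrow(node_attrs) > 0)
      region <- node_attrs$region[idx][1]
  }
  structure(list(graph = g, threshold = threshold, comparison = comparison,
                 region = region),
            class = "practice_network")
}

#' Build a practice network for one region
#'
#' Convenience wrapper: subsets the dataset to `region`, counts shared
#' patients and projects at the tie threshold.
#'
#' @param x a (filtered) [claims_dataset()].
#' @param region region label; defaults to the single region present.
#' @inheritParams project_network
#' @return a `practice_network`.
#' @export
build_practice_network <- function(x, region = NULL, threshold = 8,
                                   comparison = c("geq", "gt")) {
  regs <- regions(x)
  if (is.null(region)) {
    if (length(regs) != 1) stop("dataset has several regions; give `region`")
    region <- regs
  }
  xr <- subset_region(x, region)
  counts <- shared_patient_counts(xr)
  project_network(counts, threshold = threshold, node_attrs = xr$practices,
                  comparison = match.arg(comparison), region = region)
}

#' @export
print.practice_network <- function(x, ...) {
  cat(sprintf("<practice_network> region %s: %d practices, %d ties (threshold %s %d shared patients)\n",
              x$region %||% "?", igraph::vcount(x$graph),
              igraph::ecount(x$graph),
              if (x$comparison == "geq") ">=" else ">", x$threshold))
  invisible(x)
}

#' Export a practice network
#'
#' `write_edge_list()` writes a CSV with columns `practice_a`, `practice_b`,
#' `shared_patients`; `write_network_graphml()` writes GraphML with node
#' attributes.
#'
#' @param net a `practice_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "practice_network"))
  el <- igraph::as_edgelist(net$graph)
  df <- data.frame(practice_a = el[, 1], practice_b = el[, 2],
                   shared_patients = if (igraph::ecount(net$graph) > 0)
                     igraph::E(net$graph)$weight else numeric(),
                   stringsAsFactors = FALSE)
  df <- df[order(df$practice_a, df$practice_b), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "practice_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
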