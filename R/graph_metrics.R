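#' Convert edge weights to lengths
#'
#' Shortest-path computations on association networks need a length that
#' decreases as connection strength increases.  The default is the
#' reciprocal \code{1/w} (the usual convention for weighted connectivity
#' matrices); \code{-log(w)} is available as an alternative for weights in
#' (0, 1].
#'
#' @param w symmetric weight matrix (weights in (0, 1]; 0 = no edge) or
#'   single numeric vector of weights
#' @param transform \code{"inverse"} or \code{"neglog"}
#' @return matrix (or vector) of lengths; absent edges become \code{Inf}
#' @export
weights_to_lengths <- function(w, transform = c("inverse", "neglog")) {
  transform <- match.arg(transform)
  if (any(w < 0, na.rm = TRUE))
    stop("weights must be non-negative", call. = FALSE)
  d <- if (transform == "inverse") 1 / w else -log(w)
  d[w == 0] <- Inf
  d
}

# validate + normalise a weight matrix: symmetric, zero diagonal
as_weight_matrix <- function(w) {
  stop_if_not(is.matrix(w) && nrow(w) == ncol(w), "w must be square")
  stop_if_not(max(abs(w - t(w))) < 1e-12, "w must be symmetric")
  diag(w) <- 0
  stop_if_not(all(w >= 0), "weights must be non-negative")
  w
}

#' Weighted characteristic path length
#'
#' The mean shortest-path distance over all ordered node pairs,
#' \deqn{L^w = \frac{1}{n} \sum_{i} \frac{\sum_{j \ne i} d^w_{ij}}{n - 1},}
#' where \eqn{d^w_{ij}} is the shortest path over edge lengths derived from
#' the weights (default \code{1/w}).  Smaller values indicate a more
#' integrated network.  Self-coherence diagonals are zeroed before use.
#'
#' @param w symmetric weight matrix (e.g. a band coherence matrix)
#' @param transform length transform, see \code{\link{weights_to_lengths}}
#' @return characteristic path length (scalar)
#' @export
characteristic_path_length <- function(w, transform = "inverse") {
  w <- as_weight_matrix(w)
  n <- nrow(w)
  stop_if_not(n >= 2, "need at least 2 nodes")
  d <- weights_to_lengths(w, transform)
  d[!is.finite(d)] <- 0                      # igraph: 0 = missing edge
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  if (any(!is.finite(D[row(D) != col(D)])))
    stop("infinite path length: graph is disconnected", call. = FALSE)
  sum(D[row(D) != col(D)]) / (n * (n - 1))
}

#' Weighted clustering coefficient
#'
#' Per node, the geometric-mean triangle intensity
#' \deqn{t_i^w = \tfrac12 \sum_{j,h} (w_{ij} w_{ih} w_{jh})^{1/3}}
#' normalised by the number of neighbour pairs,
#' \eqn{C_i^w = 2 t_i^w / (k_i (k_i - 1))} with \eqn{k_i} the node degree;
#' nodes with fewer than two neighbours contribute 0.  The network value is
#' the node average, and lies in [0, 1] whenever weights do.
#'
#' @param w symmetric weight matrix with weights in [0, 1]
#' @return list: \code{average}, \code{per_node}, \code{triangles}
#'   (\eqn{t_i^w}), \code{degree}
#' @export
clustering_coefficient <- function(w) {
  w <- as_weight_matrix(w)
  n <- nrow(w)
  stop_if_not(n >= 3, "need at least 3 nodes")
  stop_if_not(all(w <= 1), "weights must not exceed 1")
  cr <- w^(1 / 3)
  t_i <- diag(cr %*% cr %*% cr) / 2
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  names(c_i) <- rownames(w)
  list(average = mean(c_i), per_node = c_i, triangles = t_i, degree = k)
}

#' Graph metrics for every frequency band
#'
#' Runs \code{\link{characteristic_path_length}} and
#' \code{\link{clustering_coefficient}} on each band's coherence matrix.
#' Networks are analysed fully weighted by default; an optional
#' proportional threshold retains only the strongest fraction of edges
#' first (an error is raised if pruning disconnects a band's graph).
#'
#' @param cms a \code{coherence_set} (or named list of weight matrices)
#' @param density optional proportional edge density in (0, 1]
#' @param transform length transform for the path-length step
#' @return data.frame with one row per band: \code{band}, \code{cpl},
#'   \code{avg_cc}
#' @export
metrics_for_bands <- function(cms, density = NULL, transform = "inverse") {
  bands <- names(cms)
  stop_if_not(!is.null(bands), "cms must be a named list of matrices")
  rows <- lapply(bands, function(b) {
    w <- as_weight_matrix(cms[[b]])
    if (!is.null(density)) w <- prune_to_density(w, density)
    data.frame(band = b,
               cpl = characteristic_path_length(w, transform),
               avg_cc = clustering_coefficient(w)$average)
  })
  do.call(rbind, rows)
}

# keep the strongest `density` fraction of off-diagonal edges
prune_to_density <- function(w, density) {
  stop_if_not(density > 0 && density <= 1, "density must be in (0, 1]")
  ut <- upper.tri(w)
  vals <- w[ut]
  keep_n <- ceiling(density * length(vals))
  thr <- sort(vals, decreasing = TRUE)[keep_n]
  w[w < thr] <- 0
  w
}
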