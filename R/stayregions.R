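#' Aggregate stay-points into stay-regions on a regular grid
#'
#' Lays a regular axis-aligned grid of spacing `G` over the stay-points,
#' anchored at the minimum (x, y) corner of their bounding box, and assigns
#' every stay-point to the cell containing it. Cells are half-open,
#' `[x0 + k*G, x0 + (k+1)*G)`, so boundary points are resolved
#' deterministically. The region centre is the cell centre. Because the
#' anchor travels with the data, assignments are invariant under rigid
#' translation of all coordinates.
#'
#' @param staypoints a [detect_staypoints()] result, or any data.frame with
#'   numeric `x` and `y` columns (one row per stay-point).
#' @param G grid spacing in metres, `> 0`.
#' @return object of class `region_assignment`: list with `method`
#'   (`"grid"`), `parameter` (`G`), `labels` (dense integer region id per
#'   stay-point, ordered by first appearance), and `centres` (data.frame
#'   `region, x, y`).
#' @export
grid_aggregate <- function(staypoints, G) {
  if (G <= 0) stopf("G must be positive")
  n <- nrow(staypoints)
  if (n < 1) stopf("need at least one stay-point")
  x0 <- min(staypoints$x)
  y0 <- min(staypoints$y)
  kx <- floor((staypoints$x - x0) / G)
  ky <- floor((staypoints$y - y0) / G)
  key <- paste(kx, ky)
  labels <- match(key, unique(key))
  first <- !duplicated(labels)
  centres <- data.frame(
    region = labels[first],
    x = x0 + (kx[first] + 0.5) * G,
    y = y0 + (ky[first] + 0.5) * G
  )
  centres <- centres[order(centres$region), , drop = FALSE]
  rownames(centres) <- NULL
  new_region_assignment("grid", G, labels, centres)
}

#' Aggregate stay-points into stay-regions by density clustering
#'
#' Density-based clustering with a minimum cluster size of one: every
#' stay-point belongs to a cluster, and clusters are exactly the connected
#' components of the graph joining stay-points at planar distance strictly
#' less than `eps`. With no minimum-size constraint there is no noise label.
#' Region centres are the centroids of member stay-points.
#'
#' @param staypoints as in [grid_aggregate()].
#' @param eps neighbourhood radius in metres, `> 0`; distances strictly below
#'   `eps` join points.
#' @return object of class `region_assignment` (`method = "dbscan"`,
#'   `parameter = eps`).
#' @export
dbscan_aggregate <- function(staypoints, eps) {
  if (eps <= 0) stopf("eps must be positive")
  n <- nrow(staypoints)
  if (n < 1) stopf("need at least one stay-point")
  if (n == 1) {
    centres <- data.frame(region = 1L, x = staypoints$x, y = staypoints$y)
    return(new_region_assignment("dbscan", eps, 1L, centres))
  }
  d <- stats::dist(cbind(staypoints$x, staypoints$y))
  adj <- which(as.vector(d) < eps)
  # row/col indices of the lower-triangle dist entries
  pair <- dist_pair_index(n, adj)
  g <- igraph::graph_from_edgelist(pair, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  labels <- match(comp, unique(comp))  # dense ids by first appearance
  centres <- data.frame(
    region = sort(unique(labels)),
    x = as.vector(tapply(staypoints$x, labels, mean)),
    y = as.vector(tapply(staypoints$y, labels, mean))
  )
  rownames(centres) <- NULL
  new_region_assignment("dbscan", eps, labels, centres)
}

# Convert linear indices of a lower-triangle `dist` vector into an
# edge matrix of (i, j) point indices.
dist_pair_index <- function(n, lin) {
  if (length(lin) == 0) return(matrix(integer(0), ncol = 2))
  # column j (1-based) occupies entries after offset (j-1)*(n - j/2)
  j <- rep(seq_len(n - 1), times = (n - 1):1)
  i <- sequence((n - 1):1) + j
  cbind(j[lin], i[lin])
}

new_region_assignment <- function(method, parameter, labels, centres) {
  structure(
    list(method = method, parameter = parameter,
         labels = as.integer(labels), centres = centres),
    class = "region_assignment"
  )
}

#' Geometric properties of stay-regions
#'
#' For each region: the number of member stay-points, the convex-hull area of
#' their coordinates (0 for fewer than three or collinear members), and
#' whether the region consists of a single stay-point.
#'
#' @param staypoints as in [grid_aggregate()].
#' @param assignment a `region_assignment` for those stay-points.
#' @return data.frame with columns `region, n_staypoints, area,
#'   is_single_point`.
#' @export
region_geometry <- function(staypoints, assignment) {
  stopifnot(inherits(assignment, "region_assignment"))
  labels <- assignment$labels
  if (length(labels) != nrow(staypoints)) stopf("assignment does not match stay-points")
  regions <- sort(unique(labels))
  out <- data.frame(
    region = regions,
    n_staypoints = as.vector(table(factor(labels, levels = regions))),
    area = vapply(regions, function(r) {
      hull_area(staypoints$x[labels == r], staypoints$y[labels == r])
    }, numeric(1))
  )
  out$is_single_point <- out$n_staypoints == 1L
  out
}

# Convex hull area by the shoelace formula; degenerate hulls get 0.
hull_area <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  xs <- x[h]; ys <- y[h]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

#' Log-spaced spatial aggregation parameters
#'
#' The sweep grid used for both the grid spacing G and the clustering radius
#' eps: `n` values evenly spaced on a log scale from `10^lo_exp` to
#' `10^hi_exp` inclusive.
#'
#' @param n number of values (default 30).
#' @param lo_exp,hi_exp base-10 exponents of the endpoints (defaults 1
#'   and 4.8).
#' @return increasing numeric vector of length `n`, in metres.
#' @export
parameter_sweep_values <- function(n = 30, lo_exp = 1, hi_exp = 4.8) {
  if (n < 2) stopf("n must be >= 2")
  10^seq(lo_exp, hi_exp, length.out = n)
}
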