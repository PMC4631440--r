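#' Mode of the distribution from maximum network degree
#'
#' The mode M is the value whose node attains the maximum degree. When
#' several values tie at the maximum degree, M is the arithmetic mean of all
#' tied values (generalising the two-way average used for bimodal real data,
#' e.g. two states at degree 11 averaging to 13.13). A boundary flag marks
#' modes lying within one zeta of the sample minimum or maximum, where
#' edge-of-support pileup can fabricate a spurious peak (exponential or
#' power-law data).
#'
#' @param net an `nb_network`.
#' @return an object of class `nb_mode`: `mode_value`, `max_degree`,
#'   `tied_values`, `boundary_flag`.
#' @export
mode_estimate <- function(net) {
  stopifnot(inherits(net, "nb_network"))
  max_degree <- max(net$degrees)
  tied <- net$values[net$degrees == max_degree]
  mode_value <- mean(tied)
  structure(
    list(mode_value = mode_value,
         max_degree = as.integer(max_degree),
         tied_values = sort(tied),
         boundary_flag = boundary_check(mode_value,
                                        nb_sample(net$values, net$label),
                                        net$zeta)),
    class = "nb_mode"
  )
}

#' @export
print.nb_mode <- function(x, ...) {
  cat(sprintf("<nb_mode: M = %.4f (degree %d, %d tied)%s>\n",
              x$mode_value, x$max_degree, length(x$tied_values),
              if (x$boundary_flag) ", boundary artifact suspected" else ""))
  invisible(x)
}

#' Flag a mode lying at the edge of the sample's support
#'
#' The degree curve piles up near the minimum or maximum of distributions
#' without an interior mode (exponential, power law): any value within zeta
#' of the support edge can only gather neighbours from one side, so an
#' apparent peak there is suspect. "Close to the boundary" is
#' operationalised as within one zeta of the sample minimum or maximum.
#'
#' @param mode_value candidate mode (value units).
#' @param sample the sample the mode came from.
#' @param zeta the half-width in force.
#' @return `TRUE` if the mode lies within `zeta` of min or max.
#' @export
boundary_check <- function(mode_value, sample, zeta) {
  sample <- as_nb_sample(sample)
  if (zeta < 0) nb_abort("zeta must be non-negative", "netfreq_invalid_parameter")
  rng <- range(sample$values)
  mode_value <= rng[1] + zeta || mode_value >= rng[2] - zeta
}

#' Local modes of the degree-versus-value curve
#'
#' A first automated pass over the binless histogram: plateaux of the degree
#' curve (over the sorted values) that strictly exceed both neighbours are
#' candidate peaks; a peak is kept when its degree exceeds the lowest degree
#' between it and the adjacent peak (or the support edge) on *both* sides by
#' at least `min_prominence_frac * max_degree`. The global mode is always
#' reported first regardless of prominence; remaining peaks follow in
#' decreasing degree order. Visual inspection of the curve remains the
#' authoritative check for secondary modes — this helper only shortlists.
#'
#' @param net an `nb_network`.
#' @param min_prominence_frac minimum prominence as a fraction of the
#'   maximum degree (default 0.10; a package convention, not a quantity with
#'   an external definition).
#' @return a list of `nb_mode` objects, global mode first.
#' @export
local_modes <- function(net, min_prominence_frac = 0.10) {
  stopifnot(inherits(net, "nb_network"))
  if (min_prominence_frac < 0 || min_prominence_frac > 1) {
    nb_abort("min_prominence_frac must be in [0, 1]",
             "netfreq_invalid_parameter")
  }
  ord <- order(net$values)
  v <- net$values[ord]
  d <- net$degrees[ord]
  n <- length(d)
  global <- mode_estimate(net)

  # collapse consecutive equal degrees into plateaux
  runs <- rle(d)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  m <- length(runs$values)
  is_peak <- vapply(seq_len(m), function(i) {
    left <- if (i == 1) -Inf else runs$values[i - 1]
    right <- if (i == m) -Inf else runs$values[i + 1]
    runs$values[i] > left && runs$values[i] > right
  }, logical(1))
  peak_idx <- which(is_peak)
  maxdeg <- max(d)
  thr <- min_prominence_frac * maxdeg

  # topographic prominence: on each side, the lowest degree between the peak
  # and the first strictly higher run (or the curve end); a noise bump beside
  # a taller peak is separated from it by a shallow dip and scores low.
  side_min <- function(p, step) {
    lo <- runs$values[p]
    i <- p + step
    while (i >= 1 && i <= m) {
      if (runs$values[i] > runs$values[p]) return(lo)
      lo <- min(lo, runs$values[i])
      i <- i + step
    }
    lo
  }
  keep <- list()
  for (p in peak_idx) {
    prom <- runs$values[p] - max(side_min(p, -1L), side_min(p, 1L))
    vals <- v[starts[p]:ends[p]]
    res <- structure(
      list(mode_value = mean(vals),
           max_degree = as.integer(runs$values[p]),
           tied_values = vals,
           boundary_flag = boundary_check(mean(vals),
                                          nb_sample(net$values, net$label),
                                          net$zeta)),
      class = "nb_mode")
    is_global_peak <- runs$values[p] == maxdeg
    if (is_global_peak || prom >= thr) {
      keep[[length(keep) + 1L]] <- res
    }
  }
  if (length(keep) == 0) {
    return(list(global))
  }
  degs <- vapply(keep, function(r) r$max_degree, integer(1))
  keep <- keep[order(-degs, vapply(keep, function(r) r$mode_value, numeric(1)))]
  # merge all global-degree peaks into the single tie-averaged global mode
  keep <- Filter(function(r) r$max_degree < global$max_degree, keep)
  c(list(global), keep)
}

# ---- shortest paths -------------------------------------------------------

spread_result <- function(diameter, avg_path_length, computable = TRUE) {
  structure(
    list(diameter = if (computable) as.integer(diameter) else NA_integer_,
         avg_path_length = if (computable) avg_path_length else NA_real_,
         computable = computable),
    class = "nb_spread")
}

#' @export
print.nb_spread <- function(x, ...) {
  if (!x$computable) {
    cat("<nb_spread: not computable (edgeless network)>\n")
  } else {
    cat(sprintf("<nb_spread: D = %d, L_avg = %.4f>\n",
                x$diameter, x$avg_path_length))
  }
  invisible(x)
}

#' Network spread via breadth-first shortest paths (reference)
#'
#' All-pairs hop distances by breadth-first search. L_avg is the mean hop
#' length over all *connected* unordered pairs (pairs in different clusters
#' are excluded — their path length is infinite); the diameter D is the
#' longest shortest path within the largest cluster. D measures spread like
#' a range, L_avg like a standard deviation, both in hops of size <= 2*zeta.
#' This is the reference route (backed by igraph BFS on the explicit edge
#' set); [shortest_paths_interval()] computes the same quantities in
#' near-linear time from the sorted structure.
#'
#' @param net an `nb_network` (practical up to a few thousand nodes; the
#'   adjacency is materialised).
#' @return an `nb_spread`: `diameter`, `avg_path_length`, `computable`.
#' @export
shortest_paths_bfs <- function(net) {
  stopifnot(inherits(net, "nb_network"))
  if (net$edge_count == 0) return(spread_result(NA, NA, computable = FALSE))
  if (net$n > 3000) {
    nb_abort("BFS reference path is capped at n = 3000; use shortest_paths_interval",
             "netfreq_invalid_parameter")
  }
  x <- net$values
  A <- abs(outer(x, x, "-")) <= net$zeta
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  dmat <- igraph::distances(g)   # unweighted => BFS
  ut <- dmat[upper.tri(dmat)]
  finite <- ut[is.finite(ut)]
  giant <- which(net$cluster_labels == net$giant_cluster)
  dsub <- dmat[giant, giant, drop = FALSE]
  spread_result(max(dsub), mean(finite))
}

#' Network spread via greedy interval-graph shortest paths (fast)
#'
#' The similarity network of 1-D data is a unit interval graph, on which the
#' greedy farthest-reach walk is optimal: from the current node, jump to the
#' rightmost value within zeta until the target is covered. For each source
#' (in sorted order) the distance to every node on its right is a step
#' function whose breakpoints are successive farthest reaches, so all-pairs
#' sums accumulate in O(total hops). Results equal [shortest_paths_bfs()]
#' exactly.
#'
#' @param net an `nb_network`.
#' @return an `nb_spread`: `diameter`, `avg_path_length`, `computable`.
#' @export
shortest_paths_interval <- function(net) {
  stopifnot(inherits(net, "nb_network"))
  if (net$edge_count == 0) return(spread_result(NA, NA, computable = FALSE))
  ord <- order(net$values)
  s <- net$values[ord]
  lab <- net$cluster_labels[ord]
  n <- length(s)
  reach <- reach_upper(s, net$zeta)  # farthest sorted index within zeta
  cluster_end <- stats::ave(seq_len(n), lab, FUN = max)  # last index of i's run
  total_len <- 0
  total_pairs <- 0
  diameter <- 0L
  giant <- net$giant_cluster
  for (i in seq_len(n - 1)) {
    if (reach[i] <= i) next          # no neighbour to the right within zeta
    ce <- cluster_end[i]             # reach never crosses a gap > zeta
    r <- i
    hops <- 0L
    while (r < ce) {
      nxt <- reach[r]
      if (nxt <= r) break
      hops <- hops + 1L
      total_len <- total_len + hops * (nxt - r)
      total_pairs <- total_pairs + (nxt - r)
      r <- nxt
    }
    if (lab[i] == giant && hops > diameter) diameter <- hops
  }
  if (total_pairs == 0) return(spread_result(NA, NA, computable = FALSE))
  spread_result(diameter, total_len / total_pairs)
}
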