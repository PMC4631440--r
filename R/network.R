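#' Build the +/-zeta similarity network of a sample
#'
#' Two values i != j are linked when |x_i - x_j| <= zeta. The diagonal is
#' excluded (simple graph), so an isolated value has degree 0 and a sample
#' of n exact duplicates forms a clique of degree n - 1 at any zeta >= 0.
#' Connectivity of this graph has a closed form: clusters are exactly the
#' maximal runs of the sorted values in which every consecutive gap is
#' <= zeta (a unit-interval graph), which the fast path exploits.
#'
#' @param sample an [nb_sample()] (or a bare numeric vector).
#' @param zeta non-negative half-width of the similarity window, in value
#'   units.
#' @param method `"fast"` (sorted binary-search degrees and gap-run clusters,
#'   O(n log n)) or `"reference"` (literal double loop over the adjacency
#'   rule, O(n^2), intended as the testing oracle; refuses n > 1000).
#' @return an object of class `nb_network`: `values` (input order), `zeta`,
#'   `degrees`, `edge_count`, `cluster_labels` (1-based, ordered by each
#'   cluster's smallest member), `giant_size`, `giant_cluster` (the label of
#'   the largest cluster, ties broken toward the cluster holding the smallest
#'   value), `n`, `label`.
#' @examples
#' net <- build_network(nb_sample(c(1, 2, 4)), zeta = 1)
#' net$degrees      # 1 1 0
#' net$edge_count   # 1
#' @export
build_network <- function(sample, zeta, method = c("fast", "reference")) {
  method <- match.arg(method)
  switch(method,
         fast = build_network_fast(sample, zeta),
         reference = build_network_reference(sample, zeta))
}

check_network_args <- function(sample, zeta) {
  sample <- as_nb_sample(sample)
  if (!is.numeric(zeta) || length(zeta) != 1 || !is.finite(zeta)) {
    nb_abort("zeta must be a single finite number", "netfreq_invalid_parameter")
  }
  if (zeta < 0) {
    nb_abort("zeta must be non-negative", "netfreq_invalid_parameter")
  }
  sample
}

# Relabel an arbitrary component labelling so that clusters are numbered
# 1..k by their smallest member value; deterministic and order-independent.
canonical_labels <- function(values, membership) {
  mins <- tapply(values, membership, min)
  new_of_old <- rank(mins, ties.method = "first")
  labels <- as.integer(new_of_old[as.character(membership)])
  labels
}

finish_network <- function(sample, zeta, degrees, edge_count, labels) {
  sizes <- tabulate(labels)
  giant_size <- max(sizes)
  # ties toward the cluster containing the smallest value: labels are
  # canonical (ordered by minimum member), so the smallest qualifying label
  giant_cluster <- which(sizes == giant_size)[1]
  structure(
    list(values = sample$values, zeta = zeta,
         degrees = as.integer(degrees), edge_count = as.numeric(edge_count),
         cluster_labels = as.integer(labels),
         giant_size = as.integer(giant_size),
         giant_cluster = as.integer(giant_cluster),
         n = sample$n, label = sample$label),
    class = "nb_network"
  )
}

#' @rdname build_network
#' @export
build_network_reference <- function(sample, zeta) {
  sample <- check_network_args(sample, zeta)
  x <- sample$values
  n <- sample$n
  if (n > 1000) {
    nb_abort("reference (O(n^2)) network construction is capped at n = 1000; use the fast method",
             "netfreq_invalid_parameter")
  }
  A <- abs(outer(x, x, "-")) <= zeta
  diag(A) <- FALSE
  degrees <- rowSums(A)
  edge_count <- sum(degrees) / 2
  if (n == 1) {
    labels <- 1L
  } else {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    labels <- canonical_labels(x, igraph::components(g)$membership)
  }
  finish_network(sample, zeta, degrees, edge_count, labels)
}

#' @rdname build_network
#' @export
build_network_fast <- function(sample, zeta) {
  sample <- check_network_args(sample, zeta)
  ord <- order(sample$values)
  net_from_sorted(sample, zeta, ord)
}

# Index of the rightmost sorted value with s_j - s_i <= zeta, for every i.
# findInterval(s + zeta, s) is only a first guess: s_i + zeta can round to
# the wrong side of a boundary value, so the guess is nudged until it agrees
# with the difference semantics |s_j - s_i| <= zeta used everywhere else
# (the nudge loops run at most once or twice, on exact-boundary ties).
reach_upper <- function(s, zeta) {
  n <- length(s)
  hi <- findInterval(s + zeta, s)
  repeat {
    adv <- hi < n & (s[pmin(hi + 1L, n)] - s) <= zeta
    if (!any(adv)) break
    hi[adv] <- hi[adv] + 1L
  }
  repeat {
    bck <- (s[hi] - s) > zeta
    if (!any(bck)) break
    hi[bck] <- hi[bck] - 1L
  }
  hi
}

# count of sorted values with s_i - s_j > zeta (strictly left of i's window)
reach_lower <- function(s, zeta) {
  n <- length(s)
  lo <- findInterval(s - zeta, s, left.open = TRUE)
  repeat {
    adv <- lo < n & (s - s[pmin(lo + 1L, n)]) > zeta
    if (!any(adv)) break
    lo[adv] <- lo[adv] + 1L
  }
  repeat {
    bck <- lo >= 1L & (s - s[pmax(lo, 1L)]) <= zeta
    if (!any(bck)) break
    lo[bck] <- lo[bck] - 1L
  }
  lo
}

# Fast-path core on a precomputed sort order (reused across a zeta sweep).
net_from_sorted <- function(sample, zeta, ord) {
  x <- sample$values
  n <- sample$n
  s <- x[ord]
  # degree of s_i = #{j: s_i - zeta <= s_j <= s_i + zeta} - 1
  hi <- reach_upper(s, zeta)
  lo <- reach_lower(s, zeta)
  deg_sorted <- hi - lo - 1L
  edge_count <- sum(deg_sorted) / 2
  # clusters: maximal runs of sorted values with consecutive gap <= zeta
  if (n == 1) {
    lab_sorted <- 1L
  } else {
    lab_sorted <- cumsum(c(1L, as.integer(diff(s) > zeta)))
  }
  degrees <- integer(n)
  labels <- integer(n)
  degrees[ord] <- deg_sorted
  labels[ord] <- lab_sorted   # already ordered by smallest member
  finish_network(sample, zeta, degrees, edge_count, labels)
}

#' Giant-cluster proportion p_g = V_g / V
#'
#' The fraction of values belonging to the largest connected cluster of the
#' similarity network; the quantity whose stability over a zeta grid drives
#' bandwidth selection.
#'
#' @param net an `nb_network`.
#' @return a real in `[0, 1]`.
#' @export
giant_cluster_proportion <- function(net) {
  stopifnot(inherits(net, "nb_network"))
  net$giant_size / net$n
}

#' @export
print.nb_network <- function(x, ...) {
  cat(sprintf(
    "<nb_network '%s': V = %d, E = %g, zeta = %g, clusters = %d, p_g = %.4f>\n",
    x$label, x$n, x$edge_count, x$zeta, max(x$cluster_labels),
    giant_cluster_proportion(x)))
  invisible(x)
}
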