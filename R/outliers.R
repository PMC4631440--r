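#' Detect outliers as values outside the giant cluster
#'
#' At the selected zeta, values that fail to join the largest cluster have
#' low or nil degree and are flagged as outliers; the giant-cluster members
#' form the retained sample (input order preserved). Because no edge crosses
#' clusters, removing outliers cannot change any degree inside the giant
#' cluster — the mode is outlier-neutral by construction.
#'
#' @param net an `nb_network`, normally built at the selected zeta_s.
#' @return an object of class `nb_outliers`: `outlier_values`,
#'   `outlier_count`, `outlier_index` (positions in the input order),
#'   `retained` (an [nb_sample()] of giant-cluster members).
#' @export
detect_outliers <- function(net) {
  stopifnot(inherits(net, "nb_network"))
  in_giant <- net$cluster_labels == net$giant_cluster
  structure(
    list(outlier_values = net$values[!in_giant],
         outlier_count = sum(!in_giant),
         outlier_index = which(!in_giant),
         retained = nb_sample(net$values[in_giant],
                              label = paste0(net$label, " [giant cluster]"))),
    class = "nb_outliers"
  )
}

#' @export
print.nb_outliers <- function(x, ...) {
  cat(sprintf("<nb_outliers: %d outlier(s), %d retained>\n",
              x$outlier_count, x$retained$n))
  invisible(x)
}

#' Seeded subsampling without replacement
#'
#' Draws `round(fraction * n)` values uniformly without replacement (the
#' "bootstrapping with no replacement" used to tame large inputs; despite
#' the borrowed name this is plain subsampling, not a resampling bootstrap).
#' Retained values keep their original relative order, and the draw is
#' reproducible for a fixed seed. Modes computed on a subsample are reported
#' as-is, without reweighting.
#'
#' @param sample an [nb_sample()] or numeric vector.
#' @param fraction fraction to keep, in (0, 1].
#' @param seed integer seed for the draw.
#' @return an `nb_sample` of the retained values.
#' @export
subsample <- function(sample, fraction, seed = 1L) {
  sample <- as_nb_sample(sample)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    nb_abort("fraction must be in (0, 1]", "netfreq_invalid_parameter")
  }
  if (fraction == 1) return(sample)
  k <- max(1L, as.integer(round(fraction * sample$n)))
  idx <- with_seed(seed, sort(sample.int(sample$n, k)))
  nb_sample(sample$values[idx],
            label = sprintf("%s [%.0f%% subsample, seed %d]",
                            sample$label, 100 * fraction, as.integer(seed)))
}
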