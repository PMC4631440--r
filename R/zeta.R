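#' Default zeta grid: equally spaced fractions of the median
#'
#' Candidate half-widths run from `min_frac` to `max_frac` of the sample
#' median (the scale statistic used in practice: 1% to 10% in 10 steps).
#' When the median is not positive the span (max - min) is used as the scale
#' instead, keeping the grid positive for any non-constant sample.
#'
#' @param sample an [nb_sample()] or numeric vector.
#' @param min_frac,max_frac smallest/largest fraction of the scale
#'   (defaults 0.01 and 0.10).
#' @param steps number of grid points (default 10).
#' @return strictly increasing numeric vector of length `steps`.
#' @export
default_grid <- function(sample, min_frac = 0.01, max_frac = 0.10,
                         steps = 10) {
  sample <- as_nb_sample(sample)
  if (!(min_frac > 0 && min_frac <= max_frac)) {
    nb_abort("need 0 < min_frac <= max_frac", "netfreq_invalid_parameter")
  }
  if (steps < 2) {
    nb_abort("grid needs at least 2 steps", "netfreq_invalid_parameter")
  }
  med <- stats::median(sample$values)
  scale <- if (med > 0) med else diff(range(sample$values))
  if (scale <= 0) {
    nb_abort("degenerate sample: no positive median and zero range; cannot form a zeta grid",
             "netfreq_degenerate_sample")
  }
  seq(min_frac * scale, max_frac * scale, length.out = steps)
}

#' Sweep zeta over a grid and record network summaries
#'
#' For each candidate zeta the similarity network is built (fast path; the
#' sample is sorted once and reused) and the giant-cluster proportion p_g,
#' giant-cluster node count V_g and edge count E are recorded. With
#' `with_paths = TRUE` the diameter D of the largest cluster and the average
#' shortest-path length L_avg over connected pairs are added as visual
#' diagnostics (both rise to a peak and then decay toward 1 as the network
#' fills in).
#'
#' @param sample an [nb_sample()] or numeric vector.
#' @param grid strictly increasing positive zeta values (see
#'   [default_grid()]).
#' @param with_paths also compute D and L_avg at every grid point?
#' @return an object of class `nb_sweep`: a list with `grid`, `pg_curve`,
#'   `vg_curve`, `e_curve`, and (if requested) `d_curve`, `l_curve`, plus
#'   `n`. Also usable as a data.frame via [as.data.frame()].
#' @export
sweep_zeta <- function(sample, grid = default_grid(sample),
                       with_paths = FALSE) {
  sample <- as_nb_sample(sample)
  grid <- as.numeric(grid)
  if (length(grid) < 1 || any(!is.finite(grid)) || any(grid <= 0) ||
      is.unsorted(grid, strictly = TRUE)) {
    nb_abort("grid must be strictly increasing and positive",
             "netfreq_invalid_parameter")
  }
  ord <- order(sample$values)
  k <- length(grid)
  pg <- vg <- ec <- numeric(k)
  dd <- ll <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    net <- net_from_sorted(sample, grid[i], ord)
    pg[i] <- giant_cluster_proportion(net)
    vg[i] <- net$giant_size
    ec[i] <- net$edge_count
    if (with_paths) {
      sp <- shortest_paths_interval(net)
      dd[i] <- sp$diameter
      ll[i] <- sp$avg_path_length
    }
  }
  structure(
    list(grid = grid, pg_curve = pg, vg_curve = as.integer(vg),
         e_curve = ec, d_curve = dd, l_curve = ll, n = sample$n),
    class = "nb_sweep"
  )
}

#' @export
as.data.frame.nb_sweep <- function(x, ...) {
  data.frame(zeta = x$grid, p_g = x$pg_curve, V_g = x$vg_curve,
             E = x$e_curve, D = x$d_curve, L_avg = x$l_curve)
}

#' @export
print.nb_sweep <- function(x, ...) {
  cat(sprintf("<nb_sweep: %d grid points over [%g, %g], n = %d>\n",
              length(x$grid), min(x$grid), max(x$grid), x$n))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Select the stable zeta from a sweep
#'
#' The network is considered stable when the giant-cluster node count V_g
#' stays identical over a run of consecutive grid points. The run length
#' required is `ceiling(window_frac * length(grid))` (default 30% of the
#' grid). Identity is integer equality of V_g, never a float comparison of
#' p_g. The first qualifying run wins and its smallest zeta is returned
#' (the onset of the plateau). If `min_pg` is given the run must also have
#' p_g >= min_pg (e.g. 0.68, akin to the one-standard-deviation mass of a
#' normal distribution). With no qualifying run the last grid zeta is
#' returned with `stable = FALSE` — a reported state, not an error.
#'
#' @param sweep an `nb_sweep` from [sweep_zeta()].
#' @param window_frac fraction of the grid that must hold an identical V_g
#'   (default 0.30).
#' @param min_pg optional minimum giant-cluster proportion for a run to
#'   qualify (default `NULL`, off).
#' @return an object of class `nb_selection`: `zeta_s`, `stable`,
#'   `pg_at_selection`, `index` (grid position of zeta_s),
#'   `stability_window`.
#' @export
select_zeta <- function(sweep, window_frac = 0.30, min_pg = NULL) {
  stopifnot(inherits(sweep, "nb_sweep"))
  if (!(window_frac > 0 && window_frac <= 1)) {
    nb_abort("window_frac must be in (0, 1]", "netfreq_invalid_parameter")
  }
  k <- length(sweep$grid)
  window <- max(2L, as.integer(ceiling(window_frac * k)))
  window <- min(window, k)
  vg <- sweep$vg_curve
  run_start <- 1L
  for (i in seq_len(k)) {
    if (i > 1 && vg[i] != vg[i - 1]) run_start <- i
    run_len <- i - run_start + 1L
    if (run_len >= window &&
        (is.null(min_pg) || sweep$pg_curve[run_start] >= min_pg)) {
      return(structure(
        list(zeta_s = sweep$grid[run_start], stable = TRUE,
             pg_at_selection = sweep$pg_curve[run_start],
             index = run_start, stability_window = window),
        class = "nb_selection"))
    }
  }
  structure(
    list(zeta_s = sweep$grid[k], stable = FALSE,
         pg_at_selection = sweep$pg_curve[k],
         index = k, stability_window = window),
    class = "nb_selection")
}

#' @export
print.nb_selection <- function(x, ...) {
  cat(sprintf("<nb_selection: zeta_s = %g (%s), p_g = %.4f, window = %d>\n",
              x$zeta_s, if (x$stable) "stable" else "no stable run",
              x$pg_at_selection, x$stability_window))
  invisible(x)
}

#' Homogeneity index H = zeta_s / M
#'
#' The selected half-width divided by the mode. Low values indicate a
#' homogeneous distribution, high values a heterogeneous one. H is bounded
#' by `[0, Inf)` but most often falls in `[0, 1]`: for H > 1, zeta_s > M and
#' every value below the mode is connected to it.
#'
#' @param zeta_s selected half-width (value units).
#' @param mode_value the mode M (value units); must be non-zero.
#' @return the dimensionless ratio zeta_s / M.
#' @examples
#' homogeneity_index(10, 98.5387)   # 0.1015 to 4 d.p.
#' @export
homogeneity_index <- function(zeta_s, mode_value) {
  if (!is.finite(mode_value) || mode_value == 0) {
    nb_abort("homogeneity index undefined for mode = 0",
             "netfreq_undefined_index")
  }
  zeta_s / mode_value
}
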