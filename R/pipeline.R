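nb_config_defaults <- function() {
  list(zeta_min_frac = 0.01, zeta_max_frac = 0.10, zeta_steps = 10,
       window_frac = 0.30, min_pg = NULL, with_paths = TRUE)
}

#' Run the full network-based frequency analysis
#'
#' Orchestrates the whole method: build the zeta grid (fractions of the
#' median), sweep it tracking the giant-cluster proportion, select the
#' stable zeta_s, rebuild the network there, and extract mode, homogeneity
#' index, spread measures and outliers.
#'
#' Degenerate inputs are handled without error: a single-value sample yields
#' an edgeless network with spread reported as not computable, and a
#' constant non-positive sample (for which no zeta grid exists) is analysed
#' at zeta = 0 with `stable = NA`.
#'
#' @param sample an [nb_sample()] or numeric vector.
#' @param config named list overriding any of: `zeta_min_frac` (0.01),
#'   `zeta_max_frac` (0.10), `zeta_steps` (10), `window_frac` (0.30),
#'   `min_pg` (`NULL`, off), `with_paths` (`TRUE`).
#' @return an object of class `nb_result`: `report` (the summary list: V,
#'   E, zeta_s, M, H, p_g, D, L_avg, outlier_count, stable, boundary_flag),
#'   `table` (per-value data.frame: value, degree, cluster, is_outlier,
#'   is_mode_tied), plus the intermediate `sweep`, `selection`, `network`,
#'   `mode`, `spread`, `outliers` objects.
#' @examples
#' res <- run_pipeline(simulate_sample(dist_spec("normal", n = 100, seed = 7)))
#' res$report$M
#' @export
run_pipeline <- function(sample, config = list()) {
  sample <- as_nb_sample(sample)
  cfg <- utils::modifyList(nb_config_defaults(), config, keep.null = TRUE)

  degenerate <- FALSE
  sweep <- NULL
  sel <- NULL
  grid <- tryCatch(
    default_grid(sample, cfg$zeta_min_frac, cfg$zeta_max_frac,
                 cfg$zeta_steps),
    netfreq_degenerate_sample = function(e) NULL)
  if (is.null(grid)) {
    degenerate <- TRUE
    zeta_s <- 0
    stable <- NA
    pg_sel <- NA_real_
  } else {
    sweep <- sweep_zeta(sample, grid, with_paths = isTRUE(cfg$with_paths))
    sel <- select_zeta(sweep, window_frac = cfg$window_frac,
                       min_pg = cfg$min_pg)
    zeta_s <- sel$zeta_s
    stable <- sel$stable
    pg_sel <- sel$pg_at_selection
  }

  net <- build_network_fast(sample, zeta_s)
  mode <- mode_estimate(net)
  spread <- shortest_paths_interval(net)
  outl <- detect_outliers(net)
  H <- if (mode$mode_value == 0) NA_real_ else zeta_s / mode$mode_value

  report <- list(
    V = net$n, E = net$edge_count, zeta_s = zeta_s,
    M = mode$mode_value, H = H,
    p_g = giant_cluster_proportion(net),
    D = spread$diameter, L_avg = spread$avg_path_length,
    outlier_count = outl$outlier_count,
    stable = stable, boundary_flag = mode$boundary_flag,
    degenerate = degenerate, label = sample$label)

  table <- data.frame(
    value = net$values,
    degree = net$degrees,
    cluster = net$cluster_labels,
    is_outlier = net$cluster_labels != net$giant_cluster,
    is_mode_tied = net$degrees == mode$max_degree)

  structure(
    list(report = report, table = table, sweep = sweep, selection = sel,
         network = net, mode = mode, spread = spread, outliers = outl),
    class = "nb_result")
}

#' Summary report as a one-row data.frame
#'
#' Columns in the conventional order V, E, zeta_s, M, H, p_g, D, L_avg,
#' followed by outlier_count, stable, boundary_flag. Values are unrounded;
#' rounding is applied only when printing.
#'
#' @param result an `nb_result` from [run_pipeline()].
#' @return a one-row data.frame.
#' @export
report_row <- function(result) {
  stopifnot(inherits(result, "nb_result"))
  r <- result$report
  data.frame(V = r$V, E = r$E, zeta_s = r$zeta_s, M = r$M, H = r$H,
             p_g = r$p_g, D = r$D, L_avg = r$L_avg,
             outlier_count = r$outlier_count, stable = r$stable,
             boundary_flag = r$boundary_flag)
}

#' @export
print.nb_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("Network-based frequency analysis — %s\n", r$label))
  cat(sprintf("  V = %d, E = %g\n", r$V, r$E))
  cat(sprintf("  zeta_s = %g (%s)\n", r$zeta_s,
              if (isTRUE(r$stable)) "stable"
              else if (is.na(r$stable)) "degenerate sample"
              else "no stable plateau; last grid value"))
  cat(sprintf("  mode M = %.2f (max degree %d, %d tied)%s\n",
              r$M, x$mode$max_degree, length(x$mode$tied_values),
              if (r$boundary_flag) " [boundary artifact suspected]" else ""))
  cat(sprintf("  H = %s\n",
              if (is.na(r$H)) "not computable (M = 0)" else sprintf("%.4f", r$H)))
  cat(sprintf("  p_g = %.4f, outliers = %d\n", r$p_g, r$outlier_count))
  if (x$spread$computable) {
    cat(sprintf("  D = %d, L_avg = %.2f\n", r$D, r$L_avg))
  } else {
    cat("  D, L_avg not computable (edgeless network)\n")
  }
  invisible(x)
}

# JSON report at full precision (no rounding)
write_report_json <- function(result, path) {
  r <- result$report
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
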