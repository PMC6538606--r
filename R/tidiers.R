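#' Tidy a PeSCAR fit
#'
#' One row per contrast direction with the total connectivity, exceedance
#' count, raw and Bonferroni-adjusted permutation p-values, and the number
#' of significant sub-ROI pairs.
#'
#' @param x A `pescar_fit`.
#' @param ... Unused.
#' @return A tibble with columns `direction`, `A`, `k`, `p`, `p_adj`,
#'   `n_sig_pairs`.
#' @export
tidy.pescar_fit <- function(x, ...) {
  sig <- x$clusters[x$clusters$significant, , drop = FALSE]
  tibble::tibble(
    direction = c("C1>C2", "C2>C1"),
    A = c(x$A12, x$A21),
    k = c(x$k12, x$k21),
    p = c(x$p12, x$p21),
    p_adj = c(x$p12_adj, x$p21_adj),
    n_sig_pairs = c(length(unique(sig$pair[sig$sign > 0])),
                    length(unique(sig$pair[sig$sign < 0])))
  )
}

#' @rdname tidy.pescar_fit
#' @export
glance.pescar_fit <- function(x, ...) {
  tibble::tibble(
    A12 = x$A12, A21 = x$A21, p12_adj = x$p12_adj, p21_adj = x$p21_adj,
    n_perm = x$n_perm, exhaustive = x$exhaustive, df = x$df,
    t_threshold = x$t_threshold, alpha = x$alpha,
    n_pairs = nrow(x$pair_index), elapsed_s = x$elapsed_s
  )
}

#' Tidy the conventional baseline fit
#'
#' One row per cluster with sign, mass, size and permutation p-value.
#'
#' @param x A `conventional_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.conventional_fit <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(cluster = cl$cluster, sign = cl$sign, mass = cl$mass,
                 n_cells = cl$n_cells, p_cluster = cl$p_cluster)
}

#' @rdname tidy.conventional_fit
#' @export
glance.conventional_fit <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters), min_p = x$min_p,
                 reject = x$reject, n_perm = x$n_perm,
                 exhaustive = x$exhaustive, df = x$df,
                 t_threshold = x$t_threshold, alpha = x$alpha)
}

#' Tidy a power analysis
#'
#' @param x A `power_result`.
#' @param ... Unused.
#' @return `tidy()`: the sensitivity summary (one row per grid point and
#'   method); `glance()`: a one-row overview.
#' @export
tidy.power_result <- function(x, ...) x$summary

#' @rdname tidy.power_result
#' @export
glance.power_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario$type,
    n_grid = length(unique(x$records$signal_scale)),
    n_replicates = x$n_replicates,
    n_failed = sum(!is.na(x$records$error)),
    n_perm = x$config$n_perm,
    master_seed = x$master_seed
  )
}

# Long tibble for a [freq x time] map.
map_to_tibble <- function(m, freqs, times) {
  tibble::tibble(
    freq = rep(freqs, times = length(times)),
    time = rep(times, each = length(freqs)),
    value = as.vector(m)
  )
}

#' Plot a PeSCAR fit
#'
#' `type = "matrix"` draws the directional original connectivity matrices
#' (sub-ROI pairs that reached significance, colour = cluster mass);
#' `type = "tf"` the unweighted time-frequency summary maps (number of
#' significant connections per time-frequency point); `type = "null"` the
#' permutation null distributions with the observed totals marked.
#'
#' @param object A `pescar_fit`.
#' @param type One of `"matrix"`, `"tf"`, `"null"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pescar_fit <- function(object, type = c("matrix", "tf", "null"),
                                ...) {
  type <- match.arg(type)
  if (type == "matrix") {
    df <- dplyr::bind_rows(lapply(names(object$original), function(d) {
      m <- object$original[[d]]
      tibble::tibble(direction = d,
                     roi1_subroi = rep(seq_len(nrow(m)), ncol(m)),
                     roi2_subroi = rep(seq_len(ncol(m)), each = nrow(m)),
                     mass = as.vector(m))
    }))
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$roi2_subroi, .data$roi1_subroi,
                                       fill = .data$mass)) +
        ggplot2::geom_tile() +
        ggplot2::facet_wrap(~direction) +
        ggplot2::scale_y_reverse() +
        ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                      mid = "white", midpoint = 0) +
        ggplot2::labs(x = "ROI2 sub-ROI", y = "ROI1 sub-ROI",
                      fill = "cluster mass",
                      title = "Original connectivity matrices")
    )
  }
  if (type == "tf") {
    df <- dplyr::bind_rows(lapply(names(object$tf_unweighted), function(d)
      dplyr::mutate(map_to_tibble(object$tf_unweighted[[d]], object$freqs,
                                  object$times), direction = d)))
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                       fill = .data$value)) +
        ggplot2::geom_raster() +
        ggplot2::facet_wrap(~direction) +
        ggplot2::scale_fill_viridis_c() +
        ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                      fill = "# significant\nconnections",
                      title = "Unweighted time-frequency summary maps")
    )
  }
  df <- dplyr::bind_rows(lapply(names(object$null), function(d)
    tibble::tibble(direction = d, A = object$null[[d]])))
  obs <- tibble::tibble(direction = names(object$null),
                        A = c(object$A12, object$A21))
  ggplot2::ggplot(df, ggplot2::aes(.data$A)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$A),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~direction, scales = "free") +
    ggplot2::labs(x = "total connectivity A under relabeling",
                  y = "count", title = "Permutation null distributions")
}

#' Plot the conventional baseline t-map
#'
#' Paired t-map of the whole-ROI averaged coherence contrast with the
#' suprathreshold cluster outlines.
#'
#' @param object A `conventional_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conventional_fit <- function(object, ...) {
  df <- map_to_tibble(object$tmap, object$freqs, object$times)
  supra <- abs(object$tmap) > object$t_threshold
  df$supra <- as.vector(supra)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = df[df$supra, , drop = FALSE], size = 0.3,
                        colour = "black") +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "t",
                  title = "Conventional averaging: paired t-map",
                  subtitle = sprintf("min cluster p = %.4g", object$min_p))
}

#' Plot power curves
#'
#' Sensitivity of each method versus the mean realized SNR (dB) per grid
#' point, with exact binomial 95% confidence ribbons.
#'
#' @param object A `power_result`.
#' @param x_axis `"snr_db"` (default) or `"signal_scale"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_result <- function(object, x_axis = c("snr_db",
                                                     "signal_scale"), ...) {
  x_axis <- match.arg(x_axis)
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(.data[[x_axis]], .data$sensitivity,
                                   colour = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi,
                                      fill = .data$method),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = if (x_axis == "snr_db") "realized SNR (dB)" else
      "signal scale",
      y = "sensitivity (power)",
      title = sprintf("Statistical power: %s sources",
                      object$scenario$type))
}
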