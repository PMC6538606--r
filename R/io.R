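#' Write / read an epoched dataset as a plain-text directory
#'
#' The on-disk layout is one directory holding `meta.json` (time axis,
#' sampling rate, ROI membership, subjects, conditions, scenario echo and
#' realized SNR) and one CSV matrix per subject and condition
#' (`data_s<subject>_<condition>.csv`, rows = sub-ROI-major epoch stacking,
#' columns = time samples).  Everything is plain text, so datasets survive
#' any toolchain and diff cleanly.
#'
#' @param dataset A `pescar_dataset` (see [sim_dataset()]).
#' @param dir Target directory (created if needed).
#' @return `write_epoch_dataset()`: `dir` invisibly;
#'   `read_epoch_dataset()`: a `pescar_dataset`.
#' @export
write_epoch_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  e1 <- dataset[[1]]
  subjects <- sort(unique(vapply(unclass(dataset), function(e) e$subject, 1)))
  sc <- attr(dataset, "scenario")
  meta <- list(
    subjects = subjects,
    conditions = c("C1", "C2"),
    times = e1$times,
    sampling_rate = e1$sfreq,
    roi = e1$roi,
    n_subrois = dim(e1$data)[1],
    n_epochs = dim(e1$data)[2],
    realized_snr_db = attr(dataset, "realized_snr_db"),
    scenario = if (!is.null(sc)) unclass(sc)[setdiff(names(sc), "active_subrois")]
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  for (e in unclass(dataset)) {
    d <- dim(e$data)
    m <- matrix(aperm(e$data, c(2, 1, 3)), d[1] * d[2], d[3])
    write.csv(m, file.path(dir, sprintf("data_s%d_%s.csv", e$subject,
                                        e$condition)), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_epoch_dataset
#' @export
read_epoch_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  sets <- list()
  for (s in meta$subjects) {
    for (cond in meta$conditions) {
      f <- file.path(dir, sprintf("data_s%d_%s.csv", s, cond))
      if (!file.exists(f)) stop_config("malformed dataset: missing %s", f)
      m <- as.matrix(read.csv(f))
      dimnames(m) <- NULL
      ns <- meta$n_subrois
      ne <- meta$n_epochs
      arr <- aperm(array(m, c(ne, ns, ncol(m))), c(2, 1, 3))
      sets[[length(sets) + 1L]] <- epoch_set(s, cond, arr, meta$times,
                                             meta$roi, meta$sampling_rate)
    }
  }
  structure(sets, realized_snr_db = meta$realized_snr_db,
            class = "pescar_dataset")
}

#' Serialize a fitted result bundle
#'
#' Writes a [pescar()] and/or [conventional_test()] result as a directory:
#' `summary.json` (p-values, totals, exceedance counts, configuration echo
#' and seed), `original_matrix_12.csv` / `original_matrix_21.csv`,
#' `clusters.csv`, `null_distributions.csv`, and the unweighted/weighted
#' time-frequency summary maps as CSV.  With `plot = TRUE` the matrix and
#' TF-map figures are written as PNG.
#'
#' @param fit A `pescar_fit`.
#' @param dir Output directory.
#' @param conventional Optional `conventional_fit` to include
#'   (`conventional_clusters.csv` plus a `conventional` block in the
#'   summary).
#' @param plot Write PNG figures too.
#' @return `dir`, invisibly.
#' @export
write_pescar_results <- function(fit, dir, conventional = NULL,
                                 plot = FALSE) {
  stopifnot(inherits(fit, "pescar_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    method = "pescar",
    A12 = fit$A12, A21 = fit$A21, k12 = fit$k12, k21 = fit$k21,
    p12 = fit$p12, p21 = fit$p21,
    p12_adj = fit$p12_adj, p21_adj = fit$p21_adj,
    n_perm = fit$n_perm, exhaustive = fit$exhaustive,
    t_threshold = fit$t_threshold, df = fit$df,
    alpha = fit$alpha, seed = fit$seed,
    config = unclass(fit$config),
    package_version = as.character(utils::packageVersion("pescar"))
  )
  if (!is.null(conventional)) {
    summary$conventional <- list(method = "conventional",
                                 min_p = conventional$min_p,
                                 reject = conventional$reject,
                                 n_clusters = nrow(conventional$clusters))
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(fit$original[["C1>C2"]],
            file.path(dir, "original_matrix_12.csv"), row.names = FALSE)
  write.csv(fit$original[["C2>C1"]],
            file.path(dir, "original_matrix_21.csv"), row.names = FALSE)
  cl <- fit$clusters[, setdiff(names(fit$clusters), "mask")]
  write.csv(cl, file.path(dir, "clusters.csv"), row.names = FALSE)
  nulls <- data.frame(A12 = fit$null[["C1>C2"]], A21 = fit$null[["C2>C1"]])
  write.csv(nulls, file.path(dir, "null_distributions.csv"),
            row.names = FALSE)
  for (d in c("12", "21")) {
    key <- if (d == "12") "C1>C2" else "C2>C1"
    write.csv(fit$tf_unweighted[[key]],
              file.path(dir, sprintf("tf_unweighted_%s.csv", d)),
              row.names = FALSE)
    write.csv(fit$tf_weighted[[key]],
              file.path(dir, sprintf("tf_weighted_%s.csv", d)),
              row.names = FALSE)
  }
  if (!is.null(conventional)) {
    ccl <- conventional$clusters[, setdiff(names(conventional$clusters),
                                           "mask")]
    write.csv(ccl, file.path(dir, "conventional_clusters.csv"),
              row.names = FALSE)
  }
  if (plot) {
    ggplot2::ggsave(file.path(dir, "original_matrices.png"),
                    autoplot(fit, "matrix"), width = 7, height = 3.6,
                    dpi = 150)
    ggplot2::ggsave(file.path(dir, "tf_summary.png"),
                    autoplot(fit, "tf"), width = 7, height = 3.6, dpi = 150)
  }
  invisible(dir)
}
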