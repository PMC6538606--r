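#' Morlet wavelet decomposition of an epoch set
#'
#' Complex Morlet coefficients per sub-ROI, epoch, frequency and
#' (decimated) time point, computed by FFT convolution with unit-energy
#' Morlet kernels \eqn{\psi_f(t) = e^{2\pi i f t} e^{-t^2/(2\sigma_t^2)}}
#' with \eqn{\sigma_t = n_{cycles}/(2\pi f)}, truncated at \eqn{\pm 3
#' \sigma_t}.  Samples closer than `edge_sd * sigma_t` to an epoch edge are
#' contaminated by the wavelet support; the per-frequency half-widths are
#' returned so downstream statistics can exclude them.
#'
#' @param x An [epoch_set()].
#' @param freqs Analysis frequencies in Hz (must lie below Nyquist).
#' @param n_cycles Morlet cycles (>= 3).
#' @param decim Integer decimation factor for the output time axis.
#' @param edge_sd Edge-exclusion half-width in wavelet time-SD units.
#' @param sample_idx Optional integer vector of sample indices (on the
#'   original time grid) at which to evaluate the coefficients; the default
#'   is the decimated grid `seq(1, n_time, decim)`.
#' @return A `tf_decomp`: list with complex `coef`
#'   `[sub-ROI x epoch x frequency x time]`, `freqs`, `times` (decimated),
#'   `edge_s` (per-frequency half-widths in seconds), and the epoch-set
#'   metadata.
#' @export
tf_morlet <- function(x, freqs, n_cycles = 7, decim = 1L, edge_sd = 2,
                      sample_idx = NULL) {
  stopifnot(inherits(x, "epoch_set"))
  fs <- x$sfreq
  if (any(freqs >= fs / 2))
    stop_config("analysis frequencies must lie below Nyquist (%g Hz)", fs / 2)
  if (any(freqs <= 0)) stop_config("analysis frequencies must be positive")
  if (n_cycles < 3) stop_config("n_cycles must be >= 3")
  decim <- as.integer(decim)
  d <- dim(x$data)
  ns <- d[1]; ne <- d[2]; nt <- d[3]
  sigma_t <- n_cycles / (2 * pi * freqs)
  half <- pmin(ceiling(3 * sigma_t * fs), nt - 1L)
  N <- stats::nextn(nt + 2L * max(half), c(2, 3, 5))

  X <- matrix(aperm(x$data, c(3, 2, 1)), nt, ns * ne)
  XF <- mvfft(rbind(X, matrix(0, N - nt, ns * ne)))
  idx <- as.integer(sample_idx %||% seq(1L, nt, by = decim))
  if (any(idx < 1L | idx > nt))
    stop_config("sample_idx must index the original time grid")
  ntd <- length(idx)
  nfq <- length(freqs)
  # inverse DFT evaluated only at the requested output samples, for all
  # frequencies in one BLAS product instead of full-length inverse FFTs
  W <- exp(2i * pi * outer(idx - 1, 0:(N - 1)) / N) / N
  WK <- matrix(0i, nfq * ntd, N)
  for (fi in seq_len(nfq)) {
    h <- half[fi]
    tt <- (-h:h) / fs
    k <- exp(2i * pi * freqs[fi] * tt) * exp(-tt^2 / (2 * sigma_t[fi]^2))
    k <- k / sqrt(sum(Mod(k)^2))
    kp <- rep(0i, N)
    kp[1:(h + 1)] <- k[(h + 1):(2 * h + 1)]
    if (h > 0) kp[(N - h + 1):N] <- k[1:h]
    KF <- fft(kp)
    WK[(fi - 1L) * ntd + seq_len(ntd), ] <- W * rep(KF, each = ntd)
  }
  Call <- WK %*% XF # (freq-major time blocks) x (epoch within sub-ROI)
  coef <- aperm(array(Call, c(ntd, nfq, ne, ns)), c(4, 3, 2, 1))
  structure(list(coef = coef, freqs = as.numeric(freqs),
                 times = x$times[idx], edge_s = edge_sd * sigma_t,
                 sfreq = fs, subject = x$subject, condition = x$condition,
                 roi = x$roi),
            class = "tf_decomp")
}

#' Magnitude coherence between two sets of wavelet coefficients
#'
#' Across-epoch coherence at every time-frequency point:
#' \deqn{Coh(f,t) = \frac{|\sum_e X_e(f,t) \overline{Y_e(f,t)}|}
#'       {\sqrt{\sum_e |X_e(f,t)|^2 \sum_e |Y_e(f,t)|^2}} \in [0, 1].}
#' Points with a zero denominator are set to 0 and counted in the
#' `n_zero_denom` attribute of the result.
#'
#' @param x,y Complex arrays `[epoch x frequency x time]` with matching
#'   shapes (e.g. one sub-ROI slice of a [tf_morlet()] decomposition).
#' @return Real matrix `[frequency x time]` with values in `[0, 1]`.
#' @export
tf_coherence <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop_config("x and y must share epoch count and time-frequency grid")
  d <- dim(x)
  ne <- d[1]
  xm <- matrix(x, ne)
  ym <- matrix(y, ne)
  num <- Mod(colSums(xm * Conj(ym)))
  den <- sqrt(.colSums(Mod(xm)^2, ne, ncol(xm)) *
                .colSums(Mod(ym)^2, ne, ncol(ym)))
  coh <- numeric(length(den))
  ok <- den > 0
  coh[ok] <- pmin(Re(num[ok] / den[ok]), 1)
  out <- matrix(coh, d[2], d[3])
  attr(out, "n_zero_denom") <- sum(!ok)
  out
}

# Statistical time window: decimated time points at least one edge
# half-width (at the lowest, i.e. widest, analysis frequency) away from
# both epoch edges.
valid_time_mask <- function(times_dec, epoch_range, edge_max) {
  times_dec >= epoch_range[1] + edge_max & times_dec <= epoch_range[2] - edge_max
}

#' Time-frequency coherence for all cross-ROI sub-ROI pairs
#'
#' Runs the Morlet decomposition for every subject and condition and
#' estimates across-epoch coherence for each of the `N x M` sub-ROI pairs
#' spanning ROI 1 and ROI 2 (within-ROI pairs are excluded).  The time axis
#' is restricted to the statistical window (epoch edges contaminated by the
#' wavelet half-width at the lowest frequency are dropped).
#'
#' @param dataset A `pescar_dataset` (see [sim_dataset()]) or any list of
#'   [epoch_set()] objects covering every subject in both conditions with
#'   identical shapes and time axes.
#' @param config A [pescar_config()].
#' @return A `pescar_coherence`: real array `coh`
#'   `[pair x frequency x time x subject x condition]` plus `pair_index`
#'   (tibble mapping pair to sub-ROI row indices), `freqs`, `times`.
#' @export
coherence_maps <- function(dataset, config = pescar_config()) {
  sets <- unclass(dataset)
  subjects <- sort(unique(vapply(sets, function(e) e$subject, 1)))
  conds <- c("C1", "C2")
  e1 <- get_epochs(dataset, subjects[1], "C1")
  dims <- dim(e1$data)
  for (e in sets) {
    if (!identical(dim(e$data), dims) || !isTRUE(all.equal(e$times, e1$times)))
      stop_config("all epoch sets must share identical shapes and time axes")
  }
  roi <- e1$roi
  i1 <- which(roi == "ROI1")
  i2 <- which(roi == "ROI2")
  if (length(i1) == 0 || length(i2) == 0)
    stop_config("dataset must contain sub-ROIs of both ROI1 and ROI2")
  pair_index <- tidyr::expand_grid(j = seq_along(i2), i = seq_along(i1))[, c("i", "j")]
  pair_index <- tibble::tibble(pair = seq_len(nrow(pair_index)),
                               roi1_subroi = pair_index$i,
                               roi2_subroi = pair_index$j,
                               row1 = i1[pair_index$i],
                               row2 = i2[pair_index$j])
  npair <- nrow(pair_index)

  # statistical time window, fixed before any decomposition: decimated
  # samples clear of the widest (lowest-frequency) wavelet half-width
  nt <- dims[3]
  idx_full <- seq(1L, nt, by = config$decim)
  edge_max <- config$edge_sd * config$n_cycles / (2 * pi * min(config$freqs))
  keep <- valid_time_mask(e1$times[idx_full], range(e1$times), edge_max)
  if (!any(keep))
    stop_config("no time points survive edge exclusion; shorten n_cycles or the frequency range")
  sample_idx <- idx_full[keep]
  ntv <- length(sample_idx)
  nf <- length(config$freqs)
  coh <- array(NA_real_, c(npair, nf, ntv, length(subjects), 2))
  times_v <- e1$times[sample_idx]
  nzero <- 0L
  for (si in seq_along(subjects)) {
    for (ci in 1:2) {
      es <- get_epochs(dataset, subjects[si], conds[ci])
      dc <- tf_morlet(es, config$freqs, config$n_cycles, config$decim,
                      config$edge_sd, sample_idx = sample_idx)
      cf <- dc$coef
      ne <- dim(cf)[2]
      ncell <- nf * ntv
      mats <- lapply(seq_len(dim(cf)[1]),
                     function(r) matrix(cf[r, , , ], ne, ncell))
      autos <- vapply(mats, function(m) .colSums(Mod(m)^2, ne, ncell),
                      numeric(ncell))
      for (p in seq_len(npair)) {
        a <- pair_index$row1[p]
        b <- pair_index$row2[p]
        num <- Mod(colSums(mats[[a]] * Conj(mats[[b]])))
        den <- sqrt(autos[, a] * autos[, b])
        v <- numeric(ncell)
        ok <- den > 0
        v[ok] <- pmin(num[ok] / den[ok], 1)
        nzero <- nzero + sum(!ok)
        coh[p, , , si, ci] <- v
      }
    }
  }
  structure(list(coh = coh, pair_index = pair_index,
                 freqs = as.numeric(config$freqs),
                 times = times_v, subjects = subjects,
                 n_zero_denom = nzero),
            class = "pescar_coherence")
}

#' @export
print.pescar_coherence <- function(x, ...) {
  d <- dim(x$coh)
  cat(sprintf("<pescar_coherence> %d pairs x %d freqs x %d times x %d subjects x 2 conditions\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# Average the sub-ROI series within each ROI, keeping the epoch structure:
# the conventional comparator operates on these two mean series.
roi_average_dataset <- function(dataset) {
  sets <- lapply(unclass(dataset), function(e) {
    i1 <- which(e$roi == "ROI1")
    i2 <- which(e$roi == "ROI2")
    d <- dim(e$data)
    avg <- array(NA_real_, c(2, d[2], d[3]))
    avg[1, , ] <- colMeans(e$data[i1, , , drop = FALSE], dims = 1)
    avg[2, , ] <- colMeans(e$data[i2, , , drop = FALSE], dims = 1)
    epoch_set(e$subject, e$condition, avg, e$times, c("ROI1", "ROI2"),
              e$sfreq)
  })
  structure(sets, scenario = attr(dataset, "scenario"),
            class = "pescar_dataset")
}

#' Whole-ROI averaged coherence (conventional comparator input)
#'
#' Averages the sub-ROI series within each ROI first, then estimates the
#' single-pair time-frequency coherence between the two mean series, per
#' subject and condition.
#'
#' @inheritParams coherence_maps
#' @return A `pescar_coherence` with exactly one pair.
#' @export
roi_average_coherence <- function(dataset, config = pescar_config()) {
  coherence_maps(roi_average_dataset(dataset), config)
}
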