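#' Hann-windowed multi-frequency burst
#'
#' Evaluates the deterministic burst waveform used as the simulated source
#' signal: a Hann-windowed, amplitude-normalized sum of sinusoids,
#' \deqn{x(t) = q_0 \frac{1}{F} \sum_{f \in \Omega} w(t - t_{on})
#'       \sin(2\pi f (t - t_{on}) + \phi),}
#' where \eqn{w(\tau) = \tfrac12 (1 - \cos(2\pi\tau/T))} is the Hann window
#' over the burst duration \eqn{T} and \eqn{F = |\Omega|}.  The waveform is
#' exactly zero outside `signal_window`.
#'
#' @param times Numeric vector of sample times in seconds.
#' @param signal_window Burst `[start, end]` in seconds; must lie within the
#'   range of `times`.
#' @param freq_set Non-empty vector of burst frequencies in Hz.
#' @param q0 Overall amplitude (default 10).
#' @param phase Phase offset in radians added to every sinusoid (default 0).
#' @return Numeric vector of the same length as `times`.
#' @export
#' @examples
#' tt <- seq(-0.25, 0.75, by = 1 / 600)
#' x <- hann_burst(tt, c(0.2, 0.4), 15:20)
#' all(x[tt < 0.2 | tt > 0.4] == 0)
hann_burst <- function(times, signal_window = c(0.2, 0.4), freq_set = 15:20,
                       q0 = 10, phase = 0) {
  if (length(freq_set) < 1 || any(!is.finite(freq_set)))
    stop_config("freq_set must be non-empty and finite")
  if (length(signal_window) != 2 || diff(signal_window) <= 0)
    stop_config("signal_window must be an increasing [start, end] pair")
  if (signal_window[1] < min(times) || signal_window[2] > max(times))
    stop_config("signal_window must lie inside the epoch time range")
  Tdur <- diff(signal_window)
  tau <- times - signal_window[1]
  inside <- times >= signal_window[1] & times <= signal_window[2]
  out <- numeric(length(times))
  if (any(inside)) {
    w <- 0.5 * (1 - cos(2 * pi * tau[inside] / Tdur))
    s <- numeric(sum(inside))
    for (f in freq_set) s <- s + sin(2 * pi * f * tau[inside] + phase)
    out[inside] <- q0 * w * s / length(freq_set)
  }
  out
}

# Power spectral density profile of the synthetic resting-state noise on a
# frequency grid: 1/f^slope broadband floor (flat below 1 Hz) plus Gaussian
# oscillatory bumps at 10 Hz (alpha) and 20 Hz (beta), scaled relative to
# the floor level at the bump centre.
noise_psd_profile <- function(freqs, slope = 1, alpha_bump = 20,
                              beta_bump = 10) {
  base <- pmax(freqs, 1)^(-slope)
  p <- base
  if (alpha_bump > 0)
    p <- p + alpha_bump * (10^(-slope)) * exp(-(freqs - 10)^2 / (2 * 1.5^2))
  if (beta_bump > 0)
    p <- p + beta_bump * (20^(-slope)) * exp(-(freqs - 20)^2 / (2 * 3^2))
  p[freqs == 0] <- 0
  p
}

#' Synthetic resting-state noise segments
#'
#' Draws epoched broadband noise for one subject: each sub-ROI series has a
#' `1/f`-type power spectrum with oscillatory alpha/beta components (see
#' [pescar_scenario()] for the spectral parameters) and shares a common
#' low-amplitude component across all sub-ROIs of both ROIs, emulating the
#' covariance structure between brain regions in resting recordings.  Output
#' is deterministic given `(scenario$seed, subject, role)`; the roles
#' `"r1"`, `"r2"` and `"c2"` are three mutually independent draws (the two
#' condition-1 noise terms and the condition-2 recording).
#'
#' @param scenario A [pescar_scenario()].
#' @param subject Subject index (1-based).
#' @param role One of `"r1"`, `"r2"`, `"c2"` selecting the independent
#'   noise stream.
#' @param n_epochs Number of epochs to draw (defaults to the scenario's).
#' @return Array `[sub-ROI x epoch x time]` covering both ROIs
#'   (`2 * n_subrois` rows), in the scenario's amplitude units
#'   (per-series standard deviation `noise_scale`).
#' @export
sim_noise <- function(scenario, subject, role = c("r2", "r1", "c2"),
                      n_epochs = NULL) {
  stopifnot(inherits(scenario, "pescar_scenario"))
  role <- match.arg(role)
  n_epochs <- as.integer(n_epochs %||% scenario$n_epochs)
  ns <- 2L * scenario$n_subrois
  nt <- epoch_samples(scenario)
  fs <- scenario$sampling_rate
  role_id <- match(role, c("r1", "r2", "c2"))
  seed <- derive_seed(scenario$seed, 101L, subject, role_id)

  # generate on a fast composite FFT length and truncate to the epoch;
  # spectral amplitude profile on the FFT grid, normalized to unit variance
  ng <- stats::nextn(nt, c(2, 3, 5))
  k <- 0:(ng - 1)
  f_fold <- pmin(k, ng - k) * fs / ng
  amp <- sqrt(noise_psd_profile(f_fold, scenario$noise_slope,
                                scenario$noise_alpha_bump,
                                scenario$noise_beta_bump))
  amp <- amp / sqrt(sum(amp^2) / ng^2) # Var(x_t) = sum(A^2)/n^2

  n_series <- ns * n_epochs + n_epochs # per-sub-ROI + per-epoch shared
  # real and imaginary parts of one complex draw are two independent real
  # series with the same spectrum, so half as many inverse FFTs are needed
  n_cplx <- ceiling(n_series / 2)
  x <- withr::with_seed(seed, {
    z <- matrix(complex(real = rnorm(ng * n_cplx),
                        imaginary = rnorm(ng * n_cplx)),
                ng, n_cplx)
    y <- mvfft(z * amp, inverse = TRUE)[seq_len(nt), , drop = FALSE] / ng
    cbind(Re(y), Im(y))[, seq_len(n_series), drop = FALSE]
  })
  indep <- array(x[, seq_len(ns * n_epochs)], c(nt, n_epochs, ns))
  shared <- x[, ns * n_epochs + seq_len(n_epochs)]
  w <- scenario$noise_shared
  out <- sqrt(1 - w) * indep +
    sqrt(w) * array(shared, c(nt, n_epochs, ns))
  aperm(out, c(3, 2, 1)) * scenario$noise_scale
}

epoch_samples <- function(scenario) {
  as.integer(round(diff(scenario$epoch_window) * scenario$sampling_rate)) + 1L
}

epoch_times <- function(scenario) {
  scenario$epoch_window[1] + (seq_len(epoch_samples(scenario)) - 1L) /
    scenario$sampling_rate
}

#' Signal-to-noise ratio in decibels
#'
#' Computes `20 * log10(S / N)` where `S` is the mean absolute signal value
#' over all channels (and epochs) within the signal window and `N` is the
#' mean absolute noise value over all channels and all time points.
#'
#' @param signal,noise Arrays of matching shape with time as the last
#'   dimension (vectors are treated as single-channel series).
#' @param times Time axis in seconds matching the last dimension.  Required
#'   when `signal_window` is given.
#' @param signal_window Optional `[start, end]` in seconds restricting the
#'   signal average; when `NULL` the whole time range is used.
#' @return SNR in dB (a single number).
#' @export
#' @examples
#' snr_db(rep(2, 100), rep(1, 100)) # 20*log10(2)
snr_db <- function(signal, noise, times = NULL, signal_window = NULL) {
  sig <- as.array(signal)
  noi <- as.array(noise)
  if (!is.null(signal_window)) {
    if (is.null(times))
      stop_config("times must be supplied with signal_window")
    nt <- dim(sig)[length(dim(sig))]
    if (length(times) != nt)
      stop_config("times must match the last (time) dimension of signal")
    keep <- times >= signal_window[1] & times <= signal_window[2]
    idx <- rep(keep, each = prod(dim(sig)) / nt)
    S <- mean(abs(sig[idx]))
  } else {
    S <- mean(abs(sig))
  }
  N <- mean(abs(noi))
  if (N == 0) stop_config("undefined SNR: noise has zero mean absolute value")
  20 * log10(S / N)
}

#' Epoched sub-ROI time series for one subject and condition
#'
#' Container for one subject-condition block: a real array
#' `[sub-ROI x epoch x time]`, its time axis, sampling rate, and the ROI
#' membership of each sub-ROI row.
#'
#' @param subject Subject identifier (integer).
#' @param condition Condition label, `"C1"` or `"C2"`.
#' @param data Array `[sub-ROI x epoch x time]`.
#' @param times Time axis in seconds (length = `dim(data)[3]`), strictly
#'   increasing and uniform.
#' @param roi Character vector of length `dim(data)[1]` assigning each
#'   sub-ROI to `"ROI1"` or `"ROI2"`.
#' @param sfreq Sampling rate in Hz.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(subject, condition, data, times, roi, sfreq) {
  stopifnot(length(dim(data)) == 3, length(times) == dim(data)[3],
            length(roi) == dim(data)[1])
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9)
    stop_config("time axis must be strictly increasing and uniform")
  if (!all(roi %in% c("ROI1", "ROI2")))
    stop_config("roi labels must be 'ROI1' or 'ROI2'")
  structure(list(subject = subject, condition = condition, data = data,
                 times = times, roi = roi, sfreq = sfreq),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s, %s: %d sub-ROIs x %d epochs x %d samples @ %g Hz\n",
              x$subject, x$condition, d[1], d[2], d[3], x$sfreq))
  invisible(x)
}

#' Generate a full synthetic dataset
#'
#' Builds the two-condition, multi-subject epoched dataset a scenario
#' describes.  Condition 1 is
#' `signal_scale * burst + noise_fraction * R1 + R2` with the burst placed
#' (identically in every epoch) in the scenario's active sub-ROIs of both
#' ROIs, so condition 1 carries genuine inter-ROI coherence; inactive
#' sub-ROIs receive noise only.  Condition 2 is an independent noise draw.
#' The realized SNR (see [snr_db()]) of the dataset is recorded as attribute
#' `realized_snr_db` (signal component vs. the total condition-1 noise).
#'
#' @param scenario A [pescar_scenario()].
#' @return A `pescar_dataset`: a list of [epoch_set()] objects (all subjects
#'   times both conditions) with attributes `scenario`, `realized_snr_db`
#'   and `snr_by_subject`.
#' @export
#' @examples
#' sc <- pescar_scenario("continuous", n_subjects = 2, n_subrois = 3,
#'                       n_epochs = 5)
#' ds <- sim_dataset(sc)
#' attr(ds, "realized_snr_db")
sim_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "pescar_scenario"))
  sc <- scenario
  times <- epoch_times(sc)
  nt <- length(times)
  ns <- 2L * sc$n_subrois
  roi <- rep(c("ROI1", "ROI2"), each = sc$n_subrois)
  burst1 <- hann_burst(times, sc$signal_window, sc$freq_set, sc$q0)
  burst2 <- hann_burst(times, sc$signal_window, sc$freq_set, sc$q0,
                       phase = sc$phase_lag)

  sets <- vector("list", 2L * sc$n_subjects)
  snr_subj <- numeric(sc$n_subjects)
  sum_abs_sig <- 0
  n_sig <- 0
  sum_abs_noi <- 0
  n_noi <- 0
  win <- times >= sc$signal_window[1] & times <= sc$signal_window[2]

  for (s in seq_len(sc$n_subjects)) {
    act <- sc$active_subrois[[s]]
    sig <- array(0, c(ns, sc$n_epochs, nt))
    for (i in act$roi1)
      sig[i, , ] <- matrix(burst1, sc$n_epochs, nt, byrow = TRUE)
    for (j in act$roi2)
      sig[sc$n_subrois + j, , ] <- matrix(burst2, sc$n_epochs, nt, byrow = TRUE)
    sig <- sc$signal_scale * sig

    r1 <- sim_noise(sc, s, "r1")
    r2 <- sim_noise(sc, s, "r2")
    noise_c1 <- sc$noise_fraction * r1 + r2
    c1 <- sig + noise_c1
    c2 <- sim_noise(sc, s, "c2")

    sets[[2 * s - 1]] <- epoch_set(s, "C1", c1, times, roi, sc$sampling_rate)
    sets[[2 * s]] <- epoch_set(s, "C2", c2, times, roi, sc$sampling_rate)

    sa <- abs(sig[, , win, drop = FALSE])
    snr_subj[s] <- if (mean(sa) > 0)
      20 * log10(mean(sa) / mean(abs(noise_c1))) else -Inf
    sum_abs_sig <- sum_abs_sig + sum(sa)
    n_sig <- n_sig + length(sa)
    sum_abs_noi <- sum_abs_noi + sum(abs(noise_c1))
    n_noi <- n_noi + length(noise_c1)
  }

  S <- sum_abs_sig / n_sig
  N <- sum_abs_noi / n_noi
  snr <- if (S > 0) 20 * log10(S / N) else -Inf
  structure(sets,
            scenario = sc,
            realized_snr_db = snr,
            snr_by_subject = snr_subj,
            class = "pescar_dataset")
}

#' @export
print.pescar_dataset <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<pescar_dataset> %d subjects x 2 conditions (%s scenario)\n",
              sc$n_subjects, sc$type))
  cat(sprintf("  realized SNR: %.2f dB\n", attr(x, "realized_snr_db")))
  invisible(x)
}

# Fetch one subject-condition block from a dataset.
get_epochs <- function(dataset, subject, condition) {
  for (e in dataset)
    if (e$subject == subject && e$condition == condition) return(e)
  stop_config("no epochs for subject %s condition %s", subject, condition)
}
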