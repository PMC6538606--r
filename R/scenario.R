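#' Define a simulation scenario
#'
#' A scenario bundles the full generative configuration for one synthetic
#' two-condition, multi-subject study: an oscillatory burst (a Hann-windowed
#' sum of sinusoids, see [hann_burst()]) is placed in selected "active"
#' sub-ROIs of both regions of interest in condition 1, on top of structured
#' broadband noise standing in for resting-state recordings; condition 2 is
#' noise only.  The three spatial layouts mirror the classic simulation
#' designs for region-of-interest connectivity testing:
#'
#' * `"continuous"`: the first three sub-ROIs of each ROI are active,
#' * `"scattered"`: sub-ROIs 1, 4, 7 (pairwise non-adjacent) are active,
#' * `"variable"`: each subject gets its own random triple of active
#'   sub-ROIs (non-adjacent within ROI 2), so the effect location varies
#'   across subjects.
#'
#' Signal strength is controlled by `signal_scale` (the study's operating
#' range is 0.04-0.1; 0 gives a null dataset with exchangeable conditions)
#' and by the noise admixture `noise_fraction` (beta in `[0, 1]`): condition
#' 1 is `signal_scale * signal + noise_fraction * R1 + R2` with `R1`, `R2`
#' independent noise draws.  The realized signal-to-noise ratio in decibels
#' is computed per dataset by [snr_db()].
#'
#' @param type Spatial layout of the active sub-ROIs; one of
#'   `"continuous"`, `"scattered"`, `"variable"`.
#' @param n_subjects Number of subjects (default 8).
#' @param n_subrois Number of sub-ROIs per ROI (default 9).
#' @param n_epochs Number of epochs per condition (default 50).
#' @param epoch_window Epoch time range in seconds (default -0.25 to 0.75).
#' @param signal_window Burst time range in seconds (default 0.2 to 0.4);
#'   must lie inside `epoch_window`.
#' @param freq_set Burst frequencies in Hz (default 15:20).
#' @param q0 Source amplitude in abstract units (default 10).
#' @param signal_scale Signal attenuation factor alpha in `[0, 0.1]`
#'   (default 0.06).
#' @param noise_fraction Extra-noise mixing weight beta in `[0, 1]`
#'   (default 0.5).
#' @param sampling_rate Sampling rate in Hz (default 600).
#' @param active_subrois Optional list (one element per subject) of lists
#'   with integer fields `roi1` and `roi2` (1-based sub-ROI indices).  When
#'   `NULL`, the sets implied by `type` are realized (using `seed` for
#'   `"variable"`).
#' @param noise_slope Spectral exponent of the broadband noise; power falls
#'   off as `1/f^noise_slope` (default 1).
#' @param noise_shared Fraction of noise variance shared across all sub-ROIs
#'   of both ROIs (induces a weak baseline inter-ROI coherence; default 0.2).
#' @param noise_alpha_bump,noise_beta_bump Peak power of the oscillatory
#'   alpha (10 Hz) and beta (20 Hz) noise components, as multiples of the
#'   `1/f` power level at the bump centre (defaults 20 and 10).  Set both to
#'   0 for a pure power-law spectrum.
#' @param noise_scale Noise amplitude (standard deviation per sub-ROI series)
#'   in the same abstract units as `q0` (default 0.017, anchoring the
#'   default `signal_scale` range 0.04-0.1 to a realized SNR range of
#'   roughly 1-9 dB).
#' @param phase_lag Burst phase lag (radians) applied in ROI 2 relative to
#'   ROI 1 (default 0: identical waveforms, maximal coherence).
#' @param seed Integer master seed for dataset generation.
#' @return An object of class `pescar_scenario` (a validated list).
#' @seealso [sim_dataset()], [hann_burst()], [sim_noise()]
#' @export
#' @examples
#' sc <- pescar_scenario("scattered", n_subjects = 4, n_epochs = 10)
#' sc$active_subrois[[1]]
pescar_scenario <- function(type = c("continuous", "scattered", "variable"),
                            n_subjects = 8,
                            n_subrois = 9,
                            n_epochs = 50,
                            epoch_window = c(-0.25, 0.75),
                            signal_window = c(0.2, 0.4),
                            freq_set = 15:20,
                            q0 = 10,
                            signal_scale = 0.06,
                            noise_fraction = 0.5,
                            sampling_rate = 600,
                            active_subrois = NULL,
                            noise_slope = 1,
                            noise_shared = 0.2,
                            noise_alpha_bump = 20,
                            noise_beta_bump = 10,
                            noise_scale = 0.017,
                            phase_lag = 0,
                            seed = 1) {
  type <- match.arg(type)
  if (!is_scalar_num(n_subjects) || n_subjects < 2)
    stop_config("n_subjects must be at least 2 (paired statistics need >= 2 subjects)")
  if (!is_scalar_num(n_subrois) || n_subrois < 1)
    stop_config("n_subrois must be a positive count")
  if (!is_scalar_num(n_epochs) || n_epochs < 2)
    stop_config("n_epochs must be at least 2")
  if (length(epoch_window) != 2 || diff(epoch_window) <= 0)
    stop_config("epoch_window must be an increasing [start, end] pair in seconds")
  if (length(signal_window) != 2 || diff(signal_window) <= 0)
    stop_config("signal_window must be an increasing [start, end] pair in seconds")
  if (signal_window[1] < epoch_window[1] || signal_window[2] > epoch_window[2])
    stop_config("signal_window must lie inside epoch_window")
  if (length(freq_set) < 1 || any(!is.finite(freq_set)) || any(freq_set <= 0))
    stop_config("freq_set must be a non-empty set of positive frequencies (Hz)")
  if (any(freq_set >= sampling_rate / 2))
    stop_config("freq_set must lie below the Nyquist frequency")
  if (!is_scalar_num(signal_scale) || signal_scale < 0 || signal_scale > 0.1)
    stop_config("signal_scale must lie in [0, 0.1] (study range 0.04-0.1; 0 = null)")
  if (!is_scalar_num(noise_fraction) || noise_fraction < 0 || noise_fraction > 1)
    stop_config("noise_fraction must lie in [0, 1]")
  if (!is_scalar_num(noise_shared) || noise_shared < 0 || noise_shared >= 1)
    stop_config("noise_shared must lie in [0, 1)")
  if (!is_scalar_num(noise_scale) || noise_scale <= 0)
    stop_config("noise_scale must be positive")

  n_subjects <- as.integer(n_subjects)
  n_subrois <- as.integer(n_subrois)
  n_epochs <- as.integer(n_epochs)

  if (is.null(active_subrois)) {
    active_subrois <- realize_active_sets(type, n_subjects, n_subrois, seed)
  }
  if (length(active_subrois) != n_subjects)
    stop_config("active_subrois must have one element per subject")
  for (s in seq_len(n_subjects)) {
    a <- active_subrois[[s]]
    if (!all(c("roi1", "roi2") %in% names(a)))
      stop_config("each active set needs fields roi1 and roi2")
    idx <- c(a$roi1, a$roi2)
    if (any(idx < 1 | idx > n_subrois))
      stop_config("active sub-ROI indices must lie in 1..n_subrois")
    if (type == "scattered") {
      for (r in c("roi1", "roi2")) {
        v <- sort(a[[r]])
        if (length(v) > 1 && min(diff(v)) < 2)
          stop_config("scattered scenario requires pairwise non-adjacent active sub-ROIs")
      }
    }
  }
  if (type == "variable" && n_subjects > 1) {
    keys <- vapply(active_subrois,
                   function(a) paste(c(a$roi1, 99, a$roi2), collapse = ","), "")
    if (length(unique(keys)) < 2)
      stop_config("variable scenario requires active sets that differ across subjects")
  }

  structure(
    list(
      type = type,
      n_subjects = n_subjects,
      n_subrois = n_subrois,
      n_epochs = n_epochs,
      epoch_window = as.numeric(epoch_window),
      signal_window = as.numeric(signal_window),
      freq_set = as.numeric(freq_set),
      q0 = q0,
      signal_scale = signal_scale,
      noise_fraction = noise_fraction,
      sampling_rate = sampling_rate,
      active_subrois = active_subrois,
      noise_slope = noise_slope,
      noise_shared = noise_shared,
      noise_alpha_bump = noise_alpha_bump,
      noise_beta_bump = noise_beta_bump,
      noise_scale = noise_scale,
      phase_lag = phase_lag,
      seed = as.integer(seed)
    ),
    class = "pescar_scenario"
  )
}

# Active sub-ROI sets implied by the scenario type (1-based indices).
realize_active_sets <- function(type, n_subjects, n_subrois, seed) {
  if (type == "continuous") {
    k <- min(3L, n_subrois)
    one <- list(roi1 = seq_len(k), roi2 = seq_len(k))
    return(rep(list(one), n_subjects))
  }
  if (type == "scattered") {
    idx <- seq(1L, n_subrois, by = 3L)
    idx <- idx[seq_len(min(3L, length(idx)))]
    one <- list(roi1 = idx, roi2 = idx)
    return(rep(list(one), n_subjects))
  }
  # variable: the ROI1 active triple is drawn once and shared by all
  # subjects; ROI2 gets a per-subject random triple constrained to be
  # pairwise non-adjacent (index distance >= 2), so the effect location
  # varies across subjects on the ROI2 side.
  k <- min(3L, n_subrois)
  cand <- utils::combn(n_subrois, k)
  spaced <- cand[, apply(cand, 2, function(v) length(v) < 2 || min(diff(v)) >= 2),
                 drop = FALSE]
  if (ncol(spaced) == 0)
    stop_config("n_subrois too small for non-adjacent active triples")
  withr::with_seed(derive_seed(seed, 7001L), {
    roi1_shared <- sort(sample(n_subrois, k))
    for (attempt in 1:100) {
      sets <- lapply(seq_len(n_subjects), function(s) {
        list(roi1 = roi1_shared,
             roi2 = sort(spaced[, sample(ncol(spaced), 1L)]))
      })
      keys <- vapply(sets, function(a) paste(a$roi2, collapse = ","), "")
      if (length(unique(keys)) >= 2 || n_subjects == 1) return(sets)
    }
    sets
  })
}

#' @export
print.pescar_scenario <- function(x, ...) {
  cat("<pescar_scenario>\n")
  cat(sprintf("  type: %s | subjects: %d | sub-ROIs/ROI: %d | epochs: %d\n",
              x$type, x$n_subjects, x$n_subrois, x$n_epochs))
  cat(sprintf("  epoch: [%g, %g] s @ %g Hz | burst: [%g, %g] s, %s Hz\n",
              x$epoch_window[1], x$epoch_window[2], x$sampling_rate,
              x$signal_window[1], x$signal_window[2],
              paste(range(x$freq_set), collapse = "-")))
  cat(sprintf("  signal_scale: %g | noise_fraction: %g | seed: %d\n",
              x$signal_scale, x$noise_fraction, x$seed))
  invisible(x)
}

#' Read or write a scenario as YAML
#'
#' Every field of the scenario is a YAML key; `active_subrois` is stored as
#' a list of `roi1`/`roi2` index vectors.
#'
#' @param path Path to a YAML file.
#' @return `read_scenario()` returns a validated [pescar_scenario()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("type")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop_config("scenario YAML is missing required key(s): %s",
                paste(miss, collapse = ", "))
  args <- y[intersect(names(y), names(formals(pescar_scenario)))]
  if (!is.null(args$active_subrois)) {
    args$active_subrois <- lapply(args$active_subrois, function(a)
      list(roi1 = as.integer(unlist(a$roi1)), roi2 = as.integer(unlist(a$roi2))))
  }
  do.call(pescar_scenario, args)
}

#' @rdname read_scenario
#' @param scenario A [pescar_scenario()] object.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "pescar_scenario"))
  y <- unclass(scenario)
  yaml::write_yaml(y, path)
  invisible(path)
}
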