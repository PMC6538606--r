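# Small builders shared across tests.

tiny_scenario <- function(type = "continuous", ...) {
  args <- list(type = type, n_subjects = 3, n_subrois = 2, n_epochs = 8,
               seed = 42)
  args <- utils::modifyList(args, list(...))
  do.call(pescar_scenario, args)
}

tiny_config <- function(...) {
  sim_profile("reduced", freqs = seq(14, 21, 1), n_perm = 64, ...)
}

# Build a pescar_coherence object directly from values in [0, 1]
# (bypassing the wavelet stage) for engine-level tests.
make_coherence <- function(n1 = 2, n2 = 2, nf = 6, nt = 8, n_subjects = 3,
                           seed = 1, coh = NULL) {
  npair <- n1 * n2
  if (is.null(coh)) {
    coh <- withr::with_seed(seed,
      array(runif(npair * nf * nt * n_subjects * 2),
            c(npair, nf, nt, n_subjects, 2)))
  }
  grid <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  structure(list(
    coh = coh,
    pair_index = tibble::tibble(pair = seq_len(npair),
                                roi1_subroi = grid$i, roi2_subroi = grid$j,
                                row1 = grid$i, row2 = n1 + grid$j),
    freqs = seq_len(nf), times = seq_len(nt) / 100,
    subjects = seq_len(n_subjects), n_zero_denom = 0L
  ), class = "pescar_coherence")
}

# White-noise epoch set (both ROIs), unit variance.
noise_epochs <- function(n_subrois = 2, n_epochs = 10, nt = 120, fs = 120,
                         subject = 1, condition = "C1", seed = 1) {
  dat <- withr::with_seed(seed,
    array(rnorm(2 * n_subrois * n_epochs * nt),
          c(2 * n_subrois, n_epochs, nt)))
  epoch_set(subject, condition, dat, (0:(nt - 1)) / fs,
            rep(c("ROI1", "ROI2"), each = n_subrois), fs)
}
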