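#' Benchmark a state classifier against the HMM baseline
#'
#' Simulates fresh two-state traces over a grid of noise levels, FRET
#' contrasts and kinetic time scales, and scores the per-frame state
#' label precision of the trained classifier and of a locally fitted
#' Gaussian HMM against the simulation ground truth on each grid cell.
#'
#' @param model a trained `"states2"` classifier ([train_model()]).
#' @param snr signal-to-noise ratios to probe.
#' @param contrast FRET differences between the two states.
#' @param dwell mean dwell times in frames.
#' @param n_traces traces per grid cell.
#' @param n_frames frames per trace.
#' @param frame_time seconds per frame.
#' @param seed simulation seed.
#' @return data.frame with one row per cell: `snr`, `contrast`, `dwell`,
#'   `precision_classifier`, `precision_hmm`, `n_frames_scored`.
#' @export
benchmark_vs_hmm <- function(model, snr = c(1, 4, 16), contrast = c(0.2, 0.5),
                             dwell = c(10, 30), n_traces = 20L,
                             n_frames = 400L, frame_time = 0.05,
                             seed = 1L) {
  stopifnot(model$spec$task == "states2")
  modality <- model$spec$modality
  grid <- expand.grid(snr = snr, contrast = contrast, dwell = dwell)
  set.seed(seed)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    ok_cls <- 0L; ok_hmm <- 0L; n <- 0L
    for (i in seq_len(n_traces)) {
      tr <- simulate_two_state(modality, grid$contrast[g], grid$dwell[g],
                               grid$snr[g], n_frames, frame_time)
      truth <- tr$states
      use <- truth > 0L
      if (!any(use)) next
      sc <- classify_states(model, tr)
      obs <- observable_series(tr$channels[, model$spec$channels,
                                           drop = FALSE], modality)
      hm <- fit_local_hmm(obs, 2L, max_iter = 500L)
      ok_cls <- ok_cls + sum(sc$states[use] == truth[use])
      ok_hmm <- ok_hmm + sum(hm$path[use] == truth[use])
      n <- n + sum(use)
    }
    data.frame(snr = grid$snr[g], contrast = grid$contrast[g],
               dwell = grid$dwell[g],
               precision_classifier = ok_cls / n,
               precision_hmm = ok_hmm / n, n_frames_scored = n)
  })
  do.call(rbind, res)
}

# one fresh two-state trace with states in canonical (ascending E) order
simulate_two_state <- function(modality, contrast, dwell, snr, n_frames,
                               frame_time, e_mid = 0.5, bleach = FALSE) {
  e <- pmin(pmax(c(e_mid - contrast / 2, e_mid + contrast / 2), 0.01), 0.99)
  fret <- switch(modality,
    "1c" = cbind(I = e),
    "2c" = , "2c_alex" = cbind(YR = e),
    "3c_alex" = cbind(BY = e, BR = c(0.3, 0.3), YR = c(0.6, 0.2)))
  k <- 1 / (dwell * frame_time)
  km <- kinetic_model(matrix(c(0, k, k, 0), 2, 2, byrow = TRUE), fret)
  dyes <- modality_dyes(modality)
  pm <- photophysics_model(
    stats::setNames(rep(150, length(dyes)), dyes),
    stats::setNames(rep(if (bleach) 1 / (n_frames * frame_time) else 0,
                        length(dyes)), dyes))
  dm <- detection_model(modality, alpha = 0.05,
                        delta = if (modality == "2c") 0 else 0.08,
                        gamma = 1.3, snr = snr)
  path <- sample_state_path(km, n_frames, frame_time)
  render_trace(path, km, pm, dm, frame_time,
               bleach_times = if (bleach) NULL else
                 stats::setNames(rep(Inf, length(dyes)), dyes))
}
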