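#' Channel metadata for a measurement modality
#'
#' Supported modalities: `"1c"` (single dye, one channel), `"2c"`
#' (two-color continuous-wave excitation: donor and FRET channel),
#' `"2c_alex"` (two-color alternating excitation, adds the
#' acceptor-excitation channel) and `"3c_alex"` (three-color alternating
#' excitation, six channels). One record per ALEX alternation cycle
#' carries all channels.
#'
#' @param modality one of `"1c"`, `"2c"`, `"2c_alex"`, `"3c_alex"`.
#' @return character vector of channel names, e.g. `c("DD","DA","AA")`.
#' @export
modality_channels <- function(modality) {
  switch(match.arg(modality, c("1c", "2c", "2c_alex", "3c_alex")),
    "1c"      = "I",
    "2c"      = c("DD", "DA"),
    "2c_alex" = c("DD", "DA", "AA"),
    "3c_alex" = c("BB", "BY", "BR", "YY", "YR", "RR"))
}

# dyes present per modality (donor-to-acceptor order)
modality_dyes <- function(modality) {
  switch(modality,
    "1c"      = "Y",
    "2c"      = ,
    "2c_alex" = c("Y", "R"),
    "3c_alex" = c("B", "Y", "R"))
}

# dye pairs with a FRET coupling per modality
modality_pairs <- function(modality) {
  switch(modality,
    "1c"      = character(0),
    "2c"      = ,
    "2c_alex" = "YR",
    "3c_alex" = c("BY", "BR", "YR"))
}

#' Per-dye photophysics: brightness and photobleaching
#'
#' Photobleaching is single-step and exponential per dye, independent
#' between dyes. `brightness` is the total detected emission of the dye
#' per frame under its own excitation when not quenched by FRET.
#'
#' @param brightness named numeric vector, counts/frame per dye.
#' @param bleach_rate named numeric vector, 1/s per dye (0 = photostable).
#' @return object of class `photophysics_model`.
#' @export
photophysics_model <- function(brightness, bleach_rate) {
  stopifnot(all(brightness > 0), all(bleach_rate >= 0),
            !is.null(names(brightness)), !is.null(names(bleach_rate)))
  structure(list(brightness = brightness, bleach_rate = bleach_rate),
            class = "photophysics_model")
}

#' Detection model: correction factors and noise
#'
#' Holds the spectroscopic correction factors of the detection path, per
#' FRET pair: `alpha` (donor-emission crosstalk into the acceptor
#' channel), `delta` (acceptor direct excitation by the donor laser,
#' normalized to the acceptor-excitation signal) and `gamma` (relative
#' detection efficiency of the pair), plus the additive Gaussian noise
#' sigma per channel. When `snr` is given, sigma is derived as
#' (mean total signal of the active dyes) / `snr`, applied to every
#' channel.
#'
#' @param modality measurement modality (see [modality_channels()]).
#' @param alpha,delta,gamma named numeric vectors with one entry per dye
#'   pair (`"YR"`; plus `"BY"`, `"BR"` for three-color). For `"2c"`
#'   (continuous-wave) data `delta` must be zero: without an
#'   acceptor-excitation channel direct excitation is neither rendered
#'   nor correctable.
#' @param noise_sigma counts/frame, recycled over channels; ignored when
#'   `snr` is given.
#' @param snr optional signal-to-noise ratio used to derive sigma at
#'   render time.
#' @return object of class `detection_model`.
#' @export
detection_model <- function(modality, alpha = 0.05, delta = 0.08,
                            gamma = 1.3, noise_sigma = 1, snr = NULL) {
  pairs <- modality_pairs(modality)
  expand <- function(x, what) {
    if (length(pairs) == 0L) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, length(pairs)), pairs)
    if (!all(pairs %in% names(x)))
      stop("'", what, "' must be named for pairs: ", paste(pairs, collapse = ", "))
    x[pairs]
  }
  alpha <- expand(alpha, "alpha"); delta <- expand(delta, "delta")
  gamma <- expand(gamma, "gamma")
  if (modality == "2c" && any(delta != 0))
    stop("continuous-wave 2c data has no acceptor-excitation channel; ",
         "direct excitation cannot be modeled, set delta = 0")
  stopifnot(all(alpha >= 0), all(delta >= 0), all(gamma > 0))
  if (is.null(snr)) stopifnot(all(noise_sigma > 0))
  structure(list(modality = modality, alpha = alpha, delta = delta,
                 gamma = gamma, noise_sigma = noise_sigma, snr = snr),
            class = "detection_model")
}

#' Simulation configuration
#'
#' Defines the simulation envelope the trace generator draws from:
#' FRET efficiencies uniform in `e_range`, mean dwell times log-uniform
#' in `dwell_range` (frames), signal-to-noise ratios log-uniform in
#' `snr_range`, and the trace-category mixture. Defaults reproduce the
#' training envelope used throughout: E in [0.01, 0.99], dwell times of
#' 1 to 100 frames and SNR from 0.3 to 50, with 2000 frames per trace
#' and a 50 ms frame time.
#'
#' @param modality `"1c"`, `"2c"`, `"2c_alex"` or `"3c_alex"`.
#' @param n_traces number of traces to generate.
#' @param n_frames frames per trace (ALEX cycles).
#' @param frame_time seconds per frame.
#' @param seed integer seed making the generated dataset reproducible.
#' @param e_range range of per-state FRET efficiencies.
#' @param dwell_range range of mean state dwell times, in frames.
#' @param snr_range range of signal-to-noise ratios.
#' @param n_states_set state counts to draw from for dynamic traces.
#' @param mixture named fractions over trace categories
#'   `dynamic`, `static`, `noisy`, `aggregate`, `artifact`; must sum to 1.
#' @param min_contrast minimum observable difference between any two
#'   states of one molecule, so that the number of states is well posed.
#' @param brightness_range range of per-dye brightness, counts/frame.
#' @param bleach_expect_range expected per-dye bleach time, as a fraction
#'   of the trace length; drawn log-uniformly per dye and trace.
#' @param alpha,delta,gamma correction factors passed to
#'   [detection_model()] (scalars or named per pair).
#' @param noise_floor SNR below which a trace is labeled `noisy`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(modality = "2c_alex", n_traces = 100L,
                       n_frames = 2000L, frame_time = 0.05, seed = 1L,
                       e_range = c(0.01, 0.99), dwell_range = c(1, 100),
                       snr_range = c(0.3, 50), n_states_set = 2:4,
                       mixture = c(dynamic = 0.5, static = 0.2,
                                   noisy = 0.1, aggregate = 0.1,
                                   artifact = 0.1),
                       min_contrast = 0.1,
                       brightness_range = c(80, 250),
                       bleach_expect_range = c(0.3, 2),
                       alpha = 0.05, delta = if (modality == "2c") 0 else 0.08,
                       gamma = 1.3, noise_floor = 1) {
  modality <- match.arg(modality, c("1c", "2c", "2c_alex", "3c_alex"))
  cats <- c("dynamic", "static", "noisy", "aggregate", "artifact")
  if (!all(names(mixture) %in% cats))
    stop("mixture categories must be among: ", paste(cats, collapse = ", "))
  mixture <- mixture[mixture > 0]
  if (abs(sum(mixture) - 1) > 1e-8)
    stop("mixture fractions must sum to 1")
  stopifnot(n_traces >= 1, n_frames >= 10, frame_time > 0,
            e_range[1] >= 0, e_range[2] <= 1, diff(e_range) >= 0,
            dwell_range[1] >= 1, dwell_range[2] <= 1e4,
            snr_range[1] > 0, diff(snr_range) >= 0, min_contrast >= 0)
  structure(list(modality = modality, n_traces = as.integer(n_traces),
                 n_frames = as.integer(n_frames), frame_time = frame_time,
                 seed = as.integer(seed), e_range = e_range,
                 dwell_range = dwell_range, snr_range = snr_range,
                 n_states_set = n_states_set, mixture = mixture,
                 min_contrast = min_contrast,
                 brightness_range = brightness_range,
                 bleach_expect_range = bleach_expect_range,
                 alpha = alpha, delta = delta, gamma = gamma,
                 noise_floor = noise_floor),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("smFRET simulation config: %s, %d traces x %d frames @ %g s\n",
              x$modality, x$n_traces, x$n_frames, x$frame_time))
  cat(sprintf("  E in [%g, %g], dwell %g-%g frames, SNR %g-%g\n",
              x$e_range[1], x$e_range[2], x$dwell_range[1], x$dwell_range[2],
              x$snr_range[1], x$snr_range[2]))
  cat("  mixture:", paste(sprintf("%s=%.2f", names(x$mixture), x$mixture),
                          collapse = ", "), "\n")
  invisible(x)
}
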