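#' Labeled trace container
#'
#' A `labeled_trace` bundles the detected multichannel intensities of one
#' molecule with (for simulated data) the per-frame ground truth: the
#' trace category of every frame, the underlying kinetic state, and the
#' forward-model parameters used to render it.
#'
#' @name labeled_trace
#' @details Fields: `channels` (`n_frames` x `n_channels` matrix of
#'   counts, columns named as in [modality_channels()]), `modality`,
#'   `frame_time` (s), `category` (per-frame character label), `states`
#'   (per-frame ground-truth state index; 0 where undefined, i.e. outside
#'   dynamic/static frames with all dyes photoactive), and `truth` (list
#'   of the kinetic, photophysics and detection models plus per-dye
#'   bleach times in seconds).
NULL

new_labeled_trace <- function(channels, modality, frame_time, category,
                              states, truth, id = NA_character_) {
  stopifnot(ncol(channels) == length(modality_channels(modality)))
  colnames(channels) <- modality_channels(modality)
  structure(list(channels = channels, modality = modality,
                 frame_time = frame_time, category = category,
                 states = states, truth = truth, id = id),
            class = "labeled_trace")
}

#' @export
print.labeled_trace <- function(x, ...) {
  cat(sprintf("labeled_trace %s: %s, %d frames @ %g s\n",
              if (is.na(x$id)) "" else x$id, x$modality,
              nrow(x$channels), x$frame_time))
  tab <- table(x$category)
  cat("  frame categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.labeled_trace <- function(x, ...) {
  t <- seq_len(nrow(x$channels)) * x$frame_time
  graphics::matplot(t, x$channels, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "counts/frame",
                    main = paste("trace", x$id), ...)
  graphics::legend("topright", colnames(x$channels), lty = 1,
                   col = seq_len(ncol(x$channels)), bty = "n", cex = 0.8)
  invisible(x)
}

#' Per-frame category alphabet of a modality
#'
#' The six base categories (dynamic, static, noisy, artifact, aggregate,
#' photobleached) expand with the number of dyes: the "photobleached"
#' family enumerates which dyes are still photoactive, so individual
#' bleaching events are identifiable per frame.
#'
#' @param modality measurement modality.
#' @return character vector of per-frame labels.
#' @export
category_alphabet <- function(modality) {
  junk <- c("noisy", "aggregate", "artifact")
  switch(match.arg(modality, c("1c", "2c", "2c_alex", "3c_alex")),
    "1c"      = c("dynamic", "static", "bleached", junk),
    "2c"      = ,
    "2c_alex" = c("DA-dynamic", "DA-static", "D-only", "A-only",
                  "bleached", junk),
    "3c_alex" = c("BYR-dynamic", "BYR-static", "BY", "BR", "YR",
                  "B", "Y", "R", "bleached", junk))
}

# label of a frame given the set of photoactive dyes
active_set_label <- function(modality, active, dynamic) {
  if (modality == "1c")
    return(if (!active["Y"]) "bleached" else if (dynamic) "dynamic" else "static")
  if (modality %in% c("2c", "2c_alex")) {
    if (active["Y"] && active["R"])
      return(if (dynamic) "DA-dynamic" else "DA-static")
    if (active["Y"]) return("D-only")
    if (active["R"]) return("A-only")
    return("bleached")
  }
  on <- paste(c("B", "Y", "R")[active[c("B", "Y", "R")]], collapse = "")
  if (on == "BYR") return(if (dynamic) "BYR-dynamic" else "BYR-static")
  if (on == "") return("bleached")
  on
}

# noise-free expected channel intensities
# occ: T x S occupancy, fret: S x P, act: T x n_dyes active fraction
expected_channels <- function(modality, occ, fret, act, brightness,
                              alpha, delta, gamma) {
  T_ <- nrow(occ)
  B <- brightness
  if (modality == "1c") {
    lvl <- drop(occ %*% fret[, "I", drop = FALSE])
    return(matrix(B["Y"] * act[, "Y"] * lvl, T_, 1,
                  dimnames = list(NULL, "I")))
  }
  if (modality %in% c("2c", "2c_alex")) {
    E <- drop(occ %*% fret[, "YR", drop = FALSE]) * act[, "R"]
    dd <- B["Y"] * act[, "Y"] * (1 - E)
    aa <- B["R"] * act[, "R"]
    da <- gamma["YR"] * B["Y"] * act[, "Y"] * E + alpha["YR"] * dd +
      delta["YR"] * aa
    out <- cbind(DD = dd, DA = da, AA = aa)
    return(out[, modality_channels(modality), drop = FALSE])
  }
  ## 3c_alex: FRET cascade after blue excitation, 2c block after yellow
  Eby <- drop(occ %*% fret[, "BY", drop = FALSE]) * act[, "Y"]
  Ebr <- drop(occ %*% fret[, "BR", drop = FALSE]) * act[, "R"]
  Eyr <- drop(occ %*% fret[, "YR", drop = FALSE]) * act[, "R"]
  bb0 <- B["B"] * act[, "B"] * (1 - Eby - Ebr)
  by0 <- B["B"] * act[, "B"] * Eby * (1 - Eyr)
  br0 <- B["B"] * act[, "B"] * (Ebr + Eby * Eyr)
  yy <- B["Y"] * act[, "Y"] * (1 - Eyr)
  yr0 <- B["Y"] * act[, "Y"] * Eyr
  rr <- B["R"] * act[, "R"]
  bb <- bb0
  by <- gamma["BY"] * by0 + alpha["BY"] * bb + delta["BY"] * yy
  br <- gamma["BR"] * br0 + alpha["BR"] * bb + alpha["YR"] * gamma["BY"] * by0 +
    delta["BR"] * rr
  yr <- gamma["YR"] * yr0 + alpha["YR"] * yy + delta["YR"] * rr
  cbind(BB = bb, BY = by, BR = br, YY = yy, YR = yr, RR = rr)
}

#' Render a labeled trace from its forward model
#'
#' Turns a continuous-time state path into detected channel intensities:
#' frame occupancies weight the per-state FRET efficiencies (so sub-frame
#' transitions produce genuinely mixed frames), per-dye photobleaching
#' truncates the respective contributions, crosstalk/direct-excitation/
#' detection-efficiency mixing is applied, and additive Gaussian noise is
#' drawn per channel. Per-frame ground-truth category and state labels
#' are emitted alongside.
#'
#' @param path result of [sample_state_path()].
#' @param kmodel a [kinetic_model()].
#' @param pmodel a [photophysics_model()].
#' @param dmodel a [detection_model()].
#' @param frame_time seconds per frame.
#' @param bleach_times optional named per-dye bleach times (s); by default
#'   drawn exponentially from `pmodel$bleach_rate`.
#' @param id trace identifier.
#' @return a [labeled_trace].
#' @export
render_trace <- function(path, kmodel, pmodel, dmodel, frame_time,
                         bleach_times = NULL, id = NA_character_) {
  modality <- dmodel$modality
  dyes <- modality_dyes(modality)
  fret <- kmodel$fret
  if (all(c("BY", "BR") %in% colnames(fret)) &&
      any(fret[, "BY"] + fret[, "BR"] > 1))
    stop("E_BY + E_BR exceeds 1; forward model is unphysical")
  occ <- path$occupancy
  T_ <- nrow(occ)
  if (is.null(bleach_times)) {
    r <- pmodel$bleach_rate[dyes]
    bleach_times <- stats::setNames(
      ifelse(r > 0, stats::rexp(length(r), pmax(r, 1e-12)), Inf), dyes)
  }
  ## within-frame active fraction and end-of-frame active flag per dye
  fr_end <- seq_len(T_) * frame_time
  act <- sapply(dyes, function(d)
    pmin(pmax((bleach_times[d] - (fr_end - frame_time)) / frame_time, 0), 1))
  act <- matrix(act, T_, length(dyes), dimnames = list(NULL, dyes))
  active_flag <- sapply(dyes, function(d) bleach_times[d] >= fr_end)
  active_flag <- matrix(active_flag, T_, length(dyes),
                        dimnames = list(NULL, dyes))
  mu <- expected_channels(modality, occ, fret, act, pmodel$brightness,
                          dmodel$alpha, dmodel$delta, dmodel$gamma)
  sigma <- if (!is.null(dmodel$snr))
    sum(pmodel$brightness[dyes]) / dmodel$snr
  else dmodel$noise_sigma
  sigma <- rep_len(sigma, ncol(mu))
  noise <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) %*%
    diag(sigma, ncol(mu))
  channels <- mu + noise
  dynamic <- kmodel$n_states > 1L
  category <- vapply(seq_len(T_), function(f)
    active_set_label(modality, active_flag[f, ], dynamic), character(1))
  states <- max.col(occ, ties.method = "first")
  all_active <- rowSums(active_flag) == length(dyes)
  states[!all_active] <- 0L
  new_labeled_trace(channels, modality, frame_time, category, states,
                    truth = list(kinetic = kmodel, photophysics = pmodel,
                                 detection = dmodel, sigma = sigma,
                                 bleach_times = bleach_times),
                    id = id)
}

#' Generate a junk trace (noisy, aggregate or artifact)
#'
#' Junk categories mirror what experimentalists discard before kinetic
#' analysis: `noisy` traces have an SNR below the configured floor,
#' `aggregate` traces carry two molecules (two bleach steps per dye,
#' above-unit stoichiometry), and `artifact` traces show uncorrelated
#' intensity jumps and non-exponential decay segments that no
#' photophysical model explains. All frames carry the junk label.
#'
#' @param kind `"noisy"`, `"aggregate"` or `"artifact"`.
#' @param config a [sim_config()].
#' @param id trace identifier.
#' @return a [labeled_trace].
#' @export
make_junk_trace <- function(kind, config, id = NA_character_) {
  kind <- match.arg(kind, c("noisy", "aggregate", "artifact"))
  T_ <- config$n_frames
  base <- function(snr, cfg = config) {
    km <- sample_kinetic_model(cfg, n_states = sample(2:3, 1L))
    pm <- draw_photophysics(cfg)
    dm <- draw_detection(cfg, snr = snr)
    path <- sample_state_path(km, T_, cfg$frame_time)
    render_trace(path, km, pm, dm, cfg$frame_time, id = id)
  }
  tr <- switch(kind,
    noisy = base(stats::runif(1, 0.2, max(config$noise_floor * 0.8, 0.25))),
    aggregate = {
      ## two molecules on one spot; bleach expectations shortened so both
      ## sets of bleach steps fall inside the trace with high probability
      cfg2 <- config
      cfg2$bleach_expect_range <- c(0.15, 0.6)
      a <- base(exp(stats::runif(1, log(5), log(max(config$snr_range)))),
                cfg2)
      b <- base(exp(stats::runif(1, log(5), log(max(config$snr_range)))),
                cfg2)
      a$channels <- a$channels + b$channels
      a
    },
    artifact = {
      a <- base(exp(stats::runif(1, log(2), log(max(config$snr_range)))))
      ch <- a$channels
      amp <- max(abs(ch))
      ## uncorrelated level jumps per channel
      for (j in seq_len(ncol(ch))) {
        n_jump <- stats::rpois(1, 3) + 1L
        at <- sort(sample.int(T_, n_jump))
        lev <- stats::runif(n_jump + 1L, -0.5, 1.5) * amp
        ch[, j] <- ch[, j] + lev[findInterval(seq_len(T_), at) + 1L]
      }
      ## a non-exponential (linear) decay ramp on one channel
      j <- sample.int(ncol(ch), 1L)
      ch[, j] <- ch[, j] * seq(1, stats::runif(1, 0, 0.4), length.out = T_)
      a$channels <- ch
      a
    })
  tr$category <- rep(kind, T_)
  tr$states <- rep(0L, T_)
  tr$truth$junk_kind <- kind
  tr
}

draw_photophysics <- function(config) {
  dyes <- modality_dyes(config$modality)
  br <- stats::setNames(stats::runif(length(dyes), config$brightness_range[1],
                                     config$brightness_range[2]), dyes)
  ## expected bleach time as a fraction of trace length, log-uniform
  frac <- exp(stats::runif(length(dyes), log(config$bleach_expect_range[1]),
                           log(config$bleach_expect_range[2])))
  rate <- stats::setNames(
    1 / (frac * config$n_frames * config$frame_time), dyes)
  photophysics_model(br, rate)
}

draw_detection <- function(config, snr = NULL) {
  if (is.null(snr))
    snr <- exp(stats::runif(1, log(config$snr_range[1]),
                            log(config$snr_range[2])))
  detection_model(config$modality, alpha = config$alpha,
                  delta = config$delta, gamma = config$gamma, snr = snr)
}

#' Generate a labeled simulated dataset
#'
#' Draws `config$n_traces` traces from the configured envelope with the
#' configured category mixture, fully reproducible from `config$seed`.
#' Every ground-truth parameter is recorded in the manifest.
#'
#' @param config a [sim_config()].
#' @return an object of class `smfret_dataset`: list with `traces` (list
#'   of [labeled_trace]), `manifest` (one data.frame row per trace) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  set.seed(config$seed)
  cats <- sample(names(config$mixture), config$n_traces, replace = TRUE,
                 prob = config$mixture)
  traces <- vector("list", config$n_traces)
  rows <- vector("list", config$n_traces)
  for (i in seq_len(config$n_traces)) {
    id <- sprintf("trace_%05d", i)
    if (cats[i] %in% c("noisy", "aggregate", "artifact")) {
      tr <- make_junk_trace(cats[i], config, id = id)
    } else {
      n_states <- if (cats[i] == "static") 1L else
        if (length(config$n_states_set) == 1L) config$n_states_set else
          sample(config$n_states_set, 1L)
      km <- sample_kinetic_model(config, n_states = n_states)
      pm <- draw_photophysics(config)
      dm <- draw_detection(config)
      path <- sample_state_path(km, config$n_frames, config$frame_time)
      tr <- render_trace(path, km, pm, dm, config$frame_time, id = id)
    }
    traces[[i]] <- tr
    rows[[i]] <- data.frame(
      id = id, category = cats[i],
      n_states = tr$truth$kinetic$n_states %||% NA_integer_,
      snr = tr$truth$detection$snr %||% NA_real_,
      sigma = tr$truth$sigma[1],
      stringsAsFactors = FALSE)
  }
  structure(list(traces = traces, manifest = do.call(rbind, rows),
                 config = config),
            class = "smfret_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.smfret_dataset <- function(x, ...) {
  cat(sprintf("smfret_dataset: %d %s traces x %d frames (seed %d)\n",
              length(x$traces), x$config$modality, x$config$n_frames,
              x$config$seed))
  print(table(x$manifest$category))
  invisible(x)
}

#' Estimate per-trace signal-to-noise ratio
#'
#' Noise sigma is estimated channel-wise from the lag-1 differences
#' (robust to slow kinetics), the signal as the upper-quartile mean of
#' the summed channels; their ratio mirrors the SNR definition used by
#' the simulator (total active-dye signal over per-channel sigma).
#'
#' @param trace a [labeled_trace] or a channel matrix.
#' @return list with `snr`, `sigma`, `signal`.
#' @export
estimate_snr <- function(trace) {
  ch <- if (inherits(trace, "labeled_trace")) trace$channels else trace
  sig <- stats::median(apply(ch, 2, function(x) stats::sd(diff(x)) / sqrt(2)))
  tot <- rowSums(ch)
  ## smooth before taking the active-plateau quantile so that at low SNR
  ## the noise itself does not masquerade as signal
  w <- min(25L, max(3L, nrow(ch) %/% 4L))
  sm <- stats::filter(tot, rep(1 / w, w))
  q <- stats::quantile(sm, 0.8, na.rm = TRUE, names = FALSE)
  ## debias: at the 0.8 quantile, smoothed noise alone contributes
  ## qnorm(0.8) * sigma * sqrt(C / w)
  signal <- q - stats::qnorm(0.8) * sig * sqrt(ncol(ch) / w)
  list(snr = signal / sig, sigma = sig, signal = signal)
}
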