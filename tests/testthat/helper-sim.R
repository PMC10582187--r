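# Shared fixtures, built in code.

# A state path with whole-frame dwells (one-hot occupancy): the exact
# case where frame labels carry no sub-frame mixing, used for
# machine-precision round-trip checks.
pure_path <- function(states, frame_time = 0.05, n_states = max(states)) {
  n <- n_states
  occ <- matrix(0, length(states), n)
  occ[cbind(seq_along(states), states)] <- 1
  r <- rle(states)
  ends <- cumsum(r$lengths)
  list(events = data.frame(state = r$values,
                           t_start = (ends - r$lengths) * frame_time,
                           t_end = ends * frame_time),
       occupancy = occ)
}

two_state_model <- function(e = c(0.2, 0.8), dwell_s = c(2, 2),
                            pairs = "YR") {
  k <- 1 / dwell_s
  fret <- matrix(e, 2, length(pairs), dimnames = list(NULL, pairs))
  kinetic_model(matrix(c(0, k[1], k[2], 0), 2, 2, byrow = TRUE), fret)
}

noise_free_dm <- function(modality = "2c_alex", alpha = 0, delta = 0,
                          gamma = 1)
  detection_model(modality, alpha = alpha, delta = delta, gamma = gamma,
                  noise_sigma = 1e-12)

std_pm <- function(modality = "2c_alex", brightness = 150) {
  dyes <- modality_dyes_t(modality)
  photophysics_model(stats::setNames(rep(brightness, length(dyes)), dyes),
                     stats::setNames(rep(0, length(dyes)), dyes))
}

modality_dyes_t <- function(modality) {
  switch(modality, "1c" = "Y", "2c" = , "2c_alex" = c("Y", "R"),
         "3c_alex" = c("B", "Y", "R"))
}

no_bleach <- function(modality = "2c_alex")
  stats::setNames(rep(Inf, length(modality_dyes_t(modality))),
                  modality_dyes_t(modality))

# render a two-state 2c-ALEX trace from an explicit per-frame state path
render_pure_2c <- function(states, e = c(0.2, 0.8), frame_time = 0.05,
                           alpha = 0, delta = 0, gamma = 1,
                           snr = NULL, sigma = 1e-12,
                           bleach = no_bleach("2c_alex")) {
  km <- two_state_model(e, dwell_s = c(2, 2))
  dm <- if (is.null(snr))
    detection_model("2c_alex", alpha, delta, gamma, noise_sigma = sigma)
  else detection_model("2c_alex", alpha, delta, gamma, snr = snr)
  render_trace(pure_path(states, frame_time, n_states = 2L), km,
               std_pm("2c_alex"), dm, frame_time, bleach_times = bleach)
}
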