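#' Kinetic model of a multi-state single-molecule system
#'
#' A `kinetic_model` couples a continuous-time Markov chain over
#' `n_states` conformational states to the observable each state emits:
#' pairwise FRET efficiencies for multi-color data, or a normalized
#' intensity level for single-color (quencher-based) data.
#'
#' @param rates square rate matrix in 1/s. Off-diagonal entries `k[i, j]`
#'   are the transition rates from state `i` to state `j`; the diagonal is
#'   overwritten with minus the off-diagonal row sums so rows sum to zero.
#'   The mean dwell time of state `i` is `-1 / rates[i, i]`.
#' @param fret numeric matrix (`n_states` rows) of per-state observables in
#'   `[0, 1]`. Column names identify the dye pair: `"YR"` for two-color
#'   data, `"BY"`, `"BR"`, `"YR"` for three-color data, `"I"` for a
#'   single-color intensity level.
#'
#' @return An object of class `kinetic_model` with elements `n_states`,
#'   `rates` and `fret`.
#' @examples
#' m <- kinetic_model(rates = matrix(c(0, 1, 0.5, 0), 2, 2, byrow = TRUE),
#'                    fret = cbind(YR = c(0.8, 0.2)))
#' stationary_distribution(m)
#' @export
kinetic_model <- function(rates, fret) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  if (ncol(rates) != n)
    stop("'rates' must be a square matrix")
  if (n < 1L || n > 4L)
    stop("between 1 and 4 states are supported")
  off <- rates
  diag(off) <- 0
  if (any(off < 0))
    stop("off-diagonal rates must be >= 0")
  diag(rates) <- -rowSums(off)
  fret <- as.matrix(fret)
  if (nrow(fret) != n)
    stop("'fret' must have one row per state")
  if (is.null(colnames(fret)))
    stop("'fret' columns must be named by dye pair (e.g. \"YR\")")
  if (any(fret < 0 | fret > 1))
    stop("per-state efficiencies must lie in [0, 1]")
  if (all(c("BY", "BR") %in% colnames(fret)) &&
      any(fret[, "BY"] + fret[, "BR"] > 0.95 + 1e-12))
    stop("E_BY + E_BR must not exceed 0.95 in any state")
  structure(list(n_states = n, rates = rates, fret = fret),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Kinetic model: %d state(s)\n", x$n_states))
  if (x$n_states > 1L) {
    dwell <- -1 / diag(x$rates)
    cat("mean dwell times (s):", paste(signif(dwell, 4), collapse = ", "),
        "\n")
  }
  cat("per-state observables:\n")
  print(round(x$fret, 3))
  invisible(x)
}

#' Stationary distribution of a kinetic model
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum_i \pi_i = 1} for the rate matrix `Q`.
#'
#' @param model a [kinetic_model()].
#' @return numeric vector of stationary occupancies.
#' @export
stationary_distribution <- function(model) {
  n <- model$n_states
  if (n == 1L) return(1)
  A <- rbind(t(model$rates), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  pi / sum(pi)
}

# expected dwell in frames for each state
dwell_frames <- function(model, frame_time) {
  if (model$n_states == 1L) return(Inf)
  -1 / diag(model$rates) / frame_time
}

#' Draw a random kinetic model from a simulation envelope
#'
#' States, per-state FRET efficiencies and exchange rates are drawn from
#' the configured ranges: efficiencies uniformly on `e_range` with a
#' minimum pairwise contrast (degenerate draws are rejected and redrawn),
#' mean dwell times log-uniformly on `dwell_range` (in frames) and
#' converted to rates using the configured frame time. For multi-state
#' models the exit rate of each state is split at random between the
#' possible destination states.
#'
#' @param config a [sim_config()].
#' @param n_states optional fixed state count; by default drawn uniformly
#'   from `config$n_states_set`.
#' @return a [kinetic_model()].
#' @export
sample_kinetic_model <- function(config, n_states = NULL) {
  if (is.null(n_states))
    n_states <- if (length(config$n_states_set) == 1L) config$n_states_set
                else sample(config$n_states_set, 1L)
  pairs <- switch(config$modality,
    "1c"      = "I",
    "2c"      = ,
    "2c_alex" = "YR",
    "3c_alex" = c("BY", "BR", "YR"))
  fret <- draw_state_observables(n_states, pairs, config$e_range,
                                 config$min_contrast)
  rates <- matrix(0, n_states, n_states)
  if (n_states > 1L) {
    ## log-uniform mean dwell in frames -> exit rate in 1/s
    dw <- exp(stats::runif(n_states, log(config$dwell_range[1]),
                           log(config$dwell_range[2])))
    exit <- 1 / (dw * config$frame_time)
    for (i in seq_len(n_states)) {
      dest <- setdiff(seq_len(n_states), i)
      w <- stats::runif(length(dest))
      rates[i, dest] <- exit[i] * w / sum(w)
    }
  }
  kinetic_model(rates, fret)
}

# rejection sampler for per-state observables with minimum contrast on
# every pair of states (applied to the kinetically informative columns)
draw_state_observables <- function(n_states, pairs, e_range, min_contrast) {
  for (attempt in seq_len(50000L)) {
    fret <- matrix(stats::runif(n_states * length(pairs),
                                e_range[1], e_range[2]),
                   n_states, length(pairs),
                   dimnames = list(NULL, pairs))
    if ("BY" %in% pairs) {
      ## keep the three-color forward model physical
      s <- fret[, "BY"] + fret[, "BR"]
      bad <- s > 0.95
      if (any(bad)) {
        fret[bad, c("BY", "BR")] <- fret[bad, c("BY", "BR")] *
          (0.95 / s[bad]) * stats::runif(sum(bad), 0.7, 1)
      }
    }
    if (n_states == 1L) return(fret)
    ## contrast: states must differ by >= min_contrast in at least one
    ## informative observable
    d <- as.matrix(stats::dist(fret, method = "maximum"))
    if (min(d[upper.tri(d)]) >= min_contrast) return(fret)
  }
  stop("could not draw ", n_states,
       " states with the requested contrast; relax 'min_contrast' or widen ",
       "'e_range'")
}

#' Sample a continuous-time Markov state path
#'
#' Draws an exact trajectory of the continuous-time Markov jump process
#' (exponential waiting times, embedded jump chain) and bins it onto
#' camera frames. Because the chain runs in continuous time, a frame over
#' which a jump occurs is genuinely mixed: the occupancy matrix records
#' the fraction of each frame spent in every state, which is what the
#' detector integrates.
#'
#' @param model a [kinetic_model()].
#' @param n_frames number of camera frames.
#' @param frame_time frame duration in seconds.
#' @return list with `events` (data.frame of `state`, `t_start`, `t_end`
#'   in seconds) and `occupancy` (`n_frames` x `n_states` matrix of
#'   within-frame occupancy fractions, rows summing to 1).
#' @export
sample_state_path <- function(model, n_frames, frame_time) {
  n <- model$n_states
  total <- n_frames * frame_time
  if (n == 1L) {
    return(list(events = data.frame(state = 1L, t_start = 0, t_end = total),
                occupancy = matrix(1, n_frames, 1L)))
  }
  pi0 <- stationary_distribution(model)
  s <- sample.int(n, 1L, prob = pi0)
  exit <- -diag(model$rates)
  jump_prob <- model$rates
  diag(jump_prob) <- 0
  jump_prob <- jump_prob / pmax(exit, .Machine$double.eps)
  ## preallocate for the expected number of jumps, grow by doubling
  cap <- max(32L, ceiling(1.5 * total * max(exit)))
  states <- integer(cap); starts <- numeric(cap)
  m <- 0L; t <- 0
  while (t < total) {
    m <- m + 1L
    if (m > cap) {
      cap <- 2L * cap
      length(states) <- cap; length(starts) <- cap
    }
    states[m] <- s; starts[m] <- t
    t <- t + stats::rexp(1L, exit[s])
    s <- sample.int(n, 1L, prob = jump_prob[s, ])
  }
  states <- states[seq_len(m)]; starts <- starts[seq_len(m)]
  ends <- c(starts[-1L], total)
  events <- data.frame(state = states, t_start = starts,
                       t_end = pmin(ends, total))
  occ <- matrix(0, n_frames, n)
  for (i in seq_len(nrow(events))) {
    f0 <- floor(events$t_start[i] / frame_time) + 1L
    f1 <- min(ceiling(events$t_end[i] / frame_time), n_frames)
    if (f1 < f0) next
    fr <- f0:f1
    ov <- pmin(events$t_end[i], fr * frame_time) -
          pmax(events$t_start[i], (fr - 1) * frame_time)
    occ[fr, events$state[i]] <- occ[fr, events$state[i]] + ov / frame_time
  }
  list(events = events, occupancy = occ)
}
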