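## Dwell-time and transition analysis of per-frame state paths.

#' Extract transitions and dwells from a state path
#'
#' Maximal constant runs of the path become dwells; each transition
#' records the states and mean observable before and after the jump.
#' The first run of a segment is truncated by the segment start, and the
#' last run never exits: transitions out of a truncated first dwell
#' still enter the TDP (both flanking dwells exist), but only interior
#' dwells enter dwell-time statistics, because truncated dwells bias
#' the fitted residence time downward.
#'
#' @param states integer per-frame state path (from a state classifier,
#'   an HMM, or ground truth); 0/NA frames are dropped from the ends.
#' @param frame_time seconds per frame.
#' @param observable optional per-frame observable (normalized intensity
#'   for one-color data, apparent FRET otherwise) averaged over each
#'   dwell for the TDP axes; defaults to the state index.
#' @return object of class `transition_table`: data.frame with
#'   `from_state`, `to_state`, `dwell_frames`, `dwell_s` (residence in
#'   `from_state` before the jump), `from_value`, `to_value`,
#'   `interior` (dwell usable for statistics).
#' @export
extract_transitions <- function(states, frame_time, observable = NULL) {
  keep <- which(!is.na(states) & states > 0L)
  empty <- data.frame(from_state = integer(0), to_state = integer(0),
                      dwell_frames = integer(0), dwell_s = numeric(0),
                      from_value = numeric(0), to_value = numeric(0),
                      interior = logical(0))
  class(empty) <- c("transition_table", "data.frame")
  attr(empty, "frame_time") <- frame_time
  if (length(keep) == 0L) return(empty)
  span <- keep[1]:keep[length(keep)]
  s <- states[span]
  obs <- if (is.null(observable)) as.numeric(states) else observable
  obs <- obs[span]
  r <- rle(s)
  n_runs <- length(r$lengths)
  if (n_runs < 2L) return(empty)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  run_mean <- vapply(seq_len(n_runs), function(i)
    mean(obs[starts[i]:ends[i]], na.rm = TRUE), numeric(1))
  j <- seq_len(n_runs - 1L)
  out <- data.frame(
    from_state = r$values[j], to_state = r$values[j + 1L],
    dwell_frames = r$lengths[j],
    dwell_s = r$lengths[j] * frame_time,
    from_value = run_mean[j], to_value = run_mean[j + 1L],
    interior = j > 1L)
  class(out) <- c("transition_table", "data.frame")
  attr(out, "frame_time") <- frame_time
  out
}

#' Merge transition tables from many traces
#'
#' @param tables list of [extract_transitions()] results.
#' @return a single `transition_table`.
#' @export
bind_transitions <- function(tables) {
  tables <- Filter(function(t) nrow(t) > 0L, tables)
  if (length(tables) == 0L)
    return(extract_transitions(integer(0), 1))
  ft <- attr(tables[[1]], "frame_time")
  out <- do.call(rbind, lapply(tables, as.data.frame))
  class(out) <- c("transition_table", "data.frame")
  attr(out, "frame_time") <- ft
  out
}

#' Transition density plot
#'
#' 2-D histogram of the mean observable before versus after each
#' transition. Clusters mark the interconverting states; for multi-pair
#' data build one TDP per pair.
#'
#' @param table a `transition_table`.
#' @param bins number of bins per axis.
#' @param range observable range covered by the histogram.
#' @return object of class `tdp`: `counts` (bins x bins, rows = value
#'   before), `mids`, `n` transitions.
#' @export
build_tdp <- function(table, bins = 100L, range = c(0, 1)) {
  if (nrow(table) == 0L) stop("empty transition table")
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  fx <- findInterval(pmin(pmax(table$from_value, range[1]), range[2]),
                     breaks, all.inside = TRUE)
  fy <- findInterval(pmin(pmax(table$to_value, range[1]), range[2]),
                     breaks, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (i in seq_along(fx))
    counts[fx[i], fy[i]] <- counts[fx[i], fy[i]] + 1L
  structure(list(counts = counts,
                 mids = (utils::head(breaks, -1) +
                           utils::tail(breaks, -1)) / 2,
                 n = nrow(table), range = range),
            class = "tdp")
}

#' @export
print.tdp <- function(x, ...) {
  cat(sprintf("tdp: %d transitions, %d x %d bins over [%g, %g]\n",
              x$n, nrow(x$counts), ncol(x$counts), x$range[1], x$range[2]))
  invisible(x)
}

#' @export
plot.tdp <- function(x, ...) {
  graphics::image(x$mids, x$mids, sqrt(x$counts),
                  xlab = "value before transition",
                  ylab = "value after transition",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Gate a transition table by TDP rectangles
#'
#' Programmatic replacement for the manual selection of TDP clusters:
#' each rectangle (in TDP coordinates: value before, value after)
#' collects the dwell times of the transitions falling inside it.
#' Rectangles are serializable, so gates rerun unattended. Overlapping
#' gates warn; transitions go to the first matching gate.
#'
#' @param table a `transition_table`.
#' @param rectangles named list of `c(xmin, xmax, ymin, ymax)`.
#' @param interior_only use only interior (untruncated) dwells.
#' @return named list of dwell-time vectors (seconds), one per gate.
#' @export
gate_tdp <- function(table, rectangles, interior_only = TRUE) {
  stopifnot(length(rectangles) >= 1L)
  tab <- if (interior_only) table[table$interior, , drop = FALSE] else table
  hit <- sapply(rectangles, function(r)
    tab$from_value >= r[1] & tab$from_value <= r[2] &
      tab$to_value >= r[3] & tab$to_value <= r[4])
  hit <- matrix(hit, nrow = nrow(tab))
  if (any(rowSums(hit) > 1L))
    warning("overlapping gates: transitions assigned to the first match")
  assign <- apply(hit, 1, function(h) if (any(h)) which(h)[1] else NA_integer_)
  out <- lapply(seq_along(rectangles), function(g)
    tab$dwell_s[!is.na(assign) & assign == g])
  names(out) <- names(rectangles) %||%
    paste0("gate", seq_along(rectangles))
  out
}

#' Fit a mono-exponential to the dwell-time CDF
#'
#' Least-squares fit of `1 - exp(-(t - t_min) / tau)` to the empirical
#' cumulative distribution at the sorted dwell values; the 95%
#' confidence interval comes from the Jacobian-based covariance estimate
#' of the fit. The `t_min` shift accounts for left-censoring: dwells
#' shorter than one frame are unobservable in frame-quantized paths, and
#' by the memorylessness of the exponential the observable dwells follow
#' a shifted exponential with the same `tau`. By default `t_min` is the
#' shortest observed dwell, which is negligible for uncensored data and
#' removes most of the quantization bias for frame-limited data.
#'
#' @param dwells dwell times in seconds (>= 10 values required).
#' @param t_min left-censoring threshold in seconds; `NULL` (default)
#'   uses the minimum observed dwell, 0 disables the shift.
#' @return object of class `dwell_fit`: `tau` (s), `ci95`, `n_dwells`,
#'   `r_squared`, `fit` (the underlying nls object).
#' @export
fit_dwell_cdf <- function(dwells, t_min = NULL) {
  dwells <- dwells[is.finite(dwells) & dwells > 0]
  n <- length(dwells)
  if (n < 10L)
    stop("need at least 10 dwells to fit, got ", n)
  t <- sort(dwells)
  if (is.null(t_min))
    t_min <- if (length(unique(t)) > 1L) t[1] else 0
  Femp <- seq_len(n) / n
  df <- data.frame(t = t - t_min, F = Femp)
  fit <- minpack.lm::nlsLM(F ~ 1 - exp(-t / tau), data = df,
                           start = list(tau = max(mean(t) - t_min, 1e-9)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  tau <- stats::coef(fit)[["tau"]]
  se <- sqrt(stats::vcov(fit)[1, 1])
  ci <- tau + c(-1, 1) * stats::qt(0.975, n - 1L) * se
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((Femp - mean(Femp))^2)
  structure(list(tau = tau, ci95 = ci, n_dwells = n,
                 r_squared = 1 - ss_res / ss_tot, fit = fit),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("dwell_fit: tau = %.4g s (95%% CI %.4g-%.4g), n = %d, R2 = %.4f\n",
              x$tau, x$ci95[1], x$ci95[2], x$n_dwells, x$r_squared))
  if (x$r_squared < 0.9)
    cat("  warning: poor mono-exponential fit (R2 < 0.9)\n")
  invisible(x)
}

#' @export
coef.dwell_fit <- function(object, ...) c(tau = object$tau)

#' Compare two empirical dwell-time CDFs
#'
#' Evaluates both empirical CDFs on a common time grid and reports the
#' pointwise difference, its maximum absolute value and mean absolute
#' value — the standard parity check between two kinetic analysis
#' routes of the same data.
#'
#' @param dwellsA,dwellsB dwell-time vectors (seconds).
#' @param grid_n number of grid points.
#' @return list with `t`, `delta` (CDF_A - CDF_B), `max_abs`, `mean_abs`.
#' @export
compare_cdfs <- function(dwellsA, dwellsB, grid_n = 200L) {
  tmax <- max(dwellsA, dwellsB)
  t <- seq(0, tmax, length.out = grid_n)
  FA <- stats::ecdf(dwellsA)(t)
  FB <- stats::ecdf(dwellsB)(t)
  delta <- FA - FB
  list(t = t, delta = delta, max_abs = max(abs(delta)),
       mean_abs = mean(abs(delta)))
}
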