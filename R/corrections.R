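## Photobleaching-based FRET correction factors and accurate FRET.
##
## Frames classified into photoactive-set categories carry the
## information needed to calibrate the detection path of a FRET pair:
## donor-only stretches give the crosstalk alpha, acceptor-only
## stretches the direct excitation delta, and an acceptor bleaching step
## inside an otherwise active region the detection-efficiency ratio
## gamma. Trace-wise values are pooled into dataset medians which stand
## in whenever a trace does not expose the required segment.

# donor/FRET/acceptor channel names of a dye pair within a modality
pair_channels <- function(modality, pair = "YR") {
  if (modality == "1c") stop("single-color data has no FRET pair")
  if (modality %in% c("2c", "2c_alex")) {
    stopifnot(pair == "YR")
    return(list(dd = "DD", da = "DA",
                aa = if (modality == "2c_alex") "AA" else NA_character_))
  }
  switch(pair,
    YR = list(dd = "YY", da = "YR", aa = "RR"),
    BY = list(dd = "BB", da = "BY", aa = "YY"),
    BR = list(dd = "BB", da = "BR", aa = "RR"),
    stop("unknown pair: ", pair))
}

pair_dyes <- function(pair) strsplit(pair, "")[[1]]

# per-channel background: mean over all-bleached frames, else 0
estimate_background <- function(trace, segments) {
  ch <- trace$channels
  bg <- stats::setNames(numeric(ncol(ch)), colnames(ch))
  idx <- which(segments$labels == "bleached")
  if (length(idx) >= 5L) bg[] <- colMeans(ch[idx, , drop = FALSE])
  bg
}

# frames where exactly the donor (or acceptor) of `pair` is active; the
# first/last `trim` frames of every such run are dropped because frames
# adjacent to a bleach step are mixed and bias the window means
pair_only_frames <- function(segments, pair, which = c("donor", "acceptor"),
                             trim = 2L) {
  which <- match.arg(which)
  d <- pair_dyes(pair)
  keep <- if (which == "donor") c(TRUE, FALSE) else c(FALSE, TRUE)
  has <- vapply(segments$labels, function(l)
    label_has_dye(l, d[1], segments$modality) == keep[1] &&
    label_has_dye(l, d[2], segments$modality) == keep[2], logical(1))
  r <- rle(has)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  unlist(lapply(which(r$values), function(i) {
    s <- starts[i] + trim; e <- ends[i] - trim
    if (s <= e) s:e else integer(0)
  }), use.names = FALSE)
}

#' Estimate the crosstalk factor alpha of one trace
#'
#' alpha is the fraction of donor emission detected in the acceptor
#' channel, measured on donor-only frames (acceptor photobleached, donor
#' active) after background subtraction.
#'
#' @param trace a [labeled_trace].
#' @param segments a [segment_trace()] result for the trace.
#' @param pair dye pair (`"YR"`, or `"BY"`/`"BR"` for three-color data).
#' @param min_frames minimum usable frames; fewer returns `NA`.
#' @return alpha, or `NA_real_` when the trace has no donor-only segment.
#' @export
estimate_alpha <- function(trace, segments, pair = "YR", min_frames = 10L) {
  chn <- pair_channels(trace$modality, pair)
  idx <- pair_only_frames(segments, pair, "donor")
  if (length(idx) < min_frames) return(NA_real_)
  bg <- estimate_background(trace, segments)
  dd <- trace$channels[idx, chn$dd] - bg[chn$dd]
  da <- trace$channels[idx, chn$da] - bg[chn$da]
  mean(da) / mean(dd)
}

#' Estimate the direct-excitation factor delta of one trace
#'
#' delta is the acceptor signal under donor excitation caused by direct
#' excitation, normalized to the acceptor-excitation signal; measured on
#' acceptor-only frames (donor photobleached). Requires alternating
#' excitation: for continuous-wave two-color data the factor is not
#' obtainable and `NA` is returned with a diagnostic attribute.
#'
#' @inheritParams estimate_alpha
#' @return delta, or `NA_real_` when not estimable.
#' @export
estimate_delta <- function(trace, segments, pair = "YR", min_frames = 10L) {
  chn <- pair_channels(trace$modality, pair)
  if (is.na(chn$aa)) {
    out <- NA_real_
    attr(out, "reason") <- "no acceptor-excitation channel (CW data)"
    return(out)
  }
  idx <- pair_only_frames(segments, pair, "acceptor")
  if (length(idx) < min_frames) return(NA_real_)
  bg <- estimate_background(trace, segments)
  da <- trace$channels[idx, chn$da] - bg[chn$da]
  aa <- trace$channels[idx, chn$aa] - bg[chn$aa]
  mean(da) / mean(aa)
}

#' Estimate the detection-efficiency factor gamma of one trace
#'
#' gamma is measured across an acceptor photobleaching step inside an
#' otherwise photoactive region: the drop in sensitized emission
#' `F_sens = I_DA - alpha * I_DD - delta * I_AA` divided by the rise in
#' donor emission. Two frames on either side of the bleach frame are
#' excluded so mixed frames do not bias the window means.
#'
#' @inheritParams estimate_alpha
#' @param alpha,delta resolved crosstalk/direct-excitation factors.
#' @param window max frames per side used for the means.
#' @param exclude frames dropped around the bleach step.
#' @return gamma, or `NA_real_` when no valid bleach step exists or the
#'   intensity differences have an unphysical sign.
#' @export
estimate_gamma <- function(trace, segments, alpha, delta, pair = "YR",
                           min_frames = 10L, window = 200L, exclude = 2L) {
  chn <- pair_channels(trace$modality, pair)
  d <- pair_dyes(pair)
  b <- segments$bleach[d[2]]
  if (is.na(b)) return(NA_real_)
  lab <- segments$labels
  both <- vapply(lab, function(l)
    label_has_dye(l, d[1], segments$modality) &&
    label_has_dye(l, d[2], segments$modality), logical(1))
  donly <- pair_only_frames(segments, pair, "donor")
  pre <- which(both)
  pre <- pre[pre < b - exclude]
  pre <- utils::tail(pre[pre >= b - exclude - window], window)
  post <- donly[donly >= b + exclude & donly <= b + exclude + window]
  ## the post window must be contiguous donor-only right after the bleach
  if (length(pre) < min_frames || length(post) < min_frames)
    return(NA_real_)
  bg <- estimate_background(trace, segments)
  ch <- sweep(trace$channels, 2, bg[colnames(trace$channels)])
  aa <- if (is.na(chn$aa)) 0 else ch[, chn$aa]
  fsens <- ch[, chn$da] - alpha * ch[, chn$dd] - delta * aa
  dF <- mean(fsens[pre]) - mean(fsens[post])
  dD <- mean(ch[post, chn$dd]) - mean(ch[pre, chn$dd])
  if (!is.finite(dF) || !is.finite(dD) || dF <= 0 || dD <= 0)
    return(NA_real_)
  dF / dD
}

#' Trace-wise and median correction factors for a set of traces
#'
#' Runs the alpha/delta/gamma estimators on every classified trace and
#' summarizes the dataset medians. Downstream corrections use the
#' trace-wise value where obtainable and the dataset median otherwise.
#'
#' @param traces list of [labeled_trace].
#' @param segments_list list of [segment_trace()] results (same order).
#' @param pair dye pair.
#' @param min_frames minimum frames per estimator segment.
#' @return object of class `correction_factors`: `table` (one row per
#'   trace: id, alpha, delta, gamma), `median` (named vector), `pair`.
#' @export
correction_factors <- function(traces, segments_list, pair = "YR",
                               min_frames = 10L) {
  stopifnot(length(traces) == length(segments_list))
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]; sg <- segments_list[[i]]
    a <- estimate_alpha(tr, sg, pair, min_frames)
    d <- estimate_delta(tr, sg, pair, min_frames)
    data.frame(id = tr$id, alpha = as.numeric(a), delta = as.numeric(d),
               gamma = NA_real_, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  med_a <- stats::median(tab$alpha, na.rm = TRUE)
  med_d <- stats::median(tab$delta, na.rm = TRUE)
  if (!is.finite(med_d)) med_d <- 0
  for (i in seq_along(traces)) {
    a <- if (is.finite(tab$alpha[i])) tab$alpha[i] else med_a
    d <- if (is.finite(tab$delta[i])) tab$delta[i] else med_d
    tab$gamma[i] <- estimate_gamma(traces[[i]], segments_list[[i]],
                                   alpha = a, delta = d, pair = pair,
                                   min_frames = min_frames)
  }
  med <- c(alpha = med_a, delta = med_d,
           gamma = stats::median(tab$gamma, na.rm = TRUE))
  structure(list(table = tab, median = med, pair = pair),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  n <- colSums(!is.na(x$table[c("alpha", "delta", "gamma")]))
  cat(sprintf("correction_factors (%s pair): medians alpha=%.4f delta=%.4f gamma=%.4f\n",
              x$pair, x$median["alpha"], x$median["delta"],
              x$median["gamma"]))
  cat(sprintf("  trace-wise estimates: alpha n=%d, delta n=%d, gamma n=%d of %d traces\n",
              n[1], n[2], n[3], nrow(x$table)))
  invisible(x)
}

# trace value if present, else dataset median; error when neither exists
resolve_factors <- function(cf, id) {
  row <- cf$table[cf$table$id == id, , drop = FALSE]
  pick <- function(nm) {
    v <- if (nrow(row) && is.finite(row[[nm]])) row[[nm]] else cf$median[[nm]]
    if (!is.finite(v)) stop("correction factor '", nm,
                            "' unavailable (no trace-wise value, no median)")
    v
  }
  c(alpha = pick("alpha"), delta = pick("delta"), gamma = pick("gamma"))
}

#' Apparent FRET efficiencies (proximity ratios)
#'
#' The uncorrected acceptor fraction per frame and dye pair:
#' `I_DexAem / (I_DexAem + I_DexDem)`. Frames with a non-positive
#' denominator are marked `NA`.
#'
#' @param trace a [labeled_trace] or channel matrix with named columns.
#' @param modality required for a bare matrix.
#' @return matrix (frames x pairs) of apparent efficiencies.
#' @export
apparent_fret <- function(trace, modality = NULL) {
  ch <- if (inherits(trace, "labeled_trace")) trace$channels else trace
  modality <- modality %||%
    (if (inherits(trace, "labeled_trace")) trace$modality else
       stop("'modality' required"))
  pairs <- modality_pairs(modality)
  out <- sapply(pairs, function(p) {
    chn <- pair_channels(modality, p)
    den <- ch[, chn$da] + ch[, chn$dd]
    e <- ch[, chn$da] / den
    e[den <= 0] <- NA_real_
    e
  })
  matrix(out, nrow = nrow(ch), dimnames = list(NULL, pairs))
}

#' Accurate FRET efficiency for two-color data
#'
#' Applies crosstalk, direct-excitation and detection-efficiency
#' corrections: `F = I_DA - alpha I_DD - delta I_AA`,
#' `E = F / (F + gamma I_DD)`. Corrected efficiencies are deliberately
#' not clipped to `[0, 1]`; noise can push them outside and clipping
#' would hide miscorrection.
#'
#' @param trace a [labeled_trace] (modality `"2c"` or `"2c_alex"`).
#' @param factors named vector/list with `alpha`, `delta`, `gamma`
#'   (e.g. from [resolve_factors()] or ground truth).
#' @param background optional named per-channel background counts.
#' @return object of class `fret_trace` with `apparent` and `corrected`
#'   (frames x pairs matrices).
#' @export
corrected_fret_2c <- function(trace, factors, background = NULL) {
  stopifnot(trace$modality %in% c("2c", "2c_alex"))
  factors <- as.list(factors)
  need <- c("alpha", "delta", "gamma")
  have <- need %in% names(factors) &
    vapply(need, function(n) is.finite(factors[[n]] %||% NA_real_),
           logical(1))
  if (!all(have))
    stop("missing correction factor(s): ", paste(need[!have], collapse = ", "))
  ch <- trace$channels
  if (!is.null(background)) ch <- sweep(ch, 2, background[colnames(ch)])
  aa <- if ("AA" %in% colnames(ch)) ch[, "AA"] else 0
  F_ <- ch[, "DA"] - factors[["alpha"]] * ch[, "DD"] - factors[["delta"]] * aa
  E <- F_ / (F_ + factors[["gamma"]] * ch[, "DD"])
  structure(list(apparent = apparent_fret(trace),
                 corrected = matrix(E, ncol = 1,
                                    dimnames = list(NULL, "YR")),
                 states = NULL, modality = trace$modality),
            class = "fret_trace")
}

#' Accurate FRET efficiencies for three-color data
#'
#' The yellow-red pair is corrected exactly as two-color data from the
#' yellow-excitation block. For the blue-excitation block the corrected
#' emissions `I_B, I_Y, I_R` (crosstalk and direct excitation
#' subtracted, gamma-scaled) are combined with the *state-averaged*
#' corrected YR efficiency of each frame's state:
#' `E_BY = I_Y / (T (1 - E_YR))`, `E_BR = 1 - I_B/T - E_BY` with
#' `T = I_B + I_Y + I_R`. Using the state mean instead of the noisy
#' per-frame `E_YR` keeps the `1/(1 - E_YR)` factor from amplifying
#' shot noise. `E_YR` state means are clamped at 0.95; frames whose mean
#' exceeds the clamp are flagged.
#'
#' @param trace a [labeled_trace] (modality `"3c_alex"`).
#' @param factors list with named per-pair vectors `alpha`, `delta`,
#'   `gamma` (names `"BY"`, `"BR"`, `"YR"`).
#' @param states per-frame state indices used for state-averaging (e.g.
#'   from [classify_states()] or ground truth); 0/NA frames fall back to
#'   the global mean.
#' @param background optional named per-channel background counts.
#' @param clamp upper bound applied to the state-averaged YR efficiency.
#' @return object of class `fret_trace` with `apparent`, `corrected`
#'   (frames x `c("BY","BR","YR")`), `flagged` frames.
#' @export
corrected_fret_3c <- function(trace, factors, states = NULL,
                              background = NULL, clamp = 0.95) {
  stopifnot(trace$modality == "3c_alex")
  al <- factors$alpha; de <- factors$delta; ga <- factors$gamma
  need <- c("BY", "BR", "YR")
  if (!all(need %in% names(al)) || !all(need %in% names(de)) ||
      !all(need %in% names(ga)))
    stop("three-color correction needs alpha/delta/gamma for pairs BY, BR, YR")
  ch <- trace$channels
  if (!is.null(background)) ch <- sweep(ch, 2, background[colnames(ch)])
  ## YR pair from the yellow-excitation block
  Fyr <- ch[, "YR"] - al["YR"] * ch[, "YY"] - de["YR"] * ch[, "RR"]
  Eyr <- Fyr / (Fyr + ga["YR"] * ch[, "YY"])
  ## state-averaged YR efficiency per frame
  if (is.null(states)) states <- rep(1L, nrow(ch))
  st <- ifelse(is.na(states) | states == 0L, NA_integer_, states)
  mns <- tapply(Eyr, st, mean, na.rm = TRUE)
  Ebar <- rep(mean(Eyr, na.rm = TRUE), nrow(ch))
  ok <- !is.na(st)
  Ebar[ok] <- mns[as.character(st[ok])]
  flagged <- which(Ebar >= clamp)
  Ebar <- pmin(Ebar, clamp)
  ## blue-excitation block: invert the cascade
  sY <- (ch[, "BY"] - al["BY"] * ch[, "BB"] - de["BY"] * ch[, "YY"]) / ga["BY"]
  sR <- (ch[, "BR"] - al["BR"] * ch[, "BB"] - al["YR"] * ga["BY"] * sY -
           de["BR"] * ch[, "RR"]) / ga["BR"]
  Tt <- ch[, "BB"] + sY + sR
  Eby <- sY / (Tt * (1 - Ebar))
  Ebr <- 1 - ch[, "BB"] / Tt - Eby
  corrected <- cbind(BY = Eby, BR = Ebr, YR = Eyr)
  structure(list(apparent = apparent_fret(trace), corrected = corrected,
                 states = states, flagged = flagged,
                 modality = trace$modality),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("fret_trace (%s): %d frames, pairs %s\n", x$modality,
              nrow(x$corrected), paste(colnames(x$corrected),
                                       collapse = ", ")))
  cat("  corrected means:",
      paste(sprintf("%s=%.3f", colnames(x$corrected),
                    colMeans(x$corrected, na.rm = TRUE)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Convert a FRET efficiency to a dye-pair distance
#'
#' `R = R0 * (1/E - 1)^(1/6)` with the Forster radius `R0` in the same
#' unit as the result (conventionally Angstrom).
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param R0 Forster radius (> 0).
#' @return distance in the unit of `R0`.
#' @examples
#' fret_to_distance(0.5, 68)   # == R0
#' @export
fret_to_distance <- function(E, R0) {
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1))
    stop("E must lie strictly inside (0, 1)")
  if (any(R0 <= 0)) stop("R0 must be positive")
  R0 * (1 / E - 1)^(1 / 6)
}

#' FRET efficiency histograms
#'
#' Frame-wise mode bins one entry per usable frame; state-wise mode bins
#' one entry per dwell (mean efficiency over the dwell) weighted by the
#' dwell length in frames, which suppresses shot noise while preserving
#' occupancy. The binning range extends beyond `[0, 1]` so that
#' miscorrection remains visible.
#'
#' @param values numeric efficiencies per frame (one pair).
#' @param states per-frame state path, required for state-wise mode.
#' @param mode `"framewise"` or `"statewise"`.
#' @param breaks histogram breaks.
#' @return data.frame with `mid` (bin center) and `count`.
#' @export
build_histograms <- function(values, states = NULL,
                             mode = c("framewise", "statewise"),
                             breaks = seq(-0.2, 1.2, by = 0.02)) {
  mode <- match.arg(mode)
  if (mode == "framewise") {
    v <- values[is.finite(values)]
    v <- v[v >= breaks[1] & v <= breaks[length(breaks)]]
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    return(data.frame(mid = h$mids, count = h$counts))
  }
  stopifnot(!is.null(states), length(states) == length(values))
  r <- rle(states)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  count <- numeric(length(mids))
  for (i in seq_along(starts)) {
    if (r$values[i] == 0L || is.na(r$values[i])) next
    m <- mean(values[starts[i]:ends[i]], na.rm = TRUE)
    bin <- findInterval(m, breaks, all.inside = TRUE)
    count[bin] <- count[bin] + r$lengths[i]
  }
  data.frame(mid = mids, count = count)
}
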