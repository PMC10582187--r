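#' Majority-filter a label sequence
#'
#' Replaces each frame's label by the majority over a centered window,
#' absorbing short spurious label islands (single-frame flicker) that
#' per-frame classifiers occasionally produce.
#'
#' @param labels character/integer vector of per-frame labels.
#' @param k window size in frames (odd).
#' @return smoothed label vector of the same type.
#' @export
majority_filter <- function(labels, k = 3L) {
  if (k <= 1L || length(labels) < k) return(labels)
  lv <- unique(labels)
  ind <- outer(labels, lv, "==") + 0
  sm <- stats::filter(ind, rep(1, k), sides = 2)
  sm[is.na(sm)] <- ind[is.na(sm)]
  lv[max.col(sm, ties.method = "first")]
}

#' Segment a classified trace
#'
#' Derives the analysis structure from per-frame category labels: the
#' longest run with all dyes photoactive (the usable segment), whether it
#' is dynamic, the first frame at which each dye is no longer photoactive
#' (its bleach index), and the full run-length table used by the
#' correction-factor estimators (donor-only, acceptor-only and
#' all-bleached stretches). Labels are majority-smoothed first.
#'
#' @param fc a [classify_frames()] result, or a character vector of
#'   per-frame labels (with `modality` supplied).
#' @param modality required when `fc` is a bare label vector.
#' @param min_run majority-filter window; label islands shorter than this
#'   are absorbed.
#' @return object of class `trace_segments`: `segment` (`c(start, end)`
#'   or `NULL` when no usable segment exists), `dynamic`, `bleach`
#'   (named per-dye first-bleached frame index, `NA` if never), `runs`
#'   (data.frame of `label`, `start`, `end`), `labels` (smoothed).
#' @export
segment_trace <- function(fc, modality = NULL, min_run = 3L) {
  if (inherits(fc, "frame_classification")) {
    labels <- fc$labels
    modality <- fc$modality
  } else labels <- fc
  if (is.null(modality)) stop("'modality' required for bare label vectors")
  labels <- majority_filter(labels, min_run)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  runs <- data.frame(label = r$values,
                     start = ends - r$lengths + 1L, end = ends,
                     stringsAsFactors = FALSE)
  all_active <- grep("dynamic|static", category_alphabet(modality),
                     value = TRUE)
  cand <- runs[runs$label %in% all_active, , drop = FALSE]
  segment <- NULL; dynamic <- FALSE
  if (nrow(cand)) {
    best <- cand[which.max(cand$end - cand$start), ]
    segment <- c(best$start, best$end)
    dynamic <- grepl("dynamic", best$label)
  }
  dyes <- modality_dyes(modality)
  bleach <- stats::setNames(rep(NA_integer_, length(dyes)), dyes)
  for (d in dyes) {
    off <- !vapply(labels, label_has_dye, logical(1), dye = d,
                   modality = modality)
    if (any(off)) bleach[d] <- which(off)[1]
  }
  structure(list(segment = segment, dynamic = dynamic, bleach = bleach,
                 runs = runs, labels = labels, modality = modality),
            class = "trace_segments")
}

# is dye `dye` photoactive under a given per-frame label?
label_has_dye <- function(label, dye, modality) {
  if (label %in% c("noisy", "aggregate", "artifact", "bleached"))
    return(FALSE)
  if (modality == "1c") return(label %in% c("dynamic", "static"))
  if (modality %in% c("2c", "2c_alex")) {
    active <- switch(label,
      "DA-dynamic" = , "DA-static" = c("Y", "R"),
      "D-only" = "Y", "A-only" = "R", character(0))
    return(dye %in% active)
  }
  active <- switch(label,
    "BYR-dynamic" = , "BYR-static" = c("B", "Y", "R"),
    strsplit(label, "")[[1]])
  dye %in% active
}

#' @export
print.trace_segments <- function(x, ...) {
  if (is.null(x$segment)) cat("trace_segments: no usable segment\n")
  else cat(sprintf("trace_segments: %s segment %d-%d (%d frames)\n",
                   if (x$dynamic) "dynamic" else "static",
                   x$segment[1], x$segment[2], diff(x$segment) + 1L))
  bl <- x$bleach[!is.na(x$bleach)]
  if (length(bl))
    cat("  bleach indices:",
        paste(sprintf("%s@%d", names(bl), bl), collapse = ", "), "\n")
  invisible(x)
}
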