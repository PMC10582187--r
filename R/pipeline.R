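#' Run the full analysis pipeline on a trace set
#'
#' Classify every frame, discard junk and low-confidence traces, segment
#' the usable region, derive correction factors from the photobleached
#' frames, compute apparent and corrected FRET, classify the kinetic
#' states of dynamic segments (or decode them with the HMM baseline),
#' pool transitions into a TDP and fit per-state dwell times. Failures
#' are isolated per trace: the run continues and failed traces are
#' listed in the report.
#'
#' @param dataset an `smfret_dataset`, list of [labeled_trace], or path
#'   to a [write_traces()] container.
#' @param models named list of trained models: `trace` (category
#'   classifier), `states` (named list `"2"`, `"3"`, `"4"` of state
#'   classifiers; at least the count you expect), optional `n_states`.
#' @param method `"classifier"` for the neural route, `"hmm"` for the
#'   Baum-Welch baseline on the same segments.
#' @param threshold trace confidence threshold.
#' @param n_states_default state count used when no `n_states` model is
#'   given.
#' @param min_segment minimum dynamic-segment length in frames.
#' @param min_dwells minimum dwell count per state for a CDF fit.
#' @return object of class `smfret_report`: category counts, correction
#'   factor medians, per-state dwell fits, pooled transition table,
#'   per-trace status.
#' @export
run_pipeline <- function(dataset, models, method = c("classifier", "hmm"),
                         threshold = 0.9, n_states_default = 2L,
                         min_segment = 63L, min_dwells = 10L) {
  method <- match.arg(method)
  traces <- if (is.character(dataset)) read_traces(dataset)
            else if (inherits(dataset, "smfret_dataset")) dataset$traces
            else dataset
  stopifnot(length(traces) >= 1L)
  modality <- traces[[1]]$modality
  frame_time <- traces[[1]]$frame_time
  status <- character(length(traces))
  seg_list <- vector("list", length(traces))
  keep <- logical(length(traces))
  cat_counts <- stats::setNames(integer(length(category_alphabet(modality))),
                                category_alphabet(modality))
  for (i in seq_along(traces)) {
    res <- tryCatch({
      fc <- classify_frames(models$trace, traces[[i]], threshold)
      maj <- names(which.max(table(fc$labels)))
      cat_counts[maj] <- cat_counts[maj] + 1L
      if (maj %in% c("noisy", "aggregate", "artifact")) "junk"
      else if (!fc$accepted) "low-confidence"
      else {
        seg_list[[i]] <- segment_trace(fc)
        keep[i] <- TRUE
        "ok"
      }
    }, error = function(e) paste("error:", conditionMessage(e)))
    status[i] <- res
  }
  ## correction factors from all accepted traces (FRET modalities)
  factors <- NULL
  if (modality != "1c" && any(keep))
    factors <- correction_factors(traces[keep], seg_list[keep])
  ## kinetics on dynamic segments
  tabs <- list()
  for (i in which(keep)) {
    sg <- seg_list[[i]]
    if (!sg$dynamic || is.null(sg$segment) ||
        diff(sg$segment) + 1L < min_segment) next
    status[i] <- tryCatch({
      span <- sg$segment[1]:sg$segment[2]
      ch <- traces[[i]]$channels[span, , drop = FALSE]
      obs <- observable_series(
        ch[, kinetic_channels(modality), drop = FALSE], modality)
      k <- if (!is.null(models$n_states)) {
        pr <- predict_n_states(models$n_states, ch)
        as.integer(names(pr)[which.max(pr)])
      } else n_states_default
      path <- if (method == "classifier") {
        sm <- models$states[[as.character(k)]]
        if (is.null(sm)) stop("no state classifier for k = ", k)
        classify_states(sm, ch)$states
      } else {
        fit_local_hmm(obs, k, max_iter = 1000L)$path
      }
      tabs[[length(tabs) + 1L]] <- extract_transitions(path, frame_time,
                                                       observable = obs)
      "dynamic"
    }, error = function(e) paste("error:", conditionMessage(e)))
  }
  table_all <- bind_transitions(tabs)
  ## per-state dwell fits on interior dwells
  dwell_fits <- list()
  if (nrow(table_all)) {
    for (s in sort(unique(table_all$from_state))) {
      d <- table_all$dwell_s[table_all$interior &
                               table_all$from_state == s]
      if (length(d) >= min_dwells)
        dwell_fits[[paste0("state", s)]] <- fit_dwell_cdf(d)
    }
  }
  structure(list(modality = modality, method = method,
                 n_traces = length(traces),
                 category_counts = cat_counts,
                 n_analyzed = sum(status == "dynamic"),
                 factors = factors, dwell_fits = dwell_fits,
                 transitions = table_all, status = status),
            class = "smfret_report")
}

#' @export
print.smfret_report <- function(x, ...) {
  cat(sprintf("smfret_report (%s, %s route): %d traces, %d analyzed dynamic\n",
              x$modality, x$method, x$n_traces, x$n_analyzed))
  cc <- x$category_counts[x$category_counts > 0]
  cat("  majority categories:",
      paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
  if (!is.null(x$factors))
    cat(sprintf("  factor medians: alpha=%.4f delta=%.4f gamma=%.4f\n",
                x$factors$median["alpha"], x$factors$median["delta"],
                x$factors$median["gamma"]))
  cat(sprintf("  %d transitions pooled\n", nrow(x$transitions)))
  for (nm in names(x$dwell_fits)) {
    f <- x$dwell_fits[[nm]]
    cat(sprintf("  %s: tau = %.3f s (95%% CI %.3f-%.3f, n = %d)\n",
                nm, f$tau, f$ci95[1], f$ci95[2], f$n_dwells))
  }
  invisible(x)
}

#' Machine-readable version of a pipeline report
#'
#' @param x an [run_pipeline()] report.
#' @return nested list safe to serialize as JSON.
#' @export
report_as_list <- function(x) {
  list(modality = x$modality, method = x$method, n_traces = x$n_traces,
       n_analyzed = x$n_analyzed,
       category_counts = as.list(x$category_counts),
       factor_medians = if (!is.null(x$factors))
         as.list(x$factors$median) else NULL,
       n_transitions = nrow(x$transitions),
       dwell_times = lapply(x$dwell_fits, function(f)
         list(tau = f$tau, ci95 = f$ci95, n = f$n_dwells)),
       status = as.list(table(x$status)))
}
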