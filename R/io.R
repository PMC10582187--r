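## Trace container I/O: per-frame CSV table + JSON manifest.
##
## The native on-disk container is deliberately plain: one CSV row per
## frame (trace_id, frame, one column per channel, category, state) and
## a JSON manifest carrying modality, frame time, seed and the full
## ground-truth parameters of simulated traces. Intensities round-trip
## losslessly (exactly for integer counts, to full double precision
## otherwise).

#' Write traces to a CSV container
#'
#' @param x an `smfret_dataset` or list of [labeled_trace].
#' @param path output CSV file; the manifest is written alongside as
#'   `<path>.json`.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path, format = "csv") {
  if (!identical(tolower(format), "csv"))
    stop("unsupported format '", format, "'; the native container is CSV")
  traces <- if (inherits(x, "smfret_dataset")) x$traces else x
  stopifnot(length(traces) >= 1L)
  modality <- traces[[1]]$modality
  rows <- lapply(traces, function(tr) {
    if (tr$modality != modality)
      stop("mixed modalities in one container")
    dt <- data.table::as.data.table(tr$channels)
    dt[, `:=`(trace_id = tr$id, frame = seq_len(nrow(tr$channels)),
              category = tr$category, state = tr$states)]
    dt
  })
  tab <- data.table::rbindlist(rows)
  data.table::setcolorder(tab, c("trace_id", "frame",
                                 modality_channels(modality),
                                 "category", "state"))
  data.table::fwrite(tab, path)
  manifest <- list(
    modality = modality,
    frame_time = traces[[1]]$frame_time,
    n_traces = length(traces),
    trace_ids = vapply(traces, function(t) t$id, character(1)),
    truth = lapply(traces, serialize_truth))
  if (inherits(x, "smfret_dataset"))
    manifest$config <- unclass(x$config)
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

serialize_truth <- function(tr) {
  tt <- tr$truth
  if (is.null(tt)) return(NULL)
  out <- list(sigma = tt$sigma, bleach_times = as.list(tt$bleach_times))
  if (!is.null(tt$kinetic))
    out$kinetic <- list(n_states = tt$kinetic$n_states,
                        rates = tt$kinetic$rates,
                        fret = tt$kinetic$fret,
                        fret_pairs = colnames(tt$kinetic$fret))
  if (!is.null(tt$photophysics))
    out$photophysics <- list(
      brightness = as.list(tt$photophysics$brightness),
      bleach_rate = as.list(tt$photophysics$bleach_rate))
  if (!is.null(tt$detection))
    out$detection <- list(alpha = as.list(tt$detection$alpha),
                          delta = as.list(tt$detection$delta),
                          gamma = as.list(tt$detection$gamma),
                          snr = tt$detection$snr)
  out$junk_kind <- tt$junk_kind
  out
}

deserialize_truth <- function(s, modality) {
  if (is.null(s)) return(NULL)
  out <- list(sigma = unlist(s$sigma),
              bleach_times = unlist(s$bleach_times))
  if (!is.null(s$kinetic)) {
    ## JSON stores matrices row-wise
    fret <- do.call(rbind, lapply(s$kinetic$fret, unlist))
    colnames(fret) <- unlist(s$kinetic$fret_pairs)
    rates <- do.call(rbind, lapply(s$kinetic$rates, unlist))
    out$kinetic <- kinetic_model(rates, fret)
  }
  if (!is.null(s$photophysics))
    out$photophysics <- photophysics_model(unlist(s$photophysics$brightness),
                                           unlist(s$photophysics$bleach_rate))
  if (!is.null(s$detection))
    out$detection <- detection_model(modality,
                                     alpha = unlist(s$detection$alpha),
                                     delta = unlist(s$detection$delta),
                                     gamma = unlist(s$detection$gamma),
                                     snr = s$detection$snr)
  out$junk_kind <- s$junk_kind
  out
}

#' Read traces from a CSV container
#'
#' @param path CSV file written by [write_traces()] (with its `.json`
#'   manifest alongside).
#' @param modality optional expected modality; a mismatch with the
#'   container is rejected with a diagnostic.
#' @return list of [labeled_trace].
#' @export
read_traces <- function(path, modality = NULL) {
  mpath <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(mpath)) stop("missing manifest: ", mpath)
  manifest <- jsonlite::read_json(mpath)
  file_mod <- manifest$modality
  if (!is.null(modality) && !identical(modality, file_mod))
    stop("container holds ", file_mod, " data (",
         length(modality_channels(file_mod)), " channels) but '",
         modality, "' was requested")
  chn <- modality_channels(file_mod)
  tab <- data.table::fread(path)
  need <- c("trace_id", "frame", chn, "category", "state")
  if (!all(need %in% names(tab)))
    stop("corrupt container: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  ids <- unlist(manifest$trace_ids)
  traces <- lapply(seq_along(ids), function(i) {
    sub <- tab[tab$trace_id == ids[i], ]
    sub <- sub[order(sub$frame), ]
    ch <- as.matrix(sub[, chn, with = FALSE])
    storage.mode(ch) <- "double"
    new_labeled_trace(ch,
                      file_mod, manifest$frame_time,
                      category = sub$category,
                      states = as.integer(sub$state),
                      truth = deserialize_truth(manifest$truth[[i]],
                                                file_mod),
                      id = ids[i])
  })
  traces
}

#' Read or write a run configuration
#'
#' Every tunable of the pipeline (thresholds, windows, bins, seeds,
#' training sizes) lives in one serializable list that round-trips
#' unchanged through YAML or JSON, keyed by file extension.
#'
#' @param config named list of settings.
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return `read_run_config` returns the list; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(config, path)
  else if (ext == "json")
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported config format: .", ext)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext)
}
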