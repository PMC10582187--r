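## Gaussian-emission hidden Markov model baseline (Baum-Welch + Viterbi).
##
## The reference kinetic analysis the classifiers are benchmarked
## against: states emit Gaussians over the observable (normalized
## intensity for one-color data, apparent FRET for two-color data), the
## Gaussian parameters serve as the prior and are iteratively updated by
## expectation-maximization, and the most likely state path is decoded
## with Viterbi.

hmm_init_from_means <- function(x, means, n_states) {
  assign <- apply(abs(outer(x, means, "-")), 1, which.min)
  vars <- vapply(seq_len(n_states), function(k) {
    xs <- x[assign == k]
    if (length(xs) > 1) stats::var(xs) else stats::var(x) / n_states
  }, numeric(1))
  vars[!is.finite(vars) | vars <= 0] <- stats::var(x) / n_states + 1e-6
  trans <- matrix((1 - 0.95) / max(n_states - 1, 1), n_states, n_states)
  diag(trans) <- 0.95
  init <- tabulate(assign, n_states) / length(x)
  init[init == 0] <- 1e-6
  list(means = means, vars = vars, trans = trans, init = init / sum(init))
}

# candidate starting points: a k-means split and a spread-quantile split.
# EM is run from each and the best final likelihood wins, which guards
# against the occasional degenerate k-means seed.
hmm_init_params <- function(x, n_states) {
  cands <- list()
  qs <- stats::quantile(x, probs = seq(0.5, n_states - 0.5) / n_states,
                        names = FALSE)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(x, centers = matrix(unique(qs)),
                                   iter.max = 20)),
    error = function(e) NULL)
  if (!is.null(km) && nrow(km$centers) == n_states)
    cands <- c(cands, list(sort(as.numeric(km$centers))))
  cands <- c(cands, list(
    stats::quantile(x, probs = seq(0.1, 0.9, length.out = n_states),
                    names = FALSE)))
  lapply(unique(cands), hmm_init_from_means, x = x, n_states = n_states)
}

hmm_mstep <- function(xs, stats_list, n_states, var_floor) {
  g_sum <- numeric(n_states); gx <- numeric(n_states)
  gx2 <- numeric(n_states); xi <- matrix(0, n_states, n_states)
  init <- numeric(n_states)
  for (i in seq_along(xs)) {
    g <- stats_list[[i]]$gamma
    g_sum <- g_sum + colSums(g)
    gx <- gx + colSums(g * xs[[i]])
    gx2 <- gx2 + colSums(g * xs[[i]]^2)
    xi <- xi + stats_list[[i]]$xi_sum
    init <- init + g[1, ]
  }
  means <- gx / g_sum
  vars <- gx2 / g_sum - means^2
  floored <- vars < var_floor
  vars[floored] <- var_floor
  trans <- xi / pmax(rowSums(xi), 1e-300)
  ## guard against empty rows (a state never left)
  bad <- rowSums(xi) <= 0
  if (any(bad)) trans[bad, ] <- 1 / n_states
  list(means = means, vars = vars, trans = trans,
       init = init / sum(init), floored = any(floored))
}

fit_hmm_core <- function(xs, n_states, tol, max_iter, var_floor) {
  all_x <- unlist(xs)
  starts <- hmm_init_params(all_x, n_states)
  runs <- lapply(starts, function(par)
    fit_hmm_from(xs, par, n_states, tol, max_iter, var_floor))
  best <- which.max(vapply(runs, function(r) utils::tail(r$loglik, 1),
                           numeric(1)))
  runs[[best]]
}

fit_hmm_from <- function(xs, par, n_states, tol, max_iter, var_floor) {
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  floored <- FALSE
  iter <- 0L
  prev_par <- par
  repeat {
    iter <- iter + 1L
    es <- lapply(xs, function(x)
      hmm_estep_cpp(x, par$means, par$vars, par$trans, par$init))
    ll <- sum(vapply(es, function(e) e$loglik, numeric(1)))
    ## the variance floor and empty-row guards can break EM's ascent
    ## guarantee; when that happens, keep the previous (better) model
    if (ll < ll_old) {
      par <- prev_par
      converged <- TRUE
      break
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    prev_par <- par
    m <- hmm_mstep(xs, es, n_states, var_floor)
    floored <- floored || m$floored
    par[c("means", "vars", "trans", "init")] <-
      m[c("means", "vars", "trans", "init")]
  }
  ## canonical order: ascending emission mean
  ord <- order(par$means)
  par$means <- par$means[ord]; par$vars <- par$vars[ord]
  par$trans <- par$trans[ord, ord, drop = FALSE]
  par$init <- par$init[ord]
  paths <- lapply(xs, function(x)
    hmm_viterbi_cpp(x, par$means, par$vars, par$trans, par$init))
  list(par = par, loglik = ll_trace, paths = paths, iterations = iter,
       converged = converged, floored = floored)
}

#' Fit a Gaussian-emission HMM to one observable trace
#'
#' Baum-Welch expectation-maximization from a k-means-style
#' initialization: per-state Gaussian emission means/variances, a
#' row-stochastic transition matrix, and the initial distribution are
#' iterated until the absolute log-likelihood improvement falls below
#' `tol` (default 1e-9, maximum 1e8 iterations). The Viterbi path is
#' decoded with states in canonical order (ascending emission mean).
#'
#' @param x numeric observable series (normalized intensity or apparent
#'   FRET).
#' @param n_states number of hidden states (default 2).
#' @param tol absolute log-likelihood convergence threshold.
#' @param max_iter iteration cap.
#' @param var_floor variance floor on the (normalized) observable scale;
#'   collapse onto single points is floored and flagged.
#' @return object of class `hmm_fit`: `model` (means, vars, trans,
#'   init, n_states), `loglik` (per-iteration trajectory), `path`
#'   (Viterbi), `iterations`, `converged`, `variance_floored`.
#' @export
fit_local_hmm <- function(x, n_states = 2L, tol = 1e-9, max_iter = 1e8,
                          var_floor = 1e-6) {
  stopifnot(length(x) > n_states)
  r <- fit_hmm_core(list(as.numeric(x)), n_states, tol, max_iter,
                    var_floor)
  structure(list(model = c(r$par, list(n_states = n_states)),
                 loglik = r$loglik, path = r$paths[[1]],
                 iterations = r$iterations, converged = r$converged,
                 variance_floored = r$floored, scope = "local"),
            class = "hmm_fit")
}

#' Fit a shared-parameter (global) HMM to a set of traces
#'
#' One Gaussian-emission parameter set maximizes the summed
#' log-likelihood over all traces; each trace receives its own Viterbi
#' path. Global fitting pools statistics and is stronger on homogeneous
#' data, but slight trace-to-trace heterogeneity (e.g. in FRET levels)
#' makes it miss transitions in outlier traces — the documented failure
#' mode local fits avoid.
#'
#' @param xs list of observable series.
#' @inheritParams fit_local_hmm
#' @return object of class `hmm_fit` with `paths` (one per trace).
#' @export
fit_global_hmm <- function(xs, n_states = 2L, tol = 1e-9, max_iter = 1e8,
                           var_floor = 1e-6) {
  stopifnot(length(xs) >= 1L)
  r <- fit_hmm_core(lapply(xs, as.numeric), n_states, tol, max_iter,
                    var_floor)
  structure(list(model = c(r$par, list(n_states = n_states)),
                 loglik = r$loglik, paths = r$paths,
                 path = if (length(xs) == 1L) r$paths[[1]] else NULL,
                 iterations = r$iterations, converged = r$converged,
                 variance_floored = r$floored, scope = "global"),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit (%s): %d states, %d EM iteration(s), %s\n",
              x$scope, x$model$n_states, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat("  emission means:", paste(signif(x$model$means, 4), collapse = ", "),
      "\n  emission sd:   ",
      paste(signif(sqrt(x$model$vars), 4), collapse = ", "), "\n")
  if (x$variance_floored) cat("  note: variance floor applied\n")
  invisible(x)
}

#' @export
logLik.hmm_fit <- function(object, ...) {
  ll <- utils::tail(object$loglik, 1)
  attr(ll, "df") <- with(object$model,
                         n_states * 2 + n_states * (n_states - 1))
  class(ll) <- "logLik"
  ll
}

#' Transition table from an HMM fit
#'
#' Extracts dwells and transitions from the Viterbi path(s) under the
#' same contract as [extract_transitions()], enabling head-to-head
#' TDP and dwell-time comparison with the classifier route.
#'
#' @param fit an [fit_local_hmm()] or [fit_global_hmm()] result.
#' @param frame_time seconds per frame.
#' @param observables optional per-trace observable series for the TDP
#'   axes (defaults to the state index).
#' @return a `transition_table`.
#' @export
hmm_transitions <- function(fit, frame_time, observables = NULL) {
  paths <- if (!is.null(fit$paths)) fit$paths else list(fit$path)
  tabs <- lapply(seq_along(paths), function(i)
    extract_transitions(paths[[i]], frame_time,
                        observable = if (is.null(observables)) NULL
                        else observables[[i]]))
  bind_transitions(tabs)
}
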