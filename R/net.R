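## Multi-scale temporal convolution networks for per-frame classification.
##
## The sequence model used by every classifier in the package: a bank of
## 1-D convolutions whose kernel sizes span all temporal scales up to
## roughly twice the longest expected dwell ("omni-scale" feature
## learning), a mixing convolution, and a per-frame softmax head. All
## linear algebra is expressed as im2col + GEMM so training runs on the
## BLAS; gradients are computed analytically.

#' Build a per-frame classifier specification
#'
#' @param modality measurement modality (see [modality_channels()]).
#' @param task one of `"trace"` (per-frame category classification over
#'   the full channel set), `"states2"`, `"states3"`, `"states4"`
#'   (state-transition classification on the kinetically informative
#'   channels only; the acceptor signal after direct acceptor excitation
#'   carries no kinetic information and is excluded) or `"n_states"`
#'   (number-of-states classification over \{2, 3, 4\}).
#' @param kernels1 odd kernel sizes of the multi-scale block; the largest
#'   should be of the order of twice the longest expected dwell.
#' @param f1 filters per kernel size in the multi-scale block.
#' @param kernel2,f2 kernel size and width of the mixing convolution.
#' @param g_units width of the global-context branch: features averaged
#'   over the whole trace are transformed and broadcast back to every
#'   frame, so trace-global evidence (bleach-step counts, stoichiometry,
#'   artifact jumps anywhere in the trace) informs per-frame decisions.
#' @return object of class `oscnn_spec`.
#' @export
build_model <- function(modality, task,
                        kernels1 = c(1, 3, 7, 15, 31, 63),
                        f1 = 6, kernel2 = 9, f2 = 32, g_units = 16) {
  modality <- match.arg(modality, c("1c", "2c", "2c_alex", "3c_alex"))
  task <- match.arg(task, c("trace", "states2", "states3", "states4",
                            "n_states"))
  channels <- if (task == "trace") modality_channels(modality)
              else kinetic_channels(modality)
  class_labels <- switch(task,
    trace = category_alphabet(modality),
    states2 = paste0("S", 1:2),
    states3 = paste0("S", 1:3),
    states4 = paste0("S", 1:4),
    n_states = c("2", "3", "4"))
  stopifnot(all(kernels1 %% 2 == 1), kernel2 %% 2 == 1)
  structure(list(modality = modality, task = task, channels = channels,
                 n_input = length(channels), n_classes = length(class_labels),
                 class_labels = class_labels, kernels1 = kernels1,
                 f1 = f1, kernel2 = kernel2, f2 = f2, g_units = g_units,
                 min_len = max(kernels1, kernel2)),
            class = "oscnn_spec")
}

#' Kinetically informative channels of a modality
#'
#' All channels except the acceptor intensity after direct acceptor
#' excitation, which is constant while the acceptor is photoactive.
#'
#' @param modality measurement modality.
#' @return character vector of channel names.
#' @export
kinetic_channels <- function(modality) {
  switch(match.arg(modality, c("1c", "2c", "2c_alex", "3c_alex")),
    "1c"      = "I",
    "2c"      = ,
    "2c_alex" = c("DD", "DA"),
    "3c_alex" = c("BB", "BY", "BR", "YY", "YR"))
}

#' @export
print.oscnn_spec <- function(x, ...) {
  cat(sprintf("oscnn spec: %s/%s, %d input channel(s) -> %d classes\n",
              x$modality, x$task, x$n_input, x$n_classes))
  cat("  multi-scale kernels:", paste(x$kernels1, collapse = ","),
      sprintf(" (%d filters each), mixing conv %d x %d\n",
              x$f1, x$kernel2, x$f2))
  invisible(x)
}

## ---- core linear algebra ------------------------------------------------

# stack sliding windows: X is C x T, result (C*k) x T, zero-padded
im2col <- function(X, k) {
  if (k == 1L) return(X)
  C <- nrow(X); T_ <- ncol(X); p <- (k - 1L) %/% 2L
  Xp <- cbind(matrix(0, C, p), X, matrix(0, C, p))
  idx <- as.vector(outer(0:(k - 1L), seq_len(T_), "+"))
  Xc <- Xp[, idx, drop = FALSE]
  dim(Xc) <- c(C * k, T_)
  Xc
}

# adjoint of im2col: fold (C*k) x T gradient back onto C x T
col2im <- function(dXc, k, C, T_) {
  if (k == 1L) return(dXc)
  p <- (k - 1L) %/% 2L
  dXp <- matrix(0, C, T_ + 2L * p)
  dim(dXc) <- c(C, k, T_)
  for (j in seq_len(k))
    dXp[, j:(j + T_ - 1L)] <- dXp[, j:(j + T_ - 1L)] + dXc[, j, ]
  dXp[, (p + 1L):(p + T_), drop = FALSE]
}

# input augmentation: append forward and backward cumulative means of
# each channel, giving every frame a summary of its past and future —
# the directional context needed to place bleach steps
augment_input <- function(X) {
  T_ <- ncol(X)
  cf <- t(apply(X, 1, cumsum)) / rep(seq_len(T_), each = nrow(X))
  cb <- t(apply(X[, T_:1, drop = FALSE], 1, cumsum))[, , drop = FALSE] /
    rep(seq_len(T_), each = nrow(X))
  cb <- cb[, T_:1, drop = FALSE]
  rbind(X, cf, cb)
}

oscnn_init <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  he <- function(fout, fin) matrix(stats::rnorm(fout * fin, 0,
                                                sqrt(2 / fin)), fout, fin)
  F1 <- spec$f1 * length(spec$kernels1)
  n_in <- 3L * spec$n_input           # channels + cumulative-mean context
  p <- list()
  p$W1 <- lapply(spec$kernels1, function(k) he(spec$f1, n_in * k))
  p$b1 <- numeric(F1)
  p$W2 <- he(spec$f2, F1 * spec$kernel2)
  p$b2 <- numeric(spec$f2)
  p$Wg <- he(spec$g_units, 2L * spec$f2)   # [mean-pool; max-pool]
  p$bg <- numeric(spec$g_units)
  p$W3 <- he(spec$n_classes, spec$f2 + spec$g_units) * 0.5
  p$b3 <- numeric(spec$n_classes)
  p
}

oscnn_forward <- function(spec, p, X, cache = FALSE) {
  X <- augment_input(X)
  T_ <- ncol(X)
  Xc1 <- lapply(spec$kernels1, function(k) im2col(X, k))
  Z1 <- do.call(rbind, lapply(seq_along(Xc1), function(i)
    p$W1[[i]] %*% Xc1[[i]]))
  Z1 <- Z1 + p$b1
  H1 <- Z1 * (Z1 > 0)
  Xc2 <- im2col(H1, spec$kernel2)
  Z2 <- p$W2 %*% Xc2 + p$b2
  H2 <- Z2 * (Z2 > 0)
  ## global-context branch: mean- and max-pooled features broadcast to
  ## every frame (max pooling expresses "this event occurs somewhere")
  gmax_at <- max.col(H2, ties.method = "first")
  gpool <- c(rowMeans(H2), H2[cbind(seq_len(nrow(H2)), gmax_at)])
  Ag <- drop(p$Wg %*% gpool) + p$bg
  U <- Ag * (Ag > 0)
  Z3 <- p$W3 %*% rbind(H2, matrix(U, spec$g_units, T_)) + p$b3
  Z3 <- Z3 - rep(apply(Z3, 2, max), each = nrow(Z3))
  P <- exp(Z3)
  P <- P / rep(colSums(P), each = nrow(P))
  out <- list(P = P)
  if (cache) out <- c(out, list(Xc1 = Xc1, Z1 = Z1, H1 = H1, Xc2 = Xc2,
                                Z2 = Z2, H2 = H2, gpool = gpool, Ag = Ag,
                                U = U, gmax_at = gmax_at))
  out
}

# cross-entropy gradient for one trace; y integer classes, m logical mask
oscnn_backward <- function(spec, p, fw, y, m) {
  T_ <- length(y)
  n <- max(sum(m), 1L)
  dZ3 <- fw$P
  dZ3[cbind(y[m], which(m))] <- dZ3[cbind(y[m], which(m))] - 1
  dZ3[, !m] <- 0
  dZ3 <- dZ3 / n
  g <- list()
  F2 <- spec$f2
  Hcat <- rbind(fw$H2, matrix(fw$U, spec$g_units, T_))
  g$W3 <- tcrossprod(dZ3, Hcat)
  g$b3 <- rowSums(dZ3)
  dHcat <- crossprod(p$W3, dZ3)
  dU <- rowSums(dHcat[(F2 + 1):(F2 + spec$g_units), , drop = FALSE])
  dAg <- dU * (fw$Ag > 0)
  g$Wg <- dAg %o% fw$gpool
  g$bg <- dAg
  dgpool <- drop(crossprod(p$Wg, dAg))
  dH2 <- dHcat[1:F2, , drop = FALSE] + dgpool[1:F2] / T_
  ## max-pool gradient routes to the winning frame of each feature
  idx <- cbind(seq_len(F2), fw$gmax_at)
  dH2[idx] <- dH2[idx] + dgpool[(F2 + 1):(2 * F2)]
  dZ2 <- dH2 * (fw$Z2 > 0)
  g$W2 <- tcrossprod(dZ2, fw$Xc2)
  g$b2 <- rowSums(dZ2)
  dXc2 <- crossprod(p$W2, dZ2)
  dH1 <- col2im(dXc2, spec$kernel2, nrow(fw$H1), T_)
  dZ1 <- dH1 * (fw$Z1 > 0)
  g$W1 <- vector("list", length(spec$kernels1))
  off <- 0L
  for (i in seq_along(spec$kernels1)) {
    rows <- (off + 1L):(off + spec$f1)
    g$W1[[i]] <- tcrossprod(dZ1[rows, , drop = FALSE], fw$Xc1[[i]])
    off <- off + spec$f1
  }
  g$b1 <- rowSums(dZ1)
  g
}

## Adam over the nested parameter list
adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  upd <- function(pp, gg, mm, vv) {
    mm <- beta1 * mm + (1 - beta1) * gg
    vv <- beta2 * vv + (1 - beta2) * gg^2
    mh <- mm / (1 - beta1^t); vh <- vv / (1 - beta2^t)
    list(p = pp - lr * mh / (sqrt(vh) + eps), m = mm, v = vv)
  }
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      for (i in seq_along(p[[nm]])) {
        u <- upd(p[[nm]][[i]], g[[nm]][[i]], st$m[[nm]][[i]],
                 st$v[[nm]][[i]])
        p[[nm]][[i]] <- u$p; st$m[[nm]][[i]] <- u$m; st$v[[nm]][[i]] <- u$v
      }
    } else {
      u <- upd(p[[nm]], g[[nm]], st$m[[nm]], st$v[[nm]])
      p[[nm]] <- u$p; st$m[[nm]] <- u$m; st$v[[nm]] <- u$v
    }
  }
  list(p = p, st = st)
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
add_grads <- function(a, b) {
  for (nm in names(a)) {
    if (is.list(a[[nm]]))
      for (i in seq_along(a[[nm]])) a[[nm]][[i]] <- a[[nm]][[i]] + b[[nm]][[i]]
    else a[[nm]] <- a[[nm]] + b[[nm]]
  }
  a
}
scale_grads <- function(a, s) rapply(a, function(x) x * s, how = "replace")

## ---- training data preparation -----------------------------------------

# per-trace normalization by one global intensity scale (the upper
# quantile of the per-frame total). No per-channel offset or scale:
# the zero (background) level, inter-channel ratios, bleach-step sizes
# and the noise-to-signal ratio all stay visible, which the trace
# categories depend on; only the absolute brightness is removed.
normalize_channels <- function(X) {
  s <- stats::quantile(colSums(X), 0.99, names = FALSE)
  X / max(s, stats::sd(X), 1e-12)
}

# turn a labeled trace into (X, y, mask) for a given spec; NULL if the
# trace does not belong in this task's training set
training_example <- function(spec, trace) {
  X <- t(trace$channels[, spec$channels, drop = FALSE])
  if (spec$task == "trace") {
    y <- match(trace$category, spec$class_labels)
    return(list(X = normalize_channels(X), y = y,
                m = rep(TRUE, length(y))))
  }
  ## state tasks train on the all-dyes-active region of dynamic traces
  k <- trace$truth$kinetic
  if (is.null(k) || k$n_states < 2L) return(NULL)
  usable <- which(trace$states > 0L)
  if (length(usable) < spec$min_len) return(NULL)
  span <- usable[1]:usable[length(usable)]
  X <- X[, span, drop = FALSE]
  if (spec$task == "n_states") {
    if (!as.character(k$n_states) %in% spec$class_labels) return(NULL)
    y <- rep(match(as.character(k$n_states), spec$class_labels),
             length(span))
    return(list(X = normalize_channels(X), y = y, m = rep(TRUE, length(y))))
  }
  if (k$n_states != spec$n_classes) return(NULL)
  ## canonical label order: ascending mean observable
  ord <- order(canonical_state_order(k, spec$modality))
  y <- match(trace$states[span], ord)
  list(X = normalize_channels(X), y = y, m = trace$states[span] > 0L)
}

# rank of each simulated state under the canonical (ascending observable)
# ordering; for 1c the observable is the intensity level, otherwise the
# FRET efficiency of the first dye pair
canonical_state_order <- function(kmodel, modality) {
  col <- if (modality == "1c") "I" else if (modality == "3c_alex") "BY"
         else "YR"
  kmodel$fret[, col]
}

#' Train a per-frame classifier
#'
#' Minimizes the masked per-frame cross-entropy with Adam over
#' mini-batches of traces. Inputs are min-max normalized per trace and
#' channel, making the network independent of absolute brightness.
#'
#' @param spec an [build_model()] specification.
#' @param dataset an `smfret_dataset` (or list of [labeled_trace]).
#' @param epochs,lr,batch_size optimizer settings.
#' @param seed seed for weight initialization and batch shuffling.
#' @param verbose print per-epoch loss/accuracy.
#' @return object of class `oscnn`: the spec, fitted parameters and a
#'   training history (`loss`, `accuracy` per epoch).
#' @export
train_model <- function(spec, dataset, epochs = 12, lr = 3e-3,
                        batch_size = 16, seed = 1L, verbose = FALSE) {
  traces <- if (inherits(dataset, "smfret_dataset")) dataset$traces
            else dataset
  ex <- Filter(Negate(is.null), lapply(traces, training_example,
                                       spec = spec))
  if (length(ex) == 0L)
    stop("no usable training traces for task '", spec$task, "'")
  present <- sort(unique(unlist(lapply(ex, function(e) e$y[e$m]))))
  if (!setequal(present, seq_len(spec$n_classes))) {
    missing <- setdiff(seq_len(spec$n_classes), present)
    stop("class(es) absent from training data: ",
         paste(spec$class_labels[missing], collapse = ", "))
  }
  set.seed(seed)
  p <- oscnn_init(spec)
  st <- list(m = zero_like(p), v = zero_like(p))
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  step <- 0L
  for (ep in seq_len(epochs)) {
    idx <- sample(length(ex))
    tot_loss <- 0; tot_ok <- 0; tot_n <- 0
    for (b0 in seq(1L, length(idx), by = batch_size)) {
      bidx <- idx[b0:min(b0 + batch_size - 1L, length(idx))]
      acc <- NULL
      for (i in bidx) {
        e <- ex[[i]]
        fw <- oscnn_forward(spec, p, e$X, cache = TRUE)
        pr <- fw$P[cbind(e$y[e$m], which(e$m))]
        tot_loss <- tot_loss - sum(log(pmax(pr, 1e-12)))
        tot_ok <- tot_ok + sum(max.col(t(fw$P[, e$m, drop = FALSE])) ==
                                 e$y[e$m])
        tot_n <- tot_n + sum(e$m)
        g <- oscnn_backward(spec, p, fw, e$y, e$m)
        acc <- if (is.null(acc)) g else add_grads(acc, g)
      }
      acc <- scale_grads(acc, 1 / length(bidx))
      step <- step + 1L
      u <- adam_step(p, acc, st, lr, step)
      p <- u$p; st <- u$st
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / tot_n,
                                   accuracy = tot_ok / tot_n))
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  acc %.4f", ep,
                      tot_loss / tot_n, tot_ok / tot_n))
  }
  structure(list(spec = spec, params = p, history = hist),
            class = "oscnn")
}

#' @export
print.oscnn <- function(x, ...) {
  print(x$spec)
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f, frame accuracy %.3f\n",
                max(x$history$epoch), utils::tail(x$history$loss, 1),
                utils::tail(x$history$accuracy, 1)))
  invisible(x)
}

# probability matrix (T x n_classes) for an input channel matrix
oscnn_probs <- function(model, X) {
  spec <- model$spec
  if (nrow(X) != spec$n_input)
    stop("expected ", spec$n_input, " input channel(s), got ", nrow(X))
  if (ncol(X) < spec$min_len)
    stop("trace shorter than the minimum window (", spec$min_len,
         " frames)")
  fw <- oscnn_forward(spec, model$params, normalize_channels(X))
  P <- t(fw$P)
  colnames(P) <- spec$class_labels
  P
}

#' Classify every frame of a trace
#'
#' Runs the trace-category classifier and reports per-frame class
#' probabilities, hard labels, and a trace confidence: the mean winning
#' probability over all frames not classified as photobleached. Traces
#' whose confidence falls below `threshold` are flagged for discard.
#'
#' @param model a trained `"trace"`-task [train_model()] model.
#' @param trace a [labeled_trace] (or channel matrix with named columns).
#' @param threshold confidence threshold in `[0, 1]`; user-adjustable.
#' @return object of class `frame_classification`: `prob` (frames x
#'   classes), `labels`, `confidence`, `accepted`.
#' @export
classify_frames <- function(model, trace, threshold = 0.9) {
  ch <- if (inherits(trace, "labeled_trace")) trace$channels else trace
  X <- t(ch[, model$spec$channels, drop = FALSE])
  P <- oscnn_probs(model, X)
  lab <- colnames(P)[max.col(P, ties.method = "first")]
  bleach_fam <- bleach_family(model$spec$modality)
  live <- !(lab %in% bleach_fam)
  conf <- if (any(live)) mean(P[cbind(which(live),
                                      max.col(P[live, , drop = FALSE],
                                              ties.method = "first"))])
          else 0
  structure(list(prob = P, labels = lab, confidence = conf,
                 accepted = conf >= threshold,
                 modality = model$spec$modality),
            class = "frame_classification")
}

# labels that belong to the photobleached family (not all dyes active)
bleach_family <- function(modality) {
  setdiff(category_alphabet(modality),
          c(grep("dynamic|static", category_alphabet(modality),
                 value = TRUE), "noisy", "aggregate", "artifact"))
}

#' @export
print.frame_classification <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("frame_classification (%s): confidence %.3f (%s)\n",
              x$modality, x$confidence,
              if (x$accepted) "accepted" else "discard"))
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Classify the kinetic states of a dynamic segment
#'
#' Applies a state-transition classifier to the kinetically informative
#' channels of a dynamic segment and returns a per-frame state path in
#' canonical order (states sorted by ascending mean observable, so state
#' indices are comparable across traces), together with the per-frame
#' winning probability and the segment confidence (their mean).
#'
#' @param model a trained `"statesK"`-task model.
#' @param x segment channel matrix (frames x kinetic channels) or a
#'   [labeled_trace] plus `segment` range.
#' @param segment optional `c(start, end)` frame range.
#' @return object of class `state_classification`: `states`, `p`,
#'   `confidence`, `prob`.
#' @export
classify_states <- function(model, x, segment = NULL) {
  ch <- if (inherits(x, "labeled_trace")) x$channels else x
  if (!is.null(segment))
    ch <- ch[segment[1]:segment[2], , drop = FALSE]
  X <- t(ch[, model$spec$channels, drop = FALSE])
  P <- oscnn_probs(model, X)
  raw <- max.col(P, ties.method = "first")
  ## canonical order: ascending mean observable among predicted states
  obs <- observable_series(ch[, model$spec$channels, drop = FALSE],
                           model$spec$modality)
  means <- tapply(obs, raw, mean)
  rank_of <- rep(NA_integer_, model$spec$n_classes)
  rank_of[as.integer(names(means))] <- rank(means, ties.method = "first")
  seen <- !is.na(rank_of)
  rank_of[!seen] <- setdiff(seq_len(model$spec$n_classes),
                            rank_of[seen])[seq_len(sum(!seen))]
  states <- rank_of[raw]
  perm <- order(rank_of)
  prob <- P[, perm, drop = FALSE]
  colnames(prob) <- paste0("S", seq_len(ncol(prob)))
  p <- P[cbind(seq_along(raw), raw)]
  structure(list(states = states, p = p, confidence = mean(p), prob = prob),
            class = "state_classification")
}

#' @export
print.state_classification <- function(x, ...) {
  cat(sprintf("state_classification: %d frames, %d states, confidence %.3f\n",
              length(x$states), length(unique(x$states)), x$confidence))
  invisible(x)
}

#' Scalar kinetic observable of a trace
#'
#' The one-dimensional series used for canonical state ordering, TDP
#' axes and HMM fitting: min-max normalized intensity for one-color
#' data, the apparent FRET (proximity ratio) of the first dye pair
#' otherwise. Ratios are clamped to `[-0.5, 1.5]`: when noise collapses
#' the denominator the raw ratio explodes without carrying information,
#' and unclamped outliers capture one Gaussian state of a downstream
#' HMM.
#'
#' @param ch channel matrix with named columns (kinetic channels
#'   suffice) or a [labeled_trace].
#' @param modality measurement modality; inferred from a trace.
#' @return numeric vector, one value per frame.
#' @export
observable_series <- function(ch, modality = NULL) {
  if (inherits(ch, "labeled_trace")) {
    modality <- ch$modality
    ch <- ch$channels
  }
  if (is.null(modality)) stop("'modality' required for a bare matrix")
  if (modality == "1c") {
    x <- ch[, "I"]
    return((x - min(x)) / max(max(x) - min(x), 1e-12))
  }
  pr <- if (modality %in% c("2c", "2c_alex"))
    ch[, "DA"] / (ch[, "DA"] + ch[, "DD"])
  else ch[, "BY"] / (ch[, "BY"] + ch[, "BB"])
  pr[!is.finite(pr)] <- 0.5
  pmin(pmax(pr, -0.5), 1.5)
}

#' Predict the number of kinetic states of a dynamic segment
#'
#' @param model a trained `"n_states"`-task model.
#' @param x segment channel matrix or [labeled_trace].
#' @param segment optional `c(start, end)` frame range.
#' @return named probability vector over `c("2", "3", "4")`; the argmax
#'   routes the segment to the matching state classifier.
#' @export
predict_n_states <- function(model, x, segment = NULL) {
  ch <- if (inherits(x, "labeled_trace")) x$channels else x
  if (!is.null(segment))
    ch <- ch[segment[1]:segment[2], , drop = FALSE]
  X <- t(ch[, model$spec$channels, drop = FALSE])
  P <- oscnn_probs(model, X)
  colMeans(P)
}

#' Confusion-matrix benchmark of a classifier on labeled traces
#'
#' Compares per-frame predictions with ground-truth labels over a
#' labeled validation set and summarizes correct and incorrect
#' predictions as a confusion matrix with per-class precision/recall.
#'
#' @param model a trained [train_model()] model.
#' @param dataset an `smfret_dataset` with ground truth.
#' @return object of class `confusion_report`: `counts` (truth x
#'   predicted), `normalized` (rows sum to 1), `precision`, `recall`,
#'   `accuracy`.
#' @export
evaluate_confusion <- function(model, dataset) {
  spec <- model$spec
  traces <- if (inherits(dataset, "smfret_dataset")) dataset$traces
            else dataset
  L <- spec$n_classes
  counts <- matrix(0, L, L,
                   dimnames = list(truth = spec$class_labels,
                                   predicted = spec$class_labels))
  for (tr in traces) {
    e <- training_example(spec, tr)
    if (is.null(e)) next
    P <- oscnn_probs(model, e$X)
    pred <- max.col(P, ties.method = "first")
    tt <- table(factor(e$y[e$m], levels = seq_len(L)),
                factor(pred[e$m], levels = seq_len(L)))
    counts <- counts + as.matrix(tt)
  }
  norm <- counts / pmax(rowSums(counts), 1)
  structure(list(counts = counts, normalized = norm,
                 precision = diag(counts) / pmax(colSums(counts), 1),
                 recall = diag(counts) / pmax(rowSums(counts), 1),
                 accuracy = sum(diag(counts)) / max(sum(counts), 1)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("confusion_report: frame accuracy %.4f\n", x$accuracy))
  print(round(x$normalized, 3))
  invisible(x)
}
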