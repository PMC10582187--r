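test_that("model specifications wire the right channels and classes", {
  expect_equal(build_model("3c_alex", "states3")$n_input, 5L)
  expect_equal(build_model("2c_alex", "trace")$n_input, 3L)
  expect_equal(build_model("2c", "trace")$n_input, 2L)
  expect_equal(build_model("1c", "n_states")$class_labels, c("2", "3", "4"))
  expect_equal(build_model("1c", "states4")$n_classes, 4L)
  expect_error(build_model("2c_alex", "blur"), "arg")
  ## kinetic channels exclude the direct acceptor-excitation signal
  expect_false("AA" %in% kinetic_channels("2c_alex"))
  expect_false("RR" %in% kinetic_channels("3c_alex"))
})

test_that("analytic gradients match finite differences", {
  spec <- build_model("2c_alex", "states2", kernels1 = c(1, 3, 5),
                      f1 = 2, kernel2 = 3, f2 = 4, g_units = 3)
  set.seed(1)
  p <- smfret:::oscnn_init(spec)
  X <- matrix(stats::runif(2 * 20), 2, 20)
  y <- sample(1:2, 20, TRUE)
  m <- rep(TRUE, 20)
  loss <- function(pp)
    -mean(log(smfret:::oscnn_forward(spec, pp, X)$P[cbind(y, 1:20)]))
  fw <- smfret:::oscnn_forward(spec, p, X, cache = TRUE)
  g <- smfret:::oscnn_backward(spec, p, fw, y, m)
  eps <- 1e-6
  for (nm in c("b1", "W2", "Wg", "W3", "b3")) {
    for (j in seq_len(min(4, length(p[[nm]])))) {
      p2 <- p
      p2[[nm]][j] <- p2[[nm]][j] + eps
      expect_equal(g[[nm]][j], (loss(p2) - loss(p)) / eps,
                   tolerance = 1e-3)
    }
  }
})

test_that("per-frame probabilities are valid distributions", {
  spec <- build_model("2c_alex", "trace", kernels1 = c(1, 3, 7), f1 = 3,
                      f2 = 8, g_units = 4)
  set.seed(2)
  model <- structure(list(spec = spec, params = smfret:::oscnn_init(spec),
                          history = data.frame()), class = "oscnn")
  tr <- render_pure_2c(rep(c(1L, 2L), 30), snr = 10)
  fc <- classify_frames(model, tr)
  expect_equal(unname(rowSums(fc$prob)), rep(1, 60), tolerance = 1e-6)
  expect_true(all(fc$prob >= 0))
  ## confidence bound: threshold above 1 rejects every trace
  expect_false(classify_frames(model, tr, threshold = 1.01)$accepted)
  ## traces shorter than the minimum window are rejected
  short <- render_pure_2c(rep(1L, 4), e = c(0.5, 0.5))
  expect_error(classify_frames(model, short), "minimum window")
})

test_that("training overfits a tiny separable set and reduces the loss", {
  set.seed(3)
  traces <- lapply(1:10, function(i)
    render_pure_2c(rep(sample(1:2, 8, TRUE), each = 25),
                   e = c(0.2, 0.8), snr = 50))
  spec <- build_model("2c_alex", "states2", kernels1 = c(1, 3, 7, 15),
                      f1 = 4, f2 = 12, g_units = 4)
  m <- train_model(spec, traces, epochs = 8, seed = 7)
  expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
  expect_gt(utils::tail(m$history$accuracy, 1), 0.95)
})

test_that("a class absent from the training data raises an error", {
  set.seed(4)
  traces <- lapply(1:5, function(i)
    render_pure_2c(rep(1L, 80), e = c(0.2, 0.8), snr = 50))
  spec <- build_model("2c_alex", "states2", kernels1 = c(1, 3), f1 = 2,
                      f2 = 4, g_units = 2)
  expect_error(train_model(spec, traces, epochs = 1), "absent")
})

test_that("200 noise-free two-state traces train to >99% frame accuracy", {
  set.seed(5)
  traces <- lapply(1:200, function(i) {
    dw <- sample(10:30, 1)
    e1 <- stats::runif(1, 0.1, 0.55)
    render_pure_2c(rep(sample(1:2, 15, TRUE), each = dw),
                   e = c(e1, e1 + 0.35), snr = 200)
  })
  spec <- build_model("2c_alex", "states2", kernels1 = c(1, 3, 7, 15, 31))
  m <- train_model(spec, traces, epochs = 12, seed = 8)
  expect_gt(utils::tail(m$history$accuracy, 1), 0.99)
})

test_that("state classification is canonically ordered by the observable", {
  m <- tiny_states2()
  set.seed(6)
  ## states supplied in descending-FRET order must come back ascending
  tr <- render_pure_2c(rep(c(1L, 2L), 20, each = 12), e = c(0.75, 0.25),
                       snr = 30)
  sc <- classify_states(m, tr)
  obs <- tr$channels[, "DA"] / rowSums(tr$channels[, c("DD", "DA")])
  expect_lt(mean(obs[sc$states == 1]), mean(obs[sc$states == 2]))
  expect_true(all(sc$p >= 0 & sc$p <= 1))
  expect_equal(sc$confidence, mean(sc$p))
})

test_that("trained two-state classifier recovers a separable path", {
  m <- tiny_states2()
  set.seed(7)
  st <- rep(sample(1:2, 12, TRUE), each = 20)
  tr <- render_pure_2c(st, e = c(0.2, 0.8), snr = 40)
  sc <- classify_states(m, tr)
  expect_gt(mean(sc$states == st), 0.98)
})

test_that("classifier confidence degrades as SNR collapses", {
  m <- tiny_states2()
  set.seed(8)
  conf <- vapply(c(30, 3, 0.3), function(s) {
    mean(replicate(4, {
      tr <- render_pure_2c(rep(sample(1:2, 10, TRUE), each = 15),
                           e = c(0.2, 0.8), snr = s)
      classify_states(m, tr)$confidence
    }))
  }, numeric(1))
  expect_true(all(diff(conf) < 0))
})

test_that("classifier accuracy is monotone over an SNR ladder", {
  m <- tiny_states2()
  set.seed(12)
  acc <- vapply(c(25, 5, 1), function(s) {
    ok <- 0L; n <- 0L
    for (i in 1:20) {
      st <- rep(sample(1:2, 10, TRUE), each = 15)
      tr <- render_pure_2c(st, e = c(0.2, 0.8), snr = s)
      sc <- classify_states(m, tr)
      ok <- ok + sum(sc$states == st); n <- n + length(st)
    }
    ok / n
  }, numeric(1))
  ## non-increasing within a 1-point tolerance
  expect_gte(acc[1], acc[2] - 0.01)
  expect_gte(acc[2], acc[3] - 0.01)
})

test_that("segmentation reads bleach indices and absorbs label flicker", {
  labels <- c(rep("DA-dynamic", 100), rep("D-only", 50),
              rep("bleached", 50))
  sg <- segment_trace(labels, modality = "2c_alex")
  expect_equal(sg$segment, c(1, 100))
  expect_true(sg$dynamic)
  expect_equal(unname(sg$bleach), c(151L, 101L))  # dyes Y, R
  ## single-frame flicker inside the dynamic run is smoothed away
  labels2 <- labels
  labels2[40] <- "A-only"
  sg2 <- segment_trace(labels2, modality = "2c_alex")
  expect_equal(sg2$segment, c(1, 100))
  ## oracle: an explicit majority filter removes the island
  expect_equal(sg2$labels, majority_filter(labels2, 3L))
  expect_equal(majority_filter(labels2, 3L)[40], "DA-dynamic")
  ## an all-junk trace yields no usable segment
  sg3 <- segment_trace(rep("noisy", 80), modality = "2c_alex")
  expect_null(sg3$segment)
})

test_that("number-of-states prediction returns a distribution over 2:4", {
  set.seed(9)
  mk <- function(k, n) lapply(seq_len(n), function(i) {
    e <- seq(0.15, 0.85, length.out = k)
    km <- kinetic_model({
      r <- matrix(0.5, k, k); diag(r) <- 0; r
    }, cbind(YR = e))
    st <- rep(sample(1:k, 20, TRUE), each = 15)
    render_trace(pure_path(st, n_states = k),
                 km, std_pm(), detection_model("2c_alex", 0, 0, 1, snr = 40),
                 0.05, bleach_times = no_bleach())
  })
  train <- c(mk(2, 80), mk(3, 80), mk(4, 80))
  spec <- build_model("2c_alex", "n_states", kernels1 = c(1, 3, 7, 15, 31))
  m <- train_model(spec, train, epochs = 25, seed = 10)
  val2 <- mk(2, 10); val3 <- mk(3, 10)
  pr2 <- vapply(val2, function(t) predict_n_states(m, t), numeric(3))
  expect_equal(unname(colSums(pr2)), rep(1, 10), tolerance = 1e-6)
  expect_gt(mean(apply(pr2, 2, which.max) == 1), 0.8)
  pr3 <- vapply(val3, function(t) predict_n_states(m, t), numeric(3))
  expect_gt(mean(apply(pr3, 2, which.max) == 2), 0.6)
})

test_that("confusion reports are row-normalized with sane extremes", {
  m <- tiny_states2()
  cfg <- states_cfg(30, 93L, 2, n_frames = 150L)
  ds <- generate_dataset(cfg)
  cr <- evaluate_confusion(m, ds)
  expect_equal(unname(rowSums(cr$normalized)), rep(1, 2), tolerance = 1e-9)
  expect_gt(cr$accuracy, 0.9)   # near-identity for a trained model
  ## an untrained model on balanced two-state data sits near chance
  spec <- m$spec
  set.seed(11)
  rnd <- structure(list(spec = spec, params = smfret:::oscnn_init(spec),
                        history = data.frame()), class = "oscnn")
  cr2 <- evaluate_confusion(rnd, ds)
  expect_gt(cr2$accuracy, 0.2)
  expect_lt(cr2$accuracy, 0.8)
})
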