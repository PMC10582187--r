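test_that("alpha/delta are read off noise-free bleached segments exactly", {
  ## acceptor bleaches mid-trace: donor-only tail gives alpha
  st <- rep(1L, 200)
  tr <- render_pure_2c(st, e = c(0.5, 0.5), alpha = 0.05, delta = 0.08,
                       gamma = 1.3, bleach = c(Y = Inf, R = 100 * 0.05))
  sg <- segment_trace(tr$category, tr$modality)
  expect_equal(estimate_alpha(tr, sg), 0.05, tolerance = 1e-9)
  ## donor bleaches: acceptor-only tail gives delta
  tr2 <- render_pure_2c(st, e = c(0.5, 0.5), alpha = 0.05, delta = 0.08,
                        gamma = 1.3, bleach = c(Y = 100 * 0.05, R = Inf))
  sg2 <- segment_trace(tr2$category, tr2$modality)
  expect_equal(estimate_delta(tr2, sg2), 0.08, tolerance = 1e-9)
  ## and the complementary estimator is unavailable on each trace
  expect_true(is.na(estimate_delta(tr, sg)))
  expect_true(is.na(estimate_alpha(tr2, sg2)))
})

test_that("continuous-wave two-color data has no delta, with a diagnostic", {
  km <- two_state_model()
  pm <- std_pm("2c")
  dm <- detection_model("2c", alpha = 0.05, delta = 0, gamma = 1,
                        noise_sigma = 1e-12)
  tr <- render_trace(pure_path(rep(1L, 60), n_states = 2L), km, pm, dm,
                     0.05, bleach_times = c(Y = 40 * 0.05, R = Inf))
  sg <- segment_trace(tr$category, tr$modality)
  d <- estimate_delta(tr, sg)
  expect_true(is.na(d))
  expect_match(attr(d, "reason"), "acceptor-excitation")
})

test_that("gamma across an acceptor bleach recovers the truth exactly", {
  st <- rep(c(1L, 2L), 60)
  for (g in c(1, 1.3)) {
    tr <- render_pure_2c(st, e = c(0.3, 0.7), alpha = 0.05, delta = 0.08,
                         gamma = g, bleach = c(Y = Inf, R = 60 * 0.05))
    sg <- segment_trace(tr$category, tr$modality)
    expect_equal(estimate_gamma(tr, sg, alpha = 0.05, delta = 0.08), g,
                 tolerance = 1e-9)
  }
  ## bleach at the trace end leaves no post window
  tr3 <- render_pure_2c(st, bleach = c(Y = Inf, R = 118 * 0.05))
  sg3 <- segment_trace(tr3$category, tr3$modality)
  expect_true(is.na(estimate_gamma(tr3, sg3, alpha = 0, delta = 0)))
})

test_that("median trace-wise factors recover ground truth within 5% at SNR 10", {
  cfg <- sim_config(n_traces = 500, n_frames = 400, seed = 7,
                    mixture = c(dynamic = 0.7, static = 0.3),
                    n_states_set = 2, e_range = c(0.1, 0.9),
                    min_contrast = 0.2, snr_range = c(10, 10),
                    alpha = 0.05, delta = 0.08, gamma = 1.3,
                    bleach_expect_range = c(0.3, 1.2))
  ds <- generate_dataset(cfg)
  segs <- lapply(ds$traces, function(t) segment_trace(t$category, t$modality))
  cf <- correction_factors(ds$traces, segs)
  truth <- c(alpha = 0.05, delta = 0.08, gamma = 1.3)
  expect_true(all(abs(cf$median - truth) / truth < 0.05))
  expect_gt(sum(is.finite(cf$table$alpha)), 1)
})

test_that("apparent FRET is the proximity ratio with guarded denominators", {
  ch <- cbind(DD = c(20, 100, 50, 0), DA = c(80, 0, 50, 0),
              AA = c(10, 10, 10, 10))
  pr <- apparent_fret(ch, modality = "2c_alex")
  expect_equal(pr[, "YR"], c(0.8, 0, 0.5, NA))
})

test_that("two-color correction inverts the forward model", {
  st <- rep(c(1L, 2L), each = 40)
  ## identity: alpha = delta = 0, gamma = 1 makes E equal the PR
  tr0 <- render_pure_2c(st, e = c(0.25, 0.75))
  f0 <- corrected_fret_2c(tr0, c(alpha = 0, delta = 0, gamma = 1))
  expect_equal(f0$corrected[, "YR"], f0$apparent[, "YR"], tolerance = 1e-9)
  ## full factors: noise-free round trip to 1e-10
  tr <- render_pure_2c(st, e = c(0.25, 0.75), alpha = 0.07, delta = 0.1,
                       gamma = 1.4)
  ft <- corrected_fret_2c(tr, c(alpha = 0.07, delta = 0.1, gamma = 1.4))
  expect_lt(max(abs(ft$corrected[, "YR"] - c(0.25, 0.75)[st])), 1e-10)
  expect_error(corrected_fret_2c(tr, c(alpha = 0.07, delta = 0.1)),
               "gamma")
})

test_that("two-state correction restores the set efficiencies of a mimic
          of the origami measurement", {
  ## states at corrected E = 0.81 / 0.08 seen through realistic factors
  set.seed(21)
  km <- two_state_model(e = c(0.08, 0.81), dwell_s = c(2.65, 1.75))
  dm <- detection_model("2c_alex", alpha = 0.05, delta = 0.08,
                        gamma = 1.3, snr = 20)
  vals <- unlist(lapply(1:40, function(i) {
    p <- sample_state_path(km, 400, 0.05)
    tr <- render_trace(p, km, std_pm(), dm, 0.05,
                       bleach_times = no_bleach())
    corrected_fret_2c(tr, c(alpha = 0.05, delta = 0.08,
                            gamma = 1.3))$corrected[, "YR"]
  }))
  h <- build_histograms(vals)
  ## modal bin within each state's neighborhood (bin width 0.02)
  low <- h[h$mid < 0.45, ]; high <- h[h$mid > 0.45, ]
  expect_lt(abs(low$mid[which.max(low$count)] - 0.08), 0.03)
  expect_lt(abs(high$mid[which.max(high$count)] - 0.81), 0.03)
})

test_that("three-color correction inverts the cascade exactly", {
  st <- rep(c(1L, 2L), each = 50)
  km <- kinetic_model(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE),
                      cbind(BY = c(0.3, 0.5), BR = c(0.1, 0.1),
                            YR = c(0.6, 0.2)))
  pm <- std_pm("3c_alex")
  al <- c(BY = 0.05, BR = 0.03, YR = 0.07)
  de <- c(BY = 0.06, BR = 0.04, YR = 0.1)
  ga <- c(BY = 1.2, BR = 0.9, YR = 1.4)
  dm <- detection_model("3c_alex", al, de, ga, noise_sigma = 1e-12)
  tr <- render_trace(pure_path(st), km, pm, dm, 0.05,
                     bleach_times = no_bleach("3c_alex"))
  ft <- corrected_fret_3c(tr, list(alpha = al, delta = de, gamma = ga),
                          states = st)
  truth <- km$fret[st, ]
  expect_lt(max(abs(ft$corrected - truth)), 1e-10)
})

test_that("with E_YR = 0 the corrected BY reduces to its emission fraction", {
  km <- kinetic_model(matrix(0, 1, 1), cbind(BY = 0.4, BR = 0.2, YR = 0))
  dm <- noise_free_dm("3c_alex")
  tr <- render_trace(pure_path(rep(1L, 50)), km, std_pm("3c_alex"), dm,
                     0.05, bleach_times = no_bleach("3c_alex"))
  ft <- corrected_fret_3c(tr, list(alpha = c(BY = 0, BR = 0, YR = 0),
                                   delta = c(BY = 0, BR = 0, YR = 0),
                                   gamma = c(BY = 1, BR = 1, YR = 1)),
                          states = rep(1L, 50))
  Tt <- rowSums(tr$channels[, c("BB", "BY", "BR")])
  expect_equal(ft$corrected[, "BY"], tr$channels[, "BY"] / Tt,
               tolerance = 1e-9)
})

test_that("a state-independent BR efficiency is bimodal apparent but static
          after correction", {
  set.seed(22)
  km <- kinetic_model(matrix(c(0, 0.7, 0.7, 0), 2, 2, byrow = TRUE),
                      cbind(BY = c(0.36, 0.36), BR = c(0.36, 0.36),
                            YR = c(0.81, 0.08)))
  al <- c(BY = 0.05, BR = 0.03, YR = 0.07)
  de <- c(BY = 0.06, BR = 0.04, YR = 0.1)
  ga <- c(BY = 1.2, BR = 0.9, YR = 1.4)
  dm <- detection_model("3c_alex", al, de, ga, snr = 40)
  app1 <- app2 <- cor1 <- cor2 <- numeric(0)
  for (i in 1:20) {
    p <- sample_state_path(km, 300, 0.05)
    tr <- render_trace(p, km, std_pm("3c_alex"), dm, 0.05,
                       bleach_times = no_bleach("3c_alex"))
    st <- max.col(p$occupancy)
    pure <- apply(p$occupancy, 1, max) > 0.999
    ft <- corrected_fret_3c(tr, list(alpha = al, delta = de, gamma = ga),
                            states = st)
    app1 <- c(app1, ft$apparent[pure & st == 1, "BR"])
    app2 <- c(app2, ft$apparent[pure & st == 2, "BR"])
    cor1 <- c(cor1, ft$corrected[pure & st == 1, "BR"])
    cor2 <- c(cor2, ft$corrected[pure & st == 2, "BR"])
  }
  ## apparent: two bands; corrected: one band, much tighter
  expect_lt(abs(mean(cor1) - mean(cor2)), 0.03)
  expect_gt(abs(mean(app1) - mean(app2)),
            3 * abs(mean(cor1) - mean(cor2)))
  expect_gt(abs(mean(app1) - mean(app2)), 0.05)
  expect_equal(mean(c(cor1, cor2)), 0.36, tolerance = 0.03)
})

test_that("corrected BY distributions widen as the state YR efficiency
          approaches 1", {
  set.seed(23)
  spread <- vapply(c(0.3, 0.6, 0.85), function(eyr) {
    km <- kinetic_model(matrix(0, 1, 1),
                        cbind(BY = 0.4, BR = 0.1, YR = eyr))
    dm <- detection_model("3c_alex", alpha = 0.03, delta = 0.03,
                          gamma = 1.1, snr = 15)
    v <- unlist(lapply(1:10, function(i) {
      tr <- render_trace(pure_path(rep(1L, 300)), km, std_pm("3c_alex"),
                         dm, 0.05, bleach_times = no_bleach("3c_alex"))
      corrected_fret_3c(tr, list(alpha = c(BY = 0.03, BR = 0.03, YR = 0.03),
                                 delta = c(BY = 0.03, BR = 0.03, YR = 0.03),
                                 gamma = c(BY = 1.1, BR = 1.1, YR = 1.1)),
                        states = rep(1L, 300))$corrected[, "BY"]
    }))
    stats::var(v)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("FRET-to-distance follows the sixth-root law", {
  expect_equal(fret_to_distance(0.5, 68), 68)
  expect_equal(round(fret_to_distance(0.81, 68)), 53)
  expect_equal(round(fret_to_distance(0.14, 68)), 92)
  ## strictly decreasing in E; scale-free in R0
  e <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(fret_to_distance(e, 68)) < 0))
  expect_equal(fret_to_distance(e, 50) / 50, fret_to_distance(e, 68) / 68)
  expect_error(fret_to_distance(0, 68), "strictly")
  expect_error(fret_to_distance(1.2, 68), "strictly")
  expect_error(fret_to_distance(0.5, -1), "positive")
})

test_that("histograms conserve counts and concentrate where they should", {
  v <- rep(0.41, 500)
  h <- build_histograms(v)
  expect_equal(sum(h$count), 500)
  expect_equal(sum(h$count > 0), 1L)
  ## state-wise mode: dwell-weighted entries conserve frame counts
  st <- rep(c(1L, 2L), times = c(300, 200))
  v2 <- c(rep(0.2, 300), rep(0.8, 200))
  h2 <- build_histograms(v2, states = st, mode = "statewise")
  expect_equal(sum(h2$count), 500)
  ## two equal-occupancy states split the mass evenly (binomial error)
  set.seed(24)
  km <- two_state_model(e = c(0.2, 0.8), dwell_s = c(1, 1))
  p <- sample_state_path(km, 20000, 0.05)
  st3 <- max.col(p$occupancy)
  h3 <- build_histograms(ifelse(st3 == 1, 0.2, 0.8))
  m1 <- sum(h3$count[abs(h3$mid - 0.2) < 0.05])
  ## frames are dwell-correlated: effective n is the dwell count (~1000),
  ## each dwell carrying ~20 frames
  n_dwell <- nrow(p$events)
  expect_lt(abs(m1 - 10000), 3.3 * sqrt(n_dwell * 0.25) * 20)
})
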