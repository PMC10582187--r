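test_that("transition extraction follows the run-length contract", {
  tt <- extract_transitions(c(1, 1, 2, 2, 2, 1), frame_time = 1)
  expect_equal(nrow(tt), 2L)
  ## one interior dwell: state 2 for 3 s
  int <- tt[tt$interior, ]
  expect_equal(int$from_state, 2L)
  expect_equal(int$dwell_s, 3)
  expect_equal(int$to_state, 1L)
  ## a constant path has no transitions
  expect_equal(nrow(extract_transitions(rep(2L, 50), 1)), 0L)
  ## leading/trailing undefined frames are dropped
  tt2 <- extract_transitions(c(0, 0, 1, 1, 2, 2, 2, 0), 1)
  expect_equal(nrow(tt2), 1L)
  expect_false(any(tt2$interior))
})

test_that("interior dwell means match the continuous-time kinetics", {
  km <- two_state_model(e = c(0.2, 0.8), dwell_s = c(2, 2))
  set.seed(31)
  ## fine discretization (100 frames per dwell) so quantization loss
  ## stays below the 3% check
  p <- sample_state_path(km, 1e6L, 0.02)
  st <- max.col(p$occupancy)
  tt <- extract_transitions(st, 0.02)
  expect_gt(nrow(tt), 8000)
  d <- tt$dwell_s[tt$interior]
  expect_equal(mean(d), 2, tolerance = 0.03)
})

test_that("dwell-count conservation and two-state TDP symmetry hold", {
  set.seed(32)
  km <- two_state_model(dwell_s = c(0.5, 1))
  n_seg <- 30L
  tabs <- lapply(1:n_seg, function(i) {
    p <- sample_state_path(km, 400L, 0.05)
    extract_transitions(max.col(p$occupancy), 0.05)
  })
  n_trans <- sum(vapply(tabs, nrow, integer(1)))
  n_interior <- sum(vapply(tabs, function(t) sum(t$interior), integer(1)))
  n_active <- sum(vapply(tabs, nrow, integer(1)) >= 1L)
  expect_equal(n_interior, n_trans - n_active)
  tab <- bind_transitions(tabs)
  n12 <- sum(tab$from_state == 1 & tab$to_state == 2)
  n21 <- sum(tab$from_state == 2 & tab$to_state == 1)
  expect_lte(abs(n12 - n21), n_seg)
})

test_that("the TDP counts every transition and clusters at the states", {
  set.seed(33)
  km <- two_state_model(e = c(0.25, 0.75), dwell_s = c(1, 1))
  p <- sample_state_path(km, 30000L, 0.05)
  st <- max.col(p$occupancy)
  obs <- c(0.25, 0.75)[st] + stats::rnorm(length(st), 0, 0.02)
  tt <- extract_transitions(st, 0.05, observable = obs)
  tdp <- build_tdp(tt, bins = 50)
  expect_equal(sum(tdp$counts), nrow(tt))
  ## two off-diagonal clusters at the state observables (+- bin width)
  peak <- which(tdp$counts == max(tdp$counts), arr.ind = TRUE)[1, ]
  expect_lt(abs(tdp$mids[peak[1]] - 0.25) * abs(tdp$mids[peak[1]] - 0.75),
            0.03 * 0.6)
  expect_gt(abs(tdp$mids[peak[1]] - tdp$mids[peak[2]]), 0.3)
  expect_error(build_tdp(extract_transitions(rep(1L, 10), 1)), "empty")
})

test_that("TDP gates partition dwells and recover per-class kinetics", {
  set.seed(34)
  km <- two_state_model(e = c(0.25, 0.75), dwell_s = c(1, 2))
  p <- sample_state_path(km, 50000L, 0.05)
  st <- max.col(p$occupancy)
  obs <- c(0.25, 0.75)[st]
  tt <- extract_transitions(st, 0.05, observable = obs)
  all_g <- gate_tdp(tt, list(all = c(0, 1, 0, 1)))
  expect_equal(length(all_g$all), sum(tt$interior))
  gates <- list(g12 = c(0, 0.5, 0.5, 1), g21 = c(0.5, 1, 0, 0.5))
  parts <- gate_tdp(tt, gates)
  expect_equal(length(parts$g12) + length(parts$g21), sum(tt$interior))
  ## the 1->2 gate holds state-1 dwells (true mean 1 s)
  expect_equal(mean(parts$g12), 1, tolerance = 0.1)
  expect_equal(mean(parts$g21), 2, tolerance = 0.1)
  expect_warning(gate_tdp(tt, list(a = c(0, 1, 0, 1), b = c(0, 1, 0, 1))),
                 "overlapping")
})

test_that("the CDF fit recovers exponential dwell times with honest CIs", {
  set.seed(35)
  d <- stats::rexp(10000, 1 / 2)
  f <- fit_dwell_cdf(d)
  expect_gt(f$tau, 1.9)
  expect_lt(f$tau, 2.1)
  expect_true(f$ci95[1] <= f$tau && f$tau <= f$ci95[2])
  expect_gt(f$r_squared, 0.99)
  ## degenerate input: finite tau, flagged by a poor R^2
  f2 <- fit_dwell_cdf(rep(3, 25))
  expect_true(is.finite(f2$tau))
  expect_lt(f2$r_squared, 0.9)
  expect_error(fit_dwell_cdf(stats::rexp(5)), "got 5")
})

test_that("dwell recovery holds across the frame-ratio span with censoring
          handled, and degrades below ratio 3", {
  set.seed(36)
  ft <- 0.05
  for (ratio in c(9)) {
    tau <- ratio * ft
    km <- two_state_model(e = c(0.2, 0.8), dwell_s = c(tau, tau))
    p <- sample_state_path(km, as.integer(12000 * ratio), ft)
    tt <- extract_transitions(max.col(p$occupancy), ft)
    for (s in 1:2) {
      f <- fit_dwell_cdf(tt$dwell_s[tt$interior & tt$from_state == s])
      expect_lt(abs(f$tau - tau) / tau, 0.05)
    }
  }
  ## below ~3 frames per dwell the averaging-out loses transitions and
  ## tau is misestimated
  tau <- 2 * ft
  km <- two_state_model(e = c(0.2, 0.8), dwell_s = c(tau, tau))
  p <- sample_state_path(km, 60000L, ft)
  tt <- extract_transitions(max.col(p$occupancy), ft)
  f <- fit_dwell_cdf(tt$dwell_s[tt$interior & tt$from_state == 1])
  expect_gt(abs(f$tau - tau) / tau, 0.1)
})

test_that("CDF comparison is zero on identical data and flags halved dwells", {
  set.seed(37)
  d <- stats::rexp(2000, 1)
  cmp0 <- compare_cdfs(d, d)
  expect_equal(cmp0$max_abs, 0)
  cmp <- compare_cdfs(d, d / 2)
  expect_gt(max(cmp$delta[cmp$t < 1] * -1), 0.2)
  expect_gt(cmp$max_abs, 0.2)
})
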