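# Trained classifier fixtures, memoized per test run. Two scales:
# "tiny" models back the unit tests (seconds to train); "smoke" models
# back the scaled-down benchmark and end-to-end tests (2000 training
# traces, separable parameters).

.model_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .model_cache))
    assign(name, build(), envir = .model_cache)
  get(name, envir = .model_cache)
}

# configs ------------------------------------------------------------------

states_cfg <- function(n, seed, k, n_frames = 300L,
                       min_contrast = if (k == 2) 0.4 else 0.35,
                       snr = if (k == 2) c(8, 30) else c(12, 35),
                       e_range = c(0.08, 0.92))
  sim_config(modality = "2c_alex", n_traces = n, n_frames = n_frames,
             frame_time = 0.05, seed = seed, e_range = e_range,
             min_contrast = min_contrast, dwell_range = c(8, 50),
             snr_range = snr, n_states_set = k,
             mixture = c(dynamic = 1), bleach_expect_range = c(3, 6))

trace_cfg <- function(n, seed, n_frames = 300L)
  sim_config(modality = "2c_alex", n_traces = n, n_frames = n_frames,
             frame_time = 0.05, seed = seed, e_range = c(0.1, 0.9),
             min_contrast = 0.3, dwell_range = c(5, 50),
             snr_range = c(5, 40), n_states_set = 2:3,
             mixture = c(dynamic = 0.35, static = 0.15, noisy = 0.15,
                         aggregate = 0.15, artifact = 0.2),
             bleach_expect_range = c(0.4, 2))

# tiny models for unit tests ----------------------------------------------

tiny_states2 <- function() cached("tiny_states2", function() {
  ds <- generate_dataset(states_cfg(250, 31L, 2, n_frames = 150L))
  train_model(build_model("2c_alex", "states2", kernels1 = c(1, 3, 7, 15, 31)),
              ds, epochs = 6, seed = 4)
})

# smoke-scale models for the benchmark / end-to-end suites -----------------

smoke_states2 <- function() cached("smoke_states2", function() {
  ds <- generate_dataset(states_cfg(2000, 103L, 2))
  train_model(build_model("2c_alex", "states2"), ds, epochs = 10, seed = 5)
})

smoke_states3 <- function() cached("smoke_states3", function() {
  ds <- generate_dataset(states_cfg(2000, 104L, 3))
  train_model(build_model("2c_alex", "states3"), ds, epochs = 12, seed = 5)
})

smoke_trace <- function() cached("smoke_trace", function() {
  ds <- generate_dataset(trace_cfg(2000, 105L))
  train_model(build_model("2c_alex", "trace", f1 = 8, f2 = 48,
                          g_units = 24),
              ds, epochs = 16, seed = 5)
})
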