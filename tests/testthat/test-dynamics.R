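test_that("crossing detector locates analytic sinusoid crossings", {
  t <- seq(0, 1, by = 1e-3)
  # phase-shifted 5 Hz sinusoid: upward zero crossings at 0.01 + k/5
  tr <- tibble::tibble(time = t, v = sin(2 * pi * 5 * t - pi / 10))
  got <- detect_crossings(tr, threshold = 0)
  expect_length(got, 5)
  expect_equal(got, 0.01 + 0.2 * (0:4), tolerance = 1e-4)
})

test_that("constant and subthreshold traces yield no crossings", {
  t <- seq(0, 1, by = 1e-3)
  expect_length(detect_crossings(tibble::tibble(time = t, v = rep(-1, length(t))),
                                 threshold = 0), 0)
  expect_length(detect_crossings(tibble::tibble(time = t[1:2], v = c(-1, -1)),
                                 threshold = 0), 0)
})

test_that("crossing detector agrees with the brute-force sign-scan oracle", {
  cases <- list(
    simulate_neuron(minimal_params(), duration = 15),
    simulate_neuron(minimal_params(g_a = 0.026, g_n = 0.77), duration = 15),
    simulate_neuron(bio_params(gbar_nmda = 6), duration = 4000)
  )
  for (traj in cases) {
    thr <- attr(traj, "params")$v_spike
    got <- detect_crossings(traj)
    ora <- oracle_upward_crossings(traj$time, traj$v, thr)
    expect_length(got, length(ora))
    # interpolated instants lie within one sample of the oracle's
    dt <- diff(traj$time[1:2])
    expect_true(all(abs(got - ora) <= dt + 1e-12))
  }
})

test_that("frequency is the mean crossing rate over the analysis window", {
  # 11 equally spaced crossings spanning exactly 1 s -> 10 Hz
  t <- seq(0, 1.05, by = 1e-4)
  tr <- tibble::tibble(time = t, v = sin(2 * pi * 10 * (t - 0.005)))
  fs <- firing_summary(tr, threshold = 0, transient = 0)
  expect_identical(fs$regime, "firing")
  expect_equal(fs$n_crossings, 11)
  expect_equal(fs$frequency, 10, tolerance = 1e-6)
})

test_that("fewer than three crossings never counts as firing", {
  t <- seq(0, 1, by = 1e-4)
  v <- ifelse(t < 0.25, sin(2 * pi * 8 * t), -0.5)
  fs <- firing_summary(tibble::tibble(time = t, v = v), threshold = 0,
                       transient = 0)
  expect_false(identical(fs$regime, "firing"))
  expect_true(is.na(fs$frequency))
})

test_that("frequency times mean inter-crossing interval is unity", {
  fs <- firing_summary(simulate_neuron(minimal_params(g_n = 0.6),
                                       duration = 20), transient = 8)
  isi <- diff(fs$crossing_times)
  expect_equal(fs$frequency * mean(isi), 1, tolerance = 1e-9)
})

test_that("tonic oscillation in isolation lies in the 1-4 Hz band", {
  fs <- firing_summary(simulate_neuron(minimal_params(), duration = 30))
  expect_identical(fs$regime, "firing")
  expect_gt(fs$frequency, 1)
  expect_lt(fs$frequency, 4)
})

test_that("strong AMPA alone provokes depolarisation block", {
  traj <- simulate_neuron(minimal_params(g_a = 0.04), duration = 20)
  fs <- firing_summary(traj, transient = 10)
  expect_identical(fs$regime, "quiescent")
  # the resting level sits above the oscillation trough of the tonic state
  tonic <- simulate_neuron(minimal_params(), duration = 20)
  expect_gt(min(traj$v[traj$time >= 10]), min(tonic$v[tonic$time >= 10]))
})

test_that("frequency estimates are refinement-invariant", {
  f_ref <- firing_summary(simulate_neuron(minimal_params(g_n = 0.6),
                                          duration = 30))$frequency
  f_tight <- firing_summary(simulate_neuron(minimal_params(g_n = 0.6),
                                            duration = 30, rtol = 5e-9,
                                            atol = 5e-9))$frequency
  expect_equal(f_tight, f_ref, tolerance = 0.01)
  f_long <- firing_summary(simulate_neuron(minimal_params(g_n = 0.6),
                                           duration = 60))$frequency
  expect_equal(f_long, f_ref, tolerance = 0.01)
})

test_that("steady frequency is insensitive to the initial state", {
  f1 <- firing_summary(simulate_neuron(minimal_params(g_n = 0.77),
                                       duration = 30))$frequency
  f2 <- firing_summary(simulate_neuron(minimal_params(g_n = 0.77),
                                       duration = 30,
                                       init = c(0.2, 6)))$frequency
  expect_equal(f1, f2, tolerance = 0.01)
  b1 <- firing_summary(simulate_neuron(bio_params(gbar_nmda = 6),
                                       duration = 12000))$frequency
  b2 <- firing_summary(simulate_neuron(bio_params(gbar_nmda = 6),
                                       duration = 12000,
                                       init = c(-80, 2, 0.5)))$frequency
  expect_equal(b1, b2, tolerance = 0.01)
})

test_that("subthreshold oscillations are distinguished from rest", {
  # just above the Hopf onset at high AMPA the cycle is tiny and stays
  # below threshold: subthreshold_oscillation, not quiescent
  hb <- hopf_boundary(minimal_params(), ampa_values = 0.04)
  gn <- hb$g_n_hopf + 0.005
  fs <- firing_summary(simulate_neuron(minimal_params(0.04, gn),
                                       duration = 40), transient = 25)
  expect_identical(fs$regime, "subthreshold_oscillation")
  # well below onset: quiescent
  fs0 <- firing_summary(simulate_neuron(minimal_params(0.04, hb$g_n_hopf - 0.3),
                                        duration = 20), transient = 10)
  expect_identical(fs0$regime, "quiescent")
})

test_that("the documented amplitude floors match fresh computation", {
  expect_equal(subthreshold_floor(minimal_params(), duration = 20),
               0.0048, tolerance = 0.05)
  expect_equal(subthreshold_floor(bio_params(), duration = 10000),
               0.48, tolerance = 0.05)
})

test_that("simulation and summary inputs are validated", {
  expect_error(simulate_neuron(minimal_params(), duration = -1), "positive")
  expect_error(simulate_neuron(minimal_params(), init = c(0, NA)), "finite")
  traj <- simulate_neuron(minimal_params(), duration = 2)
  expect_error(firing_summary(traj, transient = 5), "window")
  expect_error(detect_crossings(tibble::tibble(time = 0:1, v = c(0, 1))),
               "threshold")
})

test_that("tidy and glance methods summarise firing objects", {
  fs <- firing_summary(simulate_neuron(minimal_params(), duration = 20),
                       transient = 5)
  td <- tidy(fs)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("crossing", "time", "isi"))
  expect_true(is.na(td$isi[1]))
  gl <- glance(fs)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$frequency, fs$frequency)
})
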