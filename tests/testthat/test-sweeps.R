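# small synthetic map used for degenerate-case tests
fake_map <- function(freqs_on_line0, freqs_joint) {
  df <- tibble::tibble(
    g_ampa = rep(c(0, 0.02), each = length(freqs_on_line0)),
    g_nmda = rep(seq_along(freqs_on_line0) * 0.1, 2),
    frequency = c(freqs_on_line0, freqs_joint),
    regime = ifelse(is.na(c(freqs_on_line0, freqs_joint)),
                    "quiescent", "firing"),
    amplitude = 1, n_crossings = 10
  )
  structure(df, class = c("da_frequency_map", class(df)),
            model = "minimal", params = minimal_params(),
            ampa_axis = c(0, 0.02),
            nmda_axis = seq_along(freqs_on_line0) * 0.1,
            settings = list(duration = NULL, transient = NULL, rtol = 1e-8))
}

test_that("frequency curve and map agree on shared grid points", {
  gn <- c(0.5, 0.7)
  cur <- frequency_curve(minimal_params(), vary = "nmda", grid = gn,
                         duration = 20, transient = 10)
  map <- frequency_map(minimal_params(), ampa_grid = c(0, 0.02),
                       nmda_grid = gn, duration = 20, transient = 10)
  line0 <- map[map$g_ampa == 0, ]
  expect_equal(cur$frequency, line0$frequency)
  expect_equal(cur$regime, line0$regime)
})

test_that("a zero ratio line reproduces the NMDA-only curve", {
  gn <- c(0.4, 0.8)
  prof <- ratio_line_profile(minimal_params(), ratio = 0, nmda_grid = gn,
                             duration = 20, transient = 10)
  cur <- frequency_curve(minimal_params(), vary = "nmda", grid = gn,
                         duration = 20, transient = 10)
  expect_equal(prof$frequency, cur$frequency)
  expect_true(all(prof$g_ampa == 0))
})

test_that("the 1/30 ratio line outperforms the 1/15 line", {
  gn <- seq(0.2, 1.2, by = 0.2)
  p30 <- ratio_line_profile(minimal_params(), 1 / 30, gn,
                            duration = 20, transient = 10)
  p15 <- ratio_line_profile(minimal_params(), 1 / 15, gn,
                            duration = 20, transient = 10)
  max30 <- max(p30$frequency, na.rm = TRUE)
  max15 <- suppressWarnings(max(p15$frequency, na.rm = TRUE))
  expect_gt(max30, max15)
  expect_gt(sum(p30$regime == "firing"), sum(p15$regime == "firing"))
})

test_that("the NMDA-only frequency curve is single-peaked", {
  cur <- frequency_curve(minimal_params(), vary = "nmda",
                         grid = seq(0.1, 1.2, by = 0.1),
                         duration = 30, transient = 10)
  f <- cur$frequency[cur$regime == "firing"]
  k <- which.max(f)
  expect_true(all(diff(f[seq_len(k)]) > 0))
  expect_true(all(diff(f[k:length(f)]) < 0))
})

test_that("frequency is reported exactly where the regime is firing", {
  map <- frequency_map(minimal_params(), ampa_grid = c(0, 0.04),
                       nmda_grid = c(0.1, 0.7), duration = 20,
                       transient = 10)
  expect_identical(is.na(map$frequency), map$regime != "firing")
  expect_true(all(map$frequency[!is.na(map$frequency)] > 0))
})

test_that("synergy report handles the degenerate all-on-axis maximum", {
  m <- fake_map(c(5, 8, 6), c(4, 6, 5))
  rep <- synergy_report(m, refine = FALSE)
  expect_equal(rep$synergy_percent, 0)
  expect_equal(rep$f_joint, rep$f_nmda_only)
  expect_equal(unname(rep$argmax["g_ampa"]), 0)
})

test_that("synergy is positive when co-activation wins", {
  m <- fake_map(c(5, 8, 6), c(4, 10, 5))
  rep <- synergy_report(m, refine = FALSE)
  expect_equal(rep$synergy_percent, 25)
  expect_equal(unname(rep$argmax["g_ampa"]), 0.02)
  gl <- glance(rep)
  expect_equal(gl$synergy_percent, 25)
})

test_that("synergy is undefined without firing on the NMDA-only line", {
  m <- fake_map(c(NA, NA, NA), c(4, 10, 5))
  expect_error(synergy_report(m), "undefined")
})

test_that("sweep grids are validated", {
  expect_error(frequency_map(minimal_params(), ampa_grid = numeric()),
               "non-empty")
  expect_error(frequency_curve(minimal_params(), grid = c(0.5, 0.3)),
               "increasing")
  expect_error(ratio_line_profile(minimal_params(), ratio = -1),
               "non-negative")
})

test_that("a cache file makes sweeps resumable without recomputation", {
  cache <- withr::local_tempfile(fileext = ".csv")
  map1 <- frequency_map(minimal_params(), ampa_grid = 0,
                        nmda_grid = c(0.5, 0.7), duration = 15,
                        transient = 8, cache_file = cache)
  expect_true(file.exists(cache))
  # poison one cached point; a re-run must take it from the cache
  pts <- utils::read.csv(cache)
  pts$frequency[1] <- 99
  utils::write.csv(pts, cache, row.names = FALSE)
  map2 <- frequency_map(minimal_params(), ampa_grid = 0,
                        nmda_grid = c(0.5, 0.7), duration = 15,
                        transient = 8, cache_file = cache)
  expect_equal(map2$frequency[1], 99)
  expect_equal(map2$frequency[2], map1$frequency[2])
})

test_that("sweeps are deterministic for fixed settings", {
  a <- frequency_curve(minimal_params(), vary = "ampa", grid = c(0, 0.004),
                       duration = 15, transient = 8)
  b <- frequency_curve(minimal_params(), vary = "ampa", grid = c(0, 0.004),
                       duration = 15, transient = 8)
  expect_identical(a$frequency, b$frequency)
})
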