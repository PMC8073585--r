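# Peak detection, coelution gating and light-to-heavy ratios.

test_that("a noiseless Gaussian integrates to its closed-form area", {
  amp <- 5e4; sigma <- 0.08
  pk <- detect_peak(gaussian_trace(amp, 20, sigma))
  expect_false(is.null(pk))
  expect_equal(pk$apex_time, 20, tolerance = 0.01)
  expect_equal(pk$area, gaussian_area(amp, sigma), tolerance = 0.02 *
                 gaussian_area(amp, sigma))
})

test_that("flat or all-zero traces yield no peak", {
  expect_null(detect_peak(flat_trace(0)))
  expect_null(detect_peak(flat_trace(50)))  # constant baseline, no peak
})

test_that("with two disjoint peaks the apex sits on the taller", {
  tr <- gaussian_trace(1e4, 19.4, 0.05, from = 19, to = 21)
  tr$intensity <- tr$intensity +
    gaussian_trace(3e4, 20.6, 0.05, from = 19, to = 21)$intensity
  pk <- detect_peak(tr)
  expect_equal(pk$apex_time, 20.6, tolerance = 0.02)
})

test_that("fragment areas sum to the total area", {
  tr <- rbind(gaussian_trace(3e4, 20, 0.08, fragment = "y3"),
              gaussian_trace(2e4, 20, 0.08, fragment = "y4"))
  pk <- detect_peak(tr)
  expect_equal(sum(pk$fragment_areas), pk$area, tolerance = 1e-9)
  expect_true(pk$boundaries[1] < pk$apex_time &&
                pk$apex_time < pk$boundaries[2])
})

test_that("coelution respects the closed apex tolerance and overlap", {
  a <- detect_peak(gaussian_trace(1e4, 20.0))
  expect_true(coelution_test(a, a)$coelutes)
  expect_equal(coelution_test(a, a)$apex_delta, 0)
  b <- detect_peak(gaussian_trace(1e4, 21.0, from = 20, to = 22))
  expect_false(coelution_test(a, b, apex_tolerance = 0.2)$coelutes)
  # a delta exactly at the tolerance passes (closed boundary)
  c_ <- detect_peak(gaussian_trace(1e4, 20.1))
  delta <- coelution_test(a, c_)$apex_delta
  expect_true(coelution_test(a, c_, apex_tolerance = delta)$coelutes)
  expect_false(coelution_test(NULL, a)$coelutes)
  # symmetry in channel order
  expect_equal(coelution_test(a, c_)$apex_delta,
               coelution_test(c_, a)$apex_delta)
})

test_that("ratios behave like areas", {
  a <- detect_peak(gaussian_trace(1e4, 20))
  b <- detect_peak(gaussian_trace(1e4, 20))
  expect_equal(light_heavy_ratio(a, b), 1.0, tolerance = 1e-9)
  # scaling both channels leaves the ratio unchanged
  a2 <- detect_peak(gaussian_trace(3.7e4, 20))
  b2 <- detect_peak(gaussian_trace(3.7e4, 20))
  expect_equal(light_heavy_ratio(a2, b2), light_heavy_ratio(a, b),
               tolerance = 1e-9)
  zero <- a; zero$area <- 0
  expect_error(light_heavy_ratio(a, zero), "spike")
})

test_that("a simulated true ratio of 2 is recovered within 0.1 at 1% noise", {
  profile <- data.frame(peptide = "GADVWFK", group = "g",
                        true_ratio = 2.0, dropout = 0)
  cfg <- simulation_config(profile, samples_per_group = 5, seed = 23,
                           noise_cv = 0.01)
  sim <- simulate_xics(cfg)
  q <- quantify_xics(sim$xic)
  expect_true(all(q$detected))
  expect_true(all(abs(q$light_to_heavy_ratio - 2.0) < 0.1))
})

test_that("detection is monotone in light-channel signal", {
  set.seed(3)
  profile <- data.frame(peptide = "GADVWFK", group = "g",
                        true_ratio = 1, dropout = 0)
  cfg <- simulation_config(profile, samples_per_group = 1, seed = 17)
  base <- simulate_xics(cfg)$xic
  was_detected <- NA
  for (scale in c(1e-4, 1e-3, 1e-2, 0.1, 1, 10)) {
    x <- base
    light <- x$channel == "light"
    x$intensity[light] <- x$intensity[light] * scale
    det <- quantify_xics(x)$detected
    if (!is.na(was_detected)) expect_true(det >= was_detected)
    was_detected <- det
  }
  expect_true(was_detected)  # at the top of the ramp it is detected
})

test_that("presence calls follow coelution-gated detection per group", {
  res <- data.frame(
    sample_id = c("h_01", "h_02", "i_01", "i_02"),
    peptide = "DLYNFLK",
    coelutes = c(FALSE, FALSE, TRUE, TRUE),
    detected = c(FALSE, FALSE, TRUE, TRUE),
    light_to_heavy_ratio = c(NA, NA, 1.2, 1.4), apex_delta = 0)
  man <- data.frame(sample_id = c("h_01", "h_02", "i_01", "i_02"),
                    group = c("healthy", "healthy", "inflamed", "inflamed"))
  tab <- call_detection(res, man)
  expect_equal(tab$healthy, "-")
  expect_equal(tab$inflamed, "+")
  # panel peptides never quantified appear as all-absent rows
  tab2 <- call_detection(res, man, panel = c("DLYNFLK", "IQGTCYR"))
  expect_equal(tab2[tab2$peptide == "IQGTCYR", c("healthy", "inflamed")],
               data.frame(healthy = "-", inflamed = "-", row.names = 2L))
})

test_that("replicates are averaged at the ratio level", {
  one <- gaussian_trace(1e4, 20)
  xic <- rbind(
    cbind(sample_id = "s1", peptide = "GADVWFK", channel = "heavy",
          replicate = 1L, one),
    cbind(sample_id = "s1", peptide = "GADVWFK", channel = "light",
          replicate = 1L, transform(one, intensity = intensity * 2)),
    cbind(sample_id = "s1", peptide = "GADVWFK", channel = "heavy",
          replicate = 2L, one),
    cbind(sample_id = "s1", peptide = "GADVWFK", channel = "light",
          replicate = 2L, transform(one, intensity = intensity * 4)))
  q <- quantify_xics(xic)
  expect_equal(nrow(q), 1L)
  expect_equal(q$light_to_heavy_ratio, 3.0, tolerance = 1e-6)
})
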