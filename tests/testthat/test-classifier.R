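test_that("extrema detection: monotone traces have none, sinusoids have all", {
  mono <- make_trace(fixture_spec("sustained_exponential"))
  expect_equal(nrow(find_extrema(mono)), 0)

  # 10 * (1 - cos(2 pi t / 3600)) over 10 h: maxima of 20 at odd multiples
  # of 1800 s, interior minima of 0 at multiples of 3600 s
  t <- seq(0, 36000, by = 60)
  tr <- tgfscreen:::new_trace(t, 10 * (1 - cos(2 * pi * t / 3600)))
  ex <- find_extrema(tr)
  mx <- ex[ex$type == "max", ]
  expect_equal(nrow(mx), 10)
  expect_equal(mx$time_s, seq(1800, 34200, by = 3600))
  expect_equal(mx$value, rep(20, 10), tolerance = 1e-12)
  expect_equal(sum(ex$type == "min"), 9)
  # types alternate
  expect_true(all(ex$type[-1] != ex$type[-nrow(ex)]))
})

test_that("plateaus merge into one extremum at the plateau midpoint", {
  y <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, 1, 2)
  tr <- tgfscreen:::new_trace(seq(0, by = 60, length.out = length(y)), y)
  ex <- find_extrema(tr)
  expect_equal(nrow(ex), 2)
  expect_equal(ex$type, c("max", "min"))
  expect_equal(ex$time_s[1], (180 + 300) / 2)  # midpoint of the 3-plateau
  expect_equal(ex$value, c(3, 0))
})

test_that("damped-sinusoid extrema agree with the continuous closed form", {
  A <- 15; tau <- 40000; P <- 5400
  f <- function(t) A * exp(-t / tau) * (1 - cos(2 * pi * t / P))
  tr <- make_trace(fixture_spec("damped_sinusoid"))
  ex <- find_extrema(tr)
  mx <- ex[ex$type == "max", ]
  # continuous maxima located independently by optimisation near each peak
  for (i in seq_len(nrow(mx))) {
    opt <- stats::optimize(f, interval = mx$time_s[i] + c(-P / 4, P / 4),
                           maximum = TRUE)
    expect_lt(abs(mx$value[i] - opt$objective) / opt$objective, 0.01)
  }
})

test_that("analytic example traces get their implied labels", {
  cfg <- classifier_config()
  # flat zero: unresponsive
  expect_equal(classify_trace(make_trace(fixture_spec("constant")))$label,
               "unresponsive")
  # saturating exponential: sustained, with t90 ~ tau * ln(10) = 1382 s
  cl <- classify_trace(make_trace(fixture_spec("sustained_exponential")))
  expect_equal(cl$label, "sustained")
  expect_lt(abs(cl$t_peak90 - 600 * log(10)), 120)
  expect_equal(cl$Opeak, 20, tolerance = 1e-6)
  # biexponential pulse: transient (peak ~322 s, ends near zero)
  cl <- classify_trace(make_trace(fixture_spec("transient_biexponential")))
  expect_equal(cl$label, "transient")
  expect_equal(cl$Opeak, 30, tolerance = 5e-3)  # grid max vs continuous peak
  expect_lt(cl$Oend, 1)
  # damped sinusoid: oscillatory, sub-label from amplitude ratio
  # a5/a2 = exp(-3 * 5400 / 40000) = 0.67 >= 0.5 -> sustained oscillations
  cl <- classify_trace(make_trace(fixture_spec("damped_sinusoid")))
  expect_equal(cl$label, "sustained_oscillatory")
  expect_gte(cl$n_peaks, 4)
  # faster damping flips the sub-label: exp(-3 * 5400 / 8000) = 0.13 < 0.5
  cl <- classify_trace(make_trace(fixture_spec("damped_sinusoid",
                                               damping_s = 8000)))
  expect_equal(cl$label, "dampened_oscillatory")
  # period estimate within one grid step of the construction
  cl <- classify_trace(make_trace(fixture_spec("damped_sinusoid",
                                               duration_s = 72000)))
  expect_lt(abs(cl$period_s - 5400), 61)
})

test_that("failed and too-short traces are handled explicitly", {
  short <- tgfscreen:::new_trace(seq(0, 600, 60), rep(1, 11))
  expect_error(classify_trace(short), "horizon")
  failed <- tgfscreen:::new_trace(seq(0, 36000, 60),
                                  rep(NA_real_, 601), status = "failed")
  expect_equal(classify_trace(failed)$label, "failed")
})

test_that("labels are scale-equivariant: trace and threshold scale together", {
  fams <- list(fixture_spec("sustained_exponential"),
               fixture_spec("transient_biexponential"),
               fixture_spec("damped_sinusoid"),
               fixture_spec("damped_sinusoid", damping_s = 8000),
               fixture_spec("constant", value_pM = 15),
               fixture_spec("triangle_input"))
  for (spec in fams) {
    tr <- make_trace(spec)
    base <- classify_trace(tr)$label
    for (c_scale in c(0.05, 0.1, 10, 400)) {
      sc <- tgfscreen:::new_trace(tr$time_s, tr$output_pM * c_scale)
      lab <- classify_trace(sc, classifier_config(theta = 10 * c_scale))$label
      expect_equal(lab, base)
    }
  }
})

test_that("raising the threshold never creates responsiveness", {
  specs <- list(fixture_spec("sustained_exponential"),
                fixture_spec("transient_biexponential"),
                fixture_spec("damped_sinusoid"),
                fixture_spec("constant", value_pM = 12))
  thetas <- c(5, 10, 25, 50, 200)
  for (spec in specs) {
    tr <- make_trace(spec)
    responsive <- vapply(thetas, function(th) {
      classify_trace(tr, classifier_config(theta = th))$label !=
        "unresponsive"
    }, logical(1))
    # responsiveness is monotone non-increasing in theta
    expect_true(all(diff(responsive) <= 0))
  }
})

test_that("time stretching preserves the oscillation sub-label and scales period", {
  for (s in c(2, 5)) {
    base <- classify_trace(make_trace(fixture_spec("damped_sinusoid",
                                                   duration_s = 144000)))
    stretched <- classify_trace(make_trace(fixture_spec(
      "damped_sinusoid", period_s = 5400 * s, damping_s = 40000 * s,
      duration_s = 144000 * s)))
    expect_equal(stretched$label, base$label)
    expect_equal(stretched$period_s / base$period_s, s, tolerance = 0.05)
    expect_equal(stretched$duration_s / base$duration_s, s,
                 tolerance = 0.05)
  }
})

test_that("series mode uses the per-trace peak as threshold with a floor", {
  cfg <- classifier_config(series_mode = TRUE)
  # a tiny sustained-shaped trace is unresponsive only below the floor
  small <- make_trace(fixture_spec("sustained_exponential",
                                   amplitude_pM = 0.05))
  expect_equal(classify_trace(small, cfg)$label, "unresponsive")
  bigger <- make_trace(fixture_spec("sustained_exponential",
                                    amplitude_pM = 0.5))
  cl <- classify_trace(bigger, cfg)
  expect_equal(cl$label, "sustained")
  expect_equal(cl$theta_used, cl$Opeak)
})

test_that("extension beyond 10 h only happens for live oscillations", {
  fx <- fixture_parameter_sets()
  # non-oscillatory set: extension result identical to direct classification
  direct <- classify_trace(simulate_tgf(fx$sustained))
  ext <- classify_with_extension(fx$sustained, keep_trace = TRUE)
  expect_equal(ext$label, direct$label)
  expect_equal(max(ext$trace$time_s), 36000)
  expect_equal(ext$Opeak, direct$Opeak)
  # slowly damped oscillator: horizon extended, duration beyond 10 h
  osc <- classify_with_extension(fx$oscillatory, keep_trace = TRUE)
  expect_match(osc$label, "oscillatory")
  expect_gt(max(osc$trace$time_s), 36000)
  expect_gt(osc$duration_s, 36000)
  expect_gte(osc$n_peaks, 4)
})

test_that("classification tidies to a one-row summary", {
  cl <- classify_trace(make_trace(fixture_spec("damped_sinusoid")))
  td <- tidy(cl)
  expect_equal(nrow(td), 1)
  expect_equal(td$label, "sustained_oscillatory")
  expect_true(all(c("Opeak", "Oend", "n_peaks", "period_s") %in% names(td)))
})
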