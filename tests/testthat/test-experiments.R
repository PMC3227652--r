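test_that("saturation fit recovers parameters from self-consistent peaks", {
  x <- default_doses()
  expect_equal(x, c(0.2, 2, 6, 10, 15, 20, 50, 100, 150, 200, 1000, 2000))
  fit <- fit_saturation(x, 50 * (1 - exp(-x / 10)))
  expect_equal(fit$status, "ok")
  expect_equal(fit$eta_pM, 10, tolerance = 1e-6)
  expect_equal(fit$max_peak_pM, 50, tolerance = 1e-6)
  expect_lt(fit$resid_norm, 1e-6)
  # the curve's value at the lowest dose
  expect_equal(50 * (1 - exp(-0.2 / 10)), 0.9900663, tolerance = 1e-6)
  # low-eta curves (saturated at the first dose) are still identified
  fit2 <- fit_saturation(x, 50 * (1 - exp(-x / 0.05)))
  expect_equal(fit2$status, "ok")
  expect_equal(fit2$max_peak_pM, 50, tolerance = 1e-4)
  expect_lt(fit2$eta_pM, 0.2)

  refused <- fit_saturation(x, rep(0, 12))
  expect_equal(refused$status, "refused")
  expect_true(is.na(refused$eta_pM))
  expect_equal(glance(refused)$status, "refused")
  expect_equal(tidy(fit)$term, c("max_peak_pM", "eta_pM"))
})

test_that("dose-response of the sustained fixture saturates monotonically", {
  fx <- fixture_parameter_sets()
  fit <- dose_response(fx$sustained)
  expect_equal(fit$status, "ok")
  expect_gt(fit$eta_pM, 0)
  pk <- fit$data$Opeak_pM
  expect_true(all(diff(pk) >= -0.01 * pk[-length(pk)]))
  expect_false(dose_type_changed(fit))
})

test_that("faithfulness residual is zero on identical signals and scale-free", {
  t <- seq(0, 36000, by = 60)
  tri <- ligand_at(protocol_triangle(), t)
  expect_equal(faithfulness_residual(tri, tri), 0)
  expect_equal(faithfulness_residual(tri, 0.3 * tri), 0)
  set.seed(9)
  out <- abs(tri + stats::rnorm(length(t), sd = 50))
  r0 <- faithfulness_residual(tri, out)
  expect_gt(r0, 0)
  for (sc in c(0.01, 7)) {
    expect_equal(faithfulness_residual(tri * sc, out), r0)
    expect_equal(faithfulness_residual(tri, out * sc), r0)
  }
})

test_that("constant output against the triangle has the closed-form residual", {
  t <- seq(0, 36000, by = 60)
  tri <- ligand_at(protocol_triangle(), t)
  # normalized triangle rises 0..1 in 300 steps and back; against a
  # constant 1 the residual is 2 * sum((m/300)^2, m = 1..300)
  expected <- 2 * sum((1:300)^2) / 300^2
  expect_equal(faithfulness_residual(tri, rep(5, length(t))), expected)
  expect_equal(expected, 201.0011, tolerance = 1e-6)
})

test_that("faithfulness of the sustained fixture beats the transient one", {
  fx <- fixture_parameter_sets()
  fs <- faithfulness(fx$sustained)
  ft <- faithfulness(fx$transient)
  expect_equal(fs$status, "succeeded")
  expect_gt(fs$residual, 0)
  expect_lt(fs$residual, ft$residual)
})

test_that("decile labelling splits 10/10/80 with strict ties", {
  r <- as.numeric(1:10)
  lab <- decile_labels(r)
  expect_equal(sum(lab == "faithful"), 1)
  expect_equal(sum(lab == "unfaithful"), 1)
  expect_equal(lab[1], "faithful")
  expect_equal(lab[10], "unfaithful")

  expect_equal(decile_labels(rep(3, 12)), rep("neither", 12))

  set.seed(4)
  r100 <- sample(stats::runif(100))
  lab100 <- decile_labels(r100)
  expect_equal(as.integer(table(lab100)[c("faithful", "neither",
                                          "unfaithful")]),
               c(10L, 80L, 10L))
  expect_error(decile_labels(1:5), ">= 10")
})

test_that("totals scaling targets exactly one pool", {
  tot <- total_concentrations()
  expect_equal(unclass(scale_totals(tot, "receptor", 3)),
               c(R_tot = 3, S_tot = 60, C_tot = 100))
  expect_equal(unclass(scale_totals(tot, "cosmad", 1 / 4)),
               c(R_tot = 1, S_tot = 60, C_tot = 25))
  expect_error(scale_totals(tot, "ligand", 2))
})

test_that("switch detection requires the transient/sustained pair", {
  fx <- fixture_parameter_sets()
  # a single tested concentration can never switch
  long1 <- concentration_switch_screen(as_paramsets_row(fx$sustained),
                                       species = "cosmad", factors = 1)
  expect_false(switch_flags(long1)$switched)
  # without the feedback (k14 = 0) the label ignores Co-Smad scaling
  p0 <- unclass(fx$transient); p0["k14"] <- 0
  long0 <- concentration_switch_screen(
    as_paramsets_row(as_parameter_set(as.list(p0))),
    species = "cosmad", factors = 3^(-4:4))
  expect_equal(length(unique(long0$label)), 1)
  fl0 <- switch_flags(long0)
  expect_false(fl0$switched)
  expect_true(is.na(fl0$minimal_fold))
})

test_that("the frozen switching set has minimal fold 3 on the R-Smad grid", {
  res <- minimal_switch_fold(fold3_params(), "rsmad")
  expect_true(res$switched)
  expect_equal(res$ref_label, "transient")
  expect_equal(res$minimal_fold, 3)
})

test_that("oscillation period is unchanged by the stimulus strength", {
  fx <- fixture_parameter_sets()
  periods <- vapply(c(100, 200, 400), function(dose) {
    classify_with_extension(fx$oscillatory,
                            protocol = protocol_constant(dose))$period_s
  }, numeric(1))
  expect_true(all(is.finite(periods)))
  expect_lt(max(periods) / min(periods) - 1, 0.1)
})
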