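test_that("parameter sets validate their contents", {
  p <- midpoint_params()
  expect_s3_class(p, "tgf_params")
  expect_error(midpoint_params(k2 = -1), "negative")
  expect_error(midpoint_params(k7 = Inf), "non-finite")
  expect_error(as_parameter_set(list(k1 = 1)), "missing parameters")
  expect_error(parameter_set(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                             1, 1, 1, 1, h = 0.5), "Hill")
  # data-frame round trip
  row <- as_paramsets_row(p)
  expect_equal(unclass(as_parameter_set(row)), unclass(p))
})

test_that("rhs vanishes on the empty state and for single reactions", {
  p <- midpoint_params()
  zero <- stats::setNames(numeric(17), species_names())
  expect_equal(tgf_rhs(zero, p, L = 0.2), stats::setNames(numeric(17),
                                                          species_names()))
  # only ligand binding active: R = 1 nM, L = 0.2 nM, k2 = 1
  only_bind <- as_parameter_set(
    utils::modifyList(as.list(rep(0, 19)) |>
                        stats::setNames(paste0("k", 1:19)),
                      list(k2 = 1, k15 = 1, h = 2)))
  st <- zero; st["R"] <- 1
  d <- tgf_rhs(st, only_bind, L = 0.2)
  expect_equal(d[["R"]], -0.2)
  expect_equal(d[["LR"]], 0.2)
  expect_equal(sum(abs(d[setdiff(species_names(), c("R", "LR"))])), 0)
})

test_that("derivatives satisfy the structural conservation laws", {
  set.seed(42)
  for (i in 1:20) {
    p <- as_parameter_set(c(as.list(10^stats::runif(19, -4, 0)) |>
                              stats::setNames(paste0("k", 1:19)),
                            list(h = sample(1:4, 1))))
    st <- stats::setNames(10^stats::runif(17, -3, 2), species_names())
    d <- tgf_rhs(st, p, L = 10^stats::runif(1, -4, 0))
    expect_equal(d[["R"]] + d[["LR"]] + d[["LRa"]] + d[["LRaI"]], 0,
                 tolerance = 1e-12)
    smad <- d[["Sc"]] + d[["pSc"]] + d[["Sn"]] + d[["pSn"]] +
      2 * (d[["Dc"]] + d[["Dn"]]) + d[["Hc"]] + d[["Hn"]]
    expect_equal(smad, 0, tolerance = 1e-10)
    expect_equal(d[["Cc"]] + d[["Cn"]] + d[["Hc"]] + d[["Hn"]], 0,
                 tolerance = 1e-10)
  }
})

test_that("transcription flux saturates at k14 for large nuclear complex", {
  p <- midpoint_params()
  st <- stats::setNames(numeric(17), species_names())
  st["Hn"] <- 100 * p[["k15"]]
  d <- tgf_rhs(st, p, L = 0)
  expect_equal(d[["mn"]], p[["k14"]], tolerance = 0.01)
})

test_that("blocking phosphorylation blocks the output entirely", {
  tr <- simulate_tgf(midpoint_params(k7 = 0))
  expect_true(trace_succeeded(tr))
  expect_equal(max(abs(tr$output_pM)), 0, tolerance = 1e-9)
})

test_that("near-zero ligand in both phases stays below threshold", {
  tr <- simulate_tgf(midpoint_params(), protocol = protocol_constant(1e-6))
  expect_true(max(tr$output_pM) < 10)
})

test_that("trace grid covers the horizon densely and is monotone", {
  tr <- simulate_tgf(midpoint_params())
  expect_true(all(diff(tr$time_s) > 0))
  expect_true(max(diff(tr$time_s)) <= 60)
  expect_equal(range(tr$time_s), c(0, 36000))
  expect_true(all(tr$output_pM >= -1e-9))
})

test_that("conserved totals stay at their configured values", {
  tr <- simulate_tgf(midpoint_params(), keep_states = TRUE)
  ct <- conserved_totals(tr)
  expect_equal(ct$receptor_nM[1], 1, tolerance = 1e-6)
  expect_equal(ct$rsmad_nM[1], 60, tolerance = 1e-6)
  expect_equal(ct$cosmad_nM[1], 100, tolerance = 1e-6)
  for (col in c("receptor_nM", "rsmad_nM", "cosmad_nM")) {
    expect_lt(max(abs(ct[[col]] - ct[[col]][1])) / ct[[col]][1], 1e-6)
  }
  # doubling the R-Smad pool doubles its conservation trace exactly
  tr2 <- simulate_tgf(midpoint_params(),
                      totals = total_concentrations(S_tot = 120),
                      keep_states = TRUE)
  expect_equal(conserved_totals(tr2)$rsmad_nM, 2 * ct$rsmad_nM,
               tolerance = 1e-6)
})

test_that("an equilibrated system sits at steady state under near-zero ligand", {
  tr <- simulate_tgf(midpoint_params(),
                     protocol = protocol_constant(1e-6, duration_h = 100),
                     keep_states = TRUE)
  st <- attr(tr, "states")
  final <- st[nrow(st), ]
  d <- tgf_rhs(final, midpoint_params(), L = 1e-9)
  expect_lt(abs(d[["Hn"]]), 1e-12)
})

test_that("solver output matches the stored independent RK4 reference trace", {
  fx <- fixture_parameter_sets()
  ref <- read_trace_tsv(system.file("extdata", "fixtures",
                                    "reference_trace_sustained.tsv",
                                    package = "tgfscreen"))
  tr <- simulate_tgf(fx$sustained)
  expect_equal(tr$time_s, ref$time_s)
  expect_lt(max(abs(tr$output_pM - ref$output_pM)) / max(ref$output_pM),
            0.01)
})

test_that("non-finite parameters are rejected before integration", {
  p <- midpoint_params()
  bad <- unclass(p); bad["k5"] <- NaN
  expect_error(simulate_tgf(as.list(bad)), "invalid parameter set")
})
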