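# Shared parameter sets for tests.

# literature-midpoint rates (the centres of default_ranges())
midpoint_params <- function(...) {
  p <- list(k1 = 1e-3, k2 = 1e-3, k3 = 1e-3, k4 = 1e-3, k5 = 1e-2,
            k6 = 1e-4, k7 = 4e-4, k8 = 2.6e-3, k9 = 5.6e-3, k10 = 1.8e-3,
            k11 = 1.6e-2, k12 = 1.5e-2, k13 = 6.6e-3, k14 = 1e-3, k15 = 1,
            k16 = 1e-3, k17 = 1e-4, k18 = 1e-2, k19 = 3e-4)
  as_parameter_set(utils::modifyList(p, list(...)))
}

# a set whose response type switches under a 3-fold change of the R-Smad
# pool (found by a restricted-range switching screen and frozen; its
# minimal fold was confirmed at creation)
fold3_params <- function() {
  as_parameter_set(list(
    k1 = 0.00469963502874868, k2 = 0.00497087476707873,
    k3 = 0.0288080999953091, k4 = 0.00710812928297891,
    k5 = 0.0126450530046794, k6 = 2.50715646672194e-06,
    k7 = 0.000453376844910493, k8 = 0.00758485904284341,
    k9 = 0.00132130356586902, k10 = 0.000154121681679353,
    k11 = 0.0615030933362677, k12 = 0.1145952265417,
    k13 = 0.0131669403047415, k14 = 0.000109968385306302,
    k15 = 0.0712119247452998, k16 = 0.00538541334495514,
    k17 = 1.26924247920561e-05, k18 = 0.0423021809359197,
    k19 = 2.47450604206502e-05, h = 2))
}

# one row of a paramsets tibble from a single parameter set
as_paramsets_row <- function(p, draw = 1L) {
  dplyr::bind_cols(tibble::tibble(draw = draw),
                   tibble::as_tibble(as.list(unclass(p))))
}
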