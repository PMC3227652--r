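#' Scale one protein pool of a totals vector
#'
#' @param totals A [total_concentrations()].
#' @param species `"receptor"`, `"rsmad"` or `"cosmad"`.
#' @param factor Positive multiplier applied to that pool.
#' @return A `"tgf_totals"`.
#' @export
scale_totals <- function(totals, species, factor) {
  stopifnot(factor > 0)
  species <- match.arg(species, c("receptor", "rsmad", "cosmad"))
  el <- c(receptor = "R_tot", rsmad = "S_tot", cosmad = "C_tot")[[species]]
  tot <- unclass(totals)
  tot[el] <- tot[el] * factor
  do.call(total_concentrations, as.list(tot))
}

#' Protein-concentration switching screen
#'
#' Re-simulates each parameter set with the total concentration of one
#' protein pool (receptor, R-Smad or Co-Smad) scaled by each factor, from a
#' fresh phase-1 equilibration at the scaled totals, and classifies every
#' trace in series mode (the per-trace peak serves as threshold, so the
#' phenotype criteria stay relative across conditions).
#'
#' @param paramsets Tibble of parameter sets (columns `draw`,
#'   `k1` ... `k19`, `h`).
#' @param species Character vector of pools to scan.
#' @param factors Concentration multipliers; include 1 so that the reference
#'   condition is part of the scan (default the 100-fold pair plus the
#'   reference).
#' @param totals Reference totals `c0`.
#' @param protocol Stimulation protocol (default constant 200 pM).
#' @param cfg Classifier configuration; forced to series mode.
#' @return A `"tgf_switch"` tibble: one row per set x species x factor with
#'   `draw`, `species`, `factor`, `label`, `Opeak`.
#' @seealso [switch_flags()] for per-set switch calls and minimal folds.
#' @export
concentration_switch_screen <- function(paramsets,
                                        species = c("receptor", "rsmad",
                                                    "cosmad"),
                                        factors = c(0.01, 1, 100),
                                        totals = total_concentrations(),
                                        protocol = protocol_constant(),
                                        cfg = classifier_config()) {
  stopifnot(all(factors > 0))
  cfg$series_mode <- TRUE
  grid <- tidyr::expand_grid(i = seq_len(nrow(paramsets)),
                             species = species, factor = factors)
  recs <- purrr::pmap_dfr(grid, function(i, species, factor) {
    p <- as_parameter_set(paramsets[i, ])
    res <- classify_with_extension(p, scale_totals(totals, species, factor),
                                   protocol, cfg)
    tibble::tibble(draw = paramsets$draw[i], species = species,
                   factor = factor, label = res$label, Opeak = res$Opeak)
  })
  class(recs) <- c("tgf_switch", class(recs))
  recs
}

#' Switch calls and minimal fold-changes from a switching screen
#'
#' A parameter set *switches* for a given protein pool when it produces a
#' transient response at one tested concentration and a sustained response
#' at another. For switching sets the minimal fold-change is also reported:
#' the smallest fold away from the reference concentration at which the
#' label differs from the reference-concentration label, taken over the
#' tested factors lying on the three-fold grid `3^n, n = -4 ... 4` (so one
#' of 3, 9, 27, 81); `NA` when the set does not switch.
#'
#' @param switch_tbl Result of [concentration_switch_screen()]; must contain
#'   `factor == 1` rows for the reference labels.
#' @return Tibble with one row per `draw` x `species`: `ref_label`,
#'   `switched`, `minimal_fold`.
#' @export
switch_flags <- function(switch_tbl) {
  stopifnot(all(c("draw", "species", "factor", "label") %in%
                  names(switch_tbl)))
  if (!any(switch_tbl$factor == 1))
    stop("switch table lacks the reference concentration (factor == 1)")
  dplyr::group_by(switch_tbl, .data$draw, .data$species) |>
    dplyr::group_modify(function(d, key) {
      ref <- d$label[d$factor == 1][1]
      switched <- any(d$label == "transient") & any(d$label == "sustained")
      fold <- NA_real_
      if (switched) {
        n3 <- log(d$factor, base = 3)
        on_grid <- abs(n3 - round(n3)) < 1e-9
        hit <- on_grid & d$label != ref & d$factor != 1
        if (any(hit)) fold <- 3^min(abs(round(n3[hit])))
      }
      tibble::tibble(ref_label = ref, switched = switched,
                     minimal_fold = fold)
    }) |>
    dplyr::ungroup()
}

#' Minimal concentration fold-change that switches one parameter set
#'
#' Scans one protein pool over the three-fold grid `c0 * 3^n`,
#' `n = -4 ... 4`, and reports the switch call and minimal fold for a single
#' parameter set (see [switch_flags()]).
#'
#' @param paramset A [parameter_set()].
#' @param species `"receptor"`, `"rsmad"` or `"cosmad"`.
#' @inheritParams concentration_switch_screen
#' @return One-row tibble: `species`, `ref_label`, `switched`,
#'   `minimal_fold`.
#' @export
minimal_switch_fold <- function(paramset, species,
                                totals = total_concentrations(),
                                protocol = protocol_constant(),
                                cfg = classifier_config()) {
  p <- as_parameter_set(paramset)
  ps <- dplyr::bind_cols(tibble::tibble(draw = 1L),
                         tibble::as_tibble(as.list(unclass(p))))
  long <- concentration_switch_screen(ps, species = species,
                                      factors = 3^(-4:4), totals = totals,
                                      protocol = protocol, cfg = cfg)
  dplyr::select(switch_flags(long), -"draw")
}

#' The reference 12-point ligand dose grid (pM)
#' @return Numeric vector of doses.
#' @export
default_doses <- function() {
  c(0.2, 2, 6, 10, 15, 20, 50, 100, 150, 200, 1000, 2000)
}

#' Fit the exponential saturation curve to peak responses
#'
#' Least-squares fit of `Opeak = max_peak * (1 - exp(-x / eta))` to peak
#' output versus ligand dose, with positivity constraints; `eta` is the dose
#' scale at which the response saturates. Initial guesses are the median
#' dose for `eta` and the largest observed peak for `max_peak`. An all-zero
#' (or any non-finite) peak vector cannot identify the curve and the fit is
#' refused with an explicit status rather than an error.
#'
#' @param doses Ligand doses (pM), at least 4.
#' @param peaks Peak outputs (pM), same length.
#' @param data Optional tibble carried along (per-dose labels etc.).
#' @return A `"saturation_fit"`: list with `eta_pM`, `max_peak_pM`,
#'   `resid_norm`, `status` (`"ok"` or `"refused"`), `data`.
#' @export
#' @examples
#' x <- default_doses()
#' fit <- fit_saturation(x, 50 * (1 - exp(-x / 10)))
#' glance(fit)
fit_saturation <- function(doses, peaks, data = NULL) {
  stopifnot(length(doses) == length(peaks), length(doses) >= 4,
            all(doses > 0))
  if (is.null(data)) data <- tibble::tibble(dose_pM = doses, Opeak_pM = peaks)
  out <- structure(list(eta_pM = NA_real_, max_peak_pM = NA_real_,
                        resid_norm = NA_real_, status = "refused",
                        data = data),
                   class = "saturation_fit")
  if (any(!is.finite(peaks)) || max(peaks) <= 0) return(out)
  # primary start: median dose; fallbacks cover curves that are already
  # saturated at the smallest dose (eta far below the dose grid), where the
  # primary start leaves the Jacobian degenerate
  starts <- unique(c(stats::median(doses), min(doses), min(doses) / 100,
                     max(doses)))
  fit <- NULL
  for (eta0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        peaks ~ M * (1 - exp(-doses / eta)),
        start = list(M = max(peaks), eta = eta0),
        lower = c(M = .Machine$double.eps, eta = .Machine$double.eps),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  out$eta_pM <- unname(cf["eta"])
  out$max_peak_pM <- unname(cf["M"])
  out$resid_norm <- sqrt(sum(stats::residuals(fit)^2))
  out$status <- "ok"
  out$fit <- fit
  out
}

#' Dose-response curve of one parameter set
#'
#' Simulates the two-phase protocol at each ligand dose, records the peak
#' output and the series-mode response label per dose, and fits the
#' exponential saturation curve with [fit_saturation()].
#'
#' @param paramset A [parameter_set()].
#' @param totals A [total_concentrations()].
#' @param doses Ligand doses in pM (default the reference 12-point grid).
#' @param cfg Classifier configuration; forced to series mode for the
#'   per-dose labels.
#' @param duration_h Stimulation length per dose (h).
#' @return A `"saturation_fit"` whose `data` has one row per dose:
#'   `dose_pM`, `Opeak_pM`, `label`.
#' @export
dose_response <- function(paramset, totals = total_concentrations(),
                          doses = default_doses(),
                          cfg = classifier_config(), duration_h = 10) {
  p <- as_parameter_set(paramset)
  cfg$series_mode <- TRUE
  per_dose <- purrr::map_dfr(doses, function(x) {
    res <- classify_with_extension(p, totals,
                                   protocol_constant(x, duration_h), cfg)
    tibble::tibble(dose_pM = x, Opeak_pM = res$Opeak, label = res$label)
  })
  fit_saturation(per_dose$dose_pM, per_dose$Opeak_pM, data = per_dose)
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> status %s: eta = %.4g pM, max peak = %.4g pM\n",
              x$status, x$eta_pM, x$max_peak_pM))
  invisible(x)
}

#' @rdname fit_saturation
#' @param x A `"saturation_fit"`.
#' @param ... Unused.
#' @method tidy saturation_fit
#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble::tibble(term = c("max_peak_pM", "eta_pM"),
                 estimate = c(x$max_peak_pM, x$eta_pM))
}

#' @rdname fit_saturation
#' @method glance saturation_fit
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble::tibble(eta_pM = x$eta_pM, max_peak_pM = x$max_peak_pM,
                 resid_norm = x$resid_norm, status = x$status,
                 n_doses = nrow(x$data))
}

#' Normalized squared residual between an input and an output signal
#'
#' Both signals are first normalized by their own maximum, which removes any
#' proportionality coefficient between a faithful output and its input; the
#' residual is then `sum((input - output)^2)` over the shared grid. Zero iff
#' the normalized signals coincide at every point; invariant to rescaling
#' either signal by a positive constant.
#'
#' @param input,output Numeric vectors on a shared time grid; `input` must
#'   have a positive maximum.
#' @return Non-negative scalar.
#' @export
faithfulness_residual <- function(input, output) {
  stopifnot(length(input) == length(output), max(input) > 0)
  if (max(output) <= 0) {
    out_n <- rep(0, length(output))
  } else {
    out_n <- output / max(output)
  }
  sum((input / max(input) - out_n)^2)
}

#' Faithfulness of one parameter set to a time-varying input
#'
#' Simulates the triangular ligand protocol (0 to 720 pM over 5 h, back to 0
#' over the next 5 h), samples input and output on a shared uniform 60 s
#' grid, and computes the normalized squared residual between them. Intended
#' for parameter sets that respond sustainedly to a constant stimulus; sets
#' from the lowest residual decile of a cohort read the extracellular
#' concentration out proportionally (the morphogen regime).
#'
#' @param paramset A [parameter_set()].
#' @param totals A [total_concentrations()].
#' @param protocol Triangular protocol (default the reference ramp).
#' @param dt_out Shared grid spacing (s).
#' @return One-row tibble: `residual`, `status`.
#' @export
faithfulness <- function(paramset, totals = total_concentrations(),
                         protocol = protocol_triangle(), dt_out = 60) {
  stopifnot(protocol$type == "triangle")
  tr <- simulate_tgf(paramset, totals, protocol, dt_out = dt_out)
  if (!trace_succeeded(tr)) {
    return(tibble::tibble(residual = NA_real_, status = "failed"))
  }
  input <- ligand_at(protocol, tr$time_s)
  tibble::tibble(residual = faithfulness_residual(input, tr$output_pM),
                 status = "succeeded")
}

#' Decile labels for faithfulness residuals
#'
#' The lowest-decile residuals are labelled `faithful`, the highest-decile
#' `unfaithful`, everything in between `neither`. Thresholds are the
#' empirical 10%/90% quantiles compared strictly, so degenerate cohorts
#' (e.g. all residuals equal) label everything `neither`.
#'
#' @param residuals Numeric vector, at least 10 values.
#' @return Character vector of labels, same length and order.
#' @export
decile_labels <- function(residuals) {
  stopifnot(length(residuals) >= 10, all(is.finite(residuals)))
  q <- stats::quantile(residuals, c(0.1, 0.9), names = FALSE)
  dplyr::case_when(residuals < q[1] ~ "faithful",
                   residuals > q[2] ~ "unfaithful",
                   TRUE ~ "neither")
}

#' Did the response type change across a dose series?
#'
#' A qualitative type change means two different defined phenotypes
#' (sustained, transient, or an oscillatory sub-type) occur at different
#' doses of the same parameter set. Doses whose response is unresponsive or
#' undefined carry no type information (weak stimuli mostly slow the
#' response past the fast-response criterion) and are ignored.
#'
#' @param fit A `"saturation_fit"` from [dose_response()] (or its `data`).
#' @return Logical.
#' @export
dose_type_changed <- function(fit) {
  d <- if (inherits(fit, "saturation_fit")) fit$data else fit
  stopifnot("label" %in% names(d))
  defined <- c("sustained", "transient", "dampened_oscillatory",
               "sustained_oscillatory")
  length(unique(d$label[d$label %in% defined])) > 1
}
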