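#' Species of the state vector, in their fixed internal order
#'
#' Cytoplasmic species first (`R`, `LR`, `LRa`, `LRaI`: receptor forms;
#' `Sc`, `pSc`, `Cc`, `Dc`, `Hc`: Smad species; `mc`: I-Smad mRNA; `I`:
#' I-Smad protein), then nuclear (`Sn`, `pSn`, `Cn`, `Dn`, `Hn`, `mn`).
#' `Hn`, the nuclear phospho-R-Smad/Co-Smad heterodimer, is the monitored
#' transcription-factor output.
#'
#' @return Character vector of the 17 species names.
#' @export
species_names <- function() {
  c("R", "LR", "LRa", "LRaI", "Sc", "pSc", "Cc", "Dc", "Hc", "mc", "I",
    "Sn", "pSn", "Cn", "Dn", "Hn", "mn")
}

#' Right-hand side of the network ODEs
#'
#' Pure-R implementation of the mass-action derivatives, exposed for
#' inspection and testing; [simulate_tgf()] uses an equivalent compiled
#' version. Reactions: ligand-receptor binding/unbinding (`k2`, `k1`),
#' receptor (de)phosphorylation (`k3`, `k4`), I-Smad sequestration of the
#' active receptor (`k5`, `k6`), R-Smad phosphorylation (`k7`),
#' nucleocytoplasmic shuttling of monomers (`k8` in, `k9` out) and of dimers
#' (`k12`, import only), dimer formation/dissociation (`k10`, `k11`) in both
#' compartments, nuclear dephosphorylation of monomeric phospho-R-Smad
#' (`k13`), Hill-type transcription of I-Smad mRNA driven by the nuclear
#' heterodimer (`k14`, `k15`, `h`), mRNA export (`k16`), mRNA degradation
#' (`k17`), translation (`k18`) and I-Smad degradation (`k19`, free protein
#' only). The ligand enters only the binding flux and is never consumed.
#'
#' @param state Named numeric vector over [species_names()] (nM).
#' @param params A [parameter_set()].
#' @param L Ligand concentration (nM).
#' @return Named vector of time derivatives (nM/s).
#' @export
tgf_rhs <- function(state, params, L) {
  p <- as_parameter_set(params)
  stopifnot(L >= 0)
  s <- state[species_names()]
  with(as.list(c(p, s)), {
    v_bind <- k2 * L * R
    v_unbind <- k1 * LR
    v_act <- k3 * LR
    v_deact <- k4 * LRa
    v_seq <- k5 * LRa * I
    v_rel <- k6 * LRaI
    v_phos <- k7 * LRa * Sc
    v_Dc_on <- k10 * pSc^2; v_Dc_off <- k11 * Dc
    v_Hc_on <- k10 * pSc * Cc; v_Hc_off <- k11 * Hc
    v_Dn_on <- k10 * pSn^2; v_Dn_off <- k11 * Dn
    v_Hn_on <- k10 * pSn * Cn; v_Hn_off <- k11 * Hn
    v_txn <- if (Hn > 0) k14 * Hn^h / (k15^h + Hn^h) else 0
    d <- c(
      R = v_unbind - v_bind,
      LR = v_bind - v_unbind - v_act + v_deact,
      LRa = v_act - v_deact - v_seq + v_rel,
      LRaI = v_seq - v_rel,
      Sc = -v_phos - k8 * Sc + k9 * Sn,
      pSc = v_phos - k8 * pSc + k9 * pSn - 2 * v_Dc_on + 2 * v_Dc_off -
        v_Hc_on + v_Hc_off,
      Cc = -k8 * Cc + k9 * Cn - v_Hc_on + v_Hc_off,
      Dc = v_Dc_on - v_Dc_off - k12 * Dc,
      Hc = v_Hc_on - v_Hc_off - k12 * Hc,
      mc = k16 * mn - k17 * mc,
      I = k18 * mc - v_seq + v_rel - k19 * I,
      Sn = k8 * Sc - k9 * Sn + k13 * pSn,
      pSn = k8 * pSc - k9 * pSn - k13 * pSn - 2 * v_Dn_on + 2 * v_Dn_off -
        v_Hn_on + v_Hn_off,
      Cn = k8 * Cc - k9 * Cn - v_Hn_on + v_Hn_off,
      Dn = v_Dn_on - v_Dn_off + k12 * Dc,
      Hn = v_Hn_on - v_Hn_off + k12 * Hc,
      mn = v_txn - k16 * mn
    )
    d
  })
}

initial_state <- function(totals) {
  s <- stats::setNames(numeric(17), species_names())
  s["R"] <- totals[["R_tot"]]
  s["Sc"] <- totals[["S_tot"]]
  s["Cc"] <- totals[["C_tot"]]
  s
}

new_trace <- function(time_s, output_pM, status = "succeeded",
                      states = NULL, unit = "pM") {
  tr <- tibble::tibble(time_s = time_s, output_pM = output_pM)
  class(tr) <- c("tgf_trace", class(tr))
  attr(tr, "status") <- status
  attr(tr, "unit") <- unit
  if (!is.null(states)) attr(tr, "states") <- states
  tr
}

#' Has a simulated trace integrated successfully?
#' @param trace A `"tgf_trace"`.
#' @return Logical.
#' @export
trace_succeeded <- function(trace) {
  identical(attr(trace, "status"), "succeeded")
}

#' Simulate the network under a ligand protocol
#'
#' Runs the two-phase protocol: (1) equilibration for 1 h at a near-zero
#' ligand concentration (1e-6 pM), starting from all receptor free and all
#' R-Smad/Co-Smad cytoplasmic and unphosphorylated; (2) stimulation under
#' `protocol` from the phase-1 endpoint. The returned trace is the nuclear
#' heterodimer concentration over the stimulation phase, in pM, sampled every
#' `dt_out` seconds.
#'
#' Integration uses `deSolve::lsoda()` (stiff, variable step/order) on the
#' compiled right-hand side, with relative tolerance 1e-8 and absolute
#' tolerance 1e-12 nM. Integration failures are caught and returned as a
#' trace flagged `"failed"`, never raised, so parameter screens can proceed
#' through pathological corners of parameter space.
#'
#' @param params A [parameter_set()] (or coercible object).
#' @param totals A [total_concentrations()].
#' @param protocol A `"tgf_protocol"`; also sets the default horizon.
#' @param duration_s Stimulation horizon in seconds (defaults to the
#'   protocol's duration; may be extended, e.g. to follow slow oscillations).
#' @param dt_out Output grid spacing in seconds (must be <= 60 so that the
#'   classifier sees a dense enough grid).
#' @param keep_states Keep the full state matrix (all 17 species, both
#'   phases' phase-2 part) as attribute `"states"` for conservation checks.
#' @param rtol,atol Solver tolerances.
#' @return A `"tgf_trace"`: tibble with columns `time_s`, `output_pM`, and
#'   attributes `status` (`"succeeded"` or `"failed"`) and optionally
#'   `states`.
#' @export
#' @examples
#' p <- fixture_parameter_sets()$sustained
#' tr <- simulate_tgf(p)
#' max(tr$output_pM)
simulate_tgf <- function(params, totals = total_concentrations(),
                         protocol = protocol_constant(),
                         duration_s = protocol$duration_s, dt_out = 60,
                         keep_states = FALSE, rtol = 1e-8, atol = 1e-12) {
  p <- tryCatch(as_parameter_set(params), error = function(e) NULL)
  if (is.null(p)) stop("invalid parameter set")
  stopifnot(inherits(protocol, "tgf_protocol"), dt_out > 0, dt_out <= 60)

  y0 <- initial_state(totals)
  eq <- integrate_phase(y0, times = c(0, 3600),
                        parms = p, protocol = protocol_equilibration(),
                        rtol = rtol, atol = atol)
  times <- seq(0, duration_s, by = dt_out)
  if (times[length(times)] < duration_s) times <- c(times, duration_s)
  if (is.null(eq)) {
    return(new_trace(times, rep(NA_real_, length(times)), status = "failed"))
  }
  out <- integrate_phase(eq[nrow(eq), species_names()], times = times,
                         parms = p, protocol = protocol,
                         rtol = rtol, atol = atol)
  if (is.null(out)) {
    return(new_trace(times, rep(NA_real_, length(times)), status = "failed"))
  }
  new_trace(out[, "time"], out[, "Hn"] * 1000,
            states = if (keep_states) out[, species_names(), drop = FALSE])
}

# One integration phase on the compiled model; NULL on any solver failure.
integrate_phase <- function(y0, times, parms, protocol, rtol, atol) {
  pv <- c(unclass(parms), protocol_parms(protocol))
  out <- tryCatch(
    withCallingHandlers(
      deSolve::lsoda(y = unname(y0), times = times, func = "tgf_derivs",
                     parms = unname(pv), dllname = "tgfscreen",
                     initfunc = "tgf_initmod", rtol = rtol, atol = atol,
                     maxsteps = 20000),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) NULL
  )
  if (is.null(out)) return(NULL)
  istate <- attr(out, "istate")
  if (nrow(out) < length(times) || (!is.null(istate) && istate[1] < 0) ||
      any(!is.finite(out))) {
    return(NULL)
  }
  colnames(out) <- c("time", species_names())
  out
}

#' Conserved pool totals along a simulated trajectory
#'
#' The model has no production or degradation of receptor, R-Smad or Co-Smad,
#' so three weighted sums of the state are exact invariants:
#' receptor `R + LR + LRa + LRaI`, R-Smad
#' `Sc + pSc + Sn + pSn + 2 (Dc + Dn) + (Hc + Hn)`, and Co-Smad
#' `Cc + Cn + Hc + Hn`. Checking them against the configured totals is the
#' standard integrity check on the integrator output.
#'
#' @param trace A trace from [simulate_tgf()] with `keep_states = TRUE`.
#' @return Tibble with columns `time_s`, `receptor_nM`, `rsmad_nM`,
#'   `cosmad_nM`.
#' @export
conserved_totals <- function(trace) {
  st <- attr(trace, "states")
  if (is.null(st)) stop("trace lacks full states; rerun with keep_states = TRUE")
  tibble::tibble(
    time_s = trace$time_s,
    receptor_nM = st[, "R"] + st[, "LR"] + st[, "LRa"] + st[, "LRaI"],
    rsmad_nM = st[, "Sc"] + st[, "pSc"] + st[, "Sn"] + st[, "pSn"] +
      2 * (st[, "Dc"] + st[, "Dn"]) + st[, "Hc"] + st[, "Hn"],
    cosmad_nM = st[, "Cc"] + st[, "Cn"] + st[, "Hc"] + st[, "Hn"]
  )
}

#' @export
print.tgf_trace <- function(x, ...) {
  cat(sprintf("<tgf_trace> %d points over %.2f h, status: %s\n",
              nrow(x), max(x$time_s) / 3600, attr(x, "status")))
  cat(sprintf("  peak output %.4g pM, final %.4g pM\n",
              suppressWarnings(max(x$output_pM)),
              x$output_pM[nrow(x)]))
  invisible(x)
}
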