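#' Ligand stimulation protocols
#'
#' The extracellular TGF-beta concentration is a boundary condition of the
#' model: it drives receptor binding but is never depleted. A protocol is a
#' piecewise ligand-concentration function of time, active during the
#' stimulation phase that follows the 1-hour low-ligand equilibration.
#'
#' `protocol_constant()` holds the ligand at a fixed concentration (default
#' 200 pM for 10 h, the reference stimulus). `protocol_triangle()` ramps the
#' ligand linearly from 0 up to a peak and back down to 0 (default 0 to
#' 720 pM over 5 h, back to 0 over the next 5 h), the time-varying input used
#' for the faithfulness analysis. `protocol_equilibration()` is the near-zero
#' stimulus (1e-6 pM) used internally for phase-1 equilibration.
#'
#' @param L_pM Constant ligand concentration (pM).
#' @param duration_h Length of the stimulation phase (hours).
#' @param peak_pM Peak of the triangular ramp (pM).
#' @param rise_h,fall_h Rise and fall time of the ramp (hours).
#' @return A list of class `"tgf_protocol"` with fields `type`, the shape
#'   parameters in nM/seconds, and `duration_s`.
#' @export
protocol_constant <- function(L_pM = 200, duration_h = 10) {
  stopifnot(L_pM >= 0, duration_h > 0)
  structure(list(type = "constant", L_nM = L_pM / 1000,
                 duration_s = duration_h * 3600),
            class = "tgf_protocol")
}

#' @rdname protocol_constant
#' @export
protocol_triangle <- function(peak_pM = 720, rise_h = 5, fall_h = 5) {
  stopifnot(peak_pM > 0, rise_h > 0, fall_h > 0)
  structure(list(type = "triangle", peak_nM = peak_pM / 1000,
                 rise_s = rise_h * 3600,
                 total_s = (rise_h + fall_h) * 3600,
                 duration_s = (rise_h + fall_h) * 3600),
            class = "tgf_protocol")
}

#' @rdname protocol_constant
#' @export
protocol_equilibration <- function(duration_h = 1) {
  protocol_constant(L_pM = 1e-6, duration_h = duration_h)
}

#' Evaluate a protocol's ligand concentration over time
#'
#' @param protocol A `"tgf_protocol"`.
#' @param t Time points (s) relative to stimulation onset.
#' @return Ligand concentration in pM at each time point.
#' @export
ligand_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "tgf_protocol"))
  if (protocol$type == "constant") {
    rep(protocol$L_nM * 1000, length(t))
  } else {
    up <- protocol$rise_s
    tot <- protocol$total_s
    L <- ifelse(t <= 0 | t >= tot, 0,
                ifelse(t <= up, protocol$peak_nM * t / up,
                       protocol$peak_nM * (1 - (t - up) / (tot - up))))
    L * 1000
  }
}

#' @export
print.tgf_protocol <- function(x, ...) {
  if (x$type == "constant") {
    cat(sprintf("<tgf_protocol> constant %g pM for %g h\n",
                x$L_nM * 1000, x$duration_s / 3600))
  } else {
    cat(sprintf("<tgf_protocol> triangular 0 -> %g pM over %g h -> 0 at %g h\n",
                x$peak_nM * 1000, x$rise_s / 3600, x$total_s / 3600))
  }
  invisible(x)
}

# protocol encoded into the tail of the compiled-model parameter vector
protocol_parms <- function(protocol) {
  if (protocol$type == "constant") {
    c(ptype = 0, pa = protocol$L_nM, pb = 0, pc = 0)
  } else {
    c(ptype = 1, pa = protocol$peak_nM, pb = protocol$rise_s,
      pc = protocol$total_s)
  }
}
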