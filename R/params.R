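#' Kinetic parameter set for the TGF-beta/Smad network
#'
#' Bundles the 19 mass-action rate constants of the network together with the
#' Hill coefficient of transcriptional activation into a validated named
#' vector. Units follow the internal convention of the package: concentrations
#' in nM, time in seconds, so bimolecular rates (`k2`, `k5`, `k7`, `k10`) are
#' in 1/(nM s), `k14` is in nM/s, `k15` in nM, and all remaining rates in 1/s.
#'
#' The rate constants are, in order: ligand-receptor unbinding (`k1`) and
#' binding (`k2`); receptor phosphorylation (`k3`) and dephosphorylation
#' (`k4`); I-Smad binding to (`k5`) and release from (`k6`) the active
#' receptor; receptor-catalysed R-Smad phosphorylation (`k7`); nuclear import
#' (`k8`) and export (`k9`) of monomeric Smad species; dimer formation
#' (`k10`) and dissociation (`k11`), shared by homo- and heteromeric
#' complexes; nuclear import of dimers (`k12`); nuclear R-Smad
#' dephosphorylation (`k13`); maximal I-Smad transcription rate (`k14`) and
#' its half-saturation constant (`k15`); I-Smad mRNA nuclear export (`k16`)
#' and cytoplasmic degradation (`k17`); translation (`k18`); and free I-Smad
#' degradation (`k19`).
#'
#' @param k1,k2,k3,k4,k5,k6,k7,k8,k9,k10,k11,k12,k13,k14,k15,k16,k17,k18,k19
#'   Kinetic rate constants (strictly positive, or zero to switch a reaction
#'   off in perturbation experiments).
#' @param h Hill coefficient of the transcriptional activation of the I-Smad
#'   gene by the nuclear heterodimer; `h >= 1`, default 2.
#' @return A named numeric vector of class `"tgf_params"` with elements
#'   `k1` ... `k19` and `h`.
#' @seealso [derived_features()], [sample_parameters()], [simulate_tgf()]
#' @export
#' @examples
#' p <- parameter_set(k1 = 1e-3, k2 = 1e-3, k3 = 1e-3, k4 = 1e-3,
#'                    k5 = 1e-2, k6 = 1e-4, k7 = 4e-4, k8 = 2.6e-3,
#'                    k9 = 5.6e-3, k10 = 1.8e-3, k11 = 1.6e-2, k12 = 1.5e-2,
#'                    k13 = 6.6e-3, k14 = 1e-3, k15 = 1, k16 = 1e-3,
#'                    k17 = 1e-4, k18 = 1e-2, k19 = 3e-4)
#' derived_features(p)
parameter_set <- function(k1, k2, k3, k4, k5, k6, k7, k8, k9, k10,
                          k11, k12, k13, k14, k15, k16, k17, k18, k19,
                          h = 2) {
  p <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
         k8 = k8, k9 = k9, k10 = k10, k11 = k11, k12 = k12, k13 = k13,
         k14 = k14, k15 = k15, k16 = k16, k17 = k17, k18 = k18, k19 = k19,
         h = h)
  validate_parameter_set(p)
}

#' Coerce a named vector, list or one-row data frame to a parameter set
#'
#' @param x Object carrying numeric entries named `k1` ... `k19` and
#'   optionally `h` (defaults to 2 when absent). Extra entries are ignored.
#' @return A `"tgf_params"` vector.
#' @export
as_parameter_set <- function(x) {
  if (inherits(x, "tgf_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x <- unlist(x[intersect(c(param_names(), "h"), names(x))])
  if (!("h" %in% names(x))) x <- c(x, h = 2)
  missing <- setdiff(param_names(), names(x))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  validate_parameter_set(x[c(param_names(), "h")])
}

param_names <- function() paste0("k", 1:19)

validate_parameter_set <- function(p) {
  stopifnot(is.numeric(p), length(p) == 20L,
            identical(names(p), c(param_names(), "h")))
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (any(p[param_names()] < 0)) stop("negative rate constant")
  if (p[["h"]] < 1) stop("Hill coefficient must be >= 1")
  structure(p, class = "tgf_params")
}

#' @export
print.tgf_params <- function(x, ...) {
  cat("<tgf_params> 19 rate constants + Hill coefficient\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Total cellular protein concentrations
#'
#' The receptor, R-Smad and Co-Smad pools are conserved quantities of the
#' model: no production or degradation reactions act on them, so their totals
#' are set directly as initial conditions. Defaults are 1 nM receptor, 60 nM
#' R-Smad and 100 nM Co-Smad.
#'
#' @param R_tot Total receptor concentration (nM).
#' @param S_tot Total R-Smad concentration (nM).
#' @param C_tot Total Co-Smad concentration (nM).
#' @return Named numeric vector of class `"tgf_totals"`.
#' @export
total_concentrations <- function(R_tot = 1, S_tot = 60, C_tot = 100) {
  stopifnot(R_tot > 0, S_tot > 0, C_tot > 0)
  structure(c(R_tot = R_tot, S_tot = S_tot, C_tot = C_tot),
            class = "tgf_totals")
}

#' Composite features of a parameter set
#'
#' Three scalar combinations of rate constants summarise the axes along which
#' response phenotypes segregate:
#' \describe{
#'   \item{feedback strength `F`}{`(k14 * k18) / (k15 * k17 * k19) * (k5 / k6)`,
#'     the gain of the I-Smad negative-feedback loop (production and stability
#'     of the inhibitor times its affinity for the active receptor).}
#'   \item{dephosphorylation speed `D`}{`k8 * (k11 * k13) / k10`, the rate at
#'     which nuclear phospho-R-Smad is returned to the inactive pool (import,
#'     dimer dissociation and dephosphorylation against re-dimerisation).}
#'   \item{I-Smad turnover `T`}{`k16 * k17 * k19`, the cycling speed of the
#'     inhibitor mRNA and protein.}
#' }
#'
#' @param params A parameter set, or a data frame with columns `k1` ... `k19`
#'   (e.g. a screen result table), in which case features are computed
#'   row-wise.
#' @return For a single parameter set, a named numeric vector with elements
#'   `F`, `D`, `T`; for a data frame, a tibble with columns `F`, `D`, `T`.
#' @export
derived_features <- function(params) {
  if (is.data.frame(params)) {
    return(tibble::tibble(
      F = (params$k14 * params$k18) / (params$k15 * params$k17 * params$k19) *
        (params$k5 / params$k6),
      D = params$k8 * (params$k11 * params$k13) / params$k10,
      T = params$k16 * params$k17 * params$k19
    ))
  }
  p <- as_parameter_set(params)
  c(F = unname((p["k14"] * p["k18"]) / (p["k15"] * p["k17"] * p["k19"]) *
                 (p["k5"] / p["k6"])),
    D = unname(p["k8"] * (p["k11"] * p["k13"]) / p["k10"]),
    T = unname(p["k16"] * p["k17"] * p["k19"]))
}
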