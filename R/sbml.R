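# Reaction table of the network: reactants/products/modifiers with
# stoichiometry, and the mass-action factors of each kinetic law.
network_reactions <- function() {
  r <- function(id, react, prod, rate, mod = character()) {
    list(id = id, reactants = react, products = prod, modifiers = mod,
         rate = rate)
  }
  list(
    r("r01_bind", c(L = 1, R = 1), c(LR = 1), c("k2", "L", "R")),
    r("r02_unbind", c(LR = 1), c(L = 1, R = 1), c("k1", "LR")),
    r("r03_activate", c(LR = 1), c(LRa = 1), c("k3", "LR")),
    r("r04_deactivate", c(LRa = 1), c(LR = 1), c("k4", "LRa")),
    r("r05_sequester", c(LRa = 1, I = 1), c(LRaI = 1), c("k5", "LRa", "I")),
    r("r06_release", c(LRaI = 1), c(LRa = 1, I = 1), c("k6", "LRaI")),
    r("r07_phosphorylate", c(Sc = 1), c(pSc = 1), c("k7", "LRa", "Sc"),
      mod = "LRa"),
    r("r08a_import_S", c(Sc = 1), c(Sn = 1), c("k8", "Sc")),
    r("r08b_import_pS", c(pSc = 1), c(pSn = 1), c("k8", "pSc")),
    r("r08c_import_C", c(Cc = 1), c(Cn = 1), c("k8", "Cc")),
    r("r09a_export_S", c(Sn = 1), c(Sc = 1), c("k9", "Sn")),
    r("r09b_export_pS", c(pSn = 1), c(pSc = 1), c("k9", "pSn")),
    r("r09c_export_C", c(Cn = 1), c(Cc = 1), c("k9", "Cn")),
    r("r10a_homodimer_cyt", c(pSc = 2), c(Dc = 1), c("k10", "pSc", "pSc")),
    r("r10b_heterodimer_cyt", c(pSc = 1, Cc = 1), c(Hc = 1),
      c("k10", "pSc", "Cc")),
    r("r10c_homodimer_nuc", c(pSn = 2), c(Dn = 1), c("k10", "pSn", "pSn")),
    r("r10d_heterodimer_nuc", c(pSn = 1, Cn = 1), c(Hn = 1),
      c("k10", "pSn", "Cn")),
    r("r11a_homodissoc_cyt", c(Dc = 1), c(pSc = 2), c("k11", "Dc")),
    r("r11b_heterodissoc_cyt", c(Hc = 1), c(pSc = 1, Cc = 1),
      c("k11", "Hc")),
    r("r11c_homodissoc_nuc", c(Dn = 1), c(pSn = 2), c("k11", "Dn")),
    r("r11d_heterodissoc_nuc", c(Hn = 1), c(pSn = 1, Cn = 1),
      c("k11", "Hn")),
    r("r12a_import_D", c(Dc = 1), c(Dn = 1), c("k12", "Dc")),
    r("r12b_import_H", c(Hc = 1), c(Hn = 1), c("k12", "Hc")),
    r("r13_dephosphorylate", c(pSn = 1), c(Sn = 1), c("k13", "pSn")),
    r("r14_transcription", c(), c(mn = 1), "hill", mod = "Hn"),
    r("r16_mrna_export", c(mn = 1), c(mc = 1), c("k16", "mn")),
    r("r17_mrna_degradation", c(mc = 1), c(), c("k17", "mc")),
    r("r18_translation", c(), c(I = 1), c("k18", "mc"), mod = "mc"),
    r("r19_ismad_degradation", c(I = 1), c(), c("k19", "I"))
  )
}

species_compartment <- function() {
  c(R = "cytoplasm", LR = "cytoplasm", LRa = "cytoplasm", LRaI = "cytoplasm",
    Sc = "cytoplasm", pSc = "cytoplasm", Cc = "cytoplasm", Dc = "cytoplasm",
    Hc = "cytoplasm", mc = "cytoplasm", I = "cytoplasm",
    Sn = "nucleus", pSn = "nucleus", Cn = "nucleus", Dn = "nucleus",
    Hn = "nucleus", mn = "nucleus", L = "extracellular")
}

mml_ci <- function(x) paste0("<ci> ", x, " </ci>")

mml_times <- function(factors) {
  paste0("<apply><times/>", paste(vapply(factors, mml_ci, ""),
                                  collapse = ""), "</apply>")
}

# k14 * Hn^h / (k15^h + Hn^h)
mml_hill <- function() {
  pw <- function(base) paste0("<apply><power/>", mml_ci(base), mml_ci("h"),
                              "</apply>")
  paste0("<apply><divide/><apply><times/>", mml_ci("k14"), pw("Hn"),
         "</apply><apply><plus/>", pw("k15"), pw("Hn"), "</apply></apply>")
}

#' Export the reaction network as SBML Level 2
#'
#' Writes the full network - compartments, species (the extracellular ligand
#' as a boundary species), global parameters `k1` ... `k19` and `h`, and all
#' reactions with mass-action or Hill kinetic laws - as an SBML Level 2
#' Version 4 document. Units follow the package convention (nM, seconds).
#'
#' @param params A [parameter_set()].
#' @param totals A [total_concentrations()] (sets initial amounts).
#' @param path Output path.
#' @param ligand_pM Boundary ligand concentration recorded in the file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(params, totals = total_concentrations(), path,
                        ligand_pM = 200) {
  p <- as_parameter_set(params)
  y0 <- c(initial_state(totals), L = ligand_pM / 1000)
  comp <- species_compartment()
  sp <- paste(vapply(names(comp), function(s) {
    sprintf(paste0('<species id="%s" compartment="%s" ',
                   'initialConcentration="%.15g"%s/>'),
            s, comp[[s]], y0[[s]],
            if (s == "L") ' boundaryCondition="true"' else "")
  }, ""), collapse = "\n        ")
  pars <- paste(vapply(names(p), function(k) {
    sprintf('<parameter id="%s" value="%.15g"/>', k, p[[k]])
  }, ""), collapse = "\n        ")
  rxn <- paste(vapply(network_reactions(), function(rx) {
    refs <- function(tag, v) {
      if (length(v) == 0) return("")
      inner <- paste(sprintf('<speciesReference species="%s" stoichiometry="%d"/>',
                             names(v), as.integer(v)), collapse = "")
      sprintf("<listOf%s>%s</listOf%s>", tag, inner, tag)
    }
    mods <- if (length(rx$modifiers) > 0) {
      sprintf("<listOfModifiers>%s</listOfModifiers>",
              paste(sprintf('<modifierSpeciesReference species="%s"/>',
                            rx$modifiers), collapse = ""))
    } else ""
    math <- if (identical(rx$rate, "hill")) mml_hill() else mml_times(rx$rate)
    sprintf(paste0('<reaction id="%s" reversible="false">%s%s%s',
                   '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
                   "%s</math></kineticLaw></reaction>"),
            rx$id, refs("Reactants", rx$reactants),
            refs("Products", rx$products), mods, math)
  }, ""), collapse = "\n        ")
  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="tgf_smad_feedback" name="TGF-beta/Smad network with I-Smad feedback">
    <listOfCompartments>
      <compartment id="extracellular" size="1"/>
      <compartment id="cytoplasm" size="1"/>
      <compartment id="nucleus" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
        %s
    </listOfSpecies>
    <listOfParameters>
        %s
    </listOfParameters>
    <listOfReactions>
        %s
    </listOfReactions>
  </model>
</sbml>', sp, pars, rxn)
  # parse/serialize through xml2 to guarantee well-formedness
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

#' Import parameter values and initial concentrations from an SBML file
#'
#' Reads the global parameters (`k1` ... `k19`, `h`) and species initial
#' concentrations from an SBML Level 2 document, e.g. one produced by
#' [export_sbml()] or an equivalent published model file. Only values are
#' imported; the reaction wiring of the document is not interpreted, so a
#' file whose network differs from the built-in one cannot be simulated.
#'
#' @param path Path to an SBML file.
#' @return List with `params` (a `"tgf_params"`), `totals` (a
#'   `"tgf_totals"` reconstructed from the initial concentrations), and
#'   `initial` (named vector of all initial concentrations).
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pv <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                        xml2::xml_attr(pars, "id"))
  sps <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sv <- stats::setNames(as.numeric(xml2::xml_attr(sps,
                                                  "initialConcentration")),
                        xml2::xml_attr(sps, "id"))
  sv[is.na(sv)] <- 0
  tot <- total_concentrations(
    R_tot = sum(sv[intersect(c("R", "LR", "LRa", "LRaI"), names(sv))]),
    S_tot = sum(sv[intersect(c("Sc", "pSc", "Sn", "pSn"), names(sv))]) +
      2 * sum(sv[intersect(c("Dc", "Dn"), names(sv))]) +
      sum(sv[intersect(c("Hc", "Hn"), names(sv))]),
    C_tot = sum(sv[intersect(c("Cc", "Cn", "Hc", "Hn"), names(sv))])
  )
  list(params = as_parameter_set(as.list(pv)), totals = tot, initial = sv)
}
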