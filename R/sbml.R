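#' Export the kinetic model as SBML Level 3
#'
#' Writes the continuous (CSTR-chain) form of the four-compartment model:
#' one SBML compartment per Golgi compartment, one species per (glycan,
#' compartment) pair, clamped donor species with
#' `boundaryCondition="true"`, the competing-substrate rate laws as
#' MathML kinetic laws, and first-order inter-compartment transport
#' reactions with rate constant `1/tau`.  The sequential-batch schedule
#' itself is not expressible as a plain ODE model, so the exported file
#' corresponds to `mode = "cstr"` of [simulate_golgi()].
#'
#' Requires the suggested package \pkg{xml2}.
#'
#' @param network A `"glyconet"`.
#' @param params A `"kinetic_params"`.
#' @param layout A `"golgi_layout"`.
#' @param file Output path.
#' @param ruleset Rule set used to build the network.
#' @return `file`, invisibly.
#' @export
export_sbml <- function(network, params, layout, file,
                        ruleset = default_ruleset()) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("package 'xml2' is required for SBML export", call. = FALSE)
  sp <- network$species
  ns <- length(sp)
  comps <- layout$compartments
  sid <- function(i, ci) sprintf("S%d_%s", i, comps[ci])
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x, fixed = TRUE),
                          fixed = TRUE)

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="oglycan_golgi" substanceUnits="micromole" timeUnits="minute">',
    '<listOfCompartments>')
  for (ci in seq_along(comps))
    lines <- c(lines, sprintf(
      '<compartment id="%s" spatialDimensions="3" size="%g" constant="true"/>',
      comps[ci], layout$volume))
  lines <- c(lines, '</listOfCompartments>', '<listOfSpecies>')
  for (ci in seq_along(comps))
    for (i in seq_len(ns)) {
      init <- if (sp[i] == network$root && ci == 1L) layout$initial_conc else 0
      lines <- c(lines, sprintf(
        paste0('<species id="%s" name="%s" compartment="%s" ',
               'initialConcentration="%g" hasOnlySubstanceUnits="false" ',
               'boundaryCondition="false" constant="false"/>'),
        sid(i, ci), esc(sp[i]), comps[ci], init))
    }
  for (d in rownames(layout$donors))
    for (ci in seq_along(comps))
      if (layout$donors[d, ci] > 0)
        lines <- c(lines, sprintf(
          paste0('<species id="%s_%s" name="%s" compartment="%s" ',
                 'initialConcentration="%g" hasOnlySubstanceUnits="false" ',
                 'boundaryCondition="true" constant="true"/>'),
          d, comps[ci], d, comps[ci], layout$donors[d, ci]))
  lines <- c(lines, '</listOfSpecies>', '<listOfReactions>')

  for (ci in seq_along(comps)) {
    tab <- .compartment_tables(network, params, layout, comps[ci], ruleset)
    if (tab$n > 0L) {
      # reaction j: v = a_j * S_sub / (1 + sum_k b_k * S_subk), constants folded
      a <- tab$B * tab$xcoef
      for (j in seq_len(tab$n)) {
        same <- which(tab$enz == tab$enz[j])
        denom_terms <- paste0(vapply(same, function(k) sprintf(
          '<apply><times/><cn>%.10g</cn><ci>%s</ci></apply>',
          tab$xcoef[k], sid(tab$sub[k], ci)), character(1)), collapse = "")
        math <- sprintf(paste0(
          '<math xmlns="http://www.w3.org/1998/Math/MathML">',
          '<apply><divide/>',
          '<apply><times/><cn>%.10g</cn><ci>%s</ci><ci>%s</ci></apply>',
          '<apply><plus/><cn>1</cn>%s</apply>',
          '</apply></math>'),
          a[j] / layout$volume, comps[ci], sid(tab$sub[j], ci), denom_terms)
        prod_j <- tab$prod[j]
        lines <- c(lines, sprintf(
          '<reaction id="R%d_%s" reversible="false">', j, comps[ci]),
          '<listOfReactants>',
          sprintf('<speciesReference species="%s" stoichiometry="1" constant="true"/>',
                  sid(tab$sub[j], ci)),
          '</listOfReactants>', '<listOfProducts>',
          sprintf('<speciesReference species="%s" stoichiometry="1" constant="true"/>',
                  sid(prod_j, ci)),
          '</listOfProducts>',
          paste0('<kineticLaw>', math, '</kineticLaw>'),
          '</reaction>')
      }
    }
    if (ci < length(comps))
      for (i in seq_len(ns))
        lines <- c(lines, sprintf(
          '<reaction id="T%d_%s" reversible="false">', i, comps[ci]),
          '<listOfReactants>',
          sprintf('<speciesReference species="%s" stoichiometry="1" constant="true"/>',
                  sid(i, ci)),
          '</listOfReactants>', '<listOfProducts>',
          sprintf('<speciesReference species="%s" stoichiometry="1" constant="true"/>',
                  sid(i, ci + 1L)),
          '</listOfProducts>', '<kineticLaw>',
          sprintf(paste0(
            '<math xmlns="http://www.w3.org/1998/Math/MathML">',
            '<apply><times/><cn>%.10g</cn><ci>%s</ci><ci>%s</ci></apply></math>'),
            1 / layout$tau, comps[ci], sid(i, ci)),
          '</kineticLaw>', '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>', '</model>', '</sbml>')
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))  # validates well-formedness
  xml2::write_xml(doc, file)
  invisible(file)
}
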