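# SBML Level 3 export/import of network models (xml2-based).
#
# Kinetic laws are emitted as explicit mass-action MathML
# (kf * prod(reactants) - kr * prod(products)); rate constants are stored as
# reaction-local parameters with full decimal precision so a write/read
# round trip reproduces them exactly in decimal-string form.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"

num_str <- function(x) sprintf("%.17g", x)

# internal: MathML for kf*prod(R) - kr*prod(P)
mass_action_mathml <- function(rx) {
  term <- function(k, side) {
    cis <- paste0("<ci> ", c(k, rep(names(side), side)), " </ci>", collapse = "")
    if (length(side)) paste0("<apply><times/>", cis, "</apply>")
    else paste0("<ci> ", k, " </ci>")
  }
  inner <- if (rx$kr > 0)
    paste0("<apply><minus/>", term("kf", rx$reactants), term("kr", rx$products),
           "</apply>")
  else term("kf", rx$reactants)
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', inner, "</math>")
}

#' Write a network model as SBML Level 3
#'
#' @param model A [network_model()].
#' @param file Output path (`.xml`).
#' @param model_id Identifier recorded in the SBML model element.
#' @return Invisibly, the file path.
#' @export
write_sbml <- function(model, file, model_id = "network") {
  sp <- model$species
  rx_xml <- vapply(model$reactions, function(rx) {
    side <- function(tag, s) {
      if (!length(s)) return("")
      paste0("<listOf", tag, "s>",
             paste0('<speciesReference species="', names(s),
                    '" stoichiometry="', as.integer(s), '" constant="true"/>',
                    collapse = ""),
             "</listOf", tag, "s>")
    }
    params <- paste0('<localParameter id="kf" value="', num_str(rx$kf), '"/>',
                     if (rx$kr > 0)
                       paste0('<localParameter id="kr" value="', num_str(rx$kr), '"/>')
                     else "")
    paste0('<reaction id="', rx$id, '" reversible="', tolower(rx$kr > 0), '">',
           side("Reactant", rx$reactants), side("Product", rx$products),
           "<kineticLaw>", mass_action_mathml(rx),
           "<listOfLocalParameters>", params, "</listOfLocalParameters>",
           "</kineticLaw></reaction>")
  }, "")
  sp_xml <- paste0('<species id="', sp$name, '" compartment="cell"',
                   ' initialConcentration="', vapply(sp$initial, num_str, ""), '"',
                   ' boundaryCondition="', tolower(sp$clamped), '"',
                   ' hasOnlySubstanceUnits="false" constant="false"',
                   ' sboTerm="SBO:0000247">',
                   "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\"><p>compartment_tag: ",
                   sp$compartment, "</p></body></notes></species>", collapse = "")
  doc_txt <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="', SBML_NS, '" level="3" version="2">',
    '<model id="', model_id, '" substanceUnits="micromole" timeUnits="second">',
    '<listOfCompartments><compartment id="cell" size="1" constant="true"/></listOfCompartments>',
    "<listOfSpecies>", sp_xml, "</listOfSpecies>",
    "<listOfReactions>", paste0(rx_xml, collapse = ""), "</listOfReactions>",
    "</model></sbml>")
  xml2::write_xml(xml2::read_xml(doc_txt), file)
  invisible(file)
}

#' Read an SBML file into a network model
#'
#' Accepts Level 3 (and Level 2) documents whose kinetic laws are the
#' mass-action form written by [write_sbml()] (local parameters `kf`, `kr`).
#' Conserved-moiety and cycle declarations are not part of SBML and are left
#' empty.
#'
#' @param file SBML path.
#' @return A [network_model()].
#' @export
read_sbml <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- lapply(sp_nodes, function(n) {
    tag <- xml2::xml_find_first(n, ".//*[local-name()='p']")
    comp <- if (!inherits(tag, "xml_missing")) {
      sub("^compartment_tag: ", "", xml2::xml_text(tag))
    } else "cytosol"
    species_def(
      xml2::xml_attr(n, "id"),
      compartment = if (comp %in% c("cytosol", "PSD", "input")) comp else "cytosol",
      initial = as.numeric(xml2::xml_attr(n, "initialConcentration")),
      clamped = identical(xml2::xml_attr(n, "boundaryCondition"), "true"))
  })
  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  reactions <- lapply(rx_nodes, function(n) {
    get_side <- function(tag) {
      refs <- xml2::xml_find_all(n, paste0(".//s:", tag, "/s:speciesReference"), ns)
      if (!length(refs)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      setNames(st, xml2::xml_attr(refs, "species"))
    }
    lp <- xml2::xml_find_all(n, ".//*[local-name()='localParameter']")
    vals <- setNames(as.numeric(xml2::xml_attr(lp, "value")), xml2::xml_attr(lp, "id"))
    reaction(xml2::xml_attr(n, "id"),
             get_side("listOfReactants"), get_side("listOfProducts"),
             kf = vals[["kf"]], kr = if ("kr" %in% names(vals)) vals[["kr"]] else 0)
  })
  network_model(species, reactions)
}
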