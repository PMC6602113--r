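# The reaction list of the network in SBML terms: id, reactants, products,
# modifier-free mass action with one rate constant each.
opf_sbml_reactions <- function() {
  list(
    list(id = "A1", k = "ka1",
         react = c("ERO_rr", "PDI_red"), prod = c("ERO_r1", "PDI_ox")),
    list(id = "A2", k = "ka2",
         react = c("ERO_r1", "PDI_red"), prod = c("ERO_act_ox", "PDI_ox")),
    list(id = "R2", k = "kox",
         react = c("ERO_act_ox", "PDI_red"),
         prod = c("ERO_act_red", "PDI_ox")),
    list(id = "R1", k = "k1",
         react = c("ERO_act_red", "O2"), prod = c("ERO_act_ox", "H2O2")),
    list(id = "G1", k = "kg",
         react = c("PDI_ox", "GSH"), prod = c("PDI_mix")),
    list(id = "G2", k = "kg",
         react = c("PDI_mix", "GSH"), prod = c("PDI_red", "GSSG")),
    list(id = "D1", k = "kdtt",
         react = c("ERO_rr", "DTT_red"), prod = c("ERO_r1", "DTT_ox")),
    list(id = "D2", k = "kdtt",
         react = c("ERO_r1", "DTT_red"), prod = c("ERO_act_ox", "DTT_ox")),
    list(id = "D3", k = "kdtt",
         react = c("ERO_act_ox", "DTT_red"),
         prod = c("ERO_act_red", "DTT_ox")))
}

#' Identifier mapping between this package and an SBML file
#'
#' [import_model_parameters()] needs to know which SBML identifiers hold
#' this package's rate constants and species.  The default maps every name
#' to itself (the convention [export_sbml()] writes).  For a deposited model
#' with different identifiers, supply a mapping with the foreign ids; this
#' mapping table is the designated adaptation point.
#'
#' @param constants named character vector: package constant name ->
#'   SBML parameter id.
#' @param species named character vector: package species name ->
#'   SBML species id.
#' @export
opf_sbml_mapping <- function(constants = stats::setNames(OPF_RATE_NAMES,
                                                         OPF_RATE_NAMES),
                             species = stats::setNames(OPF_SPECIES,
                                                       OPF_SPECIES)) {
  list(constants = constants, species = species)
}

#' Export the model to SBML
#'
#' Writes an SBML Level 2 document holding the species (with initial
#' concentrations in uM), the global rate constants and the mass-action
#' reaction list of the network.  Units are uM and seconds throughout.
#'
#' @param k an [opf_constants] object.
#' @param conditions an [opf_conditions] supplying initial concentrations.
#' @param path output path.
#' @export
export_sbml <- function(k = opf_constants(),
                        conditions = opf_conditions(), path) {
  k <- as_opf_constants(k)
  init <- conditions$init
  if (is.na(init[["O2"]])) init[["O2"]] <- k[["o2_sat"]]
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4",
    level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model", id = "opf_redox_network",
                               name = "Yeast oxidative protein folding")
  comp <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "cell", size = "1")
  sp <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in OPF_SPECIES)
    xml2::xml_add_child(sp, "species", id = s, compartment = "cell",
                        initialConcentration =
                          format(init[[s]], digits = 15),
                        substanceUnits = "uM")
  par <- xml2::xml_add_child(model, "listOfParameters")
  for (p in OPF_RATE_NAMES)
    xml2::xml_add_child(par, "parameter", id = p,
                        value = format(k[[p]], digits = 15),
                        units = if (p == "kdiff") "per_s"
                                else if (p == "o2_sat") "uM"
                                else "per_uM_per_s")
  rx <- xml2::xml_add_child(model, "listOfReactions")
  for (r in opf_sbml_reactions()) {
    rn <- xml2::xml_add_child(rx, "reaction", id = r$id, reversible = "false")
    lor <- xml2::xml_add_child(rn, "listOfReactants")
    for (s in r$react)
      xml2::xml_add_child(lor, "speciesReference", species = s,
                          stoichiometry = "1")
    lop <- xml2::xml_add_child(rn, "listOfProducts")
    for (s in r$prod)
      xml2::xml_add_child(lop, "speciesReference", species = s,
                          stoichiometry = "1")
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
      xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", r$k)
    for (s in r$react) xml2::xml_add_child(ap, "ci", s)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import rate constants and initial concentrations from an SBML file
#'
#' Reads global parameters and species initial concentrations from an SBML
#' document, translating foreign identifiers through `mapping` into this
#' package's naming and unit convention (uM, seconds).  Unmapped
#' package-side names must all resolve; identifiers present in the file but
#' not used are reported in the `unmapped` element.
#'
#' @param path SBML file path.
#' @param mapping an [opf_sbml_mapping()].
#' @return List with `constants` (an [opf_constants]), `initial` (named
#'   state vector, uM) and `unmapped` (foreign ids not consumed).
#' @export
import_model_parameters <- function(path, mapping = opf_sbml_mapping()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pnodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pids <- xml2::xml_attr(pnodes, "id")
  pvals <- as.numeric(xml2::xml_attr(pnodes, "value"))
  punits <- xml2::xml_attr(pnodes, "units")
  snodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sids <- xml2::xml_attr(snodes, "id")
  svals <- as.numeric(xml2::xml_attr(snodes, "initialConcentration"))
  sunits <- xml2::xml_attr(snodes, "substanceUnits")

  need <- mapping$constants
  missing <- need[!(need %in% pids)]
  if (length(missing))
    stop("SBML file lacks mapped parameter(s): ",
         paste(sprintf("%s (for %s)", missing, names(missing)),
               collapse = ", "), call. = FALSE)
  kvals <- pvals[match(need, pids)]
  names(kvals) <- names(need)
  ku <- punits[match(need, pids)]
  expected <- ifelse(names(need) == "kdiff", "per_s",
                     ifelse(names(need) == "o2_sat", "uM", "per_uM_per_s"))
  mismatch <- !is.na(ku) & ku != expected
  if (any(mismatch))
    stop(sprintf("unit mismatch for %s: file says '%s', expected '%s'",
                 names(need)[mismatch][1], ku[mismatch][1],
                 expected[mismatch][1]), call. = FALSE)

  sneed <- mapping$species
  smissing <- sneed[!(sneed %in% sids)]
  if (length(smissing))
    stop("SBML file lacks mapped species: ",
         paste(smissing, collapse = ", "), call. = FALSE)
  init <- svals[match(sneed, sids)]
  names(init) <- names(sneed)
  su <- sunits[match(sneed, sids)]
  badu <- !is.na(su) & su != "uM"
  if (any(badu))
    stop(sprintf("unit mismatch for species %s: file says '%s', expected 'uM'",
                 names(sneed)[badu][1], su[badu][1]), call. = FALSE)

  unmapped <- setdiff(c(pids, sids), c(need, sneed))
  list(constants = as_opf_constants(kvals), initial = init,
       unmapped = unmapped)
}
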