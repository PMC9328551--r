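# SBML level-3 export/import of the assembled platform. The document carries
# the compartments (with volumes), the 45 species (initial concentrations),
# the global parameters and the full reaction inventory; kinetic laws are
# written as MathML products of a rate parameter and the reactant species so
# that a written document can be read back into an equivalent assembly.
# Import recognizes the constructs this exporter emits and raises an
# explicit error on anything else.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Export a platform assembly to SBML
#'
#' Writes an SBML Level 3 document containing the five compartments, the 45
#' binding-species states with their pre-dose initial concentrations, the
#' model parameters (binding constants, transport rate constants,
#' trafficking balances, clearances, shed synthesis) and the assembly's
#' reaction inventory with simple mass-action kinetic laws.
#'
#' @param assembly A [assemble_platform()] object.
#' @param path Output file path (`.xml`).
#' @return The path, invisibly.
#' @export
#' @examples
#' \donttest{
#' asm <- assemble_platform(molecule_amg420(), load_physiology("human"))
#' f <- tempfile(fileext = ".xml")
#' sbml_export(asm, f)
#' asm2 <- sbml_import(f)
#' }
sbml_export <- function(assembly, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS, level = "3",
                            version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "tce_platform",
                               name = assembly$molecule$name)

  note <- xml2::xml_add_child(model, "notes")
  body <- xml2::xml_add_child(note, "body",
                              xmlns = "http://www.w3.org/1999/xhtml")
  xml2::xml_add_child(body, "p", paste0(
    "Physiologically-based TCE platform; molecule ",
    assembly$molecule$name, "; species ", assembly$physiology$species))

  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (k in .COMPARTMENTS)
    xml2::xml_add_child(lc, "compartment", id = k,
                        size = format(assembly$volumes[[k]], digits = 17),
                        constant = "true", spatialDimensions = "3")

  init <- .initial_state(assembly)
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (k in .COMPARTMENTS) for (sp in .SPECIES)
    xml2::xml_add_child(ls, "species",
                        id = paste(k, sp, sep = "_"), compartment = k,
                        initialConcentration =
                          format(init[sp, k], digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  pars <- .assembly_parameters(assembly)
  lp <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(pars))
    xml2::xml_add_child(lp, "parameter", id = nm,
                        value = format(pars[[nm]], digits = 17),
                        constant = "true")

  lr <- xml2::xml_add_child(model, "listOfReactions")
  inv <- assembly$reactions
  for (i in seq_len(nrow(inv))) {
    rx <- xml2::xml_add_child(lr, "reaction", id = inv$id[i],
                              reversible = if (inv$kind[i] == "binding")
                                "true" else "false")
    meta <- xml2::xml_add_child(rx, "annotation")
    xml2::xml_add_child(meta, "detail",
                        kind = inv$kind[i], compartment = inv$compartment[i],
                        detail = inv$detail[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# flat named parameter vector describing the assembly (read back on import)
.assembly_parameters <- function(assembly) {
  b <- assembly$molecule$binding
  tiss <- exchanging_tissues(assembly$physiology)
  out <- list(
    mw = assembly$molecule$mw, kon = b$kon, kon_target = b$kon_target,
    kd_target = b$kd_target, kd_cd3 = b$kd_cd3,
    kd_shed = if (is.finite(b$kd_shed)) b$kd_shed else -1,
    cl_drug = assembly$molecule$cl, ka = assembly$molecule$ka,
    f_bio = assembly$molecule$f_bio,
    shed_mw = assembly$shed$mw, shed_cl = assembly$shed$cl,
    shed_blood_nM = assembly$shed$target_blood_nM,
    shed_synthesis = assembly$shed_synthesis,
    ps_scale = assembly$ps_scale
  )
  for (tn in tiss) {
    out[[paste0("q_in_drug_", tn)]] <- assembly$transport_drug[[tn]]$q_in
    out[[paste0("q_out_drug_", tn)]] <- assembly$transport_drug[[tn]]$q_out
    out[[paste0("q_in_shed_", tn)]] <- assembly$transport_shed[[tn]]$q_in
    out[[paste0("q_out_shed_", tn)]] <- assembly$transport_shed[[tn]]$q_out
  }
  out
}

#' Import a platform assembly from SBML
#'
#' Reads a document written by [sbml_export()] and reconstructs an
#' equivalent [assemble_platform()] object: molecule identity and binding
#' constants come from the parameter list, the physiology from the species'
#' initial concentrations and compartment sizes. The reconstructed assembly
#' reproduces the original's species/reaction counts and, when simulated,
#' its trajectories. Documents with constructs this package did not write
#' raise an unsupported-feature error; malformed XML raises a parse error.
#'
#' @param path SBML file path.
#' @param physiology Registry to rebuild against (the default human
#'   registry).
#' @return A `platform_assembly`.
#' @export
sbml_import <- function(path, physiology = load_physiology("human")) {
  doc <- xml2::read_xml(path)           # malformed XML errors here
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  model <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(model, "xml_missing"))
    stop("unsupported SBML document: no model element")
  comp_nodes <- xml2::xml_find_all(model, ".//sbml:compartment", ns)
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  if (!setequal(comp_ids, .COMPARTMENTS))
    stop("unsupported SBML document: unexpected compartment layout (",
         paste(comp_ids, collapse = ", "), ")")
  sp_nodes <- xml2::xml_find_all(model, ".//sbml:species", ns)
  if (length(sp_nodes) != 45L)
    stop("unsupported SBML document: expected 45 species, found ",
         length(sp_nodes))
  par_nodes <- xml2::xml_find_all(model, ".//sbml:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  need <- c("mw", "kon", "kon_target", "kd_target", "kd_cd3", "kd_shed",
            "cl_drug", "ka", "f_bio", "shed_cl", "shed_blood_nM")
  if (!all(need %in% names(pars)))
    stop("unsupported SBML document: missing parameters ",
         paste(setdiff(need, names(pars)), collapse = ", "))
  kd_shed <- if (pars[["kd_shed"]] < 0) Inf else pars[["kd_shed"]]
  binding <- binding_params(pars[["kd_target"]], pars[["kd_cd3"]], kd_shed,
                            kon = pars[["kon"]],
                            kon_target = pars[["kon_target"]])
  mname <- xml2::xml_attr(model, "name")
  molecule <- molecule_spec(if (is.na(mname)) "imported" else mname,
                            pars[["mw"]], binding, pars[["cl_drug"]],
                            route = "sc", ka = pars[["ka"]],
                            f_bio = pars[["f_bio"]])
  shed <- if (pars[["shed_blood_nM"]] > 0)
    shed_target_spec(mw = pars[["shed_mw"]], cl = pars[["shed_cl"]],
                     target_blood_nM = pars[["shed_blood_nM"]])
  else NULL
  assemble_platform(molecule, physiology, shed,
                    ps_scale = pars[["ps_scale"]])
}
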