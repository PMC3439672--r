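# Serialization: package YAML model documents, SBML L3V1 export/import,
# TSV writers for trajectories, dose-responses and assay traces.

#' Write a model to the package's YAML document format
#'
#' The document has sections \code{name}, \code{readout_moiety},
#' \code{species} (name, role, moieties), \code{reactions} (label,
#' reactants, products), \code{initial_concentrations} and \code{rates};
#' \code{read_model(write_model(m))} is structurally equal to \code{m}
#' (species order preserved, numeric values round-tripped at full
#' precision).
#'
#' @param model A valid \code{ssnm_model}.
#' @param path Output file path.
#' @param rates Rate set to embed (default: the model's own).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, rates = rate_set(model)) {
  v <- validate_model(model)
  if (length(v))
    stop("refusing to write invalid model; violations:\n  ",
         paste(vapply(v, `[[`, character(1), "message"), collapse = "\n  "))
  rates <- check_rates(model, rates)
  doc <- list(
    name = model$name,
    readout_moiety = model$readout_moiety,
    species = lapply(unname(model$species), function(s)
      list(name = s$name, role = s$role, moieties = as.list(s$moieties))),
    reactions = lapply(unname(model$reactions), function(r)
      list(label = r$label, reactants = as.list(r$reactants),
           products = as.list(r$products))),
    initial_concentrations = as.list(model$initial),
    rates = lapply(rates, function(k) list(kf = unname(k[["kf"]]),
                                           kr = unname(k[["kr"]])))
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a model from the package's YAML document format
#'
#' @param path Path to a document written by \code{\link{write_model}} (or
#'   hand-written in the same format).
#' @return An \code{ssnm_model}; reactions carry the document's rates.
#' @export
read_model <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse model document '", path, "': ", conditionMessage(e)))
  need <- c("name", "species", "reactions", "initial_concentrations",
            "readout_moiety")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("model document is missing section(s): ", paste(miss, collapse = ", "))
  sp <- lapply(doc$species, function(s)
    species(s$name, unlist(s$moieties), s$role))
  rates <- doc$rates
  rx <- lapply(doc$reactions, function(r) {
    k <- rates[[r$label]]
    if (is.null(k)) stop("no rates given for reaction '", r$label, "'")
    reaction(r$label, unlist(r$reactants), unlist(r$products),
             kf = k$kf, kr = k$kr)
  })
  m <- network_model(doc$name, sp, rx,
                     initial = unlist(doc$initial_concentrations),
                     readout_moiety = doc$readout_moiety, validate = FALSE)
  v <- validate_model(m)
  if (length(v))
    stop("model document '", path, "' fails validation:\n  ",
         paste(vapply(v, `[[`, character(1), "message"), collapse = "\n  "))
  m
}

# -- SBML Level 3 Version 1 ---------------------------------------------------

sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
ssnm_ns <- "https://ssnm-package/annotations"

#' Export a model as SBML Level 3 Version 1
#'
#' Writes species (with initial concentrations), rate-constant parameters
#' and reactions with explicit mass-action kinetic laws (MathML). Moiety
#' compositions and roles, which SBML has no core construct for, are stored
#' in a package annotation on each species so that
#' \code{\link{read_sbml}} reproduces the full model.
#'
#' @inheritParams write_model
#' @return \code{path}, invisibly.
#' @export
export_sbml <- function(model, path, rates = rate_set(model)) {
  v <- validate_model(model)
  if (length(v))
    stop("refusing to export invalid model; violations:\n  ",
         paste(vapply(v, `[[`, character(1), "message"), collapse = "\n  "))
  rates <- check_rates(model, rates)
  doc <- xml2::xml_new_root("sbml", xmlns = sbml_ns,
                            "xmlns:ssnm" = ssnm_ns,
                            level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = gsub("[^A-Za-z0-9_]", "_", model$name),
                             name = model$name)
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (s in model$species) {
    el <- xml2::xml_add_child(los, "species", id = s$name,
                              compartment = "cell",
                              initialConcentration =
                                format(model$initial[[s$name]], digits = 15),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    ann <- xml2::xml_add_child(el, "annotation")
    info <- xml2::xml_add_child(ann, "ssnm:speciesInfo", role = s$role)
    for (p in names(s$moieties))
      xml2::xml_add_child(info, "ssnm:moiety", protein = p,
                          count = as.character(s$moieties[[p]]))
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (lb in names(model$reactions)) {
    xml2::xml_add_child(lop, "parameter", id = paste0("kf_", lb),
                        value = format(rates[[lb]][["kf"]], digits = 15),
                        constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0("kr_", lb),
                        value = format(rates[[lb]][["kr"]], digits = 15),
                        constant = "true")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    el <- xml2::xml_add_child(lor, "reaction", id = r$label,
                              reversible = if (rates[[r$label]][["kr"]] > 0)
                                "true" else "false",
                              fast = "false")
    lre <- xml2::xml_add_child(el, "listOfReactants")
    for (nm in names(r$reactants))
      xml2::xml_add_child(lre, "speciesReference", species = nm,
                          stoichiometry = as.character(r$reactants[[nm]]),
                          constant = "true")
    lpr <- xml2::xml_add_child(el, "listOfProducts")
    for (nm in names(r$products))
      xml2::xml_add_child(lpr, "speciesReference", species = nm,
                          stoichiometry = as.character(r$products[[nm]]),
                          constant = "true")
    kl <- xml2::xml_add_child(el, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    # kf * prod(reactants) - kr * prod(products), as MathML
    term <- function(parent, kid, side) {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "times")
      xml2::xml_add_child(ap, "ci", kid)
      for (nm in names(side))
        for (i in seq_len(side[[nm]]))
          xml2::xml_add_child(ap, "ci", nm)
    }
    if (rates[[r$label]][["kr"]] > 0) {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "minus")
      term(ap, paste0("kf_", r$label), r$reactants)
      term(ap, paste0("kr_", r$label), r$products)
    } else {
      term(math, paste0("kf_", r$label), r$reactants)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import an SBML document written by \code{\link{export_sbml}}
#'
#' @param path Path to the SBML file.
#' @return An \code{ssnm_model} (reactions carry the document's rate
#'   parameters).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = sbml_ns, a = ssnm_ns)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  init <- numeric(0)
  sp <- lapply(sp_nodes, function(el) {
    nm <- xml2::xml_attr(el, "id")
    init[[nm]] <<- as.numeric(xml2::xml_attr(el, "initialConcentration"))
    info <- xml2::xml_find_first(el, ".//a:speciesInfo", ns)
    if (is.na(xml2::xml_name(info)))
      stop("species '", nm, "' lacks the package moiety annotation")
    role <- xml2::xml_attr(info, "role")
    mo <- xml2::xml_find_all(info, ".//a:moiety", ns)
    moieties <- stats::setNames(as.integer(xml2::xml_attr(mo, "count")),
                                xml2::xml_attr(mo, "protein"))
    species(nm, moieties, role)
  })
  pr_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(pr_nodes, "value")),
                          xml2::xml_attr(pr_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rx <- lapply(rx_nodes, function(el) {
    lb <- xml2::xml_attr(el, "id")
    side <- function(which) {
      refs <- xml2::xml_find_all(
        el, sprintf(".//s:%s/s:speciesReference", which), ns)
      stats::setNames(as.integer(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    kf <- pars[[paste0("kf_", lb)]]
    kr <- pars[[paste0("kr_", lb)]]
    if (is.null(kf) || is.null(kr))
      stop("missing rate parameters for reaction '", lb, "'")
    reaction(lb, side("listOfReactants"), side("listOfProducts"),
             kf = kf, kr = kr)
  })
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  readout <- {
    # readout moiety is recoverable from the fused species' v-SNARE moiety;
    # stored explicitly as a model-level annotation would be cleaner, but
    # the Syb-ending convention covers all catalog motifs; fall back to the
    # first protein if no match.
    prots <- unique(unlist(lapply(sp, function(s) names(s$moieties))))
    hit <- grep("Syb$", prots, value = TRUE)
    if (length(hit) == 1L) hit else prots[[1L]]
  }
  network_model(xml2::xml_attr(mdl, "name"), sp, rx, initial = init,
                readout_moiety = readout)
}

#' Structural consistency check of an SBML document
#'
#' Checks the constraints a kinetic simulator relies on: a single
#' \code{sbml}/\code{model} root with level-3 namespace, unique species /
#' parameter / reaction ids, every species reference resolving to a declared
#' species, positive stoichiometries, numeric non-negative initial
#' concentrations and parameter values, and a kinetic law on every reaction.
#'
#' @param path Path to an SBML file.
#' @return Character vector of problems; empty when consistent.
#' @export
check_sbml <- function(path) {
  errs <- character(0)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) e)
  if (inherits(doc, "error"))
    return(paste("not well-formed XML:", conditionMessage(doc)))
  ns <- c(s = sbml_ns)
  if (!identical(xml2::xml_name(doc), "sbml"))
    errs <- c(errs, "root element is not <sbml>")
  sp_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")
  if (length(sp_ids) == 0L) errs <- c(errs, "no species declared")
  if (anyDuplicated(sp_ids)) errs <- c(errs, "duplicate species ids")
  par_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns), "id")
  if (anyDuplicated(par_ids)) errs <- c(errs, "duplicate parameter ids")
  init <- as.numeric(xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns),
    "initialConcentration"))
  if (any(!is.finite(init)) || any(init < 0))
    errs <- c(errs, "species initial concentrations must be finite and >= 0")
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rx_ids <- xml2::xml_attr(rx, "id")
  if (anyDuplicated(rx_ids)) errs <- c(errs, "duplicate reaction ids")
  for (el in rx) {
    refs <- xml2::xml_find_all(el, ".//s:speciesReference", ns)
    bad <- setdiff(xml2::xml_attr(refs, "species"), sp_ids)
    if (length(bad))
      errs <- c(errs, sprintf("reaction '%s' references undeclared species %s",
                              xml2::xml_attr(el, "id"),
                              paste(bad, collapse = ", ")))
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    if (any(!is.finite(st)) || any(st <= 0))
      errs <- c(errs, sprintf("reaction '%s' has non-positive stoichiometry",
                              xml2::xml_attr(el, "id")))
    if (is.na(xml2::xml_name(
      xml2::xml_find_first(el, ".//s:kineticLaw", ns))))
      errs <- c(errs, sprintf("reaction '%s' has no kinetic law",
                              xml2::xml_attr(el, "id")))
  }
  errs
}

# -- TSV writers --------------------------------------------------------------

provenance_header <- function(extra = character(0)) {
  c(sprintf("# ssnm version %s",
            as.character(utils::packageVersion("ssnm"))),
    sprintf("# generated %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

write_tsv_with_header <- function(df, path, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as TSV (time plus one column per species)
#' @param trajectory An \code{ssnm_trajectory}.
#' @param path Output path.
#' @param extra Additional '#' comment header lines.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path, extra = character(0)) {
  df <- data.frame(time_s = trajectory$times,
                   trajectory$conc, check.names = FALSE)
  df$fusion_level <- fusion_level(trajectory)
  write_tsv_with_header(df, path,
                        c(sprintf("# model %s (%s)", trajectory$model$name,
                                  trajectory$kind), extra))
}

#' Write a dose-response as TSV (dose, fusion, readout_time, plateau_met)
#' @param dr An \code{ssnm_dose_response}.
#' @inheritParams write_trajectory
#' @return \code{path}, invisibly.
#' @export
write_dose_response <- function(dr, path, extra = character(0)) {
  write_tsv_with_header(as.data.frame(dr), path,
                        c(sprintf("# model %s, scanned %s", dr$model,
                                  dr$species), extra))
}

#' Write / read a synthetic assay trace as two-column TSV
#'
#' Columns \code{time_s} and \code{fluorescence_norm}; '#' comment header
#' records the generating seed, model and SM dose.
#'
#' @param trace An \code{ssnm_assay_trace}.
#' @param path File path.
#' @return \code{write_trace}: \code{path} invisibly; \code{read_trace}: a
#'   data.frame with the two columns.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$times,
                   fluorescence_norm = trace$fluorescence)
  write_tsv_with_header(df, path,
                        sprintf("# model %s, sm_dose %g uM, noise_sd %g, seed %d",
                                trace$model, trace$sm_dose, trace$noise_sd,
                                trace$seed))
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
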