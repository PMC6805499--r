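#' Load a metabolic model
#'
#' Two dialects are supported: a compact JSON dialect (schema below) and an
#' SBML Level 3 + FBC v2 subset. The biomass objective must be identifiable
#' (FBC active objective / JSON `objective` field) or supplied via
#' `objective_id`. Exchange reactions are auto-flagged and O2 metabolites
#' auto-detected on load (see [metabolic_model()]).
#'
#' JSON schema:
#' \preformatted{
#' {id, metabolites:[{id,name,compartment,formula}],
#'  reactions:[{id,name,stoich:{met:coef},lb,ub,gene_association}],
#'  objective, o2_metabolites}
#' }
#'
#' @param path file path.
#' @param format `"json"` or `"sbml_fbc"`; default guessed from the file
#'   extension (`.json` vs `.xml`/`.sbml`).
#' @param objective_id optional override when the file declares no
#'   objective.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml_fbc"),
                       objective_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json"
              else "sbml_fbc"
  }
  switch(format,
         json = load_model_json(path, objective_id),
         sbml_fbc = load_model_sbml(path, objective_id))
}

#' Write a metabolic model
#'
#' Inverse of [load_model()]: `load_model(write_model(m, p), ...)` restores
#' the network topology, bounds and objective exactly, in both dialects.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"json"` or `"sbml_fbc"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml_fbc")) {
  format <- match.arg(format)
  switch(format,
         json = write_model_json(model, path),
         sbml_fbc = write_model_sbml(model, path))
  invisible(path)
}

load_model_json <- function(path, objective_id = NULL) {
  x <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("JSON parse failure in '", path, "': ",
                             conditionMessage(e))
  )
  for (field in c("id", "metabolites", "reactions")) {
    if (is.null(x[[field]])) {
      stop("model JSON '", path, "' lacks required field '", field, "'")
    }
  }
  mets <- lapply(x$metabolites, function(m) {
    metabolite(m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else
                 m$compartment,
               formula = m$formula)
  })
  rxns <- lapply(x$reactions, function(r) {
    st <- unlist(r$stoich)
    reaction(r$id, st, name = if (is.null(r$name)) r$id else r$name,
             lower_bound = r$lb, upper_bound = r$ub,
             gene_association = r$gene_association)
  })
  obj <- if (!is.null(objective_id)) objective_id else x$objective
  if (is.null(obj)) {
    stop("no objective declared in '", path,
         "' and no objective_id override given")
  }
  metabolic_model(x$id, mets, rxns, obj,
                  o2_metabolite_ids =
                    if (is.null(x$o2_metabolites)) NULL
                    else unlist(x$o2_metabolites))
}

write_model_json <- function(model, path) {
  x <- list(
    id = model$id,
    metabolites = lapply(unname(model$metabolites), function(m) {
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      out
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      out <- list(id = r$id, name = r$name,
                  stoich = as.list(r$stoichiometry),
                  lb = r$lower_bound, ub = r$upper_bound)
      if (!is.na(r$gene_association)) out$gene_association <-
          r$gene_association
      out
    }),
    objective = model$objective_id,
    o2_metabolites = as.list(model$o2_metabolite_ids)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# ---- SBML L3 + FBC v2 subset ------------------------------------------------

sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

num17 <- function(x) sprintf("%.17g", x)

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = sbml_ns, "xmlns:fbc" = fbc_ns,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "true")
  comps <- unique(vapply(model$metabolites, `[[`, character(1),
                         "compartment"))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    sp <- xml2::xml_add_child(ls, "species", id = paste0("M_", m$id),
                              name = m$name, compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false",
                              constant = "false")
    if (!is.na(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }
  # flux bounds as shared constant parameters, one per distinct value
  vals <- sort(unique(c(
    vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
    vapply(model$reactions, `[[`, numeric(1), "upper_bound"))))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)), num17(vals))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in vals) {
    xml2::xml_add_child(lp, "parameter", id = pid[[num17(v)]],
                        value = num17(v), constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", r$id), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = pid[[num17(r$lower_bound)]],
      "fbc:upperFluxBound" = pid[[num17(r$upper_bound)]]
    )
    st <- r$stoichiometry
    if (any(st < 0)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(st)[st < 0]) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = num17(-st[[m]]),
                            constant = "true")
      }
    }
    if (any(st > 0)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(st)[st > 0]) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = num17(st[[m]]),
                            constant = "true")
      }
    }
  }
  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model$objective_id),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
}

xp <- function(node, path) {
  # namespace-agnostic xpath helper
  xml2::xml_find_all(node, path)
}

strip_sid <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

load_model_sbml <- function(path, objective_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  mdl <- xp(doc, "//*[local-name()='model']")
  if (!length(mdl)) stop("SBML file '", path, "' has no <model> element")
  mdl <- mdl[[1]]
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- "model"

  sp <- xp(mdl, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- lapply(sp, function(s) {
    formula <- xml2::xml_attr(s, "chemicalFormula")
    metabolite(strip_sid(xml2::xml_attr(s, "id"), "M"),
               name = {
                 nm <- xml2::xml_attr(s, "name")
                 if (is.na(nm)) strip_sid(xml2::xml_attr(s, "id"), "M")
                 else nm
               },
               compartment = xml2::xml_attr(s, "compartment"),
               formula = if (is.na(formula)) NULL else formula)
  })

  pars <- xp(mdl,
             ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(
    as.numeric(xml2::xml_attr(pars, "value")),
    xml2::xml_attr(pars, "id"))

  rx <- xp(mdl,
           ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxns <- lapply(rx, function(r) {
    rid <- strip_sid(xml2::xml_attr(r, "id"), "R")
    sto <- numeric()
    for (sr in xp(r, ".//*[local-name()='listOfReactants']/*")) {
      m <- strip_sid(xml2::xml_attr(sr, "species"), "M")
      sto[m] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xp(r, ".//*[local-name()='listOfProducts']/*")) {
      m <- strip_sid(xml2::xml_attr(sr, "species"), "M")
      sto[m] <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lb_ref <- xml2::xml_attr(r, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(r, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(parval)) parval[[lb_ref]]
          else if (identical(xml2::xml_attr(r, "reversible"), "true")) -1000
          else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(parval)) parval[[ub_ref]]
          else 1000
    nm <- xml2::xml_attr(r, "name")
    reaction(rid, sto, name = if (is.na(nm)) rid else nm,
             lower_bound = lb, upper_bound = ub)
  })

  if (is.null(objective_id)) {
    fo <- xp(mdl, ".//*[local-name()='fluxObjective']")
    if (!length(fo)) {
      stop("SBML file '", path, "' declares no FBC objective and no ",
           "objective_id override was given")
    }
    objective_id <- strip_sid(xml2::xml_attr(fo[[1]], "reaction"), "R")
  }
  metabolic_model(model_id, mets, rxns, objective_id)
}
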