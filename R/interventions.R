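#' Construct an intervention set
#'
#' A named list of heterologous [reaction_def()]s plus a provenance note —
#' one entry of the design library.
#'
#' @param name set name token.
#' @param reactions list of [reaction_def()]s; ids must be unique within
#'   the set.
#' @param provenance free-text citation of the source design.
#' @return an object of class `intervention_set`.
#' @export
intervention_set <- function(name, reactions, provenance = "") {
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("intervention set '", name, "': duplicate reaction ids")
  }
  names(reactions) <- ids
  structure(list(name = name, reactions = reactions,
                 provenance = provenance),
            class = "intervention_set")
}

lib_met <- local({
  formulas <- c(
    actp_c = "C2H3O5P", ac_c = "C2H3O2", atp_c = "C10H12N5O13P3",
    adp_c = "C10H12N5O10P2", pi_c = "HO4P", coa_c = "C21H32N7O16P3S",
    accoa_c = "C23H34N7O17P3S", pyr_c = "C3H3O3", acald_c = "C2H4O",
    etoh_c = "C2H6O", co2_c = "CO2", nad_c = "C21H26N7O14P2",
    nadh_c = "C21H27N7O14P2", no3_c = "NO3", no2_c = "NO2", no_c = "NO",
    n2o_c = "N2O", q8_c = "C49H74O4", q8h2_c = "C49H76O4", h2o_c = "H2O",
    h_c = "H", h_p = "H", trdox_c = "C3H4OS2", trdrd_c = "C3H6OS2",
    dhor_S_c = "C5H6N2O4", orot_c = "C5H3N2O4", fum_c = "C4H2O4",
    succ_c = "C4H4O4", asp_L_c = "C4H6NO4", iasp_c = "C4H4NO4",
    gtp_c = "C10H12N5O14P3", ctp_c = "C9H12N3O14P3",
    utp_c = "C9H11N2O15P3", datp_c = "C10H12N5O12P3",
    dgtp_c = "C10H12N5O13P3", dctp_c = "C9H12N3O13P3",
    dutp_c = "C9H11N2O14P3", pppg9_c = "C34H38N4O4",
    ppp9_c = "C34H32N4O4"
  )
  comp <- stats::setNames(ifelse(grepl("_p$", names(formulas)), "p", "c"),
                          names(formulas))
  function(ids) {
    lapply(ids, function(i) {
      metabolite(i, compartment = comp[[i]], formula = formulas[[i]])
    })
  }
})

lib_rxn <- function(id, stoich, name, provenance, lb = 0, ub = 1000) {
  reaction_def(id, stoich, name = name, lower_bound = lb, upper_bound = ub,
               provenance = provenance,
               new_metabolites = lib_met(names(stoich)))
}

#' The built-in heterologous design library
#'
#' Reaction sets for anaerobic ATP generation and for O2-independent
#' biosynthesis of essential metabolites, covering both previously
#' published anaerobic *P. putida* designs and the consolidated
#' fermentation design (class I dihydroorotate dehydrogenase + class III
#' ribonucleotide-triphosphate reductase + acetate kinase):
#' \describe{
#'   \item{ACK}{acetate kinase (acetyl-phosphate + ADP <-> acetate + ATP),
#'     with phosphotransacetylase for hosts lacking the acetyl-phosphate
#'     node.}
#'   \item{NIKEL}{ACK plus pyruvate decarboxylase and alcohol
#'     dehydrogenase II (ethanologenic redox sink).}
#'   \item{NAR}{lumped dissimilatory nitrate reduction, quinol-coupled with
#'     2 H+ translocated per nitrate (assumption, documented).}
#'   \item{NIR_NOR}{lumped nitrite -> NO -> N2O denitrification steps.}
#'   \item{ELECTRODE}{generic exogenous electron sink re-oxidizing quinol
#'     and NADH (bioelectrochemical designs), bounded demand.}
#'   \item{DHODH_I}{class I dihydroorotate dehydrogenase, fumarate- and
#'     NAD+-coupled variants.}
#'   \item{RNR_III}{class III ribonucleotide-triphosphate reductase, one
#'     reaction per NTP, thioredoxin-coupled, with an NADH-driven
#'     thioredoxin recycling reaction for hosts lacking one.}
#'   \item{NADB_FUM}{fumarate-coupled l-aspartate oxidase
#'     (l-aspartate + fumarate -> iminoaspartate + succinate).}
#'   \item{HEMG_Q}{quinone-dependent protoporphyrinogen oxidase
#'     (HemG-type; the endogenous HemJ route may make it dispensable).}
#' }
#' Stoichiometries follow the named biochemistry with standard metabolite
#' formulas and are elementally balanced for C, N, O, P and S (protons and
#' charge are host-model-specific and not balanced here); thioredoxin uses
#' a small pseudo-formula placeholder. All definitions are user-overridable
#' — the library is plain data.
#'
#' @return named list of [intervention_set()]s.
#' @export
builtin_designs <- function() {
  ackr <- lib_rxn("ACKr", c(actp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
                  "acetate kinase",
                  "E. coli ackA; prior anaerobic engineering designs",
                  lb = -1000)
  ptar <- lib_rxn("PTAr", c(accoa_c = -1, pi_c = -1, actp_c = 1, coa_c = 1),
                  "phosphotransacetylase",
                  "host coupling for the acetyl-phosphate node", lb = -1000)
  list(
    ACK = intervention_set("ACK", list(ackr, ptar),
      provenance = "acetate kinase route for anaerobic substrate-level ATP"),
    NIKEL = intervention_set("NIKEL", list(
      ackr, ptar,
      lib_rxn("PDC", c(pyr_c = -1, acald_c = 1, co2_c = 1),
              "pyruvate decarboxylase",
              "Z. mobilis pdc; ethanologenic P. putida design"),
      lib_rxn("ADHII", c(acald_c = -1, nadh_c = -1, etoh_c = 1, nad_c = 1),
              "alcohol dehydrogenase II",
              "Z. mobilis adhB; ethanologenic P. putida design")),
      provenance = "acetate kinase + ethanologenic redox sink design"),
    NAR = intervention_set("NAR", list(
      lib_rxn("NARlump",
              c(no3_c = -1, q8h2_c = -1, h_c = -2, no2_c = 1, q8_c = 1,
                h2o_c = 1, h_p = 2),
              "nitrate reductase (lumped, quinol-coupled)",
              "dissimilatory nitrate respiration designs; 2 H+/NO3- translocation assumed")),
      provenance = "anaerobic nitrate respiration machinery"),
    NIR_NOR = intervention_set("NIR_NOR", list(
      lib_rxn("NIRlump",
              c(no2_c = -1, q8h2_c = -0.5, no_c = 1, q8_c = 0.5,
                h2o_c = 1),
              "nitrite reductase (lumped)",
              "denitrification pathway designs"),
      lib_rxn("NORlump",
              c(no_c = -2, q8h2_c = -1, n2o_c = 1, q8_c = 1, h2o_c = 1),
              "nitric oxide reductase (lumped)",
              "denitrification pathway designs")),
      provenance = "nitrite/NO reduction steps of denitrification"),
    ELECTRODE = intervention_set("ELECTRODE", list(
      lib_rxn("ELECTRODE_Q", c(q8h2_c = -1, q8_c = 1),
              "exogenous electron sink (quinol re-oxidation)",
              "bioelectrochemical electron-sink designs"),
      lib_rxn("ELECTRODE_NADH", c(nadh_c = -1, nad_c = 1),
              "exogenous electron sink (NADH re-oxidation)",
              "bioelectrochemical electron-sink designs")),
      provenance = "generic anode/mediator electron sink, bounded demand"),
    DHODH_I = intervention_set("DHODH_I", list(
      lib_rxn("DHODH_FUM",
              c(dhor_S_c = -1, fum_c = -1, orot_c = 1, succ_c = 1),
              "class I dihydroorotate dehydrogenase (fumarate)",
              "L. lactis pyrK-pyrD B"),
      lib_rxn("DHODH_NAD",
              c(dhor_S_c = -1, nad_c = -1, orot_c = 1, nadh_c = 1),
              "class I dihydroorotate dehydrogenase (NAD+)",
              "L. lactis pyrK-pyrD B")),
      provenance = "quinone-independent dihydroorotate oxidation"),
    RNR_III = intervention_set("RNR_III", c(
      lapply(c(a = "atp_c", g = "gtp_c", c = "ctp_c", u = "utp_c"),
             function(ntp) {
               dntp <- paste0("d", ntp)
               st <- stats::setNames(c(-1, -1, 1, 1, 1),
                                     c(ntp, "trdrd_c", dntp, "trdox_c",
                                       "h2o_c"))
               lib_rxn(paste0("RNR3_", toupper(substr(ntp, 1, 1))), st,
                       paste0("class III ribonucleotide reductase (",
                              toupper(substr(ntp, 1, 1)), "TP)"),
                       "L. lactis nrdD-nrdG")
             }),
      list(lib_rxn("TRDR_NADH",
                   c(trdox_c = -1, nadh_c = -1, trdrd_c = 1, nad_c = 1),
                   "thioredoxin reductase (NADH)",
                   "host coupling for thioredoxin recycling"))),
      provenance = "O2-independent dNTP formation"),
    NADB_FUM = intervention_set("NADB_FUM", list(
      lib_rxn("NADB_FUM",
              c(asp_L_c = -1, fum_c = -1, iasp_c = 1, succ_c = 1),
              "l-aspartate oxidase (fumarate-coupled)",
              "E. coli nadB, fumarate as electron acceptor")),
      provenance = "O2-independent NAD+ precursor synthesis"),
    HEMG_Q = intervention_set("HEMG_Q", list(
      lib_rxn("HEMG_Q",
              c(pppg9_c = -1, q8_c = -3, ppp9_c = 1, q8h2_c = 3),
              "protoporphyrinogen oxidase (quinone-dependent)",
              "HemG-type enzyme; endogenous HemJ may substitute")),
      provenance = "O2-independent protoporphyrin IX formation")
  )
}

#' Read / write a design library as JSON
#'
#' The library file uses the same schema as the model JSON dialect's
#' reactions, grouped into named sets with provenance and optional
#' metabolite declarations — so new designs can be added without touching
#' code. The shipped copy of [builtin_designs()] lives at
#' `system.file("extdata", "design_library.json", package =
#' "anaerodesign")`.
#'
#' @param path JSON file path.
#' @return `load_design_library()`: named list of [intervention_set()]s.
#' @export
load_design_library <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(x, function(set) {
    intervention_set(
      set$name,
      lapply(set$reactions, function(r) {
        reaction_def(r$id, unlist(r$stoich), name = r$name,
                     lower_bound = r$lb, upper_bound = r$ub,
                     provenance = r$provenance,
                     new_metabolites = lapply(r$new_metabolites,
                                              function(m) {
                       metabolite(m$id, name = m$name,
                                  compartment = m$compartment,
                                  formula = m$formula)
                     }))
      }),
      provenance = set$provenance)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' @rdname load_design_library
#' @param sets named list of [intervention_set()]s.
#' @return `write_design_library()`: `path`, invisibly.
#' @export
write_design_library <- function(sets, path) {
  x <- lapply(unname(sets), function(set) {
    list(name = set$name, provenance = set$provenance,
         reactions = lapply(unname(set$reactions), function(r) {
           list(id = r$id, name = r$name,
                stoich = as.list(r$stoichiometry),
                lb = r$lower_bound, ub = r$upper_bound,
                provenance = r$provenance,
                new_metabolites = lapply(r$new_metabolites, function(m) {
                  list(id = m$id, name = m$name,
                       compartment = m$compartment,
                       formula = if (is.na(m$formula)) NULL else m$formula)
                }))
         }))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Apply an intervention set to a model
#'
#' Adds the set's reactions via [add_reactions()]. Definitions whose id the
#' host already carries are skipped (the library ships host-coupling
#' reactions, e.g. phosphotransacetylase, that many hosts have natively).
#'
#' @param model a `metabolic_model`.
#' @param set an [intervention_set()].
#' @param quiet suppress per-addition messages.
#' @return the expanded model.
#' @export
apply_intervention <- function(model, set, quiet = TRUE) {
  stopifnot(inherits(set, "intervention_set"))
  todo <- set$reactions[!vapply(set$reactions, function(r) {
    r$id %in% names(model$reactions)
  }, logical(1))]
  add_reactions(model, todo, quiet = quiet)
}

#' Classify a growth rate against a wild-type reference
#'
#' Half-open intervals: `mu < epsilon` is `"none"`; `epsilon <= mu <
#' poor_fraction * mu_ref` is `"poor"`; `mu >= poor_fraction * mu_ref` is
#' `"growth"`. So `mu = epsilon` classifies as poor and
#' `mu = poor_fraction * mu_ref` as growth.
#'
#' @param mu predicted growth rate(s), h^-1.
#' @param mu_ref wild-type reference growth rate (oxic), h^-1.
#' @param epsilon growth threshold.
#' @param poor_fraction fraction of `mu_ref` separating poor growth from
#'   growth (default 0.10).
#' @return character vector in `{"none", "poor", "growth"}`.
#' @export
classify_growth <- function(mu, mu_ref, epsilon = GROWTH_EPSILON,
                            poor_fraction = 0.10) {
  ifelse(mu < epsilon, "none",
         ifelse(mu < poor_fraction * mu_ref, "poor", "growth"))
}

#' Evaluate design combinations across media conditions
#'
#' Reproduces the design grid: for every combination of intervention sets
#' and every condition, expands the model, applies the medium, runs FBA and
#' classifies the predicted growth rate against the wild-type reference.
#' Every cell is reproducible by manual
#' `apply_intervention -> apply_medium -> fba` calls.
#'
#' @param model the host `metabolic_model`.
#' @param combos list of character vectors of design names (an empty vector
#'   is the wild type); list names become row labels, defaulting to the
#'   names joined with `"+"`.
#' @param conditions list of [medium_spec()]s (columns).
#' @param designs named list of [intervention_set()]s the combo names
#'   resolve against; defaults to [builtin_designs()]. Unknown names are an
#'   error before any solve.
#' @param ref_medium medium for the wild-type reference run (default: the
#'   first condition's base model without overlay, i.e. the model as
#'   given).
#' @param epsilon,poor_fraction classification parameters, see
#'   [classify_growth()].
#' @return a `design_grid` data.frame with columns `combo`, `condition`,
#'   `status`, `mu`, `growth_class`; `attr(, "mu_ref")` holds the
#'   reference growth rate.
#' @export
evaluate_designs <- function(model, combos, conditions,
                             designs = builtin_designs(),
                             ref_medium = NULL,
                             epsilon = GROWTH_EPSILON,
                             poor_fraction = 0.10) {
  if (inherits(conditions, "medium_spec")) conditions <- list(conditions)
  unknown <- setdiff(unique(unlist(combos)), names(designs))
  if (length(unknown)) {
    stop("unknown design name(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(names(combos))) names(combos) <- rep("", length(combos))
  labels <- ifelse(nzchar(names(combos)), names(combos),
                   vapply(combos, function(cc) {
                     if (!length(cc)) "wild_type"
                     else paste(cc, collapse = "+")
                   }, character(1)))
  ref <- if (is.null(ref_medium)) fba(model)
         else fba(apply_medium(model, ref_medium))
  rows <- list()
  for (i in seq_along(combos)) {
    expanded <- Reduce(function(m, nm) apply_intervention(m, designs[[nm]]),
                       combos[[i]], init = model)
    for (cond in conditions) {
      res <- fba(apply_medium(expanded, cond))
      rows[[length(rows) + 1L]] <- data.frame(
        combo = labels[[i]], condition = cond$name, status = res$status,
        mu = res$mu,
        growth_class = classify_growth(res$mu, ref$mu, epsilon,
                                       poor_fraction),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "mu_ref") <- ref$mu
  attr(out, "epsilon") <- epsilon
  attr(out, "poor_fraction") <- poor_fraction
  class(out) <- c("design_grid", class(out))
  out
}

#' Write a design grid as TSV
#' @param grid a `design_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
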