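#' Construct a metabolite
#'
#' Metabolites are the nodes of the stoichiometric network. The compartment
#' token matters for exchange-reaction detection: single-metabolite reactions
#' touching an extracellular metabolite are flagged as exchanges.
#'
#' @param id unique metabolite identifier (token).
#' @param name free-text name; defaults to `id`.
#' @param compartment compartment token, e.g. `"c"` (cytosol) or `"e"`
#'   (extracellular). Must be non-empty.
#' @param formula optional elemental composition string, e.g. `"C6H12O6"`.
#' @return an object of class `metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!nzchar(compartment)) {
    stop("metabolite '", id, "': compartment must be non-empty")
  }
  structure(
    list(id = id, name = name, compartment = compartment,
         formula = if (is.null(formula)) NA_character_ else formula),
    class = "metabolite"
  )
}

#' Construct a reaction
#'
#' Stoichiometry maps metabolite ids to signed coefficients (negative =
#' consumed). Bounds are in mmol/(gdw h). An exchange reaction must touch
#' exactly one metabolite; its lower bound encodes the maximal uptake rate
#' (uptake is negative flux, secretion positive).
#'
#' @param id unique reaction identifier.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param name free-text name; defaults to `id`.
#' @param lower_bound,upper_bound flux bounds, `lower_bound <= upper_bound`.
#' @param gene_association optional boolean gene-association string (stored,
#'   never evaluated).
#' @param is_exchange,is_transport flags; `NA` means "detect automatically"
#'   when the reaction is placed in a model.
#' @return an object of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, name = id,
                     lower_bound = -1000, upper_bound = 1000,
                     gene_association = NULL,
                     is_exchange = NA, is_transport = NA) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  structure(
    list(id = id, name = name,
         stoichiometry = stoichiometry[order(names(stoichiometry))],
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         gene_association = if (is.null(gene_association)) NA_character_
                            else gene_association,
         is_exchange = is_exchange, is_transport = is_transport),
    class = "reaction"
  )
}

#' Construct a heterologous reaction definition
#'
#' A `reaction_def` is a reaction plus provenance (free-text citation of the
#' source design) and, optionally, declarations of metabolites the host model
#' may lack. Used by the intervention library and [add_reactions()].
#'
#' @inheritParams reaction
#' @param provenance free-text note naming the design the reaction comes
#'   from; must be non-empty for shipped library entries.
#' @param new_metabolites optional list of [metabolite()] objects declared
#'   alongside the reaction (added to the host model if absent).
#' @return an object of class `reaction_def` (also inherits `reaction`).
#' @export
reaction_def <- function(id, stoichiometry, name = id,
                         lower_bound = -1000, upper_bound = 1000,
                         provenance = "", new_metabolites = list()) {
  r <- reaction(id, stoichiometry, name = name,
                lower_bound = lower_bound, upper_bound = upper_bound)
  r$provenance <- provenance
  r$new_metabolites <- new_metabolites
  class(r) <- c("reaction_def", "reaction")
  r
}

extracellular_tokens <- c("e", "e0", "ext", "extracellular", "external")

o2_id_pattern <- "^(M_)?o2(_[a-z0-9]+)?$"

#' Assemble and validate a metabolic model
#'
#' Checks referential integrity, auto-flags exchange reactions
#' (single-metabolite reactions in an extracellular compartment) and
#' auto-detects molecular-oxygen metabolites by elemental formula `"O2"`,
#' falling back to common id patterns (`o2`, `o2_e`, ...) when formulas are
#' absent.
#'
#' @param id model identifier.
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the biomass (objective) reaction.
#' @param o2_metabolite_ids optional explicit character vector of oxygen
#'   metabolite ids, overriding auto-detection.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective_id,
                            o2_metabolite_ids = NULL) {
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  if (!objective_id %in% rxn_ids) {
    stop("objective reaction '", objective_id, "' not found in model")
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  comp <- vapply(metabolites, `[[`, character(1), "compartment")
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing)) {
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    if (is.na(r$is_exchange)) {
      reactions[[i]]$is_exchange <-
        length(r$stoichiometry) == 1L &&
        tolower(comp[[names(r$stoichiometry)]]) %in% extracellular_tokens
    }
    if (is.na(r$is_transport)) {
      comps <- unique(tolower(comp[names(r$stoichiometry)]))
      reactions[[i]]$is_transport <-
        !reactions[[i]]$is_exchange && length(comps) > 1L
    }
  }
  if (is.null(o2_metabolite_ids)) {
    formulas <- vapply(metabolites, `[[`, character(1), "formula")
    o2_metabolite_ids <- met_ids[!is.na(formulas) & formulas == "O2"]
    if (!length(o2_metabolite_ids)) {
      o2_metabolite_ids <- met_ids[grepl(o2_id_pattern, met_ids,
                                         ignore.case = TRUE)]
    }
  } else if (!all(o2_metabolite_ids %in% met_ids)) {
    stop("o2_metabolite_ids not all present in model")
  }
  structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective_id = objective_id,
         o2_metabolite_ids = as.character(o2_metabolite_ids)),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n",
      " metabolites:", length(x$metabolites), "\n",
      " reactions:  ", length(x$reactions),
      sprintf("(%d exchange)", sum(vapply(x$reactions, `[[`, logical(1),
                                          "is_exchange"))), "\n",
      " objective:  ", x$objective_id, "\n",
      " O2 species: ", paste(x$o2_metabolite_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return a dense numeric matrix S (metabolites x reactions); `S[i, j]` is
#'   the coefficient of metabolite i in reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Reaction ids of exchange reactions
#' @param model a `metabolic_model`.
#' @return character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  ids <- names(model$reactions)
  ids[vapply(model$reactions, `[[`, logical(1), "is_exchange")]
}

#' Exchange reactions carrying molecular oxygen
#' @param model a `metabolic_model`.
#' @return character vector of exchange reaction ids whose metabolite is an
#'   O2 species.
#' @export
o2_exchange_reactions <- function(model) {
  ex <- exchange_reactions(model)
  ex[vapply(model$reactions[ex], function(r) {
    names(r$stoichiometry) %in% model$o2_metabolite_ids
  }, logical(1))]
}

# ---- media ------------------------------------------------------------------

#' Define a growth medium
#'
#' A medium is a named mapping of exchange-reaction ids to maximal uptake
#' rates (mmol/(gdw h), all non-negative). `default_uptake` applies to
#' exchanges not listed: `0` closes them for uptake; `NA` leaves them
#' untouched, which turns the medium into an *overlay* (used for the
#' oxic/anoxic oxygen switches).
#'
#' @param name medium name token.
#' @param uptake_limits named numeric vector, exchange id -> max uptake.
#' @param default_uptake uptake limit for unlisted exchanges (`0` = closed,
#'   `NA` = leave unchanged).
#' @return an object of class `medium_spec`.
#' @export
medium_spec <- function(name, uptake_limits = numeric(), default_uptake = 0) {
  if (length(uptake_limits) &&
      (is.null(names(uptake_limits)) || any(uptake_limits < 0))) {
    stop("uptake_limits must be named and non-negative")
  }
  structure(list(name = name, uptake_limits = uptake_limits,
                 default_uptake = default_uptake),
            class = "medium_spec")
}

minimal_medium_components <- c(
  "copper", "cobalt", "iron", "proton", "water", "sodium", "nickel",
  "ammonia", "ammonium", "phosphate", "sulphate", "sulfate", "nitrate"
)

#' Built-in medium presets
#'
#' Four presets, resolved against a concrete model because compound
#' identifiers differ between reconstructions:
#' \describe{
#'   \item{minimal_glucose}{glucose uptake at most 6.14 mmol/(gdw h)
#'     (experimentally measured rate); copper, cobalt, iron, protons, water,
#'     sodium, nickel, ammonia, phosphate, sulphate and nitrate effectively
#'     unlimited (1000 mmol/(gdw h)); every other exchange closed for
#'     uptake. Oxygen is governed separately by the oxic/anoxic overlay.}
#'   \item{rich}{every exchange except oxygen open for uptake at
#'     1000 mmol/(gdw h).}
#'   \item{oxic}{overlay setting the O2 exchange uptake to at most
#'     18.5 mmol/(gdw h).}
#'   \item{anoxic}{overlay closing the O2 exchange (uptake 0).}
#' }
#' Component matching is by metabolite name/formula and is overridable via
#' `extra_limits` (merged last, so explicit entries win).
#'
#' @param name one of `"minimal_glucose"`, `"rich"`, `"oxic"`, `"anoxic"`.
#' @param model the model the preset is resolved against.
#' @param extra_limits named numeric vector of exchange-id -> uptake
#'   overrides merged into the preset.
#' @return a [medium_spec()].
#' @export
medium_preset <- function(name, model, extra_limits = numeric()) {
  name <- match.arg(name, c("minimal_glucose", "rich", "oxic", "anoxic"))
  ex <- exchange_reactions(model)
  o2_ex <- o2_exchange_reactions(model)
  met_of <- vapply(model$reactions[ex],
                   function(r) names(r$stoichiometry), character(1))
  met_names <- tolower(vapply(model$metabolites[met_of], `[[`,
                              character(1), "name"))
  lim <- switch(name,
    minimal_glucose = {
      is_glc <- grepl("glucose", met_names) |
        tolower(met_of) %in% c("glc", "glc_e", "glc__d_e", "glc_d_e")
      is_min <- Reduce(`|`, lapply(minimal_medium_components,
                                   function(p) grepl(p, met_names)))
      u <- c(stats::setNames(rep(6.14, sum(is_glc)), ex[is_glc]),
             stats::setNames(rep(1000, sum(is_min)), ex[is_min]))
      medium_spec("minimal_glucose", u, default_uptake = 0)
    },
    rich = {
      open <- setdiff(ex, o2_ex)
      medium_spec("rich", stats::setNames(rep(1000, length(open)), open),
                  default_uptake = 0)
    },
    oxic = medium_spec("oxic",
                       stats::setNames(rep(18.5, length(o2_ex)), o2_ex),
                       default_uptake = NA_real_),
    anoxic = medium_spec("anoxic",
                         stats::setNames(rep(0, length(o2_ex)), o2_ex),
                         default_uptake = NA_real_)
  )
  if (length(extra_limits)) {
    lim$uptake_limits[names(extra_limits)] <- extra_limits
  }
  lim
}

#' Apply a medium to a model
#'
#' Sets the uptake-direction (lower) bound of each exchange reaction to
#' `-limit` for listed compounds and `-default_uptake` otherwise; secretion
#' (upper) bounds are left open. Stoichiometry is never altered. Returns an
#' edited copy; the input model is unchanged.
#'
#' @param model a `metabolic_model` with flagged exchange reactions.
#' @param medium a [medium_spec()].
#' @param strict if `TRUE`, a medium naming an exchange absent from the
#'   model is an error; default `FALSE` warns and skips (compound naming
#'   differs between reconstructions).
#' @return the edited `metabolic_model`.
#' @export
apply_medium <- function(model, medium, strict = FALSE) {
  stopifnot(inherits(medium, "medium_spec"))
  ex <- exchange_reactions(model)
  unknown <- setdiff(names(medium$uptake_limits), ex)
  if (length(unknown)) {
    msg <- paste0("medium '", medium$name, "' names exchange(s) absent ",
                  "from model '", model$id, "': ",
                  paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  for (id in ex) {
    lim <- if (id %in% names(medium$uptake_limits)) {
      medium$uptake_limits[[id]]
    } else {
      medium$default_uptake
    }
    if (!is.na(lim)) model$reactions[[id]]$lower_bound <- -lim
  }
  model
}

# ---- model editing ----------------------------------------------------------

#' Delete a reaction (knock-out)
#'
#' Deletion sets both bounds to zero but keeps the reaction in the model, so
#' scan reports stay aligned with the original reaction index. Returns an
#' edited copy.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id id of the reaction to knock out.
#' @return the edited `metabolic_model`.
#' @export
delete_reaction <- function(model, reaction_id) {
  if (!reaction_id %in% names(model$reactions)) {
    stop("unknown reaction id: ", reaction_id)
  }
  model$reactions[[reaction_id]]$lower_bound <- 0
  model$reactions[[reaction_id]]$upper_bound <- 0
  model
}

#' Add heterologous reactions to a model
#'
#' Expands the model with a set of [reaction_def()]s. New metabolites must
#' either already exist in the host or be declared in the def's
#' `new_metabolites`. Adding reactions is monotone for FBA: it never removes
#' feasible flux distributions.
#'
#' @param model a `metabolic_model`.
#' @param defs list of [reaction_def()] (a single def is accepted).
#' @param quiet suppress the per-addition provenance messages.
#' @return the expanded `metabolic_model`.
#' @export
add_reactions <- function(model, defs, quiet = TRUE) {
  if (inherits(defs, "reaction_def")) defs <- list(defs)
  for (d in defs) {
    if (d$id %in% names(model$reactions)) {
      stop("reaction id collision: '", d$id, "' already in model")
    }
    for (m in d$new_metabolites) {
      if (!m$id %in% names(model$metabolites)) {
        model$metabolites[[m$id]] <- m
      }
    }
    missing <- setdiff(names(d$stoichiometry), names(model$metabolites))
    if (length(missing)) {
      stop("reaction '", d$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    r <- d
    r$new_metabolites <- NULL
    class(r) <- "reaction"
    if (is.na(r$is_exchange)) {
      comp <- vapply(model$metabolites[names(r$stoichiometry)], `[[`,
                     character(1), "compartment")
      r$is_exchange <- length(r$stoichiometry) == 1L &&
        tolower(comp) %in% extracellular_tokens
      r$is_transport <- !r$is_exchange && length(unique(tolower(comp))) > 1L
    }
    model$reactions[[d$id]] <- r
    if (!quiet) {
      message("added reaction ", d$id,
              if (nzchar(d$provenance)) paste0(" [", d$provenance, "]"))
    }
  }
  model
}
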