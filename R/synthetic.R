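#' Deterministic toy metabolic model with planted O2-dependent essentials
#'
#' Builds a ~13-reaction network that reproduces, at desk scale, the
#' metabolic logic of a strict aerobe: most ATP comes from O2-dependent
#' respiration, and four biosynthetic steps (heme-like, NAD-precursor-like,
#' orotate-like, dNTP-forming) strictly require molecular oxygen. Under an
#' anoxic medium the wild-type network cannot grow; O2-independent
#' alternative reactions restore a small, ATP-limited growth rate; adding
#' acetate kinase (substrate-level phosphorylation from the acetyl-phosphate
#' overflow) exactly doubles it.
#'
#' Network (pseudo-formula scheme; C and P are conserved, O is the lumped
#' redox bookkeeping element and is deliberately not conserved):
#' \preformatted{
#' GLYC:  glc_e + s adp + (s+2) pi -> 2 acp + s atp      (redox-neutral lump)
#' ETC_O2: acp + 2 o2 + a adp + a pi -> a atp + 3 co2 + pi  (a = 2 atp_per_o2)
#' *_SYNTH_O2: acp + 0.5 o2 -> precursor + pi             (x4, planted)
#' ACP_HYDR: acp -> ac_e + pi                              (overflow, no ATP)
#' ATPM:  atp -> adp + pi        (maintenance, lower bound = maintenance_atp)
#' BIOMASS: 4 precursors + b atp -> b adp + b pi           (objective)
#' }
#'
#' With the glucose bound g, substrate-level yield s, maintenance m and
#' biomass ATP demand b, the anoxic growth rate with the four alternatives
#' is `mu_alt = (s g - m) / b` (ATP-limited) and with acetate kinase
#' `mu_ack = ((s+2) g - m) / (b+4)`. When `biomass_atp_demand` is left
#' `NULL` the generator solves `b = 8 (s g - m) / ((2 - s) g + m)` in closed
#' form so that `mu_ack = 2 mu_alt` exactly.
#'
#' @param atp_per_o2 ATP formed per O2 consumed by the respiratory lump
#'   (default 5).
#' @param biomass_atp_demand ATP consumed per unit biomass; `NULL` (default)
#'   = solve for the exact acetate-kinase doubling.
#' @param maintenance_atp fixed non-growth ATP drain, mmol/(gdw h)
#'   (default 2).
#' @param substrate_level_atp ATP per glucose from the glycolytic lump;
#'   must be < 2 for the anoxic regime to be ATP-limited (default 1).
#' @param glucose_limit maximal glucose uptake, mmol/(gdw h) (default 10).
#' @param o2_limit maximal O2 uptake under the oxic overlay (default 18.5).
#' @return a list with elements
#'   \describe{
#'     \item{model}{the `metabolic_model` (bounds as per the oxic minimal
#'       medium).}
#'     \item{truth}{the planted ground truth: `essential_o2_reactions`,
#'       `anaerobic_mu_expected` (named: `wild_type`, `alternatives`,
#'       `alternatives_ack`), and the full `parameters` record.}
#'     \item{media}{named [medium_spec()]s: `minimal`, `oxic`, `anoxic`.}
#'     \item{designs}{named [intervention_set()]s: `alternatives` (the four
#'       O2-independent biosynthesis routes) and `ACK` (acetate kinase).}
#'   }
#' @export
make_toy_model <- function(atp_per_o2 = 5, biomass_atp_demand = NULL,
                           maintenance_atp = 2, substrate_level_atp = 1,
                           glucose_limit = 10, o2_limit = 18.5) {
  s <- substrate_level_atp; m <- maintenance_atp; g <- glucose_limit
  a <- 2 * atp_per_o2
  if (any(c(atp_per_o2, m, s, g, o2_limit) <= 0)) {
    stop("all toy-model parameters must be > 0")
  }
  if (s * g <= m) {
    stop("infeasible ATP budget: substrate-level yield (s*g = ", s * g,
         ") does not cover maintenance (", m, "); no anoxic design can grow")
  }
  if ((2 - s) * g + m <= 0) {
    stop("substrate_level_atp too high ((2-s)*g + m <= 0): the anoxic ",
         "regime would not be ATP-limited")
  }
  if (is.null(biomass_atp_demand)) {
    b <- 8 * (s * g - m) / ((2 - s) * g + m)
  } else {
    b <- biomass_atp_demand
    if (b <= 0) stop("biomass_atp_demand must be > 0")
    if ((s * g - m) / b > g / 2) {
      stop("biomass_atp_demand too low: anoxic growth would be ",
           "carbon-limited, not ATP-limited")
    }
  }
  mets <- list(
    metabolite("glc_e", "D-glucose", "e", "C6"),
    metabolite("o2_e", "molecular oxygen", "e", "O2"),
    metabolite("o2", "molecular oxygen", "c", "O2"),
    metabolite("ac_e", "acetate overflow", "e", "C3"),
    metabolite("co2_e", "carbon dioxide", "e", "C1"),
    metabolite("co2", "carbon dioxide", "c", "C1"),
    metabolite("acp", "acetyl phosphate (C3 carbon unit)", "c", "C3P1"),
    metabolite("pi", "inorganic phosphate", "c", "P1"),
    metabolite("atp", "ATP", "c", "P3"),
    metabolite("adp", "ADP", "c", "P2"),
    metabolite("heme", "heme-like precursor", "c", "C3"),
    metabolite("nadc", "NAD-cofactor-like precursor", "c", "C3"),
    metabolite("oro", "orotate-like precursor", "c", "C3"),
    metabolite("dntp", "dNTP-like precursor", "c", "C3")
  )
  rxns <- list(
    reaction("EX_glc", c(glc_e = -1), "glucose exchange",
             lower_bound = -g, upper_bound = 1000),
    reaction("EX_o2", c(o2_e = -1), "oxygen exchange",
             lower_bound = -o2_limit, upper_bound = 1000),
    reaction("EX_ac", c(ac_e = -1), "acetate exchange",
             lower_bound = 0, upper_bound = 1000),
    reaction("EX_co2", c(co2_e = -1), "CO2 exchange",
             lower_bound = 0, upper_bound = 1000),
    reaction("O2t", c(o2_e = -1, o2 = 1), "oxygen transport",
             lower_bound = 0, upper_bound = 1000),
    reaction("CO2t", c(co2 = -1, co2_e = 1), "CO2 export",
             lower_bound = 0, upper_bound = 1000),
    reaction("GLYC",
             c(glc_e = -1, adp = -s, pi = -(s + 2), acp = 2, atp = s),
             "glycolytic lump (substrate-level phosphorylation)",
             lower_bound = 0, upper_bound = 1000),
    reaction("ETC_O2",
             c(acp = -1, o2 = -2, adp = -a, pi = -(a - 1), atp = a,
               co2 = 3),
             "respiration lump (electron transfer chain, O2 terminal)",
             lower_bound = 0, upper_bound = 1000),
    reaction("HEME_SYNTH_O2", c(acp = -1, o2 = -0.5, heme = 1, pi = 1),
             "protoporphyrinogen-oxidase-like heme synthesis (O2)",
             lower_bound = 0, upper_bound = 1000),
    reaction("NAD_SYNTH_O2", c(acp = -1, o2 = -0.5, nadc = 1, pi = 1),
             "l-aspartate-oxidase-like NAD precursor synthesis (O2)",
             lower_bound = 0, upper_bound = 1000),
    reaction("ORO_SYNTH_O2", c(acp = -1, o2 = -0.5, oro = 1, pi = 1),
             "dihydroorotate-dehydrogenase-like orotate synthesis (O2)",
             lower_bound = 0, upper_bound = 1000),
    reaction("RNR_O2", c(acp = -1, o2 = -0.5, dntp = 1, pi = 1),
             "class-I-RNR-like dNTP synthesis (O2)",
             lower_bound = 0, upper_bound = 1000),
    reaction("ACP_HYDR", c(acp = -1, ac_e = 1, pi = 1),
             "acetyl-phosphate overflow (no ATP recovery)",
             lower_bound = 0, upper_bound = 1000),
    reaction("ATPM", c(atp = -1, adp = 1, pi = 1),
             "non-growth ATP maintenance",
             lower_bound = m, upper_bound = 1000),
    reaction("BIOMASS",
             c(heme = -1, nadc = -1, oro = -1, dntp = -1, atp = -b,
               adp = b, pi = b),
             "biomass objective",
             lower_bound = 0, upper_bound = 1000)
  )
  model <- metabolic_model("toy_aerobe", mets, rxns, "BIOMASS")

  alt <- function(id, prec, name) {
    reaction_def(id, stats::setNames(c(-1, 1, 1), c("acp", prec, "pi")),
                 name = name, lower_bound = 0, upper_bound = 1000,
                 provenance = "toy O2-independent biosynthesis alternative")
  }
  designs <- list(
    alternatives = intervention_set(
      "anaerobic_alternatives",
      list(alt("HEME_ALT", "heme", "quinone-independent heme route"),
           alt("NAD_ALT", "nadc", "fumarate-coupled NAD precursor route"),
           alt("ORO_ALT", "oro", "class I dihydroorotate dehydrogenase"),
           alt("RNR_ALT", "dntp", "class III ribonucleotide reductase")),
      provenance = "toy anaerobic alternatives for the planted essentials"),
    ACK = intervention_set(
      "ACK",
      list(reaction_def("ACK", c(acp = -1, adp = -1, ac_e = 1, atp = 1),
                        name = "acetate kinase",
                        lower_bound = 0, upper_bound = 1000,
                        provenance = "acetate kinase (ackA) design")),
      provenance = "substrate-level ATP from acetyl-phosphate overflow")
  )
  mu_alt <- (s * g - m) / b
  mu_ack <- ((s + 2) * g - m) / (b + 4)
  truth <- list(
    essential_o2_reactions = c("HEME_SYNTH_O2", "NAD_SYNTH_O2",
                               "ORO_SYNTH_O2", "RNR_O2"),
    o2_enzymatic_reactions = c("ETC_O2", "HEME_SYNTH_O2", "NAD_SYNTH_O2",
                               "ORO_SYNTH_O2", "RNR_O2"),
    anaerobic_mu_expected = c(wild_type = 0, alternatives = mu_alt,
                              alternatives_ack = mu_ack),
    parameters = list(atp_per_o2 = atp_per_o2, biomass_atp_demand = b,
                      maintenance_atp = m, substrate_level_atp = s,
                      glucose_limit = g, o2_limit = o2_limit)
  )
  media <- list(
    minimal = medium_spec("toy_minimal", c(EX_glc = g), default_uptake = 0),
    oxic = medium_spec("oxic", c(EX_o2 = o2_limit),
                       default_uptake = NA_real_),
    anoxic = medium_spec("anoxic", c(EX_o2 = 0), default_uptake = NA_real_)
  )
  list(model = model, truth = truth, media = media, designs = designs)
}

#' Elemental balance check
#'
#' Parses metabolite formulas and verifies that every non-exchange,
#' non-objective reaction conserves the requested elements. Reactions
#' touching a metabolite with no formula are skipped (reported).
#'
#' @param model a `metabolic_model`, or a list of [reaction_def()]s when
#'   `metabolites` supplies the formula table.
#' @param elements elements to balance (default C, N, O, P, S).
#' @param exclude reaction ids exempt from the check (the model's objective
#'   and exchange reactions are always exempt).
#' @param tol allowed absolute imbalance per element.
#' @return a data.frame (reaction_id, element, imbalance) of violations;
#'   zero rows = balanced. Skipped reactions are in
#'   `attr(, "skipped")`.
#' @export
check_balance <- function(model, elements = c("C", "N", "O", "P", "S"),
                          exclude = character(), tol = 1e-9) {
  if (inherits(model, "metabolic_model")) {
    formulas <- vapply(model$metabolites, `[[`, character(1), "formula")
    rxns <- model$reactions
    exclude <- c(exclude, model$objective_id,
                 names(rxns)[vapply(rxns, `[[`, logical(1), "is_exchange")])
  } else {
    stop("check_balance expects a metabolic_model; for reaction_defs use ",
         "check_defs_balance()")
  }
  check_reaction_list(rxns, formulas, elements, exclude, tol)
}

#' Elemental balance check for a list of reaction definitions
#'
#' @param defs list of [reaction_def()]s; formulas are taken from their
#'   `new_metabolites` declarations plus `extra_formulas`.
#' @param extra_formulas named character vector metabolite id -> formula for
#'   host metabolites referenced but not declared.
#' @inheritParams check_balance
#' @return as [check_balance()].
#' @export
check_defs_balance <- function(defs, extra_formulas = character(),
                               elements = c("C", "N", "O", "P", "S"),
                               tol = 1e-9) {
  formulas <- extra_formulas
  for (d in defs) {
    for (m in d$new_metabolites) {
      if (!is.na(m$formula)) formulas[m$id] <- m$formula
    }
  }
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  check_reaction_list(defs, formulas, elements, character(), tol)
}

check_reaction_list <- function(rxns, formulas, elements, exclude, tol) {
  viol <- list(); skipped <- character()
  for (r in rxns) {
    if (r$id %in% exclude) next
    st <- r$stoichiometry
    fs <- formulas[names(st)]
    if (any(is.na(fs))) { skipped <- c(skipped, r$id); next }
    counts <- vapply(elements, function(el) {
      sum(vapply(seq_along(st), function(i) {
        st[[i]] * element_count(fs[[i]], el)
      }, numeric(1)))
    }, numeric(1))
    bad <- abs(counts) > tol
    if (any(bad)) {
      viol[[r$id]] <- data.frame(reaction_id = r$id,
                                 element = elements[bad],
                                 imbalance = counts[bad],
                                 stringsAsFactors = FALSE)
    }
  }
  out <- if (length(viol)) do.call(rbind, c(viol, make.row.names = FALSE))
         else data.frame(reaction_id = character(), element = character(),
                         imbalance = numeric(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

element_count <- function(formula, element) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)",
                                        formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    if (el != element) next
    num <- sub("^[A-Z][a-z]?", "", p)
    total <- total + if (nzchar(num)) as.numeric(num) else 1
  }
  total
}

# ---- domain annotation tables ----------------------------------------------

ipr_acc <- function(i) sprintf("IPR%06d", i)

#' Generate per-genome protein-domain tables with a planted exclusive core
#'
#' Emulates the comparative-genomics input: one simple TSV per genome
#' (columns `genome_id`, `gene_id`, `domain_id`), for a target
#' (facultative-anaerobe-like) panel and a background (obligate-aerobe-like)
#' panel. Planted structure:
#' \itemize{
#'   \item `n_exclusive` domains present in every target genome and no
#'     background genome (the recoverable exclusive core);
#'   \item `n_shared_core` domains present in all genomes, each subject to
#'     per-genome `dropout`;
#'   \item `n_noise` domains scattered per genome with independent
#'     inclusion probability `p_noise`.
#' }
#' Any non-planted domain that by chance forms a target-exclusive-core
#' pattern is deterministically broken (added to the first background
#' genome) before writing, so planted recovery is exact by construction.
#' Fully reproducible from `seed`; a `planted_truth.json` sidecar records
#' the parameters and the planted accessions.
#'
#' @param seed integer RNG seed.
#' @param dir output directory (created if needed).
#' @param n_target,n_background panel sizes (default 6 and 6).
#' @param n_exclusive planted exclusive-core size (default 47).
#' @param n_shared_core genus-core size shared by all genomes (default 800).
#' @param n_noise number of scattered accessory domains (default 2000).
#' @param dropout per-genome loss probability for shared-core domains
#'   (default 0.05); never applied to planted exclusive domains.
#' @param p_noise per-genome inclusion probability of each noise domain
#'   (default 0.3).
#' @return list with `files` (named character vector genome id -> path),
#'   `groups` (data.frame genome_id, group, path), and `truth`
#'   (`exclusive_core_domains`, `shared_core_domains`, `parameters`).
#' @export
make_domain_tables <- function(seed, dir = tempfile("domains"),
                               n_target = 6, n_background = 6,
                               n_exclusive = 47, n_shared_core = 800,
                               n_noise = 2000, dropout = 0.05,
                               p_noise = 0.3) {
  stopifnot(n_target >= 1, n_background >= 1, dropout >= 0, dropout < 1)
  if (n_exclusive == 0) {
    warning("n_exclusive = 0: recovery tests on this dataset are vacuous")
  }
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shared <- if (n_shared_core) ipr_acc(seq_len(n_shared_core)) else character()
  exclusive <- if (n_exclusive) {
    ipr_acc(n_shared_core + seq_len(n_exclusive))
  } else character()
  noise <- if (n_noise) {
    ipr_acc(n_shared_core + n_exclusive + seq_len(n_noise))
  } else character()
  genomes <- c(sprintf("anae_%02d", seq_len(n_target)),
               sprintf("aero_%02d", seq_len(n_background)))
  group <- rep(c("anaerobe", "aerobe"), c(n_target, n_background))

  presence <- lapply(seq_along(genomes), function(i) {
    keep_shared <- shared[stats::runif(length(shared)) >= dropout]
    keep_noise <- noise[stats::runif(length(noise)) < p_noise]
    sort(unique(c(keep_shared, keep_noise,
                  if (group[i] == "anaerobe") exclusive)))
  })
  names(presence) <- genomes

  # break chance target-exclusive patterns among non-planted domains
  tgt <- genomes[group == "anaerobe"]
  bgd <- genomes[group == "aerobe"]
  chance_core <- Reduce(intersect, presence[tgt])
  chance_core <- setdiff(chance_core, exclusive)
  leak <- setdiff(chance_core, unique(unlist(presence[bgd])))
  if (length(leak)) {
    presence[[bgd[1]]] <- sort(union(presence[[bgd[1]]], leak))
  }
  stopifnot(!any(exclusive %in% unlist(presence[bgd])))

  files <- character()
  for (gid in genomes) {
    doms <- presence[[gid]]
    # a couple of duplicated-gene rows to exercise de-duplication downstream
    dup <- utils::head(doms, 2)
    df <- data.frame(
      genome_id = gid,
      gene_id = sprintf("%s_g%05d", gid,
                        seq_len(length(doms) + length(dup))),
      domain_id = c(doms, dup),
      stringsAsFactors = FALSE
    )
    path <- file.path(dir, paste0(gid, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[gid] <- path
  }
  truth <- list(
    exclusive_core_domains = exclusive,
    shared_core_domains = shared,
    parameters = list(seed = seed, n_target = n_target,
                      n_background = n_background,
                      n_exclusive = n_exclusive,
                      n_shared_core = n_shared_core, n_noise = n_noise,
                      dropout = dropout, p_noise = p_noise)
  )
  jsonlite::write_json(truth, file.path(dir, "planted_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = files,
       groups = data.frame(genome_id = genomes, group = group,
                           path = unname(files),
                           stringsAsFactors = FALSE),
       truth = truth)
}
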