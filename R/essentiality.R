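#' Reactions involving molecular oxygen
#'
#' Returns, in sorted-id order, every reaction whose stoichiometry includes
#' an O2 metabolite. Exchange and transport reactions are excluded by
#' default: knocking them out merely simulates anoxia, whereas the scan is
#' after *enzymatic* O2 dependencies.
#'
#' @param model a `metabolic_model` with non-empty `o2_metabolite_ids`.
#' @param include_exchange,include_transport include O2 exchange/transport
#'   reactions (default `FALSE`).
#' @return character vector of reaction ids, sorted.
#' @export
find_o2_reactions <- function(model, include_exchange = FALSE,
                              include_transport = FALSE) {
  if (!length(model$o2_metabolite_ids)) {
    stop("model '", model$id, "' has no O2 metabolite configured; set ",
         "o2_metabolite_ids or provide formulas")
  }
  hit <- vapply(model$reactions, function(r) {
    coef <- r$stoichiometry[names(r$stoichiometry) %in%
                              model$o2_metabolite_ids]
    any(coef != 0)
  }, logical(1))
  ids <- names(model$reactions)[hit]
  keep <- vapply(model$reactions[ids], function(r) {
    (include_exchange || !r$is_exchange) &&
      (include_transport || !r$is_transport)
  }, logical(1))
  sort(ids[keep])
}

o2_role <- function(model, reaction_id) {
  coef <- model$reactions[[reaction_id]]$stoichiometry
  coef <- coef[names(coef) %in% model$o2_metabolite_ids]
  if (any(coef < 0) && any(coef > 0)) "both"
  else if (any(coef < 0)) "consumes"
  else "produces"
}

#' Single-deletion essentiality scan over O2-dependent reactions
#'
#' For each reaction involving molecular oxygen (default filters as in
#' [find_o2_reactions()]), knocks it out alone, re-runs FBA under the given
#' medium, and records whether growth survives. The model is restored
#' between deletions; the scan order (sorted ids) is deterministic and the
#' result is order-independent.
#'
#' @param model a `metabolic_model`.
#' @param medium [medium_spec()] the scan runs under; the baseline must
#'   grow on it.
#' @param epsilon growth threshold (h^-1); a post-deletion mu below it
#'   marks the reaction essential.
#' @param include_exchange,include_transport passed to
#'   [find_o2_reactions()].
#' @return data.frame with one row per scanned reaction: `reaction_id`,
#'   `reaction_name`, `o2_role` (`consumes`/`produces`/`both`),
#'   `mu_after_deletion`, `essential`. The baseline growth rate is stored
#'   in `attr(, "baseline_mu")`.
#' @export
o2_essentiality_scan <- function(model, medium = NULL,
                                 epsilon = GROWTH_EPSILON,
                                 include_exchange = FALSE,
                                 include_transport = FALSE) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  base <- fba(model)
  if (base$status != "optimal" || base$mu < epsilon) {
    stop("essentiality scan requires a growing baseline; baseline status ",
         base$status, ", mu = ", format(base$mu))
  }
  ids <- find_o2_reactions(model, include_exchange, include_transport)
  rows <- lapply(ids, function(id) {
    res <- fba(delete_reaction(model, id))
    data.frame(
      reaction_id = id,
      reaction_name = model$reactions[[id]]$name,
      o2_role = o2_role(model, id),
      mu_after_deletion = res$mu,
      essential = res$mu < epsilon,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "baseline_mu") <- base$mu
  out
}

#' Write a scan report as TSV
#'
#' @param scan result of [o2_essentiality_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
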