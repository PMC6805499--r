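#' @keywords internal
#' Solve a bounded linear program max/min c'v s.t. S v = 0, lb <= v <= ub.
#'
#' Backend contract: returns list(status, objective, solution). The default
#' backend is the package's bounded-variable two-phase simplex (see
#' R/lp.R); redundant conservation rows are dropped by QR rank reduction
#' first. All bounds must be finite: an FBA medium is always a bounded
#' construction, and a non-finite bound signals a mis-configured medium
#' (hard error rather than an unbounded solve).
solve_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(obj) == n, ncol(S) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("non-finite flux bound: the linear program would be unbounded; ",
         "check the medium configuration")
  }
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  if (nrow(S) > 0L) {
    qrS <- qr(t(S))
    S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  }
  if (nrow(S) == 0L) {
    v <- ifelse((obj > 0) == maximize, ub, lb)
    v[obj == 0] <- lb[obj == 0]
    return(list(status = "optimal", objective = sum(obj * v), solution = v))
  }
  res <- simplex_bounded(obj, S, rep(0, nrow(S)), lb, ub,
                         maximize = maximize)
  if (res$status == "unbounded") {
    stop("LP is unbounded despite finite bounds: inconsistent model")
  }
  if (res$status != "optimal") {
    return(list(status = "infeasible", objective = NA_real_,
                solution = NULL))
  }
  list(status = "optimal", objective = res$objective, solution = res$x)
}

#' Growth threshold
#'
#' Predicted growth rates below this value (h^-1) are reported as
#' "no growth" throughout the package.
#' @export
GROWTH_EPSILON <- 1e-6

#' Flux Balance Analysis
#'
#' Maximizes the flux through the biomass objective subject to steady state
#' (`S v = 0`) and the flux bounds, via linear programming. The objective
#' value is the predicted specific growth rate mu (h^-1).
#'
#' Only `mu` is contract-stable across runs and backends; when alternate
#' optima exist the returned flux vector is one arbitrary optimal vertex.
#' An infeasible model (e.g. a maintenance demand that cannot be met) is
#' reported with `status = "infeasible"` and `mu = 0` so growth screens can
#' treat it as "no growth", distinctly flagged.
#'
#' @param model a validated `metabolic_model`.
#' @param medium optional [medium_spec()] applied before solving.
#' @return an `fba_result`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `mu`, `fluxes` (named vector, `NULL` when
#'   infeasible) and `objective_id`.
#' @export
fba <- function(model, medium = NULL) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  obj <- as.numeric(names(model$reactions) == model$objective_id)
  res <- solve_lp(obj, S, lb, ub, maximize = TRUE)
  if (res$status == "infeasible") {
    out <- list(status = "infeasible", mu = 0, fluxes = NULL,
                objective_id = model$objective_id)
  } else {
    v <- stats::setNames(res$solution, names(model$reactions))
    resid <- max(abs(S %*% v))
    if (resid > 1e-6) {
      stop("FBA solution violates steady state (||S v||_inf = ",
           format(resid), ")")
    }
    mu <- res$objective
    if (mu == 0) mu <- 0  # normalize IEEE negative zero
    out <- list(status = "optimal", mu = mu, fluxes = v,
                objective_id = model$objective_id)
  }
  class(out) <- "fba_result"
  out
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result>", x$status,
      " mu =", format(x$mu, digits = 6), "h^-1",
      " objective:", x$objective_id, "\n")
  invisible(x)
}

#' Predict growth across a set of conditions
#'
#' Convenience sweep: applies an optional base medium, then each overlay in
#' turn, runs [fba()] and tabulates the predicted growth rate per
#' condition.
#'
#' @param model a `metabolic_model`.
#' @param medium optional base [medium_spec()] applied before every
#'   overlay.
#' @param overlays list of [medium_spec()] overlays, one condition each.
#' @return a data.frame with columns `condition`, `status`, `mu`.
#' @export
growth_predicts <- function(model, medium = NULL, overlays = list()) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (inherits(overlays, "medium_spec")) overlays <- list(overlays)
  rows <- lapply(overlays, function(ov) {
    r <- fba(apply_medium(model, ov))
    data.frame(condition = ov$name, status = r$status, mu = r$mu,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(condition = character(), status = character(),
                      mu = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Export a flux vector as TSV
#'
#' @param result an `fba_result` with `status = "optimal"`.
#' @param path output TSV path (columns `reaction_id`, `flux`).
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(result, path) {
  stopifnot(inherits(result, "fba_result"))
  if (is.null(result$fluxes)) stop("no flux vector to export (status = ",
                                   result$status, ")")
  utils::write.table(
    data.frame(reaction_id = names(result$fluxes), flux = result$fluxes),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
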