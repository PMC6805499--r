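# Independent oracles for the FBA engine, deliberately sharing no code with
# the package's LP kernel.

# Brute-force vertex enumeration for  max c'v : S v = 0, lb <= v <= ub.
# Every vertex of a (nonempty, bounded) polyhedron has >= n - rank(S)
# variables at a bound; enumerate all such fixings, solve the square system
# for the free variables, keep feasible points, take the best objective.
# Returns list(status, mu). Exponential — tiny networks only.
oracle_lp_vertex <- function(obj, S, lb, ub, tol = 1e-7) {
  n <- length(lb)
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  if (nrow(S)) {
    qrS <- qr(t(S))
    S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  }
  r <- nrow(S)
  best <- -Inf
  feasible <- FALSE
  check <- function(v) {
    if (all(v >= lb - tol) && all(v <= ub + tol) &&
        (r == 0 || max(abs(S %*% v)) <= tol)) {
      feasible <<- TRUE
      best <<- max(best, sum(obj * v))
    }
  }
  if (r == 0) {
    check(ifelse(obj > 0, ub, lb))
  } else {
    fixed_sets <- utils::combn(n, n - r, simplify = FALSE)
    for (fx in fixed_sets) {
      free <- setdiff(seq_len(n), fx)
      Sf <- S[, free, drop = FALSE]
      if (abs(det(Sf)) < 1e-10) next
      n_fx <- length(fx)
      for (mask in 0:(2^n_fx - 1)) {
        at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(n_fx) - 1)))
        vfx <- ifelse(at_ub, ub[fx], lb[fx])
        v <- numeric(n)
        v[fx] <- vfx
        rhs <- -S[, fx, drop = FALSE] %*% vfx
        v[free] <- solve(Sf, rhs)
        check(v)
      }
    }
  }
  if (!feasible) list(status = "infeasible", mu = NA_real_)
  else list(status = "optimal", mu = best)
}

oracle_fba <- function(model) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  obj <- as.numeric(names(model$reactions) == model$objective_id)
  oracle_lp_vertex(obj, S, lb, ub)
}

# Dual bound for max c'v : S v = 0, lb <= v <= ub. The dual is
#   min  u'p - l'q   s.t.  S'y + p - q = c,  p, q >= 0,  y free,
# solved here through the package's kernel on an independent formulation;
# strong duality makes the optimum equal the primal mu.
dual_bound_fba <- function(model) {
  S <- stoichiometric_matrix(model)
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  qrS <- qr(t(S))
  S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  cc <- as.numeric(names(model$reactions) == model$objective_id)
  m <- nrow(S); n <- ncol(S)
  # variables: y+ (m), y- (m), p (n), q (n); constraint S'y + p - q = c
  A <- cbind(t(S), -t(S), diag(n), -diag(n))
  big <- 1e4
  anaerodesign:::simplex_bounded(
    cc = c(rep(0, 2 * m), ub, -lb),
    A = A, b = cc,
    lb = rep(0, 2 * m + 2 * n),
    ub = rep(big, 2 * m + 2 * n),
    maximize = FALSE
  )
}

# Random small networks with finite bounds for engine-vs-oracle equivalence.
# Metabolite count ~ half the reaction count; integer coefficients in
# -3..3; a mix of irreversible, reversible and "uptake-like" bounds.
random_small_model <- function(n_rxn, seed) {
  set.seed(seed)
  n_met <- max(2L, n_rxn %/% 2L)
  mets <- lapply(seq_len(n_met), function(i) {
    metabolite(paste0("m", i), compartment = "c")
  })
  rxns <- vector("list", n_rxn)
  for (j in seq_len(n_rxn)) {
    k <- sample(1:min(3, n_met), 1)
    touch <- sample(n_met, k)
    coef <- sample(c(-3:-1, 1:3), k, replace = TRUE)
    b <- sort(sample(c(-10, -5, 0, 0, 5, 10, 20), 2, replace = TRUE))
    if (b[1] == b[2]) b[2] <- b[2] + 5
    rxns[[j]] <- reaction(sprintf("r%02d", j),
                          stats::setNames(coef, paste0("m", touch)),
                          lower_bound = b[1], upper_bound = b[2])
  }
  metabolic_model(paste0("rand", seed), mets, rxns,
                  objective_id = sprintf("r%02d", sample(n_rxn, 1)),
                  o2_metabolite_ids = character())
}

# Brute-force exclusive-core oracle over the presence/absence matrix:
# explicit double loop, no set algebra.
oracle_exclusive_core <- function(target_sets, background_sets) {
  all_doms <- sort(unique(unlist(c(lapply(target_sets, `[[`, "domains"),
                                   lapply(background_sets, `[[`,
                                          "domains")))))
  keep <- character()
  for (d in all_doms) {
    in_all_targets <- TRUE
    for (g in target_sets) {
      if (!(d %in% g$domains)) { in_all_targets <- FALSE; break }
    }
    if (!in_all_targets) next
    in_any_background <- FALSE
    for (g in background_sets) {
      if (d %in% g$domains) { in_any_background <- TRUE; break }
    }
    if (!in_any_background) keep <- c(keep, d)
  }
  keep
}

# Shared toy fixture (deterministic; built once per test run).
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_model()
    cache
  }
})
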