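# Bounded-variable two-phase primal simplex.
#
# Solves  max/min c'v  s.t.  A v = b,  lb <= v <= ub  for dense, desk-scale
# problems. Bland's rule guarantees termination under degeneracy (FBA
# systems routinely carry redundant conservation rows and degenerate
# vertices). Basic values are recomputed from the basis factorization at
# every iteration, trading speed for numerical robustness — the problems
# this package solves have tens of columns.

simplex_bounded <- function(cc, A, b, lb, ub, maximize = TRUE,
                            tol = 1e-9, maxit = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(lb) == n, length(ub) == n,
            length(b) == m)
  if (maximize) cc <- -cc                      # minimize internally
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }

  # artificial columns give a trivially feasible starting basis
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)      # nonbasic at a finite bound
  resid <- as.vector(b - A %*% x)
  sgn <- ifelse(resid >= 0, 1, -1)
  Atot <- cbind(A, diag(sgn, m))
  lbt <- c(lb, rep(0, m))
  ubt <- c(ub, rep(Inf, m))
  xt <- c(x, abs(resid))
  basis <- n + seq_len(m)
  at_upper <- c(x == ub & lb != ub, rep(FALSE, m))

  run_phase <- function(cost, allowed) {
    for (it in seq_len(maxit)) {
      B <- Atot[, basis, drop = FALSE]
      Binv_ok <- TRUE
      xt[basis] <<- tryCatch({
        nb <- setdiff(seq_len(n + m), basis)
        solve(B, b - Atot[, nb, drop = FALSE] %*% xt[nb])
      }, error = function(e) { Binv_ok <<- FALSE; xt[basis] })
      if (!Binv_ok) stop("LP kernel: singular basis")
      y <- solve(t(B), cost[basis])
      nonbasic <- setdiff(which(allowed), basis)
      d <- cost[nonbasic] - as.vector(crossprod(y, Atot[, nonbasic,
                                                        drop = FALSE]))
      lower_ok <- d < -tol & !at_upper[nonbasic]
      upper_ok <- d > tol & at_upper[nonbasic]
      cand <- nonbasic[lower_ok | upper_ok]
      if (!length(cand)) return("optimal")
      j <- min(cand)                           # Bland: smallest index
      dir <- if (at_upper[j]) -1 else 1
      w <- as.vector(solve(B, Atot[, j]))      # x_B change = -dir*delta*w
      span_j <- ubt[j] - lbt[j]
      delta <- span_j; leave <- 0L             # bound flip of entering var
      for (i in seq_len(m)) {
        g <- dir * w[i]
        if (g > tol) {
          r <- (xt[basis[i]] - lbt[basis[i]]) / g
        } else if (g < -tol) {
          r <- (ubt[basis[i]] - xt[basis[i]]) / (-g)
        } else next
        if (r < delta - tol ||
            (r < delta + tol && leave > 0L && basis[i] < basis[leave])) {
          delta <- max(r, 0); leave <- i
        }
      }
      if (!is.finite(delta)) return("unbounded")
      xt[j] <<- xt[j] + dir * delta
      if (leave == 0L) {                       # entering flips to its other bound
        at_upper[j] <<- !at_upper[j]
      } else {
        out <- basis[leave]
        g <- dir * w[leave]
        at_upper[out] <<- g < 0                # left at upper bound iff it rose
        xt[out] <<- if (g < 0) ubt[out] else lbt[out]
        basis[leave] <<- j
      }
    }
    stop("LP kernel: iteration limit reached (", maxit, ")")
  }

  # phase 1: minimize the artificial sum
  cost1 <- c(rep(0, n), rep(1, m))
  st <- run_phase(cost1, allowed = rep(TRUE, n + m))
  if (st != "optimal") stop("LP kernel: phase 1 ", st)
  if (sum(xt[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # phase 2: original objective; artificials locked at zero
  ubt[n + seq_len(m)] <- 0
  xt[n + seq_len(m)] <- 0
  cost2 <- c(cc, rep(0, m))
  st <- run_phase(cost2, allowed = c(rep(TRUE, n), rep(FALSE, m)))
  if (st == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  x <- pmin(pmax(xt[seq_len(n)], lb), ub)      # clip roundoff at bounds
  obj <- sum(cc * x)
  list(status = "optimal",
       objective = if (maximize) -obj else obj, x = x)
}
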