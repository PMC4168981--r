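#' Bounded-variable two-phase revised simplex
#'
#' Solves min/max obj'x subject to A x = b and lb <= x <= ub. This is the LP
#' core behind FBA, FVA and the GIMME penalty program. It is a textbook
#' revised simplex with bounded variables, phase-1 artificials and Bland's
#' anti-cycling rule: flux LPs are heavily degenerate (conserved-moiety row
#' dependencies, zero-width bounds after gene deletions) and general-purpose
#' dense simplex routines available to us fail on them, so the solver is
#' kept in-house where its pivoting can be controlled.
#'
#' @param obj objective coefficients (length n).
#' @param A constraint matrix (m x n); m may be 0.
#' @param b right-hand side (length m).
#' @param lb,ub finite variable bounds.
#' @param maximize direction.
#' @param tol pivoting/feasibility tolerance.
#' @param max_iter iteration cap per phase.
#' @return list with \code{status} ("optimal"/"infeasible"/"iteration_limit"),
#'   \code{x}, \code{objective}.
#' @keywords internal
bounded_simplex <- function(obj, A, b, lb, ub, maximize = FALSE,
                            tol = 1e-9, max_iter = 50000L) {
  n <- length(obj)
  A <- matrix(A, ncol = n)
  m <- nrow(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)))
  if (any(ub < lb - tol)) return(list(status = "infeasible"))
  cc <- if (maximize) -obj else obj
  if (m == 0L) {
    x <- ifelse(cc > 0, lb, ub)
    return(list(status = "optimal", x = x,
                objective = sum(obj * x)))
  }
  # start structural variables at the bound of smaller magnitude
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  stat <- ifelse(x == lb, -1L, 1L)            # -1 at lower, +1 at upper
  r <- b - as.numeric(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  N <- n + m
  xf <- c(x, abs(r))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  statf <- c(stat, rep(0L, m))
  basis <- (n + 1L):N
  run_phase <- function(costs, xf, statf, basis, ubf) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      B <- Afull[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), costs[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular_basis"))
      nonbasic <- which(statf != 0L)
      d <- costs[nonbasic] - as.numeric(crossprod(Afull[, nonbasic, drop = FALSE], y))
      cand <- nonbasic[(statf[nonbasic] == -1L & d < -tol) |
                       (statf[nonbasic] == 1L & d > tol)]
      if (!length(cand)) {
        return(list(status = "optimal", xf = xf, statf = statf, basis = basis))
      }
      j <- min(cand)                           # Bland's rule
      sig <- if (statf[j] == -1L) 1 else -1    # +1: entering increases
      w <- as.numeric(solve(B, Afull[, j]))
      # basic values change by -sig * w * t as entering moves by t >= 0
      delta <- -sig * w
      ts <- rep(Inf, m)
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (delta[i] > tol) {
          ts[i] <- max(0, (ubf[bi] - xf[bi]) / delta[i])
        } else if (delta[i] < -tol) {
          ts[i] <- max(0, (lbf[bi] - xf[bi]) / delta[i])
        }
      }
      span <- ubf[j] - lbf[j]
      tstar <- min(span, ts)
      if (!is.finite(tstar)) return(list(status = "unbounded"))
      blocking <- which(ts <= tstar + 1e-12)
      xf[basis] <- xf[basis] + delta * tstar
      if (statf[j] == -1L) xf[j] <- lbf[j] + tstar else xf[j] <- ubf[j] - tstar
      if (!length(blocking)) {
        statf[j] <- -statf[j]                  # bound flip, basis unchanged
      } else {
        leave <- blocking[which.min(basis[blocking])]   # Bland tie-break
        out <- basis[leave]
        hit_ub <- delta[leave] > 0
        xf[out] <- if (hit_ub) ubf[out] else lbf[out]
        statf[out] <- if (hit_ub) 1L else -1L
        basis[leave] <- j
        statf[j] <- 0L
      }
    }
  }
  p1 <- run_phase(c(rep(0, n), rep(1, m)), xf, statf, basis, ubf)
  if (p1$status != "optimal") return(list(status = p1$status))
  art_sum <- sum(p1$xf[(n + 1L):N])
  if (art_sum > 1e-7) return(list(status = "infeasible"))
  # freeze artificials at zero for phase 2
  ubf2 <- ubf
  ubf2[(n + 1L):N] <- 0
  xf2 <- p1$xf
  xf2[(n + 1L):N] <- 0
  p2 <- run_phase(c(cc, rep(0, m)), xf2, p1$statf, p1$basis, ubf2)
  if (p2$status != "optimal") return(list(status = p2$status))
  x <- p2$xf[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(obj * x))
}
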