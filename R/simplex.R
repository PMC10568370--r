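# Dense bounded-variable revised simplex.
#
# Solves  min c'x  s.t.  A x = b,  lb <= x <= ub  (bounds may be infinite)
# with a two-phase method: phase 1 minimizes the sum of artificial
# variables from an all-artificial starting basis, phase 2 the true cost.
# Nonbasic variables rest at a finite bound (free variables at 0); the
# ratio test allows bound-to-bound flips. Dantzig pricing with a switch to
# Bland's rule guards against cycling; redundant equality rows keep their
# artificial basic at zero. Dense LU solves per iteration are ample for
# the problem sizes this package targets (tens to a few hundred
# variables).

.SIMPLEX_TOL <- 1e-9

.simplexCore <- function(A, b, cvec, lb, ub, maxIter = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(maxIter)) maxIter <- 200L * (n + m) + 2000L

  # scale rows of A/b to unit max-abs for numerical sanity
  rs <- apply(abs(A), 1, max)
  rs[rs < 1e-12] <- 1
  A <- A / rs; b <- b / rs

  # initial nonbasic resting points: lower bound if finite, else upper
  # bound if finite, else free at 0 (must match the status codes below)
  startVal <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))

  # artificials: columns sign(resid) * e_i, bounds [0, Inf)
  resid <- b - as.numeric(A %*% startVal)
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lbF <- c(lb, rep(0, m)); ubF <- c(ub, rep(Inf, m))
  ntot <- n + m
  basis <- n + seq_len(m)
  # status: 0 basic, 1 at lower, 2 at upper, 3 free-at-zero
  status <- integer(ntot)
  status[seq_len(n)] <- ifelse(is.finite(lb), 1L,
                        ifelse(is.finite(ub), 2L, 3L))
  status[basis] <- 0L
  x <- c(startVal, abs(resid))

  runPhase <- function(cost, phase) {
    it <- 0L; sinceBland <- 0L; useBland <- FALSE
    repeat {
      it <- it + 1L
      if (it > maxIter) return("iteration_limit")
      B <- Afull[, basis, drop = FALSE]
      luB <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(luB)) return("singular_basis")
      xB <- as.numeric(luB %*% (b - Afull[, status != 0L, drop = FALSE] %*%
                                  x[status != 0L]))
      x[basis] <<- xB
      y <- as.numeric(crossprod(luB, cost[basis]))
      nb <- which(status != 0L)
      dj <- cost[nb] - as.numeric(crossprod(Afull[, nb, drop = FALSE], y))
      # candidate directions: increase from lower/free if dj < -tol,
      # decrease from upper/free if dj > tol
      canInc <- (status[nb] == 1L | status[nb] == 3L) & dj < -.SIMPLEX_TOL
      canDec <- (status[nb] == 2L | status[nb] == 3L) & dj > .SIMPLEX_TOL
      cand <- which(canInc | canDec)
      if (!length(cand)) {
        x[basis] <<- xB
        return("optimal")
      }
      pick <- if (useBland) cand[which.min(nb[cand])]
              else cand[which.max(abs(dj[cand]))]
      e <- nb[pick]
      dir <- if (canInc[pick]) 1 else -1
      w <- as.numeric(luB %*% Afull[, e])
      # ratio test
      tMax <- if (is.finite(ubF[e]) && is.finite(lbF[e])) ubF[e] - lbF[e] else Inf
      leave <- 0L; leaveBound <- NA_integer_
      for (i in seq_len(m)) {
        wi <- dir * w[i]
        if (wi > 1e-10) {
          lim <- (xB[i] - lbF[basis[i]]) / wi
          if (is.finite(lim) && lim < tMax - 1e-12) { tMax <- max(lim, 0); leave <- i; leaveBound <- 1L }
        } else if (wi < -1e-10) {
          lim <- (ubF[basis[i]] - xB[i]) / (-wi)
          if (is.finite(lim) && lim < tMax - 1e-12) { tMax <- max(lim, 0); leave <- i; leaveBound <- 2L }
        }
      }
      if (!is.finite(tMax)) return("unbounded")
      if (tMax < 1e-11) sinceBland <- sinceBland + 1L else sinceBland <- 0L
      if (sinceBland > 2L * (n + m)) useBland <- TRUE
      newXe <- x[e] + dir * tMax
      if (leave == 0L) {
        # bound-to-bound flip of the entering variable
        x[e] <<- newXe
        status[e] <<- if (dir > 0) 2L else 1L
      } else {
        lv <- basis[leave]
        x[lv] <<- if (leaveBound == 1L) lbF[lv] else ubF[lv]
        status[lv] <<- leaveBound
        x[e] <<- newXe
        status[e] <<- 0L
        basis[leave] <<- e
        x[basis] <<- xB - dir * tMax * w
        x[e] <<- newXe
      }
    }
  }

  costP1 <- c(rep(0, n), rep(1, m))
  st1 <- runPhase(costP1, 1L)
  if (st1 != "optimal") return(list(status = "solver_error", message = st1))
  p1obj <- sum(x[n + seq_len(m)])
  if (p1obj > 1e-7)
    return(list(status = "infeasible",
                message = sprintf("phase-1 residual %.3g", p1obj)))
  # pin artificials to zero so they never re-enter
  ubF[n + seq_len(m)] <- 0
  lbF[n + seq_len(m)] <- 0
  x[n + seq_len(m)][status[n + seq_len(m)] != 0L] <- 0
  costP2 <- c(cvec, rep(0, m))
  st2 <- runPhase(costP2, 2L)
  if (st2 == "unbounded")
    return(list(status = "unbounded", message = "objective unbounded below"))
  if (st2 != "optimal") return(list(status = "solver_error", message = st2))
  xOut <- x[seq_len(n)]
  list(status = "optimal", x = xOut, objval = sum(cvec * xOut), message = NULL)
}

# Canonical-form front end shared with the QP route: converts Ain x <= bin
# into equality rows with slack variables.
.solveCanonicalLP <- function(lcost, Aeq, beq, Ain, bin, lb, ub,
                              nIter = NULL) {
  n <- length(lcost)
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, n); beq <- numeric() }
  A <- Aeq; b <- beq
  cvec <- as.numeric(lcost); lbF <- as.numeric(lb); ubF <- as.numeric(ub)
  if (!is.null(Ain) && nrow(Ain) > 0L) {
    k <- nrow(Ain)
    A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), k)),
               cbind(Ain, diag(k)))
    b <- c(beq, bin)
    cvec <- c(cvec, rep(0, k))
    lbF <- c(lbF, rep(0, k)); ubF <- c(ubF, rep(Inf, k))
  }
  bad <- lbF > ubF
  if (any(bad))
    return(list(status = "infeasible", x = NULL, objval = NA_real_,
                message = "conflicting variable bounds"))
  res <- .simplexCore(A, b, cvec, lbF, ubF, maxIter = nIter)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, objval = NA_real_,
                message = res$message))
  x <- res$x[seq_len(n)]
  names(x) <- names(lcost)
  list(status = "optimal", x = x, objval = sum(as.numeric(lcost) * x),
       message = NULL)
}
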