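# Independent brute-force oracles for the LP/QP backends. These share no
# code with the solvers under test: the LP oracle enumerates vertices
# (basic solutions with n - rank variables at finite bounds), the QP oracle
# enumerates active sets of bound constraints and solves each KKT system
# directly.

bruteForceLP <- function(cc, Aeq, beq, lb, ub, tol = 1e-7) {
  n <- length(cc)
  r <- qr(Aeq)$rank
  nfix <- n - r
  best <- Inf
  consider <- function(x) {
    if (any(x < lb - tol) || any(x > ub + tol)) return()
    if (max(abs(Aeq %*% x - beq)) > tol) return()
    val <- sum(cc * x)
    if (val < best) best <<- val
  }
  if (nfix == 0L) {
    x <- tryCatch(qr.solve(Aeq, beq), error = function(e) NULL)
    if (!is.null(x)) consider(as.numeric(x))
    return(best)
  }
  for (S in utils::combn(n, nfix, simplify = FALSE)) {
    opts <- lapply(S, function(j) {
      v <- c(if (is.finite(lb[j])) lb[j], if (is.finite(ub[j])) ub[j])
      if (length(v)) v else NA_real_
    })
    if (any(vapply(opts, function(o) any(is.na(o)), TRUE))) next
    grid <- expand.grid(opts)
    for (gi in seq_len(nrow(grid))) {
      xS <- as.numeric(grid[gi, ])
      Afree <- Aeq[, -S, drop = FALSE]
      rhs <- beq - as.numeric(Aeq[, S, drop = FALSE] %*% xS)
      xF <- tryCatch(qr.solve(Afree, rhs), error = function(e) NULL)
      if (is.null(xF)) next
      x <- numeric(n)
      x[S] <- xS; x[-S] <- as.numeric(xF)
      consider(x)
    }
  }
  best
}

# Diagonal-quadratic objective q x^2 + c x over {Aeq x = beq, lb<=x<=ub}:
# enumerate for every variable the states free / at-lb / at-ub, solve the
# equality-constrained KKT system of the free block, keep feasible
# candidates.
bruteForceQP <- function(qq, cc, Aeq, beq, lb, ub, tol = 1e-7) {
  n <- length(qq)
  m <- nrow(Aeq)
  best <- Inf
  states <- expand.grid(rep(list(0:2), n))
  for (si in seq_len(nrow(states))) {
    st <- as.integer(states[si, ])
    fixedVal <- ifelse(st == 1L, lb, ifelse(st == 2L, ub, NA))
    if (any(st != 0L & !is.finite(fixedVal))) next
    Fv <- st == 0L
    nf <- sum(Fv)
    rhs <- beq - as.numeric(Aeq[, !Fv, drop = FALSE] %*% fixedVal[!Fv])
    if (nf == 0L) {
      x <- fixedVal
      if (max(abs(Aeq %*% x - beq)) > tol) next
    } else {
      K <- rbind(cbind(diag(2 * qq[Fv], nf), t(Aeq[, Fv, drop = FALSE])),
                 cbind(Aeq[, Fv, drop = FALSE], matrix(0, m, m)))
      kr <- c(-cc[Fv], rhs)
      sol <- tryCatch(MASS::ginv(K) %*% kr, error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(K %*% sol - kr)) > tol) next  # inconsistent KKT
      x <- fixedVal
      x[Fv] <- sol[seq_len(nf)]
    }
    if (any(x < lb - tol) || any(x > ub + tol)) next
    if (max(abs(Aeq %*% x - beq)) > tol) next
    val <- sum(qq * x^2) + sum(cc * x)
    if (val < best) best <- val
  }
  best
}

# Run both package backends and the matching oracle on the canonical
# arrays of an AdjustmentProblem.
oracleObjective <- function(problem) {
  v <- problem@variables
  Aeq <- problem@Aeq; beq <- problem@beq
  if (!is.null(problem@Ain) && nrow(problem@Ain) > 0L)
    stop("oracle helpers assume no general inequality block")
  if (problem@mode == "lp")
    bruteForceLP(v$lcost, Aeq, beq, v$lb, v$ub)
  else
    bruteForceQP(v$qcost, v$lcost, Aeq, beq, v$lb, v$ub)
}
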