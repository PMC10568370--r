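# QP backend and FBA front end. (The LP backend, a bounded-variable
# revised simplex, lives in simplex.R; both share the canonical form
#   min sum(lcost * x) + sum(qcost * x^2)
#   s.t. Aeq x = beq, Ain x <= bin, lb <= x <= ub .)
# The QP route uses the Goldfarb-Idnani dual method in quadprog. Variables
# without a quadratic cost receive a tiny ridge (the method requires strict
# positive definiteness); the reported objective is always evaluated with
# the original costs.

# Row-rank screen for the equality block: quadprog rejects linearly
# dependent active constraints, and stoichiometric matrices routinely carry
# conserved-moiety dependencies. Returns the indices of an independent row
# subset, or NULL when the dropped rows are inconsistent with beq.
.independentRows <- function(Aeq, beq, tol = 1e-9) {
  if (nrow(Aeq) == 0L) return(integer())
  qrA <- qr(t(Aeq), tol = tol)
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  qrAug <- qr(t(cbind(Aeq, unname(beq))), tol = tol)
  if (qrAug$rank > qrA$rank) return(NULL)  # inconsistent system
  keep
}

# Presolve: repeatedly fix variables pinned by singleton equality rows
# (e.g. hard-fixed measured rates), substituting them into the remaining
# rows. Returns NULL when a pinned value violates its bounds.
.eliminateSingletons <- function(Aeq, beq, lb, ub, tol = 1e-7) {
  n <- ncol(Aeq)
  fixed <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  rows <- rep(TRUE, nrow(Aeq))
  repeat {
    nz <- abs(Aeq) > 1e-12
    nz[, !active] <- FALSE
    cnt <- rowSums(nz)
    hit <- which(rows & cnt == 1L)
    if (!length(hit)) break
    i <- hit[1]
    j <- which(nz[i, ])[1]
    v <- beq[i] / Aeq[i, j]
    if (v < lb[j] - tol || v > ub[j] + tol) return(NULL)
    fixed[j] <- v
    active[j] <- FALSE
    beq <- beq - Aeq[, j] * v
    Aeq[, j] <- 0
    rows[i] <- FALSE
  }
  empty <- which(rows & rowSums(abs(Aeq) > 1e-12) == 0L)
  if (length(empty)) {
    if (any(abs(beq[empty]) > tol)) return(NULL)
    rows[empty] <- FALSE
  }
  list(Aeq = Aeq[rows, , drop = FALSE], beq = beq[rows],
       fixed = fixed, active = active)
}

.solveCanonicalQP <- function(lcost, qcost, Aeq, beq, Ain, bin, lb, ub,
                              ridge = 1e-10) {
  nAll <- length(qcost)
  vnames <- names(qcost)
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, nAll); beq <- numeric() }
  pre <- .eliminateSingletons(Aeq, beq, lb, ub)
  if (is.null(pre))
    return(list(status = "infeasible", x = NULL, objval = NA_real_,
                message = "a hard-fixed value violates its constraints"))
  act <- pre$active
  finish <- function(xAct, message = NULL) {
    x <- pre$fixed
    x[act] <- xAct
    names(x) <- vnames
    list(status = "optimal", x = x,
         objval = sum(qcost * x^2) + sum(lcost * x), message = message)
  }
  checkFull <- function(xAct, tol = 1e-7) {
    x <- pre$fixed; x[act] <- xAct
    if (!is.null(Ain) && nrow(Ain) > 0L &&
        any(Ain %*% x > bin + tol)) return(FALSE)
    all(x >= lb - tol & x <= ub + tol)
  }
  A <- pre$Aeq[, act, drop = FALSE]
  b <- pre$beq
  n <- sum(act)
  if (n == 0L) {
    if (!checkFull(numeric(0)))
      return(list(status = "infeasible", x = NULL, objval = NA_real_,
                  message = "fully determined point violates constraints"))
    return(finish(numeric(0)))
  }
  keep <- .independentRows(A, b)
  if (is.null(keep))
    return(list(status = "infeasible", x = NULL, objval = NA_real_,
                message = "equality constraints are inconsistent"))
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  if (nrow(A) == n) {
    # zero degrees of freedom: the equalities determine the point
    xAct <- tryCatch(as.numeric(solve(A, b)), error = function(e) NULL)
    if (is.null(xAct) || !checkFull(xAct))
      return(list(status = "infeasible", x = NULL, objval = NA_real_,
                  message = "fully determined point violates constraints"))
    return(finish(xAct))
  }
  d <- diag(2 * pmax(qcost[act], 0), n)
  zero <- qcost[act] <= 0
  if (any(zero)) diag(d)[zero] <- ridge
  Amat <- t(A); bvec <- b
  meq <- nrow(A)
  if (!is.null(Ain) && nrow(Ain) > 0L) {
    rhs <- bin - as.numeric(Ain[, !act, drop = FALSE] %*%
                              pre$fixed[!act])
    Amat <- cbind(Amat, -t(Ain[, act, drop = FALSE]))
    bvec <- c(bvec, -rhs)
  }
  lbA <- lb[act]; ubA <- ub[act]
  fl <- is.finite(lbA); fu <- is.finite(ubA)
  if (any(fl)) {
    E <- diag(n)[, fl, drop = FALSE]
    Amat <- cbind(Amat, E); bvec <- c(bvec, lbA[fl])
  }
  if (any(fu)) {
    E <- diag(n)[, fu, drop = FALSE]
    Amat <- cbind(Amat, -E); bvec <- c(bvec, -ubA[fu])
  }
  res <- tryCatch(
    quadprog::solve.QP(Dmat = d, dvec = -lcost[act], Amat = Amat,
                       bvec = bvec, meq = meq),
    error = function(e) e)
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    status <- if (grepl("inconsistent|no solution", msg)) "infeasible"
              else "solver_error"
    return(list(status = status, x = NULL, objval = NA_real_, message = msg))
  }
  finish(res$solution)
}

# Plain FBA: maximize obj over steady state, bounds and general constraints,
# with optional hard-fixed rates. Returns list(status, fluxes, objval).
.fba <- function(model, objective = NULL, fixed = NULL, maximize = TRUE) {
  rxns <- reactionIds(model)
  n <- length(rxns)
  if (is.null(objective)) objective <- model@objective
  obj <- stats::setNames(numeric(n), rxns)
  obj[names(objective)] <- as.numeric(objective)
  Aeq <- as.matrix(model@stoichiometry)
  beq <- numeric(nrow(Aeq))
  if (!is.null(fixed) && length(fixed)) {
    F <- matrix(0, length(fixed), n, dimnames = list(NULL, rxns))
    F[cbind(seq_along(fixed), match(names(fixed), rxns))] <- 1
    Aeq <- rbind(Aeq, F)
    beq <- c(beq, as.numeric(fixed))
  }
  Ain <- model@constraints$A
  bin <- model@constraints$b
  sol <- .solveCanonicalLP(lcost = if (maximize) -obj else obj,
                           Aeq = Aeq, beq = beq, Ain = Ain, bin = bin,
                           lb = model@lowerBounds, ub = model@upperBounds)
  if (sol$status != "optimal")
    return(list(status = sol$status, fluxes = NULL, objval = NA_real_,
                message = sol$message))
  list(status = "optimal", x = sol$x,
       fluxes = stats::setNames(sol$x, rxns),
       objval = sum(obj * sol$x), message = NULL)
}

#' Flux balance analysis optimum
#'
#' Maximizes the model objective (by default the biomass reaction, i.e. the
#' growth rate) subject to steady state, flux bounds and any general linear
#' constraints; optionally with hard-fixed reaction rates.
#'
#' @param model a \code{\link{MetabolicModel-class}}.
#' @param fixed optional named numeric of reaction rates to fix exactly.
#' @return list with \code{status}, named \code{fluxes}, and
#'   \code{objval} (the optimal objective, e.g. growth rate in 1/h).
#' @export
optimizeModel <- function(model, fixed = NULL) {
  res <- .fba(model, fixed = fixed, maximize = TRUE)
  res[c("status", "fluxes", "objval")]
}
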