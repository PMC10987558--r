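# Bounded-variable two-phase simplex for LPs of the form
#   opt c'v  subject to  A v = b,  lb <= v <= ub   (all bounds finite).
# Bland's rule throughout (deterministic, cycle-free). Sizes here are small
# (toy and community models, at most a few hundred variables), so the basis
# system is re-solved densely at every iteration for robustness.
solveLP <- function(obj, A, b, lb, ub, maximize = TRUE,
                    tol = 1e-9, maxIter = 20000L) {
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solveLP requires finite bounds")
  if (any(lb > ub)) stop("lb > ub")
  # shift to y = v - lb in [0, u]
  u <- ub - lb
  b2 <- b - as.vector(A %*% lb)
  flip <- b2 < 0
  A2 <- A
  A2[flip, ] <- -A2[flip, , drop = FALSE]
  b2[flip] <- -b2[flip]
  # augment with artificials
  N <- n + m
  Afull <- cbind(A2, diag(m))
  uFull <- c(u, rep(Inf, m))
  cPhase1 <- c(rep(0, n), rep(1, m))
  cPhase2 <- c(if (maximize) -obj else obj, rep(0, m))

  basis <- n + seq_len(m)
  atUpper <- rep(FALSE, N)

  runSimplex <- function(cost, basis, atUpper, uFull) {
    Im <- diag(m)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > maxIter) stop("simplex iteration limit reached")
      B <- Afull[, basis, drop = FALSE]
      isBasic <- logical(N)
      isBasic[basis] <- TRUE
      xFull <- numeric(N)
      xFull[!isBasic & atUpper] <- uFull[!isBasic & atUpper]
      rhs <- b2 - as.vector(Afull %*% xFull)
      Binv <- tryCatch(solve(B, Im), error = function(e)
        stop("singular basis in simplex"))
      xB <- as.vector(Binv %*% rhs)
      y <- as.vector(crossprod(Binv, cost[basis]))
      dAll <- cost - as.vector(y %*% Afull)
      eligible <- !isBasic & uFull > tol &  # fixed variables never enter
        ((!atUpper & dAll < -tol) | (atUpper & dAll > tol))
      if (!any(eligible)) {
        xFull[basis] <- xB
        return(list(basis = basis, atUpper = atUpper, xB = xB,
                    value = sum(cost * xFull), status = "optimal"))
      }
      j <- which(eligible)[1]  # Bland's rule: smallest entering index
      w <- as.vector(Binv %*% Afull[, j])
      # per unit increase of t (movement of x_j away from its bound),
      # basic variables change by delta * t
      delta <- if (!atUpper[j]) -w else w
      ratios <- rep(Inf, m)
      hits <- rep(NA_character_, m)
      dn <- delta < -tol
      up <- delta > tol & is.finite(uFull[basis])
      ratios[dn] <- xB[dn] / (-delta[dn])
      hits[dn] <- "lower"
      ratios[up] <- (uFull[basis[up]] - xB[up]) / delta[up]
      hits[up] <- "upper"
      ratios <- pmax(ratios, 0)  # clamp tiny negative (degenerate) ratios
      minRatio <- min(ratios)
      tStar <- min(minRatio, uFull[j])
      if (!is.finite(tStar)) return(list(status = "unbounded"))
      if (uFull[j] < minRatio - tol) {
        atUpper[j] <- !atUpper[j]  # bound flip, basis unchanged
      } else {
        tied <- which(ratios <= minRatio + tol)
        leave <- tied[which.min(basis[tied])]  # Bland's leaving rule
        lv <- basis[leave]
        basis[leave] <- j
        atUpper[j] <- FALSE
        atUpper[lv] <- hits[leave] == "upper"
      }
    }
  }

  ph1 <- runSimplex(cPhase1, basis, atUpper, uFull)
  if (ph1$status != "optimal" || ph1$value > 1e-7)
    return(list(status = "infeasible"))
  # fix artificials at zero for phase 2 (handles redundant rows gracefully)
  uFull[n + seq_len(m)] <- 0
  atUpper <- ph1$atUpper
  atUpper[n + seq_len(m)] <- FALSE
  ph2 <- runSimplex(cPhase2, ph1$basis, atUpper, uFull)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  x <- ifelse(ph2$atUpper[seq_len(n)], u, 0)
  inB <- ph2$basis[ph2$basis <= n]
  x[inB] <- ph2$xB[ph2$basis <= n]
  x <- pmin(pmax(x, 0), u)
  v <- x + lb
  list(status = "optimal", x = v, value = sum(obj * v))
}

# Dense stoichiometric matrix (metabolites x reactions) of a model.
stoichMatrix <- function(model) {
  met <- model@metabolites$id
  rxn <- model@reactions
  S <- matrix(0, nrow = length(met), ncol = nrow(rxn),
              dimnames = list(met, rxn$id))
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[i]]
    S[names(s), i] <- s
  }
  S
}

#' Flux balance analysis
#'
#' Solves the linear program opt c'v subject to S v = 0 and lb <= v <= ub
#' with the package's deterministic bounded-variable simplex. When the
#' primary objective is optimal and `parsimonious = TRUE` (the default), a
#' secondary minimization of total absolute flux at the fixed optimum
#' resolves degenerate alternative optima, so boundary-flux profiles are
#' unique and reproducible.
#'
#' @param model a [MetabolicModel-class] (reconstruction or community
#'   model).
#' @param direction `"max"` (default) or `"min"` of the model objective.
#' @param parsimonious run the secondary total-flux minimization (default
#'   `TRUE`).
#' @param tol feasibility tolerance for the steady-state and bound checks
#'   (default 1e-6).
#' @return a [FluxSolution-class].
#' @examples
#' m <- chainModel()
#' objectiveValue(fba(m))  # 10: capacity-limited linear chain
#' @export
fba <- function(model, direction = c("max", "min"), parsimonious = TRUE,
                tol = 1e-6) {
  direction <- match.arg(direction)
  stopifnot(is(model, "MetabolicModel"))
  validObject(model)
  rxn <- model@reactions
  S <- stoichMatrix(model)
  obj <- rxn$objective
  lb <- rxn$lb
  ub <- rxn$ub
  sol <- solveLP(obj, S, rep(0, nrow(S)), lb, ub,
                 maximize = direction == "max")
  if (sol$status != "optimal")
    return(new("FluxSolution", status = sol$status, fluxes = numeric(0),
               objective = NA_real_, tolerance = tol))
  v <- sol$x
  if (parsimonious) {
    # minimize total |v| at the fixed optimum; negative parts are only
    # needed for reactions whose lower bound admits negative flux
    n <- length(v)
    zStar <- sol$value
    negIdx <- which(lb < 0)
    A2 <- rbind(cbind(S, -S[, negIdx, drop = FALSE]),
                c(obj, -obj[negIdx]))
    b2 <- c(rep(0, nrow(S)), zStar)
    lb2 <- c(pmax(lb, 0), pmax(-ub[negIdx], 0))
    ub2 <- c(pmax(ub, 0), -lb[negIdx])
    sol2 <- solveLP(rep(1, n + length(negIdx)), A2, b2, lb2, ub2,
                    maximize = FALSE)
    if (sol2$status == "optimal") {
      v <- sol2$x[seq_len(n)]
      v[negIdx] <- v[negIdx] - sol2$x[n + seq_along(negIdx)]
    }
  }
  resid <- max(abs(S %*% v))
  if (resid > tol || any(v < lb - 1e-6) || any(v > ub + 1e-6))
    stop(sprintf("solver returned an out-of-tolerance solution (|Sv| = %g)",
                 resid))
  names(v) <- rxn$id
  new("FluxSolution", status = "optimal", fluxes = v,
      objective = sum(obj * v), tolerance = tol)
}

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxSolution", function(x) x@fluxes)

#' @rdname accessors
#' @export
setMethod("solutionStatus", "FluxSolution", function(x) x@status)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxSolution", function(x) x@objective)

setMethod("show", "FluxSolution", function(object) {
  cat(sprintf("FluxSolution: %s", object@status))
  if (object@status == "optimal")
    cat(sprintf(", objective = %.6g, %d reactions", object@objective,
                length(object@fluxes)))
  cat("\n")
})

#' Net community exchange fluxes per extracellular metabolite
#'
#' Maps the exchange-reaction fluxes of an optimal solution to the
#' secretion-positive convention: positive values are net secretion of the
#' metabolite into the environment, negative values net consumption.
#' Extracellular metabolites without exchange activity report 0.
#'
#' @param solution an optimal [FluxSolution-class].
#' @param model the model that was solved.
#' @return named numeric vector, one entry per extracellular metabolite.
#' @export
boundaryFluxes <- function(solution, model) {
  stopifnot(is(solution, "FluxSolution"), is(model, "MetabolicModel"))
  if (solutionStatus(solution) != "optimal")
    stop("boundary fluxes require an optimal solution")
  met <- model@metabolites
  ext <- met$id[met$compartment == "extracellular"]
  out <- stats::setNames(rep(0, length(ext)), ext)
  rxn <- model@reactions
  v <- fluxes(solution)
  for (i in which(rxn$exchange)) {
    s <- rxn$stoich[[i]]
    # coefficient -1 means positive flux removes the metabolite from the
    # system, i.e. secretion; generalize to arbitrary coefficient sign
    out[names(s)] <- out[names(s)] + v[rxn$id[i]] * (-unname(s))
  }
  out
}
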