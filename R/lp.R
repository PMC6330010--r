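# Internal LP layer.
#
# All linear programs in the package go through lp_solve(): FVA, FBA, tope
# feasibility and conformal decomposition certificates. It wraps the two-phase
# tableau simplex of boot::simplex behind a bounded-variable interface:
#
#   optimize  obj' v   s.t.  Aeq v = beq,  Ale v <= ble,  lb <= v <= ub
#
# boot::simplex works on x >= 0 with nonnegative right-hand sides only, so
# variables are shifted by their (finite or artificially capped) lower bounds
# and constraint rows are routed to the <=, >= or = blocks with the sign of
# the right-hand side normalized. Infinite bounds are capped at `big`; an
# optimum that escapes beyond big/2 is reported as unbounded (the artificial
# box is four orders of magnitude above any desk-scale flux used here).

lp_solve <- function(obj, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                     lb, ub, maximize = FALSE, big = 1e6, eps = 1e-10,
                     .recheck = TRUE) {
  n <- length(obj)
  lbw <- pmax(lb, -big)
  ubw <- pmin(ub, big)
  if (any(lbw > ubw)) return(list(status = "infeasible"))
  if (!is.null(Aeq)) {
    Aeq <- matrix(Aeq, ncol = n)
    zero_row <- rowSums(Aeq != 0) == 0
    if (any(zero_row)) {
      if (any(abs(beq[zero_row]) > eps)) return(list(status = "infeasible"))
      Aeq <- Aeq[!zero_row, , drop = FALSE]
      beq <- beq[!zero_row]
      if (!nrow(Aeq)) { Aeq <- NULL; beq <- NULL }
    }
  }

  # shift: v = lbw + s, 0 <= s <= ubw - lbw
  A1 <- diag(n)
  b1 <- ubw - lbw
  if (!is.null(Ale)) {
    Ale <- matrix(Ale, ncol = n)
    A1 <- rbind(A1, Ale)
    b1 <- c(b1, ble - as.vector(Ale %*% lbw))
  }
  A2 <- NULL; b2 <- NULL
  neg <- b1 < 0
  if (any(neg)) {
    A2 <- -A1[neg, , drop = FALSE]
    b2 <- -b1[neg]
    A1 <- A1[!neg, , drop = FALSE]
    b1 <- b1[!neg]
  }
  A3 <- NULL; b3 <- NULL
  if (!is.null(Aeq)) {
    A3 <- matrix(Aeq, ncol = n)
    b3 <- beq - as.vector(A3 %*% lbw)
    negq <- b3 < 0
    A3[negq, ] <- -A3[negq, , drop = FALSE]
    b3[negq] <- -b3[negq]
  }

  res <- tryCatch(
    boot::simplex(a = obj,
                  A1 = if (nrow(A1)) A1 else NULL, b1 = if (nrow(A1)) b1 else NULL,
                  A2 = A2, b2 = b2, A3 = A3, b3 = b3,
                  maxi = maximize, eps = eps,
                  n.iter = 50L * (n + nrow(A1) + length(b2) + length(b3))),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    return(list(status = "solver_error", message = conditionMessage(res)))
  }
  if (res$solved == -1) return(list(status = "infeasible"))
  if (res$solved != 1) return(list(status = "maxiter"))

  v <- lbw + res$soln
  objval <- sum(obj * v)
  # hitting the artificial box on a direction whose true bound is infinite:
  # the optimum may only be an artifact of the cap, so re-solve once with a
  # wider box and compare — a growing objective certifies unboundedness
  at_cap <- (v > big / 2 & !is.finite(ub)) | (v < -big / 2 & !is.finite(lb))
  if (any(at_cap)) {
    if (any(obj[at_cap] != 0)) {
      return(list(status = "unbounded", v = v, at_cap = which(at_cap)))
    }
    if (.recheck) {
      res2 <- lp_solve(obj, Aeq, beq, Ale, ble, lb, ub, maximize,
                       big = 8 * big, eps = eps, .recheck = FALSE)
      if (res2$status == "unbounded") return(res2)
      if (res2$status == "ok" &&
          abs(res2$objval - objval) > 1e-6 * max(1, abs(objval))) {
        return(list(status = "unbounded", v = res2$v, at_cap = which(at_cap)))
      }
      if (res2$status == "ok") return(res2)
    }
  }
  list(status = "ok", objval = objval, v = v)
}

# Feasibility of a fully bounded system: Aeq v = beq, lb <= v <= ub (finite).
lp_feasible <- function(Aeq, beq, lb, ub, eps = 1e-10) {
  if (any(lb > ub)) return(list(feasible = FALSE))
  res <- lp_solve(rep(0, length(lb)), Aeq = Aeq, beq = beq,
                  lb = lb, ub = ub, eps = eps)
  if (res$status == "solver_error") {
    stop("LP solver failure: ", res$message, call. = FALSE)
  }
  if (res$status == "maxiter") {
    stop("LP solver iteration limit reached on feasibility check", call. = FALSE)
  }
  if (res$status != "ok") return(list(feasible = FALSE))
  list(feasible = TRUE, witness = res$v)
}
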