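#' Flux balance analysis
#'
#' Maximizes a linear objective `c' v` over the flux polyhedron
#' `N v = 0`, `lb <= v <= ub`.
#'
#' @param network A `metabolic_network` (its bounds define the polyhedron).
#' @param objective A reaction id, a numeric coefficient vector of length r,
#'   or `NULL` to use the network's stored objective.
#' @return An `fba_fit`: `list(objective_value, flux, objective)`.
#' @examples
#' toy <- with_bounds(toy_model(), ub = c(R1 = 10, R3 = 10))
#' fba(toy, "R2")$objective_value # 30
#' @export
fba <- function(network, objective = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  cc <- .resolve_objective(network, objective)
  res <- lp_solve(cc, Aeq = network$N, beq = rep(0, nrow(network$N)),
                  lb = network$lb, ub = network$ub, maximize = TRUE)
  if (res$status == "infeasible") stop("flux polyhedron is infeasible", call. = FALSE)
  if (res$status == "unbounded") {
    stop("objective unbounded; growth direction includes reaction(s) ",
         paste(network$reaction_ids[res$at_cap], collapse = ", "), call. = FALSE)
  }
  if (res$status != "ok") stop("LP failure in flux balance analysis (",
                               res$status, ")", call. = FALSE)
  structure(list(objective_value = res$objval,
                 flux = stats::setNames(res$v, network$reaction_ids),
                 objective = cc),
            class = "fba_fit")
}

#' @export
print.fba_fit <- function(x, ...) {
  cat(sprintf("<fba_fit> optimum %.6g over %d reactions\n",
              x$objective_value, length(x$flux)))
  invisible(x)
}

.resolve_objective <- function(network, objective) {
  r <- ncol(network$N)
  if (is.null(objective)) {
    if (is.null(network$objective)) stop("no objective given", call. = FALSE)
    return(network$objective)
  }
  if (is.character(objective)) {
    idx <- match(objective, network$reaction_ids)
    if (anyNA(idx)) stop("unknown reaction id: ", objective[is.na(idx)][1],
                         call. = FALSE)
    cc <- numeric(r); cc[idx] <- 1
    return(cc)
  }
  if (length(objective) != r) {
    stop("`objective` must have one coefficient per reaction", call. = FALSE)
  }
  as.numeric(objective)
}

#' The polyhedron of optimal fluxes
#'
#' Appends the optimality constraint `c' v = d_opt` (implemented as the
#' interval `d_opt - tol <= c' v <= d_opt` to absorb solver-level jitter) to
#' the flux polyhedron, then makes the resulting optimal polyhedron
#' consistent by flux variability analysis: reactions forced to zero flux at
#' the optimum are removed from the sign-vector alphabet (reported
#' separately), and reversible reactions that lost one direction become
#' irreversible (backward-only columns are negated and recorded in the
#' orientation).
#'
#' @param network A `metabolic_network`.
#' @param objective As in [fba()].
#' @param d_opt The attained optimum; computed by [fba()] when missing.
#' @param tol Equality tolerance; default `1e-6 * max(1, |d_opt|)`.
#' @return A `flux_polyhedron`: `list(network, extra_eq, d_opt, tol,
#'   objective, removed_at_optimum, fixed_forward, fixed_backward)`. The
#'   `network` covers surviving reactions only; `extra_eq` is the optimality
#'   constraint restricted to them.
#' @export
optimal_polyhedron <- function(network, objective = NULL, d_opt = NULL,
                               tol = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  cc <- .resolve_objective(network, objective)
  if (is.null(d_opt)) d_opt <- fba(network, cc)$objective_value
  if (is.null(tol)) tol <- 1e-6 * max(1, abs(d_opt))
  extra <- list(a = cc, b_lo = d_opt - tol, b_hi = d_opt)
  fva <- tryCatch(flux_variability(network, extra_eq = extra),
                  error = function(e) {
                    stop("optimality constraint infeasible at tolerance ", tol,
                         call. = FALSE)
                  })
  ftol <- 1e-6
  blocked <- abs(fva$min) < ftol & abs(fva$max) < ftol
  fix_f <- network$reversible & !blocked & fva$min > -ftol
  fix_b <- network$reversible & !blocked & fva$max < ftol
  keep <- !blocked
  N <- network$N[, keep, drop = FALSE]
  if (!ncol(N)) stop("all reactions are zero at the optimum", call. = FALSE)
  rev <- network$reversible[keep]
  lb <- network$lb[keep]; ub <- network$ub[keep]
  ori <- network$orientation[keep]
  ck <- cc[keep]
  f <- fix_f[keep]; b <- fix_b[keep]
  rev[f | b] <- FALSE
  lb[f] <- pmax(lb[f], 0)
  if (any(b)) {
    N[, b] <- -N[, b, drop = FALSE]
    tmp <- lb[b]; lb[b] <- pmax(-ub[b], 0); ub[b] <- -tmp
    ori[b] <- -ori[b]
    ck[b] <- -ck[b]
  }
  net2 <- metabolic_network(N, network$reaction_ids[keep],
                            network$metabolite_ids,
                            reversible = rev, lb = lb, ub = ub)
  net2$orientation <- ori
  structure(list(network = net2,
                 extra_eq = list(a = ck, b_lo = d_opt - tol, b_hi = d_opt),
                 d_opt = d_opt, tol = tol, objective = cc,
                 removed_at_optimum = network$reaction_ids[blocked],
                 fixed_forward = network$reaction_ids[fix_f],
                 fixed_backward = network$reaction_ids[fix_b]),
            class = "flux_polyhedron")
}

#' @export
print.flux_polyhedron <- function(x, ...) {
  cat(sprintf("<flux_polyhedron> optimum %.6g; %d reactions survive (%d reversible), %d zero at optimum\n",
              x$d_opt, ncol(x$network$N), sum(x$network$reversible),
              length(x$removed_at_optimum)))
  invisible(x)
}

#' Enumerate the flux topes of the optimal flux polyhedron
#'
#' Composes [fba()], [optimal_polyhedron()] and [enumerate_topes()] with the
#' optimality constraint carried inside every feasibility LP, so only
#' optimal topes are visited — without enumerating the (possibly much larger)
#' set of all cone topes first.
#'
#' @inheritParams optimal_polyhedron
#' @param ... Passed to [enumerate_topes()] (`max_level`, `limit`, `threads`,
#'   `lb_mag`, `ub_mag`).
#' @return A `tope_enumeration` over the surviving reactions, with the
#'   `flux_polyhedron` attached as `$optimality`.
#' @examples
#' toy <- with_bounds(toy_model(), ub = c(R1 = 10, R3 = 10))
#' enumerate_optimal_topes(toy, "R2") # two optimal topes
#' @export
enumerate_optimal_topes <- function(network, objective = NULL, d_opt = NULL,
                                    tol = NULL, ...) {
  poly <- optimal_polyhedron(network, objective, d_opt = d_opt, tol = tol)
  res <- enumerate_topes(poly$network, extra_eq = poly$extra_eq,
                         check_consistent = FALSE, ...)
  res$optimality <- poly
  res
}
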