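#' Flux variability analysis
#'
#' Minimizes and maximizes each reaction flux over the network's flux cone or
#' polyhedron (`N v = 0`, `lb <= v <= ub`), optionally under an extra
#' equality `a' v = b` (used for the optimal flux polyhedron). Directions
#' along which the problem is unbounded are reported as `-Inf`/`Inf`.
#'
#' @param network A `metabolic_network`.
#' @param extra_eq Optional extra linear constraint: `list(a, b)` for the
#'   equality `a' v = b`, or `list(a, b_lo, b_hi)` for the interval
#'   `b_lo <= a' v <= b_hi`.
#' @param big Artificial box used to detect unboundedness; fluxes beyond
#'   `big / 2` on an unbounded direction are reported infinite.
#' @return A tibble with columns `reaction`, `min`, `max`.
#' @examples
#' flux_variability(with_bounds(toy_model(), ub = c(R1 = 10, R3 = 10)))
#' @export
flux_variability <- function(network, extra_eq = NULL, big = 1e6) {
  stopifnot(inherits(network, "metabolic_network"))
  r <- ncol(network$N)
  Aeq <- network$N
  beq <- rep(0, nrow(network$N))
  Ale <- NULL; ble <- NULL
  if (!is.null(extra_eq)) {
    if (!is.null(extra_eq$b)) {
      Aeq <- rbind(Aeq, extra_eq$a)
      beq <- c(beq, extra_eq$b)
    } else {
      Ale <- rbind(extra_eq$a, -extra_eq$a)
      ble <- c(extra_eq$b_hi, -extra_eq$b_lo)
    }
  }
  lo <- numeric(r); hi <- numeric(r)
  for (i in seq_len(r)) {
    ei <- numeric(r); ei[i] <- 1
    for (dirn in c("min", "max")) {
      res <- lp_solve(ei, Aeq = Aeq, beq = beq, Ale = Ale, ble = ble,
                      lb = network$lb, ub = network$ub,
                      maximize = (dirn == "max"), big = big)
      val <- switch(res$status,
                    ok = res$objval,
                    unbounded = if (dirn == "max") Inf else -Inf,
                    infeasible = stop("constraint system infeasible",
                                      call. = FALSE),
                    stop("LP failure during flux variability analysis (",
                         res$status, ")", call. = FALSE))
      if (dirn == "min") lo[i] <- val else hi[i] <- val
    }
  }
  tibble::tibble(reaction = network$reaction_ids, min = lo, max = hi)
}

#' Make the flux cone consistent
#'
#' Removes all reactions that cannot carry nonzero steady-state flux and
#' converts reversible reactions that cannot carry flux in both directions
#' into irreversible ones. Backward-only reactions have their column negated
#' (recorded in the network's `orientation`, and inverted again in all
#' user-facing sign-vector output). Idempotent: applying it to a consistent
#' network returns it unchanged with an empty report.
#'
#' @param network A `metabolic_network`.
#' @param tol Feasibility threshold: a direction with `|flux| < tol` over the
#'   whole cone is unusable. Default 1e-6, the LP flux lower bound used by
#'   tope feasibility checks, so blocked-detection and tope feasibility work
#'   on the same scale.
#' @return `list(network, report)` where `report` has fields `removed`,
#'   `fixed_forward`, `fixed_backward`, `n_before`, `n_after`.
#' @export
make_consistent <- function(network, tol = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  removed <- character(0); fwd <- character(0); bwd <- character(0)
  n_before <- ncol(network$N)
  repeat {
    fva <- flux_variability(network)
    blocked <- abs(fva$min) < tol & abs(fva$max) < tol
    fix_f <- network$reversible & !blocked & fva$min > -tol
    fix_b <- network$reversible & !blocked & fva$max < tol
    if (!any(blocked | fix_f | fix_b)) break
    removed <- c(removed, network$reaction_ids[blocked])
    fwd <- c(fwd, network$reaction_ids[fix_f])
    bwd <- c(bwd, network$reaction_ids[fix_b])
    keep <- !blocked
    N <- network$N[, keep, drop = FALSE]
    rev <- network$reversible[keep]
    lb <- network$lb[keep]; ub <- network$ub[keep]
    ori <- network$orientation[keep]
    obj <- if (is.null(network$objective)) NULL else network$objective[keep]
    f <- fix_f[keep]; b <- fix_b[keep]
    rev[f | b] <- FALSE
    lb[f] <- pmax(lb[f], 0)
    # negate backward-only columns so their usable direction is forward
    if (any(b)) {
      N[, b] <- -N[, b, drop = FALSE]
      tmp <- lb[b]; lb[b] <- pmax(-ub[b], 0); ub[b] <- -tmp
      ori[b] <- -ori[b]
      if (!is.null(obj)) obj[b] <- -obj[b]
    }
    if (!ncol(N)) stop("all reactions are blocked; empty model", call. = FALSE)
    # removing blocked reactions can orphan metabolites (all-zero rows)
    live <- rowSums(N != 0) > 0
    N <- N[live, , drop = FALSE]
    net2 <- metabolic_network(N, network$reaction_ids[keep],
                              network$metabolite_ids[live],
                              reversible = rev, lb = lb, ub = ub,
                              objective = obj)
    net2$orientation <- ori
    network <- net2
  }
  list(network = network,
       report = list(removed = removed, fixed_forward = fwd,
                     fixed_backward = bwd,
                     n_before = n_before, n_after = ncol(network$N)))
}

#' Is the flux cone consistent?
#'
#' @param network A `metabolic_network`.
#' @param tol Feasibility threshold as in [make_consistent()].
#' @return Logical scalar: `TRUE` when no reaction is blocked and every
#'   reversible reaction can carry flux in both directions.
#' @export
is_consistent <- function(network, tol = 1e-6) {
  fva <- tryCatch(flux_variability(network), error = function(e) NULL)
  if (is.null(fva)) return(FALSE)
  all(fva$max > tol) && all(fva$min[network$reversible] < -tol)
}

#' Nullspace basis of a stoichiometric matrix
#'
#' Computes `K` with `N K = 0` and `rank(K) = d = r - rank(N)`. For integer
#' or rational `N` the basis is computed by exact fraction-free elimination
#' (rows are scaled to integers first), removing any rank ambiguity; other
#' matrices fall back to the floating-point nullspace of \pkg{pracma} with a
#' relative rank tolerance of `1e-9 * sigma_max`.
#'
#' @param N Stoichiometric matrix (or a `metabolic_network`).
#' @param pivots Optional indices of `d` reactions whose rows of `K` should
#'   form the identity (the free flux coordinates `v = K x`,
#'   `x = v[pivots]`). Must select linearly independent rows.
#' @return An r x d matrix `K`; attribute `"exact"` says whether the exact
#'   path was taken.
#' @examples
#' K <- nullspace_basis(toy_model()$N, pivots = c(1, 2, 4))
#' K[c(1, 2, 4), ] # identity
#' @export
nullspace_basis <- function(N, pivots = NULL) {
  if (inherits(N, "metabolic_network")) N <- N$N
  N <- as.matrix(N)
  if (all(N == 0)) stop("stoichiometric matrix is zero", call. = FALSE)
  Ni <- .integerize_rows(N)
  if (!is.null(Ni)) {
    K <- .int_nullspace(Ni)
    exact <- TRUE
  } else {
    K <- pracma::nullspace(N)
    if (is.null(K)) K <- matrix(0, ncol(N), 0)
    exact <- FALSE
  }
  d <- ncol(K)
  if (d == 0) stop("trivial nullspace: the network admits no nonzero flux",
                   call. = FALSE)
  if (!is.null(pivots)) {
    if (length(pivots) != d) {
      stop("`pivots` must select exactly d = ", d, " reactions", call. = FALSE)
    }
    B <- K[pivots, , drop = FALSE]
    if (abs(det(B)) < 1e-12) {
      stop("selected pivot rows are linearly dependent", call. = FALSE)
    }
    K <- K %*% solve(B)
    K[abs(K) < 1e-12] <- 0
  }
  structure(K, exact = exact)
}

#' Detect dependent reactions from the nullspace basis
#'
#' Two reactions whose rows of `K` are scalar multiples carry proportional
#' flux in every flux mode and hence flip direction in lockstep. Rows are
#' partitioned into independent representatives (first occurrence in reaction
#' order) and dependents, each with the sign of its scalar multiplier.
#'
#' @param K Nullspace basis matrix (rows = reactions).
#' @param tol Proportionality tolerance: rows i, j are multiples when all
#'   2 x 2 minors of their row pair are below `tol` after normalizing each
#'   row to unit maximum entry (scale-invariant).
#' @return A `reaction_dependency` list with fields `independent` (indices),
#'   `dependent` (tibble: `index`, `rep`, `sign`), `r_ind`, and `class`
#'   (the representative index for every reaction).
#' @export
reaction_dependencies <- function(K, tol = 1e-9) {
  K <- as.matrix(K)
  r <- nrow(K)
  norms <- apply(abs(K), 1, max)
  if (any(norms == 0)) {
    stop("zero row in nullspace basis: reaction ",
         which(norms == 0)[1],
         " is blocked; run make_consistent first", call. = FALSE)
  }
  Kn <- K / norms
  rep_of <- integer(r); sgn <- integer(r)
  reps <- integer(0)
  for (i in seq_len(r)) {
    found <- 0L
    for (j in reps) {
      # all 2x2 minors of rows (j, i) below tol <=> proportional
      minors <- outer(Kn[j, ], Kn[i, ]) - outer(Kn[i, ], Kn[j, ])
      if (max(abs(minors)) < tol) { found <- j; break }
    }
    if (found) {
      rep_of[i] <- found
      k <- which.max(abs(Kn[found, ]))
      sgn[i] <- if (Kn[found, k] * Kn[i, k] > 0) 1L else -1L
    } else {
      reps <- c(reps, i)
      rep_of[i] <- i
      sgn[i] <- 1L
    }
  }
  dep <- setdiff(seq_len(r), reps)
  structure(list(independent = reps,
                 dependent = tibble::tibble(index = dep,
                                            rep = rep_of[dep],
                                            sign = sgn[dep]),
                 r_ind = length(reps),
                 class = rep_of,
                 coupling_sign = sgn),
            class = "reaction_dependency")
}

#' @export
print.reaction_dependency <- function(x, ...) {
  cat(sprintf("<reaction_dependency> %d independent, %d dependent reactions\n",
              x$r_ind, nrow(x$dependent)))
  invisible(x)
}

#' Initial flux tope of a consistent network
#'
#' In a consistent flux cone every reaction is supported by a flux mode with
#' full support; the sign vector of such a flux defines a tope, and flipping
#' the reversible reactions with a minus entry re-orients it to all-plus. The
#' full-support witness is built constructively by conformal combination of
#' single-reaction feasibility witnesses, then certified by the tope
#' feasibility LP.
#'
#' @param network A consistent `metabolic_network`.
#' @param lb_mag,ub_mag LP flux magnitude bounds for the certificate, see
#'   [check_tope_feasible()].
#' @param extra_eq Optional `list(a, b_lo, b_hi)` interval constraint
#'   `b_lo <= a' v <= b_hi`, honored by the witness (used for optimality).
#' @return `list(tau, flips, witness)`: the tope sign vector (all `+1` except
#'   at `flips`), the indices of reversible reactions used backward, and the
#'   witness flux.
#' @export
initial_tope <- function(network, lb_mag = 1e-6, ub_mag = 1e3, extra_eq = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  r <- ncol(network$N)
  # the all-plus orientation often survives preprocessing; try it first
  direct <- check_tope_feasible(network, rep(1L, r), lb_mag = lb_mag,
                                ub_mag = ub_mag, extra_eq = extra_eq)
  if (direct$feasible) {
    return(list(tau = rep(1L, r), flips = integer(0), witness = direct$witness))
  }
  Ale <- NULL; ble <- NULL
  if (!is.null(extra_eq)) {
    Ale <- rbind(extra_eq$a, -extra_eq$a)
    ble <- c(extra_eq$b_hi, -extra_eq$b_lo)
  }
  v <- numeric(r)
  eps <- 1e-9
  for (i in seq_len(r)) {
    if (abs(v[i]) > eps) next
    ei <- numeric(r); ei[i] <- 1
    res <- lp_solve(ei, Aeq = network$N, beq = rep(0, nrow(network$N)),
                    Ale = Ale, ble = ble,
                    lb = network$lb, ub = pmin(network$ub, 1e3),
                    maximize = TRUE)
    if (res$status != "ok" || res$v[i] <= eps) {
      # reversible reactions may only support backward flux here
      res <- lp_solve(ei, Aeq = network$N, beq = rep(0, nrow(network$N)),
                      Ale = Ale, ble = ble,
                      lb = pmax(network$lb, -1e3), ub = network$ub,
                      maximize = FALSE)
      if (res$status != "ok" || abs(res$v[i]) <= eps) {
        stop("no flux supports reaction ", network$reaction_ids[i],
             ": network is inconsistent; run make_consistent first",
             call. = FALSE)
      }
    }
    w <- res$v
    if (all(abs(v) <= eps)) {
      v <- w
    } else {
      # convex combination preserves steady state, bounds and any extra
      # (inhomogeneous) constraint, and small lambda preserves settled signs
      opp <- which(v * w < 0 & abs(v) > eps)
      lam <- if (length(opp)) {
        0.5 * min(0.5, min(abs(v[opp]) / (abs(v[opp]) + abs(w[opp]))))
      } else 0.5
      v <- (1 - lam) * v + lam * w
    }
  }
  tau <- ifelse(v > 0, 1L, -1L)
  if (any(tau < 0 & !network$reversible)) {
    stop("irreversible reaction forced backward; inconsistent network",
         call. = FALSE)
  }
  chk <- check_tope_feasible(network, tau, lb_mag = lb_mag, ub_mag = ub_mag,
                             extra_eq = extra_eq)
  if (!chk$feasible) {
    stop("failed to certify an initial full-support tope; ",
         "network appears inconsistent", call. = FALSE)
  }
  list(tau = tau, flips = which(tau < 0), witness = chk$witness)
}
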