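#' LP feasibility of a full sign vector
#'
#' A full sign vector `tau` over \{-1, +1\} defines a flux tope exactly when
#' the LP  `N v = 0`, `lb_mag <= tau_i v_i <= ub_mag` (intersected with the
#' network's own bounds) is feasible. The LP is solved on the sparse
#' stoichiometric matrix directly, in the variables `w_i = tau_i v_i`.
#'
#' @param network A `metabolic_network`.
#' @param tau Integer vector over \{-1, +1\}, one entry per reaction, `+1` at
#'   every irreversible position.
#' @param lb_mag,ub_mag Flux magnitude bounds of the feasibility LP. The
#'   defaults 1e-6 and 1e3 bound every flux away from zero and from
#'   numerically harmful magnitudes.
#' @param extra_eq Optional `list(a, b_lo, b_hi)` adding
#'   `b_lo <= a' v <= b_hi` (used for optimality constraints).
#' @param lp_tol Solver feasibility tolerance (default 1e-10); must not
#'   exceed `lb_mag / 10` so feasibility and the flux floor stay separated.
#' @return `list(feasible, witness)`; `witness` is a flux vector with
#'   `sign_of(witness)` conforming to `tau` when feasible, otherwise `NULL`.
#' @examples
#' check_tope_feasible(toy_model(), c(1L, 1L, 1L, 1L, 1L, 1L))$feasible
#' @export
check_tope_feasible <- function(network, tau, lb_mag = 1e-6, ub_mag = 1e3,
                                extra_eq = NULL, lp_tol = 1e-10) {
  stopifnot(inherits(network, "metabolic_network"))
  r <- ncol(network$N)
  if (length(tau) != r) stop("`tau` must have one entry per reaction", call. = FALSE)
  if (!all(tau %in% c(-1L, 1L))) {
    stop("`tau` must be a full sign vector over {-1, +1}", call. = FALSE)
  }
  if (any(tau < 0 & !network$reversible)) {
    stop("`tau` must be + at every irreversible position", call. = FALSE)
  }
  if (!(lb_mag > 0 && lb_mag < ub_mag)) stop("need 0 < lb_mag < ub_mag", call. = FALSE)
  if (!(lp_tol > 0 && lp_tol <= lb_mag / 10)) {
    stop("need 0 < lp_tol <= lb_mag / 10", call. = FALSE)
  }
  # bounds in w = tau * v coordinates
  lo <- pmax(lb_mag, ifelse(tau > 0, network$lb, -network$ub))
  hi <- pmin(ub_mag, ifelse(tau > 0, network$ub, -network$lb))
  if (any(lo > hi)) return(list(feasible = FALSE, witness = NULL))
  Aw <- network$N * rep(tau, each = nrow(network$N))
  Ale <- NULL; ble <- NULL
  if (!is.null(extra_eq)) {
    aw <- extra_eq$a * tau
    Ale <- rbind(aw, -aw)
    ble <- c(extra_eq$b_hi, -extra_eq$b_lo)
  }
  res <- lp_solve(rep(0, r), Aeq = Aw, beq = rep(0, nrow(Aw)),
                  Ale = Ale, ble = ble, lb = lo, ub = hi, eps = lp_tol)
  if (res$status == "solver_error") {
    stop("LP solver failure on sign vector ", sign_to_string(as.integer(tau)),
         ": ", res$message, call. = FALSE)
  }
  if (res$status != "ok") return(list(feasible = FALSE, witness = NULL))
  list(feasible = TRUE, witness = tau * res$v)
}

#' Child sign vectors of a tope in the breadth-first search
#'
#' For each independent reversible reaction currently oriented with the root,
#' returns the sign vector with that reaction — and its whole dependency
#' class, which flips in lockstep — reversed. Children therefore have exactly
#' one more minus entry among independent reversible reactions.
#'
#' @param tau Full sign vector (\{-1, +1\}, one entry per reaction).
#' @param deps A `reaction_dependency` from [reaction_dependencies()].
#' @param reversible Logical vector of reversibility flags.
#' @param root Reference orientation (default all `+1`); only positions where
#'   `tau` still agrees with `root` are flipped.
#' @return List of child sign vectors.
#' @export
children <- function(tau, deps, reversible, root = rep(1L, length(tau))) {
  indrev <- intersect(deps$independent, which(reversible))
  out <- list()
  for (i in indrev) {
    if (tau[i] == root[i]) {
      child <- tau
      members <- which(deps$class == i)
      child[members] <- -child[members]
      out[[length(out) + 1L]] <- child
    }
  }
  out
}

#' Are two topes adjacent?
#'
#' Two full sign vectors are adjacent when they differ in exactly one
#' independent reversible position; dependent reactions flip in lockstep with
#' their representative and do not count separately.
#'
#' @param t1,t2 Full sign vectors of equal length.
#' @param indrev Indices of independent reversible reactions (default: all
#'   positions).
#' @return Logical scalar.
#' @export
are_adjacent <- function(t1, t2, indrev = seq_along(t1)) {
  if (length(t1) != length(t2)) stop("sign vectors differ in length", call. = FALSE)
  sum(t1[indrev] != t2[indrev]) == 1L
}

#' Enumerate all flux topes of a consistent network
#'
#' Breadth-first search over full sign vectors: level `n` visits all sign
#' vectors with `n` minus entries (relative to the initial tope) among
#' independent reversible reactions that are children of feasible level
#' `n - 1` sign vectors. Each candidate is LP-checked at most once (a visited
#' table keyed on the packed bit pattern of independent reversible signs
#' caches the outcome). The search terminates when a level yields no feasible
#' sign vector or when `n` reaches the number of independent reversible
#' reactions.
#'
#' @param network A consistent `metabolic_network` (see [make_consistent()]).
#' @param max_level Stop after this BFS level (partial result,
#'   `complete = FALSE` if topes may remain).
#' @param limit Stop once this many topes have been found (partial result).
#' @param threads Worker count for the per-level feasibility checks
#'   (`parallel::mclapply`); the returned tope set is identical for any
#'   thread count, and rows are reported in canonical (BFS level, then
#'   lexicographic) order.
#' @param check_consistent Verify consistency first (2r LPs) and fail with a
#'   pointer to [make_consistent()] if it does not hold.
#' @inheritParams check_tope_feasible
#' @return A `tope_enumeration` object: `topes` (\{-1, +1\} matrix in the
#'   model's original reaction orientation, one row per tope), `levels`,
#'   `parents`, `witnesses`, `incremental_counts`, `lp_checks`, `complete`,
#'   plus the network, dependency structure and independent reversible index
#'   set used. See [tidy.tope_enumeration()].
#' @examples
#' enumerate_topes(toy_model())
#' @export
enumerate_topes <- function(network, max_level = Inf, limit = Inf, threads = 1L,
                            lb_mag = 1e-6, ub_mag = 1e3, extra_eq = NULL,
                            lp_tol = 1e-10, check_consistent = TRUE) {
  stopifnot(inherits(network, "metabolic_network"))
  if (check_consistent && !is_consistent(network)) {
    stop("network is not consistent; run make_consistent() first", call. = FALSE)
  }
  r <- ncol(network$N)
  K <- nullspace_basis(network$N)
  deps <- reaction_dependencies(K)
  indrev <- intersect(deps$independent, which(network$reversible))
  root <- initial_tope(network, lb_mag = lb_mag, ub_mag = ub_mag,
                       extra_eq = extra_eq)
  tau0 <- root$tau

  visited <- new.env(hash = TRUE, parent = emptyenv())
  lp_checks <- 1L
  topes <- list(tau0)
  witnesses <- list(root$witness)
  levels <- 0L
  parents <- NA_integer_
  incremental <- c(`0` = 1L)
  frontier_tau <- list(tau0)
  frontier_idx <- 1L
  assign(.sign_key(tau0 * tau0, indrev), TRUE, envir = visited) # root key (all +)

  complete <- TRUE
  n <- 0L
  n_max <- length(indrev)
  check_fun <- function(tau) check_tope_feasible(network, tau, lb_mag, ub_mag,
                                                 extra_eq, lp_tol = lp_tol)
  while (length(frontier_tau) > 0 && n < n_max) {
    n <- n + 1L
    if (n > max_level) { complete <- FALSE; break }
    # collect unvisited children of all parents, first discovering parent wins
    cand_tau <- list(); cand_parent <- integer(0); seen_keys <- character(0)
    for (p in seq_along(frontier_tau)) {
      kids <- children(frontier_tau[[p]], deps, network$reversible, root = tau0)
      for (child in kids) {
        key <- .sign_key(child * tau0, indrev)
        if (!is.null(visited[[key]]) || key %in% seen_keys) next
        seen_keys <- c(seen_keys, key)
        cand_tau[[length(cand_tau) + 1L]] <- child
        cand_parent <- c(cand_parent, frontier_idx[p])
      }
    }
    if (!length(cand_tau)) break
    ord <- order(vapply(cand_tau, function(t) .sign_key(t * tau0, indrev), ""))
    cand_tau <- cand_tau[ord]; cand_parent <- cand_parent[ord]
    feas <- if (threads > 1L) {
      parallel::mclapply(cand_tau, check_fun, mc.cores = threads)
    } else {
      lapply(cand_tau, check_fun)
    }
    lp_checks <- lp_checks + length(cand_tau)
    ok <- vapply(feas, function(x) x$feasible, TRUE)
    for (k in seq_along(cand_tau)) {
      assign(.sign_key(cand_tau[[k]] * tau0, indrev), ok[k], envir = visited)
    }
    new_idx <- integer(0)
    for (k in which(ok)) {
      topes[[length(topes) + 1L]] <- cand_tau[[k]]
      witnesses[[length(witnesses) + 1L]] <- feas[[k]]$witness
      levels <- c(levels, n)
      parents <- c(parents, cand_parent[k])
      new_idx <- c(new_idx, length(topes))
    }
    incremental[as.character(n)] <- sum(ok)
    frontier_tau <- cand_tau[ok]
    frontier_idx <- new_idx
    if (length(topes) >= limit) {
      if (n < n_max && length(frontier_tau) > 0) complete <- FALSE
      break
    }
  }
  M_net <- do.call(rbind, topes)
  # report sign vectors in the model's original orientation
  M <- M_net * rep(network$orientation, each = nrow(M_net))
  storage.mode(M) <- "integer"
  colnames(M) <- colnames(M_net) <- network$reaction_ids
  W <- do.call(rbind, witnesses) * rep(network$orientation, each = nrow(M_net))
  colnames(W) <- network$reaction_ids
  structure(list(topes = M, topes_net = M_net, witnesses = W,
                 levels = levels, parents = parents,
                 incremental_counts = incremental,
                 lp_checks = lp_checks, complete = complete,
                 reaction_ids = network$reaction_ids,
                 indrev = indrev, deps = deps, root = tau0,
                 network = network),
            class = "tope_enumeration")
}

#' @export
print.tope_enumeration <- function(x, ...) {
  cat(sprintf("<tope_enumeration> %d topes over %d reactions (%d independent reversible)%s\n",
              nrow(x$topes), length(x$reaction_ids), length(x$indrev),
              if (x$complete) "" else " [partial]"))
  cat("  incremental counts by level:",
      paste(sprintf("%s:%d", names(x$incremental_counts), x$incremental_counts),
            collapse = " "), "\n")
  invisible(x)
}
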