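# Double description in exact integer arithmetic.
#
# Extreme rays of the pointed cone {x in R^d : A x >= 0} for an integer
# matrix A of full column rank. Incremental DD: start from a nonsingular
# d-row subsystem (rays = columns of the adjugate), insert the remaining
# inequalities one at a time ("most zeros first"), combine adjacent
# positive/negative ray pairs, gcd-reduce every ray. Adjacency is decided by
# the combinatorial test (no third ray's zero set contains the pair's common
# zero set), which is exact for pointed cones.
.dd_rays <- function(A) {
  d <- ncol(A); r <- nrow(A)
  if (d == 0L) return(matrix(0, 0, 0))
  # initial nonsingular subsystem
  sel <- integer(0)
  for (i in seq_len(r)) {
    if (length(sel) == d) break
    if (.int_rank(A[c(sel, i), , drop = FALSE]) > length(sel)) sel <- c(sel, i)
  }
  if (length(sel) < d) stop("constraint matrix is rank deficient; cone is not pointed",
                            call. = FALSE)
  B <- A[sel, , drop = FALSE]
  dB <- det(B)
  Rays <- round(solve(B) * dB)
  if (max(abs(B %*% Rays - diag(dB, d))) > 0.5) {
    stop("integer adjugate verification failed", call. = FALSE)
  }
  if (dB < 0) Rays <- -Rays
  rays <- lapply(seq_len(d), function(j) .reduce_int(Rays[, j]))
  processed <- sel
  todo <- setdiff(seq_len(r), sel)
  todo <- todo[order(rowSums(A[todo, , drop = FALSE] != 0))] # most zeros first
  for (i in todo) {
    RM <- do.call(rbind, rays)
    s <- as.vector(RM %*% A[i, ])
    if (all(s >= 0)) { processed <- c(processed, i); next }
    Z <- abs(RM %*% t(A[processed, , drop = FALSE])) == 0
    pos <- which(s > 0); neg <- which(s < 0)
    new <- list()
    for (p in pos) for (q in neg) {
      zpn <- Z[p, ] & Z[q, ]
      adjacent <- TRUE
      for (t in seq_along(rays)) {
        if (t != p && t != q && all(Z[t, zpn])) { adjacent <- FALSE; break }
      }
      if (adjacent) {
        new[[length(new) + 1L]] <- .reduce_int(s[p] * rays[[q]] - s[q] * rays[[p]])
      }
    }
    rays <- c(rays[s >= 0], new)
    keys <- vapply(rays, paste, "", collapse = ",")
    rays <- rays[!duplicated(keys)]
    processed <- c(processed, i)
  }
  do.call(rbind, rays)
}

.efm_canonical <- function(v) {
  v <- .reduce_int(v)
  v
}

#' Enumerate the elementary flux modes of one flux tope
#'
#' Within a tope all reaction directions are fixed, so the tope is a pointed
#' cone `{v : N v = 0, tau_i v_i >= 0}` whose extreme rays are exactly the
#' EFMs conforming to `tau`. Columns are oriented by `tau`, every reaction is
#' treated as irreversible, and the double description method runs in the
#' nullspace representation — without reaction splitting, so the problem
#' dimension never grows. All arithmetic is exact (integer).
#'
#' @param network A `metabolic_network` with rational stoichiometry.
#' @param tau Full sign vector (\{-1, +1\}) defining the tope, in the
#'   network's reaction orientation.
#' @param check Verify that `tau` is LP-feasible first.
#' @return An `efm_set`: `efms` is an integer matrix, one row per EFM in
#'   canonical normalization (coprime integer entries, oriented by `tau`),
#'   columns named by reaction.
#' @examples
#' nrow(enumerate_efms_in_tope(toy_model(), rep(1L, 6))$efms) # 3
#' @export
enumerate_efms_in_tope <- function(network, tau, check = TRUE) {
  stopifnot(inherits(network, "metabolic_network"))
  r <- ncol(network$N)
  if (length(tau) != r || !all(tau %in% c(-1L, 1L))) {
    stop("`tau` must be a full sign vector over {-1, +1}", call. = FALSE)
  }
  if (check) {
    chk <- check_tope_feasible(network, tau)
    if (!chk$feasible) stop("`tau` is not a feasible tope sign vector", call. = FALSE)
  }
  Ni <- .integerize_rows(network$N)
  if (is.null(Ni)) {
    stop("EFM enumeration requires rational stoichiometric coefficients",
         call. = FALSE)
  }
  Nt <- Ni * rep(tau, each = nrow(Ni))
  K <- .int_nullspace(Nt)
  if (!ncol(K)) stop("trivial nullspace: the network admits no nonzero flux",
                     call. = FALSE)
  X <- .dd_rays(K) # extreme rays in nullspace coordinates
  W <- X %*% t(K)  # oriented fluxes, one row per ray, all >= 0
  if (nrow(W) && min(W) < 0) stop("double description produced an infeasible ray",
                                  call. = FALSE)
  E <- W * rep(tau, each = nrow(W))
  E <- t(apply(E, 1, .efm_canonical))
  E <- E[!duplicated(apply(E, 1, paste, collapse = ",")), , drop = FALSE]
  colnames(E) <- network$reaction_ids
  structure(list(efms = E, tope = tau, reaction_ids = network$reaction_ids),
            class = "efm_set")
}

#' @export
print.efm_set <- function(x, ...) {
  lab <- if (is.character(x$tope)) x$tope else sign_to_string(as.integer(x$tope))
  cat(sprintf("<efm_set> %d EFMs over %d reactions (tope: %s)\n",
              nrow(x$efms), length(x$reaction_ids), lab))
  invisible(x)
}

#' Enumerate all elementary flux modes through the tope decomposition
#'
#' The flux cone is the union of its topes, so enumerating the EFMs of every
#' tope and deduplicating (by the canonical coprime-integer normalization —
#' sign patterns alone are not sufficient since distinct EFMs can share
#' support) yields the global EFM set. EFMs conforming to several topes are
#' enumerated once per containing tope; the `duplication_factor` reports the
#' resulting redundancy.
#'
#' @param network A consistent `metabolic_network`.
#' @param topes Optional precomputed `tope_enumeration`; computed when absent.
#' @param ... Passed to [enumerate_topes()].
#' @return An `efm_set` with `tope = "global"` plus fields `per_tope` (list
#'   of per-tope EFM row indices into `efms`), `containment` (tibble: `efm`,
#'   `n_topes`), `duplication_factor` and the `tope_enumeration` used.
#' @examples
#' nrow(enumerate_efms_via_topes(toy_model())$efms) # 6
#' @export
enumerate_efms_via_topes <- function(network, topes = NULL, ...) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(topes)) topes <- enumerate_topes(network, ...)
  if (!topes$complete) stop("tope enumeration is partial; global EFM set undefined",
                            call. = FALSE)
  net <- topes$network
  seen <- new.env(hash = TRUE, parent = emptyenv())
  efms <- list()
  per_tope <- vector("list", nrow(topes$topes_net))
  slot_total <- 0L
  for (t in seq_len(nrow(topes$topes_net))) {
    es <- enumerate_efms_in_tope(net, topes$topes_net[t, ], check = FALSE)
    # map back to the model's original orientation
    E <- es$efms * rep(net$orientation, each = nrow(es$efms))
    idx <- integer(nrow(E))
    for (k in seq_len(nrow(E))) {
      key <- paste(E[k, ], collapse = ",")
      hit <- seen[[key]]
      if (is.null(hit)) {
        efms[[length(efms) + 1L]] <- E[k, ]
        hit <- length(efms)
        assign(key, hit, envir = seen)
      }
      idx[k] <- hit
    }
    per_tope[[t]] <- idx
    slot_total <- slot_total + length(idx)
  }
  E <- do.call(rbind, efms)
  colnames(E) <- net$reaction_ids
  containment <- tibble::tibble(
    efm = seq_len(nrow(E)),
    n_topes = vapply(seq_len(nrow(E)),
                     function(k) sum(vapply(per_tope, function(ix) k %in% ix, TRUE)),
                     1L))
  structure(list(efms = E, tope = "global", reaction_ids = net$reaction_ids,
                 per_tope = per_tope, containment = containment,
                 duplication_factor = slot_total / nrow(E),
                 topes = topes),
            class = "efm_set")
}

#' Certify a conformal decomposition of a flux mode
#'
#' Every flux mode can be written as a conformal sum of EFMs: nonnegative
#' coefficients over EFMs that each conform to the flux (no component used
#' with opposite sign). The certificate is found by LP, minimizing the
#' residual of the decomposition restricted to conformal EFMs.
#'
#' @param v A flux vector in the cone (`N v ~ 0`, irreversibilities
#'   respected); violating inputs raise an error.
#' @param efms An `efm_set` (typically of `v`'s tope or the global set).
#' @param network Optional `metabolic_network` used to validate `v`.
#' @param tol Residual tolerance relative to `max(1, max(abs(v)))`.
#' @return `list(ok, coefficients, residual)`; `coefficients` is named by EFM
#'   row index, nonzero only on EFMs conformal to `v`.
#' @export
conformal_decomposition_check <- function(v, efms, network = NULL, tol = 1e-6) {
  stopifnot(inherits(efms, "efm_set"))
  r <- length(v)
  if (!is.null(network)) {
    if (max(abs(network$N %*% v)) > tol * max(1, max(abs(v)))) {
      stop("`v` violates steady state; not a flux mode", call. = FALSE)
    }
    if (any(v < -tol & !network$reversible)) {
      stop("`v` violates irreversibility; not a flux mode", call. = FALSE)
    }
  }
  if (max(abs(v)) <= tol) {
    return(list(ok = TRUE, coefficients = numeric(0), residual = 0))
  }
  E <- efms$efms
  conf <- which(vapply(seq_len(nrow(E)), function(k) is_conformal(E[k, ], v), TRUE))
  if (!length(conf)) return(list(ok = FALSE, coefficients = numeric(0),
                                 residual = Inf))
  Ec <- t(E[conf, , drop = FALSE]) # r x nE
  nE <- ncol(Ec)
  # minimize sum of residual slacks t+ + t- with Ec lambda + t+ - t- = v
  obj <- c(rep(0, nE), rep(1, 2 * r))
  Aeq <- cbind(Ec, diag(r), -diag(r))
  res <- lp_solve(obj, Aeq = Aeq, beq = v,
                  lb = rep(0, nE + 2 * r), ub = rep(Inf, nE + 2 * r),
                  maximize = FALSE)
  if (res$status != "ok") return(list(ok = FALSE, coefficients = numeric(0),
                                      residual = Inf))
  lam <- stats::setNames(res$v[seq_len(nE)], conf)
  residual <- res$objval
  list(ok = residual < tol * max(1, max(abs(v))), coefficients = lam,
       residual = residual)
}

#' Verify the duality between flux topes and maximal conformal EFM sets
#'
#' For a network small enough for global EFM enumeration, checks that
#' (a) each tope's EFM set is exactly the subset of global EFMs conforming to
#' the tope's sign vector, (b) each such set is maximally conformal (adding
#' any outside EFM breaks pairwise conformality with some member), and
#' (c) the union of the per-tope sets is the global set.
#'
#' @param network A consistent `metabolic_network`.
#' @param ... Passed to [enumerate_efms_via_topes()].
#' @return A list with logical fields `conforming_exact`,
#'   `maximal_conformal`, `union_equals_global`, overall `ok`, and a
#'   `violations` character vector describing any failures.
#' @export
verify_tope_efm_duality <- function(network, ...) {
  glob <- enumerate_efms_via_topes(network, ...)
  E <- glob$efms
  topes <- glob$topes$topes # original orientation, as are the EFMs
  violations <- character(0)
  conforming_exact <- TRUE; maximal_conformal <- TRUE
  for (t in seq_len(nrow(topes))) {
    tau <- topes[t, ]
    in_tope <- sort(glob$per_tope[[t]])
    conf <- which(vapply(seq_len(nrow(E)),
                         function(k) conforms(sign_of(E[k, ]), as.integer(tau)),
                         TRUE))
    if (!identical(in_tope, conf)) {
      conforming_exact <- FALSE
      violations <- c(violations, sprintf(
        "tope %s: enumerated EFMs differ from conforming subset",
        sign_to_string(as.integer(tau))))
    }
    for (k in setdiff(seq_len(nrow(E)), in_tope)) {
      clash <- any(vapply(in_tope,
                          function(j) !is_conformal(E[k, ], E[j, ]), TRUE))
      if (!clash) {
        maximal_conformal <- FALSE
        violations <- c(violations, sprintf(
          "tope %s: EFM %d extends the set conformally",
          sign_to_string(as.integer(tau)), k))
      }
    }
  }
  union_idx <- sort(unique(unlist(glob$per_tope)))
  union_equals_global <- identical(union_idx, seq_len(nrow(E)))
  if (!union_equals_global) {
    violations <- c(violations, "union of per-tope EFM sets misses global EFMs")
  }
  list(ok = conforming_exact && maximal_conformal && union_equals_global,
       conforming_exact = conforming_exact,
       maximal_conformal = maximal_conformal,
       union_equals_global = union_equals_global,
       n_efms = nrow(E), n_topes = nrow(topes),
       violations = violations)
}

#' Algebraic support-minimality of a flux vector
#'
#' A nonzero flux mode is elementary iff the submatrix of `N` restricted to
#' its support has nullspace dimension one (deleting any support element then
#' forces the zero solution). Used as the extreme-ray correctness oracle in
#' the test suite.
#'
#' @param network A `metabolic_network`.
#' @param v Flux vector.
#' @return Logical scalar.
#' @export
is_support_minimal <- function(network, v) {
  supp <- which(sign_of(v) != 0L)
  if (!length(supp)) return(FALSE)
  Ns <- network$N[, supp, drop = FALSE]
  Ni <- .integerize_rows(Ns)
  rk <- if (!is.null(Ni)) .int_rank(Ni) else qr(Ns)$rank
  (length(supp) - rk) == 1L
}
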