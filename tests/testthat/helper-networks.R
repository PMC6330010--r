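# Shared fixtures and the exhaustive tope oracle.

# Exhaustive enumeration over all 2^n_indrev full sign vectors: the
# independent reference the BFS is checked against. Iterates every candidate
# (no parent pruning, no visited tree) and LP-checks each one.
brute_force_topes <- function(network, lb_mag = 1e-6, ub_mag = 1e3) {
  K <- nullspace_basis(network$N)
  deps <- reaction_dependencies(K)
  r <- ncol(network$N)
  indrev <- intersect(deps$independent, which(network$reversible))
  n <- length(indrev)
  stopifnot(n <= 12)
  found <- list()
  for (bits in 0:(2^n - 1)) {
    assign_ind <- rep(1L, r)
    if (n > 0) {
      minus <- as.logical(bitwAnd(bits, 2^(seq_len(n) - 1L)))
      assign_ind[indrev[minus]] <- -1L
    }
    tau <- deps$coupling_sign * assign_ind[deps$class]
    if (any(tau < 0 & !network$reversible)) next
    if (check_tope_feasible(network, tau, lb_mag, ub_mag)$feasible) {
      found[[length(found) + 1L]] <- tau * network$orientation
    }
  }
  M <- do.call(rbind, found)
  colnames(M) <- network$reaction_ids
  M
}

tope_pattern_set <- function(M) {
  sort(apply(M, 1, function(s) sign_to_string(as.integer(s))), method = "radix")
}

# the five tope sign patterns of the toy network (order R1..R6), derived by
# exhaustive LP over the 8 candidates
TOY_TOPES <- sort(c("++++++", "+++-++", "++-+++", "++-+-+", "++--++"),
                  method = "radix")

# the six toy EFMs in canonical coprime-integer normalization, reconstructed
# by double description and pinned by the internal-cycle identity
# (0,0,0,-2,2,2) and the containment counts of the toy table
TOY_EFMS <- matrix(c(
  2, 0, -1, 0, 0, 2,
  0, 2, 1, 0, 2, 0,
  0, 0, 0, -1, 1, 1,
  1, 1, 0, 0, 1, 1,
  2, 0, -1, 2, -2, 0,
  1, 1, 0, 1, 0, 0), ncol = 6, byrow = TRUE,
  dimnames = list(NULL, paste0("R", 1:6)))

efm_key_set <- function(M) {
  sort(apply(M, 1, paste, collapse = ","), method = "radix")
}

# two irreversible reactions in an unbranched chain: nullspace rows are
# proportional with positive sign
chain_network <- function() {
  metabolic_network(matrix(c(1, -1), 1, 2,
                           dimnames = list("A", c("R1", "R2"))),
                    reversible = c(FALSE, FALSE))
}

# toy network plus a dead-end reaction A -> D (D has no consumer)
toy_with_dead_end <- function() {
  N <- toy_model()$N
  N <- rbind(N, D = 0)
  N <- cbind(N, R7 = c(-1, 0, 0, 1))
  metabolic_network(N, reversible = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
}
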