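# Exact integer linear algebra for rational stoichiometric matrices.
#
# Stoichiometric coefficients in practice are small rationals; after clearing
# row denominators the matrix is integer and all elimination can be done
# fraction-free (Bareiss-style cross-multiplication with per-row gcd
# reduction), so ranks, nullspace bases and extreme rays are exact as long as
# intermediate integers stay below 2^52 — guarded explicitly. Entries are
# stored in doubles, which represent integers of that size exactly.

.INT_GUARD <- 2^52

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

.gcdv <- function(v) {
  g <- 0
  for (x in v) {
    g <- .gcd2(g, x)
    if (g == 1) break
  }
  g
}

.reduce_int <- function(v) {
  g <- .gcdv(v)
  if (g > 1) v <- v / g
  if (max(abs(v)) >= .INT_GUARD) {
    stop("integer overflow in exact elimination; matrix too ill-conditioned",
         call. = FALSE)
  }
  v
}

# Convert a numeric matrix with (near-)rational entries to an integer matrix
# with the same nullspace, by scaling each row by the lcm of its denominators.
# Denominators are recovered by continued fractions, capped at max_den.
.integerize_rows <- function(M, max_den = 10000L, tol = 1e-9) {
  for (i in seq_len(nrow(M))) {
    row <- M[i, ]
    if (all(abs(row - round(row)) < tol)) { M[i, ] <- round(row); next }
    L <- 1
    for (x in row) {
      d <- .denominator(x, max_den, tol)
      if (is.na(d)) return(NULL)
      L <- L * d / .gcd2(L, d)
    }
    scaled <- row * L
    if (any(abs(scaled - round(scaled)) > tol * max(1, L))) return(NULL)
    M[i, ] <- round(scaled)
  }
  M
}

.denominator <- function(x, max_den, tol) {
  if (abs(x - round(x)) < tol) return(1)
  # continued-fraction expansion
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; y <- x
  for (k in 1:64) {
    a <- floor(y)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) return(NA_real_)
    if (abs(x - p2 / q2) < tol) return(q2)
    frac <- y - a
    if (frac < 1e-15) return(NA_real_)
    y <- 1 / frac
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  NA_real_
}

# Fraction-free row echelon form. Returns list(R, pivcols) with R integer.
.int_echelon <- function(M) {
  m <- nrow(M); n <- ncol(M)
  R <- M
  pivcols <- integer(0)
  pr <- 0L
  for (j in seq_len(n)) {
    if (pr == m) break
    cand <- which(R[, j] != 0)
    cand <- cand[cand > pr]
    if (!length(cand)) next
    # pick the smallest-magnitude pivot to limit growth
    p <- cand[which.min(abs(R[cand, j]))]
    pr <- pr + 1L
    if (p != pr) { tmp <- R[pr, ]; R[pr, ] <- R[p, ]; R[p, ] <- tmp }
    piv <- R[pr, j]
    for (i in seq_len(m)) {
      if (i != pr && R[i, j] != 0) {
        R[i, ] <- .reduce_int(R[i, ] * piv - R[pr, ] * R[i, j])
      }
    }
    pivcols <- c(pivcols, j)
  }
  list(R = R, pivcols = pivcols)
}

# exact rank of an integer matrix
.int_rank <- function(M) {
  if (!length(M)) return(0L)
  length(.int_echelon(M)$pivcols)
}

# Integer basis of the nullspace of an integer matrix (columns of K, N K = 0).
# Each basis column is gcd-reduced with positive entry at its free coordinate.
.int_nullspace <- function(M) {
  n <- ncol(M)
  ech <- .int_echelon(M)
  R <- ech$R; pivcols <- ech$pivcols
  free <- setdiff(seq_len(n), pivcols)
  d <- length(free)
  K <- matrix(0, n, d)
  if (!d) return(K)
  npiv <- length(pivcols)
  piv <- if (npiv) R[cbind(seq_len(npiv), pivcols)] else numeric(0)
  for (k in seq_len(d)) {
    f <- free[k]
    x <- numeric(n)
    L <- 1
    for (pv in piv) L <- L * abs(pv) / .gcd2(L, pv)
    x[f] <- L
    if (npiv) {
      # back-substitute against the (reduced) echelon rows, bottom-up
      for (i in rev(seq_len(npiv))) {
        s <- sum(R[i, ] * x) - R[i, pivcols[i]] * x[pivcols[i]]
        val <- -s / piv[i]
        if (abs(val - round(val)) > 1e-7 * max(1, abs(val))) {
          # keep exactness: rescale the whole vector by the pivot
          x <- x * abs(piv[i])
          s <- sum(R[i, ] * x) - R[i, pivcols[i]] * x[pivcols[i]]
          val <- -s / piv[i]
        }
        x[pivcols[i]] <- round(val)
      }
    }
    x <- .reduce_int(x)
    if (x[f] < 0) x <- -x
    K[, k] <- x
  }
  K
}
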