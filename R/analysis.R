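#' Histogram of tope adjacency counts
#'
#' For every tope of a complete enumeration, counts how many other topes are
#' adjacent (differ in exactly one independent reversible position; dependent
#' reactions flip in lockstep and are not counted separately), and tabulates
#' the counts.
#'
#' @param result A complete `tope_enumeration`.
#' @return A tibble with columns `neighbors` and `count`; the per-tope
#'   neighbor counts are attached as attribute `"per_tope"`.
#' @examples
#' adjacency_histogram(enumerate_topes(toy_model()))
#' @export
adjacency_histogram <- function(result) {
  stopifnot(inherits(result, "tope_enumeration"))
  if (!result$complete) {
    stop("enumeration is partial; adjacency structure is undefined", call. = FALSE)
  }
  M <- result$topes[, result$indrev, drop = FALSE]
  n <- nrow(M)
  deg <- integer(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (sum(M[i, ] != M[j, ]) == 1L) {
          deg[i] <- deg[i] + 1L
          deg[j] <- deg[j] + 1L
        }
      }
    }
  }
  tab <- table(deg)
  out <- tibble::tibble(neighbors = as.integer(names(tab)),
                        count = as.integer(tab))
  attr(out, "per_tope") <- deg
  out
}

#' Forward-direction frequency per reaction
#'
#' Fraction of topes using each reaction in the forward direction.
#' Irreversible reactions are always forward, so their fraction is 1. A
#' fraction of 0.5 means the tope set shows no preference for either
#' direction; fractions near 0 or 1 mark rigidly coordinated reactions.
#'
#' @param result A `tope_enumeration` with at least one tope.
#' @return A tibble with columns `reaction`, `reversible`, `forward_fraction`.
#' @export
direction_frequencies <- function(result) {
  stopifnot(inherits(result, "tope_enumeration"))
  M <- result$topes
  if (!nrow(M)) stop("empty tope set", call. = FALSE)
  rev <- result$network$reversible[match(colnames(M), result$network$reaction_ids)]
  frac <- colMeans(M > 0)
  frac[!rev] <- 1
  tibble::tibble(reaction = colnames(M), reversible = rev,
                 forward_fraction = unname(frac))
}

#' Pair-direction coordination matrix
#'
#' For every unordered pair of reversible reactions and each of the four
#' direction combinations, counts the topes supporting the combination.
#' Combinations supported by no tope are flagged infeasible — they reveal
#' thermodynamic-style coordination between reaction directions.
#'
#' @param result A `tope_enumeration` with at least two reversible reactions.
#' @return A long tibble with columns `reaction_a`, `reaction_b`, `dir_a`,
#'   `dir_b` (`"+"`/`"-"`), `count`, `frequency`, `infeasible`. For each pair
#'   the four counts sum to the number of topes.
#' @export
pair_direction_matrix <- function(result) {
  stopifnot(inherits(result, "tope_enumeration"))
  M <- result$topes
  rev_ids <- colnames(M)[result$network$reversible[
    match(colnames(M), result$network$reaction_ids)]]
  if (length(rev_ids) < 2) {
    stop("need at least two reversible reactions", call. = FALSE)
  }
  n_topes <- nrow(M)
  combos <- expand.grid(a = seq_along(rev_ids), b = seq_along(rev_ids),
                        da = c(1L, -1L), db = c(1L, -1L))
  combos <- combos[combos$a < combos$b, ]
  count <- mapply(function(a, b, da, db) {
    sum(M[, rev_ids[a]] == da & M[, rev_ids[b]] == db)
  }, combos$a, combos$b, combos$da, combos$db)
  out <- tibble::tibble(
    reaction_a = rev_ids[combos$a],
    reaction_b = rev_ids[combos$b],
    dir_a = ifelse(combos$da > 0, "+", "-"),
    dir_b = ifelse(combos$db > 0, "+", "-"),
    count = as.integer(count),
    frequency = count / n_topes,
    infeasible = count == 0L)
  dplyr::arrange(out, .data$reaction_a, .data$reaction_b,
                 dplyr::desc(.data$dir_a), dplyr::desc(.data$dir_b))
}

#' Gaussian extrapolation of tope counts from a truncated search
#'
#' When full enumeration is infeasible, the incremental number of topes per
#' BFS level is empirically close to a discretized normal curve. Fitting
#' `a * exp(-(n - mu)^2 / (2 sigma^2))` to the observed levels by nonlinear
#' least squares and summing the fitted curve over all levels `0..n_total`
#' estimates the total tope count.
#'
#' @param incremental_counts Numeric vector of per-level tope counts, or a
#'   `tope_enumeration` (its counts are used).
#' @param levels Integer levels matching the counts (default `0, 1, ...`).
#' @param n_total Last level of the full search (the number of independent
#'   reversible reactions); defaults to `3 * mu` of the fit, capped below by
#'   the observed range.
#' @return A `gaussian_fit`: `mu`, `sigma`, `amplitude`, `total_estimate`,
#'   `observed_total`, plus observed and fitted values. The fit is on raw
#'   counts with nonnegative amplitude; at least 4 positive levels required.
#' @examples
#' counts <- round(1e4 * exp(-((0:12) - 8)^2 / 8))
#' fit_incremental_gaussian(counts, n_total = 30)
#' @export
fit_incremental_gaussian <- function(incremental_counts, levels = NULL,
                                     n_total = NULL) {
  if (inherits(incremental_counts, "tope_enumeration")) {
    res <- incremental_counts
    incremental_counts <- as.numeric(res$incremental_counts)
    if (is.null(levels)) levels <- as.integer(names(res$incremental_counts))
    if (is.null(n_total)) n_total <- length(res$indrev)
  }
  y <- as.numeric(incremental_counts)
  if (is.null(levels)) levels <- seq_along(y) - 1L
  x <- as.numeric(levels)
  pos <- y > 0
  if (sum(pos) < 4) {
    stop("need at least 4 levels with positive counts for a Gaussian fit",
         call. = FALSE)
  }
  w <- y[pos] / sum(y[pos])
  mu0 <- sum(w * x[pos])
  sig0 <- sqrt(max(sum(w * (x[pos] - mu0)^2), 0.25))
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)),
                      data = data.frame(x = x, y = y),
                      start = list(a = a0, mu = mu0, sigma = sig0),
                      lower = c(a = 0, mu = 0, sigma = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop("Gaussian fit did not converge", call. = FALSE)
  par <- stats::coef(fit)
  if (par[["sigma"]] < 1e-2) stop("degenerate Gaussian fit (sigma ~ 0)", call. = FALSE)
  if (is.null(n_total)) n_total <- max(ceiling(3 * par[["mu"]]), max(x))
  grid <- 0:n_total
  curve <- par[["a"]] * exp(-(grid - par[["mu"]])^2 / (2 * par[["sigma"]]^2))
  total <- max(sum(curve), sum(y))
  structure(list(mu = par[["mu"]], sigma = par[["sigma"]],
                 amplitude = par[["a"]],
                 total_estimate = total, observed_total = sum(y),
                 levels = x, observed = y,
                 fitted = par[["a"]] * exp(-(x - par[["mu"]])^2 /
                                             (2 * par[["sigma"]]^2)),
                 n_total = n_total,
                 converged = TRUE),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu = %.3f, sigma = %.3f, amplitude = %.4g\n",
              x$mu, x$sigma, x$amplitude))
  cat(sprintf("  observed total %.4g over levels %g..%g; estimated total %.4g\n",
              x$observed_total, min(x$levels), max(x$levels), x$total_estimate))
  invisible(x)
}

# ---------------------------------------------------------------------------
# plots

#' Plot methods for enumeration results and Gaussian fits
#'
#' `autoplot.tope_enumeration()` shows incremental and cumulative tope counts
#' per BFS level; `autoplot.gaussian_fit()` overlays the fitted normal curve
#' on the observed incremental counts; `plot_pair_directions()` draws the
#' pair-direction coordination matrix with infeasible combinations marked.
#'
#' @param object A `tope_enumeration` or `gaussian_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name fluxtope-plots
NULL

#' @rdname fluxtope-plots
#' @method autoplot tope_enumeration
#' @export
autoplot.tope_enumeration <- function(object, ...) {
  df <- tibble::tibble(level = as.integer(names(object$incremental_counts)),
                       incremental = as.numeric(object$incremental_counts))
  df$cumulative <- cumsum(df$incremental)
  long <- tidyr::pivot_longer(df, c("incremental", "cumulative"),
                              names_to = "series", values_to = "topes")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$topes)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "BFS level (minus entries)", y = "flux topes") +
    ggplot2::theme_minimal()
}

#' @rdname fluxtope-plots
#' @method autoplot gaussian_fit
#' @export
autoplot.gaussian_fit <- function(object, ...) {
  obs <- tibble::tibble(level = object$levels, count = object$observed)
  grid <- seq(0, object$n_total, by = 0.1)
  fit <- tibble::tibble(level = grid,
                        count = object$amplitude *
                          exp(-(grid - object$mu)^2 / (2 * object$sigma^2)))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$level, y = .data$count)) +
    ggplot2::geom_col(width = 0.7, alpha = 0.6) +
    ggplot2::geom_line(data = fit, linetype = "dashed") +
    ggplot2::labs(x = "BFS level", y = "incremental flux topes") +
    ggplot2::theme_minimal()
}

#' @rdname fluxtope-plots
#' @param pairs A tibble from [pair_direction_matrix()].
#' @export
plot_pair_directions <- function(pairs, ...) {
  df <- dplyr::mutate(pairs,
                      xa = paste0(.data$reaction_a, " ", .data$dir_a),
                      xb = paste0(.data$reaction_b, " ", .data$dir_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$xa, y = .data$xb,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$infeasible),
                        shape = 4, size = 2) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "tope\nfrequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
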