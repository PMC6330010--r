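#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tope enumeration
#'
#' One row per tope: the sign pattern (alphabet `-+`, model orientation), the
#' BFS level (number of minus entries among independent reversible reactions
#' relative to the initial tope) and the discovering parent.
#'
#' @param x A `tope_enumeration`.
#' @param ... Ignored.
#' @return A tibble with columns `tope`, `pattern`, `level`, `parent`.
#' @method tidy tope_enumeration
#' @export
tidy.tope_enumeration <- function(x, ...) {
  tibble::tibble(
    tope = seq_len(nrow(x$topes)),
    pattern = apply(x$topes, 1, function(s) sign_to_string(as.integer(s))),
    level = x$levels,
    parent = x$parents)
}

#' @rdname tidy.tope_enumeration
#' @return `glance()` returns a one-row tibble: `n_topes`, `n_reactions`,
#'   `n_indrev` (independent reversible reactions), `upper_bound`
#'   (`2^n_indrev`), `n_levels`, `lp_checks`, `complete`.
#' @method glance tope_enumeration
#' @export
glance.tope_enumeration <- function(x, ...) {
  tibble::tibble(
    n_topes = nrow(x$topes),
    n_reactions = length(x$reaction_ids),
    n_indrev = length(x$indrev),
    upper_bound = tope_upper_bound(length(x$indrev)),
    n_levels = length(x$incremental_counts),
    lp_checks = x$lp_checks,
    complete = x$complete)
}

#' Tidy an EFM set
#'
#' @param x An `efm_set`.
#' @param ... Ignored.
#' @return A tibble with one row per EFM: `efm`, `pattern` (sign string),
#'   `support_size`, `n_topes` (when containment information is available),
#'   and one integer flux column per reaction.
#' @method tidy efm_set
#' @export
tidy.efm_set <- function(x, ...) {
  E <- x$efms
  out <- tibble::tibble(
    efm = seq_len(nrow(E)),
    pattern = apply(E, 1, function(v) sign_to_string(sign_of(v))),
    support_size = rowSums(E != 0))
  if (!is.null(x$containment)) out$n_topes <- x$containment$n_topes
  dplyr::bind_cols(out, tibble::as_tibble(E))
}

#' Tidy a Gaussian tope-count fit
#'
#' @param x A `gaussian_fit`.
#' @param ... Ignored.
#' @return `tidy()`: one row per parameter (`term`, `estimate`); `glance()`:
#'   a one-row tibble with the parameters, `total_estimate` and
#'   `observed_total`.
#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "mu", "sigma"),
                 estimate = c(x$amplitude, x$mu, x$sigma))
}

#' @rdname tidy.gaussian_fit
#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, mu = x$mu, sigma = x$sigma,
                 total_estimate = x$total_estimate,
                 observed_total = x$observed_total,
                 converged = x$converged)
}
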