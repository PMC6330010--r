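#' Construct a metabolic network
#'
#' The central input object of the package: an m x r stoichiometric matrix of
#' internal metabolites, per-reaction reversibility flags, optional flux
#' bounds and an optional linear objective. A reaction is irreversible
#' exactly when its lower bound is nonnegative, so `reversible` and `lb` are
#' kept in lockstep.
#'
#' @param N Numeric m x r matrix of net stoichiometric coefficients.
#' @param reaction_ids Character vector of r unique reaction identifiers.
#' @param metabolite_ids Character vector of m unique metabolite identifiers.
#' @param reversible Logical vector of length r. Defaults to `lb < 0` when
#'   `lb` is given, otherwise all `FALSE`.
#' @param lb,ub Flux bounds (may be infinite). Default `-Inf` for reversible
#'   and `0` for irreversible reactions, and `+Inf` above.
#' @param objective Optional numeric vector of r objective coefficients.
#' @return An object of class `metabolic_network`.
#' @seealso [toy_model()], [read_model()], [make_consistent()]
#' @export
metabolic_network <- function(N, reaction_ids = colnames(N),
                              metabolite_ids = rownames(N),
                              reversible = NULL, lb = NULL, ub = NULL,
                              objective = NULL) {
  N <- as.matrix(N)
  m <- nrow(N); r <- ncol(N)
  if (r == 0) stop("network has no reactions", call. = FALSE)
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(r))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(m))
  if (anyDuplicated(reaction_ids)) {
    stop("duplicate reaction id: ",
         reaction_ids[duplicated(reaction_ids)][1], call. = FALSE)
  }
  if (length(reaction_ids) != r || length(metabolite_ids) != m) {
    stop("id vectors do not match matrix dimensions", call. = FALSE)
  }
  if (is.null(reversible)) {
    reversible <- if (is.null(lb)) rep(FALSE, r) else lb < 0
  }
  if (is.null(lb)) lb <- ifelse(reversible, -Inf, 0)
  if (is.null(ub)) ub <- rep(Inf, r)
  if (length(reversible) != r || length(lb) != r || length(ub) != r) {
    stop("`reversible`, `lb`, `ub` must have one entry per reaction", call. = FALSE)
  }
  if (any(!reversible & lb < 0)) {
    stop("irreversible reactions must have lb >= 0", call. = FALSE)
  }
  if (any(reversible & lb >= 0)) {
    stop("reversible reactions must have lb < 0 (a reaction is irreversible iff lb >= 0)",
         call. = FALSE)
  }
  if (any(lb > ub)) stop("lb > ub for some reaction", call. = FALSE)
  if (!is.null(objective) && length(objective) != r) {
    stop("`objective` must have one coefficient per reaction", call. = FALSE)
  }
  dimnames(N) <- list(metabolite_ids, reaction_ids)
  structure(list(N = N, reaction_ids = reaction_ids,
                 metabolite_ids = metabolite_ids,
                 reversible = as.logical(reversible),
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 objective = objective,
                 orientation = rep(1L, r)),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites x %d reactions (%d reversible)\n",
              nrow(x$N), ncol(x$N), sum(x$reversible)))
  if (!is.null(x$objective) && any(x$objective != 0)) {
    cat("  objective on:", paste(x$reaction_ids[x$objective != 0], collapse = ", "), "\n")
  }
  if (any(is.finite(x$lb) & x$lb != 0) || any(is.finite(x$ub))) {
    cat("  finite flux bounds present (flux polyhedron)\n")
  }
  invisible(x)
}

#' Set flux bounds on selected reactions
#'
#' Convenience wrapper turning a flux cone into a flux polyhedron by tightening
#' bounds on named reactions. Reversibility flags are re-derived from the new
#' lower bounds (a reaction with `lb >= 0` becomes irreversible).
#'
#' @param network A `metabolic_network`.
#' @param lb,ub Named numeric vectors, names are reaction ids.
#' @return The modified network.
#' @examples
#' toy <- with_bounds(toy_model(), ub = c(R1 = 10, R3 = 10))
#' @export
with_bounds <- function(network, lb = NULL, ub = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  set_named <- function(cur, upd) {
    if (is.null(upd)) return(cur)
    idx <- match(names(upd), network$reaction_ids)
    if (anyNA(idx)) stop("unknown reaction id: ",
                         names(upd)[is.na(idx)][1], call. = FALSE)
    cur[idx] <- upd
    cur
  }
  new_lb <- set_named(network$lb, lb)
  new_ub <- set_named(network$ub, ub)
  metabolic_network(network$N, network$reaction_ids, network$metabolite_ids,
                    reversible = new_lb < 0, lb = new_lb, ub = new_ub,
                    objective = network$objective)
}

#' The built-in six-reaction toy network
#'
#' A network of three internal metabolites (A, B, C) and six reactions
#' (R1..R6), with R1, R2, R6 irreversible and R3, R4, R5 reversible. R3
#' produces two molecules of C; all other stoichiometric coefficients are
#' one. Its flux cone is consistent, has a three-dimensional nullspace, and
#' decomposes into exactly five flux topes generated by six elementary flux
#' modes — small enough that every quantity in the package can be verified by
#' brute force.
#'
#' @return A `metabolic_network`.
#' @examples
#' toy_model()
#' @export
toy_model <- function() {
  N <- matrix(c(1, 0, 0, -1, 0, -1,
                0, -1, 0, 1, 1, 0,
                0, 0, 2, 0, -1, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("R", 1:6)))
  metabolic_network(N, reversible = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
}

# ---------------------------------------------------------------------------
# readers / writers

#' Read a metabolic model
#'
#' Supported dialects: SBML Level 2/3 (species flagged `boundaryCondition`
#' are dropped, so the matrix covers internal metabolites only), the native
#' JSON schema (see Details) and a long-format TSV of
#' (metabolite, reaction, coefficient) triplets with `#!`-prefixed metadata
#' lines. Reaction order is preserved from the file.
#'
#' @details The native JSON schema is
#' `{"metabolites": [ids], "reactions": [{"id", "stoich": {met: coef},
#' "reversible", "lb", "ub", "obj"}]}`, with `lb`/`ub`/`obj` optional and
#' the strings `"-Inf"`/`"Inf"` accepted for unbounded values.
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"sbml"`, `"json"`, `"tsv"`.
#' @return A `metabolic_network`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml",
                     json = "json",
                     tsv = , txt = "tsv",
                     stop("cannot guess model format from extension of ", path,
                          call. = FALSE))
  }
  switch(format,
         sbml = .read_sbml(path),
         json = .read_json_model(path),
         tsv = .read_tsv_model(path))
}

.num_or_inf <- function(x, default) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(default)
  if (is.character(x)) return(as.numeric(sub("^\\+", "", x)))
  as.numeric(x)
}

.read_json_model <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- unlist(doc$metabolites)
  rxns <- doc$reactions
  if (!length(rxns)) stop("parse error: empty reaction list in ", path, call. = FALSE)
  ids <- vapply(rxns, function(x) as.character(x$id), "")
  if (anyDuplicated(ids)) {
    stop("parse error: duplicate reaction id ", ids[duplicated(ids)][1], call. = FALSE)
  }
  if (is.null(mets)) {
    mets <- unique(unlist(lapply(rxns, function(x) names(x$stoich))))
  }
  N <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  rev <- logical(length(ids)); lb <- numeric(length(ids)); ub <- numeric(length(ids))
  obj <- numeric(length(ids)); has_obj <- FALSE
  for (k in seq_along(rxns)) {
    rx <- rxns[[k]]
    st <- rx$stoich
    if (length(st)) {
      bad <- setdiff(names(st), mets)
      if (length(bad)) {
        stop("parse error: reaction ", ids[k], " references unknown metabolite ",
             bad[1], call. = FALSE)
      }
      N[names(st), k] <- unlist(st)
    }
    rev[k] <- isTRUE(rx$reversible)
    lb[k] <- .num_or_inf(rx$lb, if (rev[k]) -Inf else 0)
    ub[k] <- .num_or_inf(rx$ub, Inf)
    if (!is.null(rx$obj)) { obj[k] <- as.numeric(rx$obj); has_obj <- TRUE }
  }
  metabolic_network(N, ids, mets, reversible = rev, lb = lb, ub = ub,
                    objective = if (has_obj) obj else NULL)
}

.read_tsv_model <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#!")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2) stop("parse error: no triplet rows in ", path, call. = FALSE)
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("metabolite", "reaction", "coefficient")
  mets <- unique(df$metabolite)
  ids <- unique(df$reaction)
  N <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  N[cbind(match(df$metabolite, mets), match(df$reaction, ids))] <- df$coefficient
  rev <- logical(length(ids)); names(rev) <- ids
  lb <- ifelse(rev, -Inf, 0); ub <- rep(Inf, length(ids))
  names(lb) <- names(ub) <- ids
  obj <- numeric(length(ids)); names(obj) <- ids; has_obj <- FALSE
  for (ln in meta) {
    parts <- strsplit(sub("^#!", "", ln), "\t")[[1]]
    key <- parts[1]
    if (key == "rev") {
      rev[parts[-1]] <- TRUE
    } else if (key %in% c("lb", "ub", "obj") && length(parts) == 3) {
      val <- as.numeric(parts[3])
      if (key == "lb") lb[parts[2]] <- val
      if (key == "ub") ub[parts[2]] <- val
      if (key == "obj") { obj[parts[2]] <- val; has_obj <- TRUE }
    }
  }
  lb[rev & lb >= 0] <- -Inf
  metabolic_network(N, ids, mets, reversible = lb < 0, lb = lb, ub = ub,
                    objective = if (has_obj) unname(obj) else NULL)
}

.read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  boundary <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  internal <- sp_id[!boundary]
  # fbc flux bound parameters
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("parse error: empty reaction list in ", path, call. = FALSE)
  ids <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(ids)) {
    stop("parse error: duplicate reaction id ", ids[duplicated(ids)][1], call. = FALSE)
  }
  rev_attr <- tolower(xml2::xml_attr(rx_nodes, "reversible"))
  rev <- ifelse(is.na(rev_attr), TRUE, rev_attr == "true") # SBML default: reversible
  N <- matrix(0, length(internal), length(ids), dimnames = list(internal, ids))
  lb <- ifelse(rev, -Inf, 0); ub <- rep(Inf, length(ids))
  add_stoich <- function(k, node, sgn) {
    refs <- xml2::xml_find_all(node, "./speciesReference")
    for (ref in refs) {
      sp <- xml2::xml_attr(ref, "species")
      coef <- xml2::xml_attr(ref, "stoichiometry")
      coef <- if (is.na(coef)) 1 else as.numeric(coef)
      if (sp %in% internal) N[sp, k] <<- N[sp, k] + sgn * coef
    }
  }
  for (k in seq_along(rx_nodes)) {
    rx <- rx_nodes[[k]]
    reac <- xml2::xml_find_first(rx, "./listOfReactants")
    prod <- xml2::xml_find_first(rx, "./listOfProducts")
    if (!inherits(reac, "xml_missing")) add_stoich(k, reac, -1)
    if (!inherits(prod, "xml_missing")) add_stoich(k, prod, +1)
    for (attr in c("lowerFluxBound", "fbc:lowerFluxBound")) {
      ref <- xml2::xml_attr(rx, attr)
      if (!is.na(ref) && ref %in% names(par_val)) lb[k] <- par_val[[ref]]
    }
    for (attr in c("upperFluxBound", "fbc:upperFluxBound")) {
      ref <- xml2::xml_attr(rx, attr)
      if (!is.na(ref) && ref %in% names(par_val)) ub[k] <- par_val[[ref]]
    }
  }
  drop <- colSums(N != 0) == 0 & vapply(seq_along(ids), function(k) {
    # reactions touching only boundary species become exchange columns (kept,
    # all-zero rows removed below); fully empty reactions are dropped
    length(xml2::xml_find_all(rx_nodes[[k]], ".//speciesReference")) == 0
  }, TRUE)
  if (any(drop)) {
    N <- N[, !drop, drop = FALSE]; ids <- ids[!drop]
    rev <- rev[!drop]; lb <- lb[!drop]; ub <- ub[!drop]
  }
  metabolic_network(N, ids, internal, reversible = lb < 0, lb = lb, ub = ub)
}

#' Write a metabolic model
#'
#' @param network A `metabolic_network`.
#' @param path Output path.
#' @param format `"json"` (native schema) or `"tsv"` (long-format triplets
#'   with `#!` metadata lines). SBML writing is out of scope.
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "metabolic_network"))
  if (format == "json") {
    rxns <- lapply(seq_along(network$reaction_ids), function(k) {
      nz <- which(network$N[, k] != 0)
      x <- list(id = network$reaction_ids[k],
                stoich = as.list(stats::setNames(network$N[nz, k],
                                                 network$metabolite_ids[nz])),
                reversible = network$reversible[k],
                lb = if (is.finite(network$lb[k])) network$lb[k] else
                  as.character(network$lb[k]),
                ub = if (is.finite(network$ub[k])) network$ub[k] else
                  as.character(network$ub[k]))
      if (!is.null(network$objective)) x$obj <- network$objective[k]
      x
    })
    jsonlite::write_json(list(metabolites = network$metabolite_ids,
                              reactions = rxns),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (any(network$reversible)) {
      writeLines(paste(c("#!rev", network$reaction_ids[network$reversible]),
                       collapse = "\t"), con)
    }
    for (k in seq_along(network$reaction_ids)) {
      if (is.finite(network$lb[k]) && network$lb[k] != 0) {
        writeLines(sprintf("#!lb\t%s\t%.17g", network$reaction_ids[k],
                           network$lb[k]), con)
      }
      if (is.finite(network$ub[k])) {
        writeLines(sprintf("#!ub\t%s\t%.17g", network$reaction_ids[k],
                           network$ub[k]), con)
      }
      if (!is.null(network$objective) && network$objective[k] != 0) {
        writeLines(sprintf("#!obj\t%s\t%.17g", network$reaction_ids[k],
                           network$objective[k]), con)
      }
    }
    writeLines("metabolite\treaction\tcoefficient", con)
    idx <- which(network$N != 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(idx))) {
      writeLines(sprintf("%s\t%s\t%.17g",
                         network$metabolite_ids[idx[i, 1]],
                         network$reaction_ids[idx[i, 2]],
                         network$N[idx[i, 1], idx[i, 2]]), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# synthetic networks

#' Generate a random consistent metabolic network
#'
#' Builds an integer stoichiometric matrix (coefficients in \[-3, 3\]) that by
#' construction admits a strictly positive steady-state flux: every matrix row
#' is a sum of disjoint two-column "exchange pair" vectors orthogonal to a
#' hidden positive flux vector. No reaction can therefore be blocked, and
#' [make_consistent()] only needs to fix the direction of reversible
#' reactions that cannot run backward. Used as the study-condition generator
#' for the property-based test suites.
#'
#' @param m Number of metabolites (>= 1).
#' @param r Number of reactions (> m).
#' @param n_rev Number of reactions initially flagged reversible.
#' @param density Target fraction of nonzero coefficients (default 0.3).
#' @param seed Integer seed; identical seeds give identical networks. The
#'   global RNG state is left untouched.
#' @return A consistent `metabolic_network` (already passed through
#'   [make_consistent()]); the surviving number of reversible reactions may be
#'   smaller than `n_rev`.
#' @export
random_network <- function(m, r, n_rev, density = 0.3, seed = 1L) {
  if (!(r > m && m >= 1)) stop("need r > m >= 1", call. = FALSE)
  if (n_rev < 0 || n_rev > r) stop("need 0 <= n_rev <= r", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (attempt in 1:100) {
    net <- .random_network_once(m, r, n_rev, density)
    if (is.null(net)) next
    res <- tryCatch(make_consistent(net), error = function(e) NULL)
    if (is.null(res)) next
    if (n_rev > 0 && !any(res$network$reversible)) next
    if (ncol(res$network$N) < 2) next
    return(res$network)
  }
  stop("failed to generate a consistent nonzero network in 100 attempts",
       call. = FALSE)
}

.random_network_once <- function(m, r, n_rev, density) {
  v_star <- sample(1:3, r, replace = TRUE)
  N <- matrix(0, m, r)
  used <- vector("list", m) # columns already used per row
  add_pair <- function(row, j, k) {
    if (j %in% used[[row]] || k %in% used[[row]]) return(FALSE)
    N[row, j] <<- v_star[k]
    N[row, k] <<- -v_star[j]
    used[[row]] <<- c(used[[row]], j, k)
    TRUE
  }
  # coverage: pair up all columns from a random permutation, spread over rows
  perm <- sample(r)
  base_pairs <- split(perm[seq_len(2 * (r %/% 2))],
                      rep(seq_len(r %/% 2), each = 2))
  if (r %% 2 == 1) base_pairs <- c(base_pairs, list(c(perm[r], perm[1])))
  row_i <- 0L
  for (p in base_pairs) {
    placed <- FALSE
    for (try in seq_len(m)) {
      row_i <- row_i %% m + 1L
      if (add_pair(row_i, p[1], p[2])) { placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  # densify
  n_extra <- max(0L, round(density * m * r / 2) - length(base_pairs))
  for (e in seq_len(n_extra)) {
    row <- sample.int(m, 1)
    avail <- setdiff(seq_len(r), used[[row]])
    if (length(avail) >= 2) {
      jk <- sample(avail, 2)
      add_pair(row, jk[1], jk[2])
    }
  }
  if (any(colSums(N != 0) == 0) || any(rowSums(N != 0) == 0)) return(NULL)
  rev <- rep(FALSE, r)
  if (n_rev > 0) rev[sample.int(r, n_rev)] <- TRUE
  metabolic_network(N, paste0("R", seq_len(r)), paste0("M", seq_len(m)),
                    reversible = rev)
}

# ---------------------------------------------------------------------------
# result writers

#' Write and read flux topes as TSV
#'
#' One column per reaction (header = reaction ids), one row per tope, entries
#' `-` or `+`, in the model's original reaction orientation. Rows are ordered
#' lexicographically by sign pattern so output is canonical regardless of
#' discovery order or thread count.
#'
#' @param topes A `tope_enumeration` result or a \{-1, +1\} matrix with one
#'   column per reaction.
#' @param path Output path.
#' @param reaction_ids Header ids (taken from the object when absent).
#' @return `path` invisibly; `read_topes()` returns a \{-1, +1\} integer
#'   matrix with reaction ids as column names.
#' @export
write_topes <- function(topes, path, reaction_ids = NULL) {
  M <- if (inherits(topes, "tope_enumeration")) topes$topes else as.matrix(topes)
  if (is.null(reaction_ids)) reaction_ids <- colnames(M)
  if (is.null(reaction_ids) && inherits(topes, "tope_enumeration")) {
    reaction_ids <- topes$reaction_ids
  }
  if (is.null(reaction_ids)) stop("no reaction-id header available", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(reaction_ids, collapse = "\t"), con)
  if (nrow(M)) {
    chr <- matrix(ifelse(M > 0, "+", "-"), nrow = nrow(M))
    rows <- apply(chr, 1, paste, collapse = "\t")
    writeLines(rows[order(apply(chr, 1, paste, collapse = ""))], con)
  }
  invisible(path)
}

#' @rdname write_topes
#' @export
read_topes <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t")[[1]]
  if (length(lines) == 1) {
    return(matrix(integer(0), 0, length(ids), dimnames = list(NULL, ids)))
  }
  rows <- strsplit(lines[-1], "\t")
  M <- t(vapply(rows, function(x) ifelse(x == "+", 1L, -1L),
                integer(length(ids))))
  colnames(M) <- ids
  M
}

#' Write elementary flux modes as TSV
#'
#' One row per EFM in canonical integer normalization (coprime integer
#' entries), header = reaction ids.
#'
#' @param efms An `efm_set` or a numeric matrix (EFMs in rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_efms <- function(efms, path) {
  M <- if (inherits(efms, "efm_set")) efms$efms else as.matrix(efms)
  ids <- colnames(M)
  if (is.null(ids)) stop("no reaction-id header available", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  if (nrow(M)) {
    ord <- order(apply(M, 1, paste, collapse = ","))
    for (i in ord) writeLines(paste(format(M[i, ], scientific = FALSE, trim = TRUE),
                                    collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a run report as JSON
#'
#' @param report A list (per-level counts, preprocessing log, timings, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
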