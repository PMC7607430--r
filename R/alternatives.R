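# Expansion of uncertainty annotations: "/" element alternatives, "//"
# complete-SU alternatives, and "index%" fragment placements.

su_concrete_variants <- function(su) {
  expand_one <- function(s) {
    s$alts <- NULL
    ms_opts <- if (length(s$ms) > 1) as.list(s$ms) else list(s$ms)
    an_opts <- if (length(s$anomer) > 1) as.list(s$anomer) else list(s$anomer)
    po_opts <- if (length(s$pos) > 1) as.list(s$pos) else list(s$pos)
    out <- list()
    for (m in ms_opts) for (a in an_opts) for (p in po_opts) {
      v <- s
      v$ms <- m; v$anomer <- a; v$pos <- p
      out[[length(out) + 1]] <- v
    }
    out
  }
  out <- expand_one(su)
  for (alt in su$alts %||% list()) out <- c(out, expand_one(alt))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

node_variants <- function(node) {
  su_opts <- su_concrete_variants(node$su)
  child_opts <- lapply(node$children, node_variants)
  combos <- list(list())
  for (opts in child_opts) {
    combos <- unlist(lapply(combos, function(prefix)
      lapply(opts, function(o) c(prefix, list(o)))), recursive = FALSE)
  }
  out <- list()
  for (s in su_opts) for (kids in combos) {
    v <- node
    v$su <- s
    v$children <- kids
    out[[length(out) + 1]] <- v
  }
  out
}

# All document-order marker sites for a fragment index; each site returns a
# function that attaches the fragment there.
marker_sites <- function(root, index) {
  paths <- list()
  walk <- function(node, path) {
    if (index %in% node$frag_markers)
      paths[[length(paths) + 1]] <<- path
    for (k in seq_along(node$children))
      walk(node$children[[k]], c(path, k))
  }
  walk(root, integer(0))
  paths
}

attach_at <- function(root, path, child) {
  if (!length(path)) {
    root$children <- c(root$children, list(child))
    return(root)
  }
  k <- path[1]
  root$children[[k]] <- attach_at(root$children[[k]], path[-1], child)
  root
}

strip_markers <- function(node) {
  node$frag_markers <- integer(0)
  node$children <- lapply(node$children, strip_markers)
  node
}

#' Enumerate concrete structures of an uncertain glycan
#'
#' Expands every "/" element alternative, every "//" complete-SU
#' alternative, and every fragment placement ("index%" markers) into the
#' Cartesian product of concrete glycans, in document order with the
#' left-most option first. Duplicates arising after canonicalization are
#' removed.
#'
#' @param g Glycan or glycan string.
#' @param registry Registry used for parsing and canonical output.
#' @return List of concrete `licorr_glycan` objects.
#' @export
#' @examples
#' sapply(enumerate_alternatives("Ab4//Ga2Aa3"), serialize_glycan)
enumerate_alternatives <- function(g, registry = default_registry()) {
  g <- as_glycan(g, registry = registry)
  if (is.null(g$root)) stop("cannot enumerate a repeat-only glycan")
  roots <- node_variants(g$root)
  # fragment placements
  for (f in g$fragments) {
    placed <- list()
    for (r in roots) {
      sites <- marker_sites(r, f$index)
      if (!length(sites))
        lc_error("bad_fragment", 0,
                 paste0("fragment ", f$index, " has no marker sites"))
      for (p in sites)
        placed[[length(placed) + 1]] <- attach_at(r, p, f$glycan$root)
    }
    roots <- placed
  }
  out <- list()
  seen <- character(0)
  for (r in roots) {
    gg <- new_glycan(strip_markers(r), g$conjugate, dialect = g$dialect)
    key <- serialize_glycan(gg, registry)
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1]] <- gg
    }
  }
  out
}

#' Expand a repeat annotation
#'
#' Concatenates the repeat unit of a `{n...}` glycan head-to-tail `n`
#' times. With `n = 1` the dangling attachment position of the final
#' (reducing-end) unit is dropped, collapsing `{nGb4}` to `"Gb"`. Cyclic
#' repeats (tail marker `"c"`) and units with `-X-` head markers are
#' refused as unsupported.
#'
#' @param g Glycan or glycan string carrying a repeat annotation.
#' @param n Number of repeats (>= 1).
#' @param registry Registry used for parsing.
#' @return A concrete `licorr_glycan`; glycans without a repeat annotation
#'   are returned unchanged.
#' @export
#' @examples
#' serialize_glycan(expand_repeats("{nGb4}", 3))
expand_repeats <- function(g, n, registry = default_registry()) {
  g <- as_glycan(g, registry = registry)
  if (is.null(g$repeat_)) return(g)
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  unit <- g$repeat_$unit
  if (grepl("-", unit, fixed = TRUE) || grepl("c", unit, fixed = TRUE))
    stop("cyclic or head-marked repeat units are not supported for expansion")
  s <- strrep(unit, as.integer(n))
  if (n == 1) s <- sub("(?<=[ab?])[1-9?]$", "", s, perl = TRUE)
  out <- parse_glycan(s, g$dialect, registry)
  out$conjugate <- g$conjugate
  out
}
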