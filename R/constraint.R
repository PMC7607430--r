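#' Reaction-rule constraints
#'
#' A constraint cell is a boolean expression over pattern atoms and
#' residue-count atoms. "!" (legacy "~") negates and binds tightest, "&"
#' conjoins, and the word "or" (loosest) disjoins; there is no
#' parenthesized grouping because parentheses are glycan syntax - wider
#' grouping is expressed by splitting rules. A pattern atom is true when
#' the pattern matches anywhere in the glycan; an atom containing the site
#' anchor "@" ("*" in the legacy dialect) is true only when some match
#' places the anchor exactly at the reaction site under evaluation. Count
#' atoms compare residue counts: LiCoRR `"nA=0"`, legacy `"#A = 0"`,
#' IUPAC-condensed `"nMan(a1-?)>4"`. Named macros (e.g. `Gnbis`, the
#' bisecting GlcNAc motif) expand to pattern atoms.
#'
#' @name constraint
NULL

cx <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "licorr_constraint")
}

#' Default constraint macros
#'
#' Currently the single entry `Gnbis`, the bisecting GlcNAc motif
#' `"Ma3(GNb4)(...Ma6)Mb4"`.
#'
#' @return Named character vector mapping macro names to pattern text.
#' @export
default_macros <- function() {
  c(Gnbis = "Ma3(GNb4)(...Ma6)Mb4")
}

#' Parse a constraint cell
#'
#' @param text Constraint text; blank parses to the always-true EMPTY
#'   constraint. Whitespace around operators and comparators is ignored.
#' @param dialect `"licorr"` (default) or `"legacy"`.
#' @param registry Registry for pattern literals and count selectors.
#' @return A `licorr_constraint`.
#' @export
#' @examples
#' parse_constraint("!Ma6")
#' parse_constraint("~Ma6", dialect = "legacy")
#' parse_constraint("nMan(a1-?)>4 & nMan(a1-?)<8")
parse_constraint <- function(text, dialect = "licorr",
                             registry = default_registry()) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text)))
    return(cx("empty"))
  s <- gsub("…", "...", text)
  neg_sym <- if (dialect == "legacy") "~" else "!"
  if (grepl("(^|&|\\bor\\b)[[:space:]]*($|&|\\bor\\b)", s))
    lc_error("dangling_operator", 0, "operator with no operand")
  disjuncts <- strsplit(s, "\\bor\\b")[[1]]
  parse_conj <- function(piece) {
    conjuncts <- strsplit(piece, "&", fixed = TRUE)[[1]]
    atoms <- lapply(conjuncts, function(a) {
      a <- gsub("[[:space:]]+", "", a)
      if (!nzchar(a))
        lc_error("dangling_operator", 0, "operator with no operand")
      n_neg <- 0L
      while (startsWith(a, neg_sym)) {
        n_neg <- n_neg + 1L
        a <- substr(a, nchar(neg_sym) + 1, nchar(a))
        if (!nzchar(a))
          lc_error("dangling_operator", 0, "negation with no operand")
      }
      atom <- parse_atom(a, dialect, registry)
      for (k in seq_len(n_neg)) atom <- cx("not", child = atom)
      atom
    })
    if (length(atoms) == 1) atoms[[1]] else cx("and", children = atoms)
  }
  parts <- lapply(disjuncts, parse_conj)
  if (length(parts) == 1) parts[[1]] else cx("or", children = parts)
}

parse_atom <- function(a, dialect, registry) {
  m <- regmatches(a, regexec("^[n#](.+?)(<=|>=|=|<|>)([0-9]+)$", a))[[1]]
  if (length(m) && grepl("^[n#]", a)) {
    sel <- tryCatch(parse_count_selector(m[2], registry), error = function(e) e)
    if (!inherits(sel, "error"))
      return(cx("count", selector = m[2], sel = sel, cmp = m[3],
                value = as.integer(m[4])))
  }
  # macro names contain lowercase letters that never occur in glycan code
  if (grepl("^[A-Za-z]+$", a) && grepl("[c-np-z]", gsub("[abo]", "", a)))
    return(cx("macro", name = a))
  p <- parse_pattern(a, dialect, registry)
  anchored <- any(vapply(p$tokens, function(t) t$type == "site", logical(1)))
  cx("pattern", pattern = p, anchored = anchored)
}

#' Expand constraint macros
#'
#' Replaces every macro reference by a pattern atom parsed from the macro
#' table; macro values may themselves be macro names, but cycles are
#' refused.
#'
#' @param e A `licorr_constraint`.
#' @param table Named character vector of macros (see [default_macros()]).
#' @param dialect Dialect in which macro bodies are parsed.
#' @param registry Registry.
#' @return The expanded constraint; idempotent once no macros remain.
#' @export
expand_macros <- function(e, table = default_macros(), dialect = "licorr",
                          registry = default_registry()) {
  resolve <- function(name, seen = character(0)) {
    if (name %in% seen)
      stop("recursive macro definition: ", paste(c(seen, name), collapse = " -> "))
    if (!name %in% names(table)) stop("unknown macro: ", name)
    val <- table[[name]]
    if (val %in% names(table)) return(resolve(val, c(seen, name)))
    val
  }
  walk <- function(x) {
    switch(x$kind,
           empty = x,
           macro = {
             p <- parse_pattern(resolve(x$name), dialect, registry)
             anchored <- any(vapply(p$tokens, function(t) t$type == "site",
                                    logical(1)))
             cx("pattern", pattern = p, anchored = anchored)
           },
           not = { x$child <- walk(x$child); x },
           and = , or = { x$children <- lapply(x$children, walk); x },
           x)
  }
  walk(e)
}

#' Evaluate a constraint against a glycan
#'
#' @param e Constraint (or constraint text, parsed in `dialect`).
#' @param g Glycan or glycan string.
#' @param site 0-based reaction-site index over the sentineled canonical
#'   string, required when `e` contains a site-anchored atom.
#' @param dialect Dialect for text input.
#' @param registry Registry.
#' @param macros Macro table for expansion.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' evaluate_constraint("Ma6 & Ma3", "Ma3(Ma6)Mb4GNb4GN")
#' evaluate_constraint("!Ma6", "Ma3(Ma6)Mb4GNb4GN")
#' evaluate_constraint("nA=0", "GNb2Ma3(GNb2Ma6)Mb4GNb4GN")
evaluate_constraint <- function(e, g, site = NULL, dialect = "licorr",
                                registry = default_registry(),
                                macros = default_macros()) {
  if (is.character(e)) e <- parse_constraint(e, dialect, registry)
  e <- expand_macros(e, macros, "licorr", registry)
  g <- as_glycan(g, registry = registry)
  ev <- function(x) {
    switch(x$kind,
           empty = TRUE,
           not = !ev(x$child),
           and = all(vapply(x$children, ev, logical(1))),
           or = any(vapply(x$children, ev, logical(1))),
           count = {
             cnt <- count_residues(g, x$sel, registry)
             switch(x$cmp,
                    "=" = cnt == x$value, "<" = cnt < x$value,
                    ">" = cnt > x$value, "<=" = cnt <= x$value,
                    ">=" = cnt >= x$value)
           },
           pattern = {
             ms <- find_matches(x$pattern, g, registry = registry)
             if (!x$anchored) return(length(ms) > 0)
             if (is.null(site))
               stop("site-anchored constraint evaluated without a site index")
             any(vapply(ms, function(m) isTRUE(m$site == site), logical(1)))
           },
           stop("unknown constraint node: ", x$kind))
  }
  ev(e)
}

#' Split a constraint into OR-free alternatives
#'
#' Distributes top-level (and AND-nested) disjunctions into a list of
#' OR-free constraints whose disjunction is equivalent to the input.
#'
#' @param e A `licorr_constraint`.
#' @return List of `licorr_constraint` with no `or` nodes.
#' @export
atomize_disjunction <- function(e) {
  switch(e$kind,
         or = unlist(lapply(e$children, atomize_disjunction),
                     recursive = FALSE),
         and = {
           parts <- lapply(e$children, atomize_disjunction)
           combos <- list(list())
           for (opts in parts)
             combos <- unlist(lapply(combos, function(pre)
               lapply(opts, function(o) c(pre, list(o)))), recursive = FALSE)
           lapply(combos, function(cs)
             if (length(cs) == 1) cs[[1]] else cx("and", children = cs))
         },
         list(e))
}

#' Render a constraint in canonical LiCoRR text
#' @param e A `licorr_constraint`.
#' @return Constraint text using LiCoRR symbols.
#' @export
render_constraint <- function(e) {
  switch(e$kind,
         empty = "",
         not = paste0("!", render_constraint(e$child)),
         and = paste(vapply(e$children, render_constraint, character(1)),
                     collapse = " & "),
         or = paste(vapply(e$children, render_constraint, character(1)),
                    collapse = " or "),
         count = paste0("n", e$selector, e$cmp, e$value),
         macro = e$name,
         pattern = render_pattern(e$pattern))
}

#' @export
print.licorr_constraint <- function(x, ...) {
  cat("<licorr_constraint> ", render_constraint(x), "\n", sep = "")
  invisible(x)
}
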