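#' LiCoRRICE: the IUPAC-condensed flavor
#'
#' LiCoRRICE keeps LiCoRR's rule semantics but writes residues with
#' IUPAC-condensed names ("Gal(b1-3)GlcNAc(b1-"), uses square brackets for
#' branches, and collapses the three branch-specific wildcards to a single
#' "...". The anomeric carbon in each linkage comes from the registry
#' (1 by default; 2 for the sialic acids, KDN, Kdo and fructose).
#'
#' @name licorrice
NULL

greek_anomer <- function(a, greek) {
  if (!greek) return(a)
  chartr("ab", "αβ", a)
}

latin_anomer <- function(a) chartr("αβ", "ab", a)

licorrice_su <- function(su, registry, greek, is_root, reducing_tail) {
  if (nzchar(su$marker))
    stop("stereo/ring markers have no IUPAC-condensed rendering: ",
         su_to_string(su))
  if ("?" %in% su$ms || "*" %in% su$ms)
    stop("unknown residues cannot be rendered in IUPAC-condensed form")
  name_of <- function(code) {
    e <- ms_lookup(registry, code)
    if (is.null(e)) stop("unmapped monosaccharide code: ", code)
    e
  }
  entries <- lapply(su$ms, name_of)
  name <- paste(vapply(entries, `[[`, character(1), "iupac_name"),
                collapse = "/")
  ac <- entries[[1]]$anomeric_carbon
  mods <- ""
  if (length(su$mods)) {
    mods <- paste(vapply(su$mods, function(m) {
      code <- mod_iupac(registry, m$code)
      paste0(paste(m$pos, collapse = ","), code)
    }, character(1)), collapse = "")
  }
  anomer <- greek_anomer(paste(su$anomer, collapse = "/"), greek)
  pos <- paste(su$pos, collapse = "/")
  link <- if (is_root) {
    if (reducing_tail && nzchar(anomer)) paste0("(", anomer, ac, "-") else ""
  } else {
    if (!nzchar(anomer)) anomer <- "?"
    if (!nzchar(pos)) pos <- "?"
    paste0("(", anomer, ac, "-", pos, ")")
  }
  paste0(name, mods, link)
}

mod_iupac <- function(registry, code) {
  i <- match(code, registry$mods$lc_code)
  if (is.na(i)) stop("unmapped modification code: ", code)
  registry$mods$iupac_name[i]
}

#' Convert a glycan to IUPAC-condensed (LiCoRRICE) text
#'
#' @param g Glycan or glycan string.
#' @param greek Emit Greek anomer letters (`"β"`) instead of `"b"`.
#' @param reducing_tail Emit the trailing open linkage (`"(b1-"`) on the
#'   reducing-end residue when its anomer is known.
#' @param registry Registry supplying IUPAC names and anomeric carbons.
#' @return IUPAC-condensed string.
#' @export
#' @examples
#' to_licorrice("Ab3GNb")
#' to_licorrice("Ab3(Fa4)GNb", greek = TRUE)
to_licorrice <- function(g, greek = FALSE, reducing_tail = TRUE,
                         registry = default_registry()) {
  g <- as_glycan(g, registry = registry)
  if (is.null(g$root)) stop("repeat-only glycans have no condensed form")
  render <- function(node, is_root) {
    kids <- canonical_children(node$children)
    out <- ""
    if (length(kids)) {
      out <- render(kids[[1]], FALSE)
      if (length(kids) > 1)
        for (k in 2:length(kids))
          out <- paste0(out, "[", render(kids[[k]], FALSE), "]")
    }
    paste0(out, licorrice_su(node$su, registry, greek, is_root,
                             reducing_tail))
  }
  out <- render(g$root, TRUE)
  if (!is.null(g$conjugate))
    out <- paste0(out, g$conjugate$sep, g$conjugate$text)
  out
}

#' Parse an IUPAC-condensed (LiCoRRICE) glycan
#'
#' Accepts Greek or Latin anomer letters, with or without the trailing
#' reducing-end linkage. The string is transcoded residue by residue into
#' Linear Code and parsed with [parse_glycan()].
#'
#' @param text IUPAC-condensed glycan string.
#' @param registry Registry for reverse name lookup.
#' @return A `licorr_glycan`.
#' @export
#' @examples
#' serialize_glycan(from_licorrice("Gal(β1-3)GlcNAc(β1-"))
from_licorrice <- function(text, registry = default_registry()) {
  s <- gsub("[[:space:]]+", "", latin_anomer(text))
  conj <- NULL
  parts <- split_conjugate(s)
  s <- parts$glycan
  conj <- parts$conjugate
  lc <- transcode_licorrice(s, registry)
  g <- parse_glycan(lc, "licorr", registry)
  g$conjugate <- conj
  g
}

transcode_licorrice <- function(s, registry) {
  cv <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(cv)
  names_sorted <- iupac_names(registry)
  mods_sorted <- mod_iupac_names(registry)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- cv[i]
    if (ch == "[") { out <- c(out, "("); i <- i + 1L; next }
    if (ch == "]") { out <- c(out, ")"); i <- i + 1L; next }
    rest <- substr(s, i, n)
    hit <- names_sorted[startsWith(rest, names_sorted)]
    if (!length(hit))
      lc_error("unknown_code", i - 1L,
               paste0("no registered residue name matches '",
                      substr(rest, 1, 8), "'"))
    name <- hit[1]
    code <- ms_from_iupac(registry, name)
    i <- i + nchar(name)
    # inline modifications: digits then a modification name ("Gal3S")
    mods <- character(0)
    repeat {
      save_i <- i
      pos <- character(0)
      while (i <= n && (is_digit(cv[i]) || cv[i] == "?")) {
        pos <- c(pos, cv[i]); i <- i + 1L
        if (i <= n && cv[i] == ",") i <- i + 1L else break
      }
      if (!length(pos)) break
      rest2 <- substr(s, i, n)
      mhit <- mods_sorted[startsWith(rest2, mods_sorted)]
      if (!length(mhit)) { i <- save_i; break }
      mcode <- mod_from_iupac(registry, mhit[1])
      mods <- c(mods, paste0(paste(pos, collapse = ","), mcode))
      i <- i + nchar(mhit[1])
    }
    su_txt <- paste0(code,
                     if (length(mods)) paste0("[", paste(mods, collapse = ","), "]"))
    # linkage "(a2-3)" / trailing "(b1-" / absent
    if (i <= n && cv[i] == "(") {
      j <- i + 1L
      anomer <- if (j <= n && cv[j] %in% c("a", "b", "?")) {
        a <- cv[j]; j <- j + 1L; a
      } else "?"
      while (j <= n && (is_digit(cv[j]) || cv[j] == "?")) j <- j + 1L  # anomeric carbon
      if (j > n || cv[j] != "-")
        lc_error("bad_linkage", i - 1L, "expected '-' in linkage")
      j <- j + 1L
      pos <- ""
      if (j <= n && (is_digit(cv[j]) || cv[j] == "?")) {
        pos <- cv[j]; j <- j + 1L
      }
      if (j <= n && cv[j] == ")") {
        j <- j + 1L
        su_txt <- paste0(su_txt, anomer, if (nzchar(pos)) pos else "?")
      } else if (j == n + 1L) {
        # trailing reducing-end "(b1-"
        su_txt <- paste0(su_txt, if (anomer != "?") anomer)
      } else {
        lc_error("bad_linkage", i - 1L, "unterminated linkage")
      }
      i <- j
    }
    out <- c(out, su_txt)
  }
  paste(out, collapse = "")
}

#' Convert a pattern (and optional constraint) to LiCoRRICE
#'
#' All three branch wildcards collapse to `"..."` (IUPAC branching is not
#' deterministic, so branch direction is meaningless there); parentheses
#' become square brackets except a leading branch-terminal sentinel, which
#' is dropped; `!`, `&`, `or` and `@` carry over; count atoms render as
#' `nName(anomer-position)`.
#'
#' @param p A `licorr_pattern` (or pattern text).
#' @param constraint Optional `licorr_constraint` to render instead.
#' @param greek Greek anomer letters.
#' @param registry Registry.
#' @param macros Macro table (macros are expanded before rendering).
#' @return LiCoRRICE text.
#' @export
#' @examples
#' pattern_to_licorrice("(GNb2+Ma3")
pattern_to_licorrice <- function(p = NULL, constraint = NULL, greek = FALSE,
                                 registry = default_registry(),
                                 macros = default_macros()) {
  if (!is.null(constraint)) {
    if (is.character(constraint)) constraint <- parse_constraint(constraint)
    e <- expand_macros(constraint, macros, registry = registry)
    return(render_licorrice_constraint(e, greek, registry))
  }
  if (is.character(p)) p <- parse_pattern(p)
  render_licorrice_pattern(p, greek, registry)
}

render_licorrice_pattern <- function(p, greek, registry) {
  out <- character(0)
  first <- TRUE
  for (tk in p$tokens) {
    piece <- switch(tk$type,
      su = licorrice_su(tk$su, registry, greek, is_root = FALSE,
                        reducing_tail = FALSE),
      open = if (first) "" else "[",
      close = "]",
      ligand = , continuation = , branch = "...",
      site = "@",
      any_su = "...",
      raw = tk$text)
    first <- FALSE
    out <- c(out, piece)
  }
  paste(out, collapse = "")
}

render_licorrice_constraint <- function(e, greek, registry) {
  switch(e$kind,
         empty = "",
         not = paste0("!", render_licorrice_constraint(e$child, greek, registry)),
         and = paste(vapply(e$children, render_licorrice_constraint,
                            character(1), greek, registry), collapse = " & "),
         or = paste(vapply(e$children, render_licorrice_constraint,
                           character(1), greek, registry), collapse = " or "),
         count = {
           sel <- e$sel
           entry <- ms_lookup(registry, sel$ms)
           paste0("n", entry$iupac_name, "(",
                  greek_anomer(sel$anomer %||% "?", greek),
                  entry$anomeric_carbon, "-", sel$pos %||% "?", ")",
                  e$cmp, e$value)
         },
         pattern = render_licorrice_pattern(e$pattern, greek, registry),
         macro = e$name)
}

#' Read a LiCoRRICE pattern back into LiCoRR tokens
#'
#' `"..."` maps to the ligand wildcard (the conversion is many-to-one, so
#' this direction is lossy: the result is flagged with a `lossy`
#' attribute), and square brackets map back to parentheses.
#'
#' @param text LiCoRRICE pattern text.
#' @param registry Registry.
#' @return A `licorr_pattern` with attribute `lossy = TRUE` when a
#'   wildcard was recovered.
#' @export
pattern_from_licorrice <- function(text, registry = default_registry()) {
  s <- gsub("[[:space:]]+", "", latin_anomer(gsub("…", "...", text)))
  pieces <- strsplit(s, "...", fixed = TRUE)[[1]]
  lossy <- grepl("...", s, fixed = TRUE)
  lc_pieces <- vapply(pieces, function(pc) {
    if (!nzchar(pc)) return("")
    transcode_licorrice(pc, registry)
  }, character(1))
  p <- parse_pattern(paste(lc_pieces, collapse = "..."), "licorr", registry)
  attr(p, "lossy") <- lossy
  p
}
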