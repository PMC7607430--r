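#' Glycan structures in Linear Code
#'
#' A `licorr_glycan` is a rooted tree of saccharide units. The written
#' Linear Code reads from the non-reducing termini (left) to the reducing
#' end (right); at every residue the child that continues the
#' lowest-carbon-index chain is written unparenthesized and the remaining
#' children appear as parenthesized branches. A glycan may carry a
#' glycoconjugate suffix (amino acid after ";", lipid after ":", other
#' glycoside after "#"), fragment annotations ("index%" markers with the
#' fragment split off by "|"), and a repeat annotation ("{nGb4}").
#'
#' @name glycan
NULL

new_glycan <- function(root, conjugate = NULL, fragments = list(),
                       repeat_ = NULL, dialect = "licorr") {
  structure(list(root = root, conjugate = conjugate, fragments = fragments,
                 repeat_ = repeat_, dialect = dialect),
            class = "licorr_glycan")
}

new_node <- function(su, children = list(), frag_markers = integer(0)) {
  list(su = su, children = children, frag_markers = frag_markers)
}

#' Parse a Linear Code / LiCoRR glycan string
#'
#' Accepts non-canonical branch order (use [serialize_glycan()] to obtain
#' the canonical form). The glycoconjugate is split off at the last
#' top-level ";", ":" or "#"; fragment definitions ("FRAG=1%") are split
#' off at top-level "|"; "{n...}" repeat annotations are retained.
#'
#' @param text Glycan string.
#' @param dialect `"licorr"`, `"legacy"`, or `"olc"`. Glycan structure
#'   syntax is shared across dialects; the dialect is recorded for
#'   round-tripping.
#' @param registry A [default_registry()]-shaped registry.
#' @return A `licorr_glycan`.
#' @export
#' @examples
#' g <- parse_glycan("Ab3GNb")
#' serialize_glycan(g)
parse_glycan <- function(text, dialect = "licorr",
                         registry = default_registry()) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    lc_error("empty_input", 0, "input must be a single string")
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) lc_error("empty_input", 0, "empty glycan string")

  parts <- split_conjugate(s)
  core <- parts$glycan
  conj <- parts$conjugate

  # repeat annotation
  m <- regmatches(core, regexec("^\\{(n|[0-9]+)(.+)\\}$", core))[[1]]
  if (length(m)) {
    count <- if (m[2] == "n") "n" else as.integer(m[2])
    unit <- m[3]
    root <- tryCatch(parse_glycan(unit, dialect, registry)$root,
                     error = function(e) NULL)
    return(new_glycan(root, conj,
                      repeat_ = list(count = count, unit = unit),
                      dialect = dialect))
  }

  # fragment definitions
  fragments <- list()
  segs <- split_top_level(core, "|")
  if (length(segs$pieces) > 1) {
    core <- segs$pieces[[length(segs$pieces)]]
    core_off <- segs$offsets[[length(segs$pieces)]]
    for (k in seq_len(length(segs$pieces) - 1)) {
      piece <- segs$pieces[[k]]
      fm <- regmatches(piece, regexec("^(.+)=([0-9]+)%$", piece))[[1]]
      if (!length(fm))
        lc_error("bad_fragment", segs$offsets[[k]],
                 "fragment definition must look like 'FRAG=1%'")
      fragments[[length(fragments) + 1]] <-
        list(index = as.integer(fm[3]),
             glycan = parse_glycan(fm[2], dialect, registry))
    }
  } else {
    core_off <- 0L
  }

  toks <- tokenize_glycan(core, registry, offset0 = core_off)
  root <- build_chain(toks, 1L, length(toks))
  g <- new_glycan(root, conj, fragments, dialect = dialect)
  check_structure(g)
  g
}

split_conjugate <- function(s) {
  cv <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cut <- NA_integer_
  brk <- 0L
  for (i in seq_along(cv)) {
    ch <- cv[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "[") brk <- brk + 1L
    else if (ch == "]") brk <- brk - 1L
    else if (depth == 0L && brk == 0L && ch %in% c(";", ":", "#"))
      cut <- i
  }
  if (is.na(cut)) return(list(glycan = s, conjugate = NULL))
  if (cut == 1L || cut == length(cv))
    lc_error("bad_conjugate", cut - 1L, "empty glycan or conjugate part")
  list(glycan = substr(s, 1, cut - 1),
       conjugate = list(sep = cv[cut],
                        text = substr(s, cut + 1, nchar(s))))
}

# Split on a character at parenthesis depth 0, tracking 0-based offsets.
split_top_level <- function(s, sep) {
  cv <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  pieces <- list()
  offsets <- list()
  start <- 1L
  for (i in seq_along(cv)) {
    ch <- cv[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == sep && depth == 0L) {
      pieces[[length(pieces) + 1]] <- substr(s, start, i - 1)
      offsets[[length(offsets) + 1]] <- start - 1L
      start <- i + 1L
    }
  }
  pieces[[length(pieces) + 1]] <- substr(s, start, nchar(s))
  offsets[[length(offsets) + 1]] <- start - 1L
  list(pieces = pieces, offsets = offsets)
}

# Tokenize a glycan core into SU / paren / fragment-marker tokens.
tokenize_glycan <- function(s, registry, offset0 = 0L) {
  cv <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(cv)
  toks <- list()
  depth <- 0L
  i <- 1L
  pending_markers <- integer(0)
  while (i <= n) {
    ch <- cv[i]
    off <- offset0 + i - 1L
    if (ch == "(") {
      depth <- depth + 1L
      toks[[length(toks) + 1]] <- list(type = "open", offset = off)
      i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        lc_error("unbalanced_paren", off, "')' without matching '('")
      toks[[length(toks) + 1]] <- list(type = "close", offset = off)
      i <- i + 1L
    } else if (is_digit(ch) && i < n && cv[i + 1] == "%") {
      pending_markers <- c(pending_markers, as.integer(ch))
      i <- i + 2L
    } else if (is_upper(ch) || ch %in% c("*", "?")) {
      res <- parse_su_at(cv, i, registry)
      su <- res$su
      i <- res$i
      # complete-SU alternatives
      while (i < n && cv[i] == "/" && cv[i + 1] == "/") {
        res2 <- parse_su_at(cv, i + 2L, registry)
        su$alts <- c(su$alts, list(res2$su))
        i <- res2$i
      }
      toks[[length(toks) + 1]] <- list(type = "su", su = su, offset = off,
                                       markers = pending_markers)
      pending_markers <- integer(0)
    } else {
      lc_error("invalid_char", off,
               paste0("unexpected character '", ch, "'"))
    }
  }
  if (depth > 0L)
    lc_error("unbalanced_paren", offset0 + n, "'(' without matching ')'")
  if (length(pending_markers))
    lc_error("bad_fragment", offset0 + n, "fragment marker with no residue")
  toks
}

# Build the tree for token range [lo, hi]. The rightmost token of a chain
# is its reducing-most residue; scanning left we collect parenthesized
# branches and finally the unparenthesized main chain.
build_chain <- function(toks, lo, hi) {
  if (hi < lo) {
    off <- if (lo <= length(toks)) toks[[lo]]$offset else 0L
    lc_error("empty_branch", off, "empty chain")
  }
  last <- toks[[hi]]
  if (last$type != "su")
    lc_error("expected_su", last$offset, "chain must end in a saccharide unit")
  node <- new_node(last$su, frag_markers = last$markers)
  branches <- list()
  i <- hi - 1L
  while (i >= lo && toks[[i]]$type == "close") {
    depth <- 1L
    j <- i - 1L
    while (j >= lo && depth > 0L) {
      if (toks[[j]]$type == "close") depth <- depth + 1L
      else if (toks[[j]]$type == "open") depth <- depth - 1L
      if (depth == 0L) break
      j <- j - 1L
    }
    if (depth > 0L)
      lc_error("unbalanced_paren", toks[[i]]$offset, "')' without '('")
    if (j + 1L > i - 1L)
      lc_error("empty_branch", toks[[j]]$offset, "empty branch '()'")
    branches <- c(list(build_chain(toks, j + 1L, i - 1L)), branches)
    i <- j - 1L
  }
  children <- list()
  if (i >= lo) {
    if (toks[[i]]$type == "open")
      lc_error("unbalanced_paren", toks[[i]]$offset, "'(' without ')'")
    children <- list(build_chain(toks, lo, i))
  }
  node$children <- c(children, branches)
  node
}

# Structural invariants enforced after parsing.
check_structure <- function(g) {
  frag_idx <- vapply(g$fragments, function(f) f$index, integer(1))
  if (anyDuplicated(frag_idx))
    lc_error("bad_fragment", 0, "duplicate fragment indices")
  seen <- integer(0)
  walk <- function(node, is_root) {
    if (node$su$open && !is_root)
      lc_error("open_form_not_root", 0,
               "open-form 'o' is legal only on the reducing-end residue")
    seen <<- c(seen, node$frag_markers)
    kp <- vapply(node$children, function(ch) su_pos_key(ch$su), numeric(1))
    known <- kp[kp < 100]
    if (anyDuplicated(known))
      lc_error("duplicate_position", 0,
               "two branches attach at the same carbon position")
    for (ch in node$children) walk(ch, FALSE)
  }
  if (!is.null(g$root)) walk(g$root, TRUE)
  for (idx in frag_idx)
    if (!idx %in% seen)
      lc_error("bad_fragment", 0,
               paste0("fragment ", idx, " has no '", idx, "%' marker in the core"))
  invisible(g)
}

# Children in canonical order: ascending known attachment position;
# unknown/absent positions after all known ones; ties keep written order
# (stable), so schematic glycans without positions serialize as written.
canonical_children <- function(children) {
  if (length(children) < 2) return(children)
  key <- vapply(children, function(ch) su_pos_key(ch$su), numeric(1))
  children[order(key)]
}

serialize_node <- function(node) {
  kids <- canonical_children(node$children)
  out <- ""
  if (length(kids)) {
    out <- serialize_node(kids[[1]])
    if (length(kids) > 1)
      for (k in 2:length(kids))
        out <- paste0(out, "(", serialize_node(kids[[k]]), ")")
  }
  marker <- if (length(node$frag_markers))
    paste0(node$frag_markers, "%", collapse = "") else ""
  paste0(out, marker, su_to_string(node$su))
}

#' Serialize a glycan to its canonical LiCoRR string
#'
#' At each residue the child attached at the lowest carbon position is
#' written unparenthesized (the lowest-carbon-index chain); remaining
#' children follow as parenthesized branches in ascending position order,
#' so read right-to-left from the parent the attachment positions decrease.
#'
#' @param g A `licorr_glycan` (or a string, which is parsed first).
#' @param registry Registry used if `g` is a string.
#' @return The canonical glycan string.
#' @export
#' @examples
#' serialize_glycan("Ab4(GNb4GNb3)(GNb6)Ab4Gb")
serialize_glycan <- function(g, registry = default_registry()) {
  g <- as_glycan(g, registry = registry)
  core <- if (!is.null(g$repeat_)) {
    paste0("{", g$repeat_$count, g$repeat_$unit, "}")
  } else {
    serialize_node(g$root)
  }
  frags <- vapply(g$fragments, function(f)
    paste0(serialize_glycan(f$glycan), "=", f$index, "%"), character(1))
  out <- paste0(paste0(frags, collapse = "|"),
                if (length(frags)) "|" else "", core)
  if (!is.null(g$conjugate))
    out <- paste0(out, g$conjugate$sep, g$conjugate$text)
  out
}

#' @rdname serialize_glycan
#' @param text Glycan string to canonicalize.
#' @param dialect Dialect of `text`.
#' @export
canonicalize <- function(text, dialect = "licorr",
                         registry = default_registry()) {
  serialize_glycan(parse_glycan(text, dialect, registry), registry)
}

as_glycan <- function(x, dialect = "licorr", registry = default_registry()) {
  if (inherits(x, "licorr_glycan")) x
  else parse_glycan(x, dialect, registry)
}

#' @export
print.licorr_glycan <- function(x, ...) {
  cat("<licorr_glycan> ", serialize_glycan(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.licorr_glycan <- function(x, ...) serialize_glycan(x)

glycan_nodes <- function(g) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1]] <<- node
    for (ch in node$children) walk(ch)
  }
  if (!is.null(g$root)) walk(g$root)
  out
}

#' Count residues in a glycan
#'
#' With no selector, counts every saccharide unit (including unknown "*"
#' units). A Linear Code selector such as `"A"` counts residues whose
#' monosaccharide identity is exactly that code, so `"A"` never counts
#' `"AN"` residues. An IUPAC-condensed selector such as `"Man(a1-?)"`
#' counts residues by name, anomer, and (optionally) linkage position,
#' with `"?"` matching anything.
#'
#' @param g Glycan or glycan string.
#' @param selector `NULL`, an lc code, or an IUPAC-condensed selector.
#' @param registry Registry for code lookup.
#' @return Integer count.
#' @export
#' @examples
#' count_residues("ANb3*A")
#' count_residues("Ma2Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN", "M")
count_residues <- function(g, selector = NULL,
                           registry = default_registry()) {
  g <- as_glycan(g, registry = registry)
  nodes <- glycan_nodes(g)
  if (is.null(selector)) return(length(nodes))
  sel <- parse_count_selector(selector, registry)
  sum(vapply(nodes, function(nd) su_matches_selector(nd$su, sel), logical(1)))
}

# "A" or "Man(a1-?)" -> list(ms, anomer, pos); NULL fields match anything.
parse_count_selector <- function(selector, registry) {
  if (is.list(selector)) return(selector)
  m <- regmatches(selector,
                  regexec("^([A-Za-z0-9-]+?)(\\(([ab?])([0-9?])?-([0-9?])?\\)?)?$",
                          selector))[[1]]
  if (!length(m))
    stop("cannot parse residue selector: ", selector)
  name <- m[2]
  if (grepl("^[A-Z]+$", name) && name %in% registry$mono$lc_code) {
    ms <- name
  } else {
    ms <- ms_from_iupac(registry, name)
    if (is.null(ms)) stop("unregistered residue selector: ", selector)
  }
  anomer <- if (nzchar(m[4]) && m[4] != "?") m[4] else NULL
  pos <- if (length(m) >= 6 && nzchar(m[6]) && m[6] != "?") m[6] else NULL
  list(ms = ms, anomer = anomer, pos = pos)
}

su_matches_selector <- function(su, sel) {
  if (!identical(paste(su$ms, collapse = "/"), sel$ms)) return(FALSE)
  if (!is.null(sel$anomer) &&
      !(length(su$anomer) && all(su$anomer == sel$anomer))) return(FALSE)
  if (!is.null(sel$pos) &&
      !(length(su$pos) && all(su$pos == sel$pos))) return(FALSE)
  TRUE
}

#' Validate a glycan string
#'
#' Returns machine-readable diagnostics instead of raising errors: an empty
#' data frame means the string parses and is already canonical. Syntax
#' problems are reported as errors with 0-based character offsets;
#' non-canonical branch order is reported as a warning.
#'
#' @inheritParams parse_glycan
#' @return Data frame with columns `severity`, `code`, `offset`, `message`.
#' @export
#' @examples
#' validate_glycan("Ab3GNb")
#' validate_glycan("Ab3(GNb")
validate_glycan <- function(text, dialect = "licorr",
                            registry = default_registry()) {
  diag <- data.frame(severity = character(0), code = character(0),
                     offset = integer(0), message = character(0),
                     stringsAsFactors = FALSE)
  g <- tryCatch(parse_glycan(text, dialect, registry),
                licorr_parse_error = function(e) e)
  if (inherits(g, "licorr_parse_error")) {
    return(rbind(diag, data.frame(severity = "error", code = g$code,
                                  offset = g$offset, message = g$detail,
                                  stringsAsFactors = FALSE)))
  }
  s <- gsub("[[:space:]]+", "", text)
  canon <- serialize_glycan(g, registry)
  if (!identical(canon, s))
    diag <- rbind(diag, data.frame(
      severity = "warning", code = "non_canonical", offset = 0L,
      message = paste0("canonical form is '", canon, "'"),
      stringsAsFactors = FALSE))
  diag
}
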