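#' Patterns and wildcard matching
#'
#' Reaction-rule patterns are written over the sentineled canonical glycan
#' string: an initial "(" is prepended to the glycan so that the terminal
#' end of every branch is a left parenthesis, which lets a leading "(" in a
#' pattern anchor a residue as branch-terminal. Patterns mix literal
#' saccharide units and parentheses with the wildcard operators:
#'
#' * ligand `"..."` - any substring with all parentheses matched
#'   (including the empty string): a fragment removable with one cut.
#' * continuation `"_"` - any substring where every "(" is closed later,
#'   but ")" may be unmatched: a path that may exit branches toward the
#'   root.
#' * possible branch `"+"` (`"|"` in the legacy dialect) - `""`, `")"`,
#'   `"(B)"`, or `")(B)"` for balanced `B`.
#' * `"*"` - exactly one complete saccharide unit with its linkage
#'   (LiCoRR; in the legacy dialect `"*"` marks the reaction site).
#' * `"@"` - the zero-width reaction-site anchor (LiCoRR).
#' * `"$"` - possible modification on the preceding residue.
#'
#' @name pattern
NULL

#' Prepend the branch-terminal sentinel
#'
#' @param text Canonical glycan string (conjugate stripped).
#' @return The string with "(" prepended.
#' @export
#' @examples
#' sentinel("Ab3GNb")
sentinel <- function(text) paste0("(", text)

#' Classify a substring against a wildcard class
#'
#' @param kind `"ligand"`, `"continuation"`, or `"branch"`.
#' @param s Candidate substring.
#' @return `TRUE` if `s` is a valid binding for the wildcard class.
#' @export
#' @examples
#' classify_substring("ligand", "XX(XXX)XX")
#' classify_substring("continuation", "X)(XX)XX")
#' classify_substring("branch", ")(C)")
classify_substring <- function(kind, s) {
  cv <- if (nzchar(s)) strsplit(s, "", fixed = TRUE)[[1]] else character(0)
  switch(match.arg(kind, c("ligand", "continuation", "branch")),
    ligand = {
      depth <- 0L
      for (ch in cv) {
        if (ch == "(") depth <- depth + 1L
        else if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
      }
      depth == 0L
    },
    continuation = {
      open <- 0L
      for (ch in cv) {
        if (ch == "(") open <- open + 1L
        else if (ch == ")" && open > 0L) open <- open - 1L
      }
      open == 0L
    },
    branch = {
      if (!length(cv)) return(TRUE)
      if (identical(s, ")")) return(TRUE)
      body <- if (cv[1] == ")") cv[-1] else cv
      wrapped_balanced(body)
    })
}

# "(B)" with B balanced and the outer pair actually matching.
wrapped_balanced <- function(cv) {
  n <- length(cv)
  if (n < 2 || cv[1] != "(" || cv[n] != ")") return(FALSE)
  depth <- 0L
  for (i in seq_len(n)) {
    if (cv[i] == "(") depth <- depth + 1L
    else if (cv[i] == ")") depth <- depth - 1L
    if (depth == 0L && i < n) return(FALSE)
    if (depth < 0L) return(FALSE)
  }
  depth == 0L
}

pattern_symbols <- function(dialect) {
  switch(dialect,
         licorr = list(branch = "+", site = "@", any = "*"),
         legacy = list(branch = "|", site = "*", any = NULL),
         olc    = list(branch = NULL, site = NULL, any = "*"),
         stop("unknown dialect: ", dialect))
}

#' Parse a LiCoRR / legacy pattern
#'
#' Literal parentheses inside a pattern need not balance (a pattern such as
#' `"(GNb2+Ma3"` is legal). At most one site anchor is allowed.
#'
#' @param text Pattern string. The Unicode ellipsis is accepted for "...".
#' @param dialect `"licorr"` (default), `"legacy"`, or `"olc"`.
#' @param registry Registry used to read saccharide-unit literals.
#' @return A `licorr_pattern` (token list).
#' @export
#' @examples
#' parse_pattern("(GNb2+Ma3")
#' parse_pattern("Ma3|(*_Ma6)Mb4", dialect = "legacy")
parse_pattern <- function(text, dialect = "licorr",
                          registry = default_registry()) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text))
    lc_error("empty_input", 0, "empty pattern")
  syms <- pattern_symbols(dialect)
  s <- gsub("…", "...", gsub("[[:space:]]+", "", text))
  cv <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(cv)
  toks <- list()
  push <- function(type, ...) {
    toks[[length(toks) + 1]] <<- list(type = type, ...)
  }
  i <- 1L
  n_site <- 0L
  while (i <= n) {
    ch <- cv[i]
    if (ch == "." && i + 2 <= n && cv[i + 1] == "." && cv[i + 2] == ".") {
      push("ligand"); i <- i + 3L
    } else if (ch == "_") {
      push("continuation"); i <- i + 1L
    } else if (identical(ch, syms$branch)) {
      push("branch"); i <- i + 1L
    } else if (identical(ch, syms$site)) {
      n_site <- n_site + 1L
      if (n_site > 1)
        lc_error("duplicate_site", i - 1L, "more than one site anchor")
      push("site"); i <- i + 1L
    } else if (identical(ch, syms$any)) {
      push("any_su"); i <- i + 1L
    } else if (ch == "(") {
      push("open"); i <- i + 1L
    } else if (ch == ")") {
      push("close"); i <- i + 1L
    } else if (is_upper(ch) || ch == "?") {
      res <- parse_su_at(cv, i, registry)
      push("su", su = res$su)
      i <- res$i
    } else {
      # raw literal characters (e.g. the dangling position in "@2Ma3(...")
      j <- i
      while (j <= n && !cv[j] %in% c(".", "_", "(", ")") &&
             !identical(cv[j], syms$branch) && !identical(cv[j], syms$site) &&
             !identical(cv[j], syms$any) && !is_upper(cv[j]))
        j <- j + 1L
      push("raw", text = paste(cv[i:(j - 1)], collapse = ""))
      i <- j
    }
  }
  structure(list(tokens = toks, dialect = dialect, source_text = text),
            class = "licorr_pattern")
}

render_token <- function(tk) {
  switch(tk$type,
         su = su_to_string(tk$su),
         open = "(", close = ")",
         ligand = "...", continuation = "_", branch = "+",
         site = "@", any_su = "*",
         raw = tk$text)
}

#' Render a pattern in canonical LiCoRR symbols
#' @param p A `licorr_pattern`.
#' @return Pattern text using the LiCoRR symbol set.
#' @export
render_pattern <- function(p) {
  paste(vapply(p$tokens, render_token, character(1)), collapse = "")
}

#' @export
print.licorr_pattern <- function(x, ...) {
  cat("<licorr_pattern> ", render_pattern(x), "\n", sep = "")
  invisible(x)
}

wildcard_kinds <- c("ligand", "continuation", "branch", "any_su")

pattern_wildcards <- function(p) {
  kinds <- vapply(p$tokens, `[[`, character(1), "type")
  kinds[kinds %in% wildcard_kinds]
}

# ---------------------------------------------------------------------------
# Subject indexing: the sentineled canonical string plus, for every
# saccharide-unit token, its character span and element layout.

subject_index <- function(g, registry = default_registry()) {
  if (is.character(g)) {
    # subjects that are not well-formed glycans (e.g. unbalanced test
    # strings) are matched over their literal token sequence
    parsed <- tryCatch(parse_glycan(g, registry = registry),
                       licorr_parse_error = function(e) e)
    if (inherits(parsed, "licorr_parse_error")) {
      s <- gsub("[[:space:]]+", "", g)
      return(raw_subject_index(s, registry, parsed))
    }
    g <- parsed
  }
  core <- new_glycan(strip_markers(g$root), dialect = g$dialect)
  s <- serialize_glycan(core, registry)
  S <- sentinel(s)
  toks <- tokenize_glycan(s, registry)
  tok_at <- new.env(parent = emptyenv())
  for (tk in toks) {
    if (tk$type != "su") next
    start0 <- tk$offset + 1L  # +1 for the sentinel character
    layout <- su_layout(tk$su, start0)
    assign(as.character(start0), layout, envir = tok_at)
  }
  list(S = S, cv = strsplit(S, "", fixed = TRUE)[[1]], n = nchar(S),
       tok_at = tok_at, glycan = g)
}

raw_subject_index <- function(s, registry, parse_err) {
  if (!parse_err$code %in% c("unbalanced_paren")) stop(parse_err)
  cv <- strsplit(s, "", fixed = TRUE)[[1]]
  S <- sentinel(s)
  tok_at <- new.env(parent = emptyenv())
  i <- 1L
  while (i <= length(cv)) {
    ch <- cv[i]
    if (ch %in% c("(", ")")) { i <- i + 1L; next }
    res <- parse_su_at(cv, i, registry)
    start0 <- i  # 0-based in S: (i - 1) + 1 sentinel
    assign(as.character(start0), su_layout(res$su, start0), envir = tok_at)
    i <- res$i
  }
  list(S = S, cv = strsplit(S, "", fixed = TRUE)[[1]], n = nchar(S),
       tok_at = tok_at, glycan = NULL)
}

# Element spans (0-based, half-open) of one canonical SU token.
su_layout <- function(su, start0) {
  at <- start0
  ms_str <- paste(su$ms, collapse = "/")
  at <- at + nchar(ms_str)
  elems <- list()
  add <- function(kind, str, value = NULL) {
    elems[[length(elems) + 1]] <<- list(kind = kind, start = at,
                                        end = at + nchar(str), value = value)
    at <<- at + nchar(str)
  }
  if (nzchar(su$marker)) add("marker", su$marker, su$marker)
  if (length(su$mods)) add("mods", mods_string(su$mods), mods_string(su$mods))
  if (!is.null(su$dollar))
    add("dollar", paste0("$", if (!is.null(su$dollar$spec))
      mods_string(su$dollar$spec) else ""))
  if (length(su$anomer))
    add("anomer", paste(su$anomer, collapse = "/"),
        paste(su$anomer, collapse = "/"))
  if (length(su$pos))
    add("pos", paste(su$pos, collapse = "/"), paste(su$pos, collapse = "/"))
  if (su$open) add("open", "o", "o")
  # "//" alternatives serialize after the primary SU; treat the remainder
  # as an opaque tail that only ANY_SU can consume.
  tail_str <- ""
  if (!is.null(su$alts) && length(su$alts))
    tail_str <- paste0("//",
                       paste(vapply(su$alts, su_core_string, character(1)),
                             collapse = "//"))
  list(su = su, start = start0, ms_end = start0 + nchar(ms_str),
       elems = elems, end = at + nchar(tail_str))
}

# ---------------------------------------------------------------------------
# The matcher: recursive descent over pattern tokens with full enumeration
# of wildcard bindings.

#' Find all matches of a pattern in a glycan
#'
#' The glycan is canonicalized, its conjugate and fragment annotations are
#' set aside, and matching runs over the sentineled canonical string.
#' Every distinct combination of start offset and wildcard bindings is
#' returned, ordered by start offset and then lexicographically by
#' bindings. Saccharide-unit literals match token-aligned: a literal can
#' only match at the start of a subject saccharide unit whose
#' monosaccharide identity is exactly the literal's (so `"A"` never
#' matches inside an `"AN"` token), and elements the literal leaves
#' unspecified are not consumed, which lets a trailing literal such as
#' `"Ma"` in `"(Ma2Ma"` match the head of an `"Ma2"` token.
#'
#' @param p Pattern (or pattern string, parsed in `dialect`).
#' @param g Glycan (or glycan string).
#' @param dialect Dialect used when `p` is given as text.
#' @param registry Registry.
#' @return List of matches; each has `start`, `end` (0-based, half-open
#'   over the sentineled string), `bindings` (one per wildcard occurrence,
#'   in pattern order), `site` (0-based index of the site anchor or `NA`),
#'   and `matched` (the matched substring).
#' @export
#' @examples
#' find_matches("GN", "Ab3GNb")
#' find_matches("B...A", "B(C)A", registry = abstract_registry())
find_matches <- function(p, g, dialect = "licorr",
                         registry = default_registry()) {
  if (is.character(p)) p <- parse_pattern(p, dialect, registry)
  idx <- subject_index(g, registry)
  out <- list()
  for (start in 0:idx$n) {
    out <- c(out, match_here(p$tokens, idx, start))
  }
  finish_matches(out, idx)
}

match_here <- function(tokens, idx, start) {
  results <- list()
  recurse <- function(k, j, bindings, site) {
    if (k > length(tokens)) {
      results[[length(results) + 1]] <<-
        list(start = start, end = j, bindings = bindings, site = site)
      return(invisible())
    }
    tk <- tokens[[k]]
    switch(tk$type,
      open = , close = {
        ch <- if (tk$type == "open") "(" else ")"
        if (j < idx$n && idx$cv[j + 1] == ch)
          recurse(k + 1, j + 1L, bindings, site)
      },
      raw = {
        len <- nchar(tk$text)
        if (j + len <= idx$n &&
            substr(idx$S, j + 1, j + len) == tk$text)
          recurse(k + 1, j + len, bindings, site)
      },
      site = recurse(k + 1, j, bindings, j),
      any_su = {
        layout <- get0(as.character(j), envir = idx$tok_at)
        if (!is.null(layout))
          recurse(k + 1, layout$end,
                  c(bindings, substr(idx$S, j + 1, layout$end)), site)
      },
      su = {
        res <- match_su_literal(tk$su, idx, j)
        if (!is.null(res))
          recurse(k + 1, res$end, c(bindings, res$bindings), site)
      },
      ligand = , continuation = , branch = {
        for (end in j:idx$n) {
          s <- substr(idx$S, j + 1, end)
          if (classify_substring(tk$type, s))
            recurse(k + 1, end, c(bindings, s), site)
        }
      })
    invisible()
  }
  recurse(1L, start, character(0), NA_integer_)
  results
}

# Match one SU literal at 0-based subject offset j. Returns NULL or
# list(end, bindings) where bindings holds any "$" capture.
match_su_literal <- function(psu, idx, j) {
  layout <- get0(as.character(j), envir = idx$tok_at)
  if (is.null(layout)) return(NULL)
  ssu <- layout$su
  # monosaccharide identity
  sms <- paste(ssu$ms, collapse = "/")
  if (!("?" %in% psu$ms) && !(sms %in% psu$ms) &&
      !(length(ssu$ms) == 1 && ssu$ms %in% psu$ms)) return(NULL)
  at <- layout$ms_end
  bindings <- character(0)
  selems <- layout$elems
  si <- 1L
  pelems <- pattern_elems(psu)
  for (pi in seq_along(pelems)) {
    pe <- pelems[[pi]]
    if (pe$kind == "dollar") {
      cap_start <- at
      if (si <= length(selems) && selems[[si]]$kind == "mods") {
        if (!is.null(pe$spec) &&
            !identical(mods_string(pe$spec), selems[[si]]$value)) return(NULL)
        at <- selems[[si]]$end
        si <- si + 1L
      }
      if (pi == length(pelems)) {
        # bare "$" at the end of the literal swallows the rest of the
        # token so a following literal lands on the next SU boundary
        at <- layout$end
        si <- length(selems) + 1L
      }
      bindings <- c(bindings, substr(idx$S, cap_start + 1, at))
    } else {
      if (si > length(selems)) return(NULL)
      se <- selems[[si]]
      if (se$kind != pe$kind) return(NULL)
      if (!element_value_match(pe, se)) return(NULL)
      at <- se$end
      si <- si + 1L
    }
  }
  list(end = at, bindings = bindings)
}

pattern_elems <- function(su) {
  out <- list()
  if (nzchar(su$marker))
    out[[length(out) + 1]] <- list(kind = "marker", value = su$marker)
  if (length(su$mods))
    out[[length(out) + 1]] <- list(kind = "mods", value = mods_string(su$mods))
  if (!is.null(su$dollar))
    out[[length(out) + 1]] <- list(kind = "dollar", spec = su$dollar$spec)
  if (length(su$anomer))
    out[[length(out) + 1]] <- list(kind = "anomer", value = su$anomer)
  if (length(su$pos))
    out[[length(out) + 1]] <- list(kind = "pos", value = su$pos)
  if (su$open)
    out[[length(out) + 1]] <- list(kind = "open", value = "o")
  out
}

element_value_match <- function(pe, se) {
  pv <- pe$value
  sv <- se$value
  if (pe$kind == "anomer") {
    if ("?" %in% pv) return(TRUE)
    return(sv %in% pv)
  }
  if (pe$kind == "pos") {
    if ("?" %in% pv) return(grepl("^[1-9?]$", sv))
    return(sv %in% pv)
  }
  identical(paste(pv, collapse = "/"), sv)
}

finish_matches <- function(ms, idx) {
  if (!length(ms)) return(list())
  keys <- vapply(ms, function(m)
    paste(m$start, m$end, paste(m$bindings, collapse = "\x01"),
          m$site, sep = "\x02"), character(1))
  keep <- !duplicated(keys)
  ms <- ms[keep]
  starts <- vapply(ms, function(m) as.numeric(m$start), numeric(1))
  bindkey <- vapply(ms, function(m)
    paste(m$bindings, collapse = "\x01"), character(1))
  ends <- vapply(ms, function(m) as.numeric(m$end), numeric(1))
  ord <- order(starts, xtfrm_c(bindkey), ends)
  ms <- ms[ord]
  lapply(ms, function(m) {
    m$start <- as.integer(m$start)
    m$end <- as.integer(m$end)
    m$site <- as.integer(m$site)
    m$matched <- substr(idx$S, m$start + 1, m$end)
    class(m) <- "licorr_match"
    m
  })
}

# C-locale (byte-order) ranking for deterministic lexicographic sorting.
xtfrm_c <- function(x) {
  if (!length(x)) return(integer(0))
  match(x, sort(unique(x), method = "radix"))
}

#' Exhaustive oracle matcher
#'
#' Independently re-derives the match set of [find_matches()] by
#' enumerating, at every start offset, every possible substring assignment
#' to every wildcard, keeping assignments whose classes pass
#' [classify_substring()] and whose concatenation with the literal pattern
#' text reproduces the subject substring. Intended as a test oracle on
#' small subjects; patterns using "?", "/", or "$" uncertainty inside
#' saccharide-unit literals are outside its scope.
#'
#' @inheritParams find_matches
#' @param max_len Guard on the sentineled subject length (default 60).
#' @return As [find_matches()].
#' @export
brute_force_matches <- function(p, g, dialect = "licorr",
                                registry = default_registry(),
                                max_len = 60) {
  if (is.character(p)) p <- parse_pattern(p, dialect, registry)
  idx <- subject_index(g, registry)
  if (idx$n > max_len)
    stop("sentineled subject longer than max_len (", idx$n, " > ", max_len, ")")
  for (tk in p$tokens) {
    if (tk$type == "su") {
      su <- tk$su
      if ("?" %in% su$ms || "?" %in% su$anomer || "?" %in% su$pos ||
          length(su$ms) > 1 || length(su$anomer) > 1 || length(su$pos) > 1 ||
          !is.null(su$dollar) || !is.null(su$alts))
        stop("oracle supports exact saccharide-unit literals only")
    }
  }
  su_starts <- integer(0)
  for (nm in ls(idx$tok_at)) su_starts <- c(su_starts, as.integer(nm))
  out <- list()
  for (start in 0:idx$n) {
    out <- c(out, oracle_here(p$tokens, idx, start, su_starts))
  }
  finish_matches(out, idx)
}

oracle_here <- function(tokens, idx, start, su_starts) {
  results <- list()
  recurse <- function(k, j, bindings, site) {
    if (k > length(tokens)) {
      results[[length(results) + 1]] <<-
        list(start = start, end = j, bindings = bindings, site = site)
      return(invisible())
    }
    tk <- tokens[[k]]
    if (tk$type %in% c("ligand", "continuation", "branch")) {
      for (end in j:idx$n) {
        s <- substr(idx$S, j + 1, end)
        if (classify_substring(tk$type, s))
          recurse(k + 1, end, c(bindings, s), site)
      }
    } else if (tk$type == "any_su") {
      layout <- get0(as.character(j), envir = idx$tok_at)
      if (!is.null(layout))
        recurse(k + 1, layout$end,
                c(bindings, substr(idx$S, j + 1, layout$end)), site)
    } else if (tk$type == "site") {
      recurse(k + 1, j, bindings, j)
    } else {
      txt <- render_token(tk)
      len <- nchar(txt)
      if (j + len <= idx$n && substr(idx$S, j + 1, j + len) == txt) {
        if (tk$type == "su" && !(j %in% su_starts)) return(invisible())
        # an SU literal must cover the subject monosaccharide code fully:
        # reject "N" matching the head of an "NN" token
        if (tk$type == "su") {
          layout <- get0(as.character(j), envir = idx$tok_at)
          if (nchar(paste(layout$su$ms, collapse = "/")) !=
              nchar(paste(tk$su$ms, collapse = "/"))) return(invisible())
        }
        recurse(k + 1, j + len, bindings, site)
      }
    }
    invisible()
  }
  recurse(1L, start, character(0), NA_integer_)
  results
}
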