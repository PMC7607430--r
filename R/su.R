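# Saccharide units
#
# A saccharide unit (SU) is one monosaccharide with its stereo/ring marker,
# modifications, anomericity, and the carbon position by which it attaches
# to the next residue toward the reducing end. Elements are stored as
# character vectors so that "/" alternatives ("ANb3/4") keep all options;
# length zero means the element is absent/unspecified.

new_su <- function(ms = character(0), marker = "", mods = list(),
                   dollar = NULL, anomer = character(0), pos = character(0),
                   open = FALSE, alts = NULL) {
  structure(list(ms = ms, marker = marker, mods = mods, dollar = dollar,
                 anomer = anomer, pos = pos, open = open, alts = alts),
            class = "licorr_su")
}

# Parse one SU starting at 1-based index i of character vector cv
# (offsets reported 0-based). Returns list(su, i) with i just past the SU.
# Grammar: MS code (maximal munch) | "*" | "?", then optional stereo/ring
# marker (' ^ ~), "[mods]", "$"[spec], anomer (a/b/?), position (1-9/?),
# open-form "o". "/" joins in-element alternatives; "//" is handled by the
# caller (complete-SU alternatives).
parse_su_at <- function(cv, i, registry) {
  n <- length(cv)
  start <- i
  su <- new_su()

  read_code <- function(i, codes, what) {
    j <- i
    while (j <= n && is_upper(cv[j])) j <- j + 1
    run <- paste(cv[i:(j - 1)], collapse = "")
    hit <- codes[startsWith(run, codes)]
    if (!length(hit))
      lc_error("unknown_code", i - 1,
               paste0("no registered ", what, " code matches '", run, "'"))
    hit[1]
  }

  # monosaccharide (possibly a "/" set)
  if (cv[i] == "*") {
    su$ms <- "*"
    return(list(su = su, i = i + 1))
  }
  codes <- ms_codes(registry)
  repeat {
    if (i > n || !(is_upper(cv[i]) || cv[i] == "?"))
      lc_error("expected_ms", i - 1, "expected a monosaccharide code")
    if (cv[i] == "?") {
      su$ms <- c(su$ms, "?")
      i <- i + 1
    } else {
      code <- read_code(i, codes, "monosaccharide")
      su$ms <- c(su$ms, code)
      i <- i + nchar(code)
    }
    if (i < n && cv[i] == "/" && (is_upper(cv[i + 1]) || cv[i + 1] == "?")) {
      i <- i + 1
      next
    }
    break
  }

  # stereo/ring marker
  if (i <= n && cv[i] %in% c("'", "^", "~")) {
    su$marker <- cv[i]
    i <- i + 1
  }

  # modifications
  if (i <= n && cv[i] == "[") {
    res <- parse_mod_block(cv, i, registry)
    su$mods <- res$mods
    i <- res$i
  }

  # possible modification "$"
  if (i <= n && cv[i] == "$") {
    i <- i + 1
    su$dollar <- list(spec = NULL)
    if (i <= n && cv[i] == "[") {
      res <- parse_mod_block(cv, i, registry)
      su$dollar$spec <- res$mods
      i <- res$i
    }
  }

  # anomer
  if (i <= n && cv[i] %in% c("a", "b", "?")) {
    repeat {
      su$anomer <- c(su$anomer, cv[i])
      i <- i + 1
      if (i < n && cv[i] == "/" && cv[i + 1] %in% c("a", "b")) {
        i <- i + 1
        next
      }
      break
    }
    # position (only meaningful after an anomer slot)
    if (i <= n && (is_digit(cv[i]) || cv[i] == "?")) {
      repeat {
        su$pos <- c(su$pos, cv[i])
        i <- i + 1
        if (i < n && cv[i] == "/" && (is_digit(cv[i + 1]) || cv[i + 1] == "?")) {
          i <- i + 1
          next
        }
        break
      }
    }
  } else if (i <= n && is_digit(cv[i])) {
    lc_error("position_without_anomer", i - 1,
             "linkage position must follow an anomer (a, b or ?)")
  }

  # open form
  if (i <= n && cv[i] == "o") {
    su$open <- TRUE
    i <- i + 1
  }

  list(su = su, i = i)
}

# "[...]" modification block. Positions accumulate until a modification
# code, which consumes all pending positions: "[2,6D]" is D at carbons 2
# and 6; "[6D,2N]" is D at 6 and N at 2.
parse_mod_block <- function(cv, i, registry) {
  n <- length(cv)
  open_at <- i
  i <- i + 1
  mods <- list()
  pending <- character(0)
  codes <- mod_codes(registry)
  repeat {
    if (i > n) lc_error("unterminated_mods", open_at - 1,
                        "'[' without matching ']'")
    ch <- cv[i]
    if (ch == "]") { i <- i + 1; break }
    if (ch == ",") { i <- i + 1; next }
    p <- character(0)
    if (is_digit(ch) || ch == "?") {
      p <- ch
      i <- i + 1
    }
    if (i <= n && is_upper(cv[i])) {
      j <- i
      while (j <= n && is_upper(cv[j])) j <- j + 1
      run <- paste(cv[i:(j - 1)], collapse = "")
      hit <- codes[startsWith(run, codes)]
      if (!length(hit))
        lc_error("unknown_code", i - 1,
                 paste0("no registered modification code matches '", run, "'"))
      code <- hit[1]
      i <- i + nchar(code)
      mods[[length(mods) + 1]] <- list(pos = c(pending, p), code = code)
      pending <- character(0)
    } else if (length(p)) {
      pending <- c(pending, p)
    } else {
      lc_error("bad_modification", i - 1,
               paste0("unexpected character '", ch, "' in modification block"))
    }
  }
  if (length(pending))
    lc_error("bad_modification", open_at - 1,
             "positions with no modification code")
  list(mods = mods, i = i)
}

# Canonical text of one modification item: positions ascending, "?" last.
mod_item_string <- function(m) {
  p <- m$pos
  if (length(p)) {
    known <- sort(p[p != "?"])
    p <- c(known, p[p == "?"])
  }
  paste0(paste(p, collapse = ","), m$code)
}

mods_string <- function(mods) {
  if (!length(mods)) return("")
  key <- vapply(mods, function(m) {
    if (!length(m$pos) || all(m$pos == "?")) 99 else min(as.integer(m$pos[m$pos != "?"]))
  }, numeric(1))
  items <- vapply(mods[order(key)], mod_item_string, character(1))
  paste0("[", paste(items, collapse = ","), "]")
}

# Canonical written form of an SU (not including "//" alternatives).
su_core_string <- function(su) {
  paste0(paste(su$ms, collapse = "/"),
         su$marker,
         mods_string(su$mods),
         if (!is.null(su$dollar))
           paste0("$", if (!is.null(su$dollar$spec)) mods_string(su$dollar$spec) else ""),
         paste(su$anomer, collapse = "/"),
         paste(su$pos, collapse = "/"),
         if (su$open) "o" else "")
}

su_to_string <- function(su) {
  out <- su_core_string(su)
  if (!is.null(su$alts) && length(su$alts))
    out <- paste(c(out, vapply(su$alts, su_core_string, character(1))),
                 collapse = "//")
  out
}

# Sort key for sibling ordering: known single positions ascend; anything
# unknown, absent, or ambiguous sorts after them. Ties keep written order.
su_pos_key <- function(su) {
  if (length(su$pos) == 1 && su$pos != "?") as.integer(su$pos) else 100L
}
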