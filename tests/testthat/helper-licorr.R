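# Shared helpers for the licorr test suite.

abs_reg <- abstract_registry()

match_sig <- function(ms) {
  vapply(ms, function(m)
    paste(m$start, m$end, m$site, paste(m$bindings, collapse = "|"),
          sep = ":"), character(1))
}

# Splice a match's bindings back into the pattern and drop the site
# anchor; by the matching contract this reproduces the matched substring.
splice_match <- function(p, m) {
  out <- character(0)
  bi <- 1L
  for (tk in p$tokens) {
    if (tk$type %in% c("ligand", "continuation", "branch", "any_su")) {
      out <- c(out, m$bindings[bi]); bi <- bi + 1L
    } else if (tk$type == "su" && !is.null(tk$su$dollar)) {
      su <- tk$su; su$dollar <- NULL
      pre <- licorr:::su_to_string(su)
      out <- c(out, pre, m$bindings[bi]); bi <- bi + 1L
    } else if (tk$type == "site") {
      # zero width
    } else {
      out <- c(out, licorr:::render_token(tk))
    }
  }
  paste(out, collapse = "")
}

# Multiset of (parent, child, link position) edges, order-free.
edge_multiset <- function(g, registry = default_registry()) {
  g <- licorr:::as_glycan(g, registry = registry)
  out <- character(0)
  walk <- function(node) {
    for (ch in node$children) {
      out <<- c(out, paste(paste(node$su$ms, collapse = "/"),
                           paste(ch$su$ms, collapse = "/"),
                           paste(ch$su$pos, collapse = "/"), sep = "~"))
      walk(ch)
    }
  }
  walk(g$root)
  sort(out)
}

n_leaves <- function(g, registry = default_registry()) {
  g <- licorr:::as_glycan(g, registry = registry)
  n <- 0L
  walk <- function(node) {
    if (!length(node$children)) n <<- n + 1L
    for (ch in node$children) walk(ch)
  }
  walk(g$root)
  n
}
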