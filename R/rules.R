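#' Reaction rules
#'
#' A reaction rule is an enzyme name, a substrate pattern, a product
#' pattern, and a constraint, optionally with a compartment (e.g. cis /
#' medial / trans Golgi, ER, lysosome) and an Enzyme Commission number.
#' Substrate and product must carry the same wildcard occurrences in the
#' same order so that bindings transfer positionally; the reaction site is
#' never written in the patterns - it is computed as the position of the
#' first difference between the substrate and product strings.
#'
#' @name rules
NULL

#' Construct a reaction rule
#'
#' @param enzyme Enzyme name.
#' @param substrate,product Patterns (text or `licorr_pattern`) sharing
#'   the same wildcard occurrence sequence.
#' @param constraint Constraint text or `licorr_constraint` (blank means
#'   unconstrained).
#' @param compartment,ec Optional compartment name and EC number.
#' @param dialect Dialect in which text arguments are parsed.
#' @param annotations Named list of opaque annotations (e.g. rate
#'   strings), carried but never interpreted.
#' @param registry Registry.
#' @return A `licorr_rule`.
#' @export
#' @examples
#' new_rule("b4GalT", "(GN", "(Ab4GN", "!@GNb4)(...Ma6)Mb4")
new_rule <- function(enzyme, substrate, product, constraint,
                     compartment = NA_character_, ec = NA_character_,
                     dialect = "licorr", annotations = list(),
                     registry = default_registry()) {
  sub_p <- if (inherits(substrate, "licorr_pattern")) substrate
           else parse_pattern(substrate, dialect, registry)
  prod_p <- if (inherits(product, "licorr_pattern")) product
            else parse_pattern(product, dialect, registry)
  con <- if (inherits(constraint, "licorr_constraint")) constraint
         else parse_constraint(constraint, dialect, registry)
  if (!identical(pattern_wildcards(sub_p), pattern_wildcards(prod_p)))
    stop("substrate and product wildcard sequences differ for enzyme ",
         enzyme)
  if (any(vapply(sub_p$tokens, function(t) t$type == "site", logical(1))) ||
      any(vapply(prod_p$tokens, function(t) t$type == "site", logical(1))))
    stop("the reaction site is computed, not written: remove the site ",
         "anchor from the substrate/product of enzyme ", enzyme)
  structure(list(enzyme = enzyme, substrate = sub_p, product = prod_p,
                 constraint = con, compartment = compartment, ec = ec,
                 dialect = dialect, annotations = annotations),
            class = "licorr_rule")
}

#' Construct a rule table from a list of rules
#'
#' @param rules List of `licorr_rule` objects.
#' @param source Optional provenance string.
#' @return A `licorr_ruletable`.
#' @export
new_rule_table <- function(rules, source = "") {
  structure(list(rules = rules, source = source), class = "licorr_ruletable")
}

#' @export
length.licorr_ruletable <- function(x) length(x$rules)

#' @export
print.licorr_ruletable <- function(x, ...) {
  cat("<licorr_ruletable> ", length(x$rules), " rules\n", sep = "")
  invisible(x)
}

rule_col <- function(tab, names_wanted) {
  hit <- match(names_wanted, tolower(names(tab)))
  hit <- hit[!is.na(hit)]
  if (length(hit)) names(tab)[hit[1]] else NULL
}

#' Read a reaction-rule table
#'
#' Reads a TSV (or CSV) with a header row. Required columns (case
#' insensitive): `enzyme`, `reactant` or `substrate`, `product`,
#' `constraint`; optional: `compartment`, `ec`. Any further columns (such
#' as rate or adjustment strings) are carried verbatim as annotations and
#' never interpreted.
#'
#' @param path File path or connection.
#' @param dialect Dialect of the patterns and constraints.
#' @param registry Registry.
#' @param sep Field separator; inferred from the file extension
#'   (`.csv` means comma) when `NULL`.
#' @param strict Abort on the first malformed row instead of skipping it
#'   with a warning.
#' @return A `licorr_ruletable`.
#' @export
read_rule_table <- function(path, dialect = "licorr",
                            registry = default_registry(), sep = NULL,
                            strict = FALSE) {
  if (is.null(sep))
    sep <- if (is.character(path) && grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  enz_c <- rule_col(tab, "enzyme")
  sub_c <- rule_col(tab, c("reactant", "substrate"))
  prd_c <- rule_col(tab, "product")
  con_c <- rule_col(tab, "constraint")
  missing <- c(enzyme = is.null(enz_c), substrate = is.null(sub_c),
               product = is.null(prd_c), constraint = is.null(con_c))
  if (any(missing))
    stop("rule table lacks required column(s): ",
         paste(names(missing)[missing], collapse = ", "))
  cmp_c <- rule_col(tab, c("compartment", "localization"))
  ec_c <- rule_col(tab, c("ec", "ec_number"))
  extra <- setdiff(names(tab), c(enz_c, sub_c, prd_c, con_c, cmp_c, ec_c))
  rules <- list()
  for (i in seq_len(nrow(tab))) {
    ann <- as.list(tab[i, extra, drop = FALSE])
    r <- tryCatch(
      new_rule(tab[i, enz_c], tab[i, sub_c], tab[i, prd_c], tab[i, con_c],
               compartment = if (!is.null(cmp_c)) tab[i, cmp_c] else NA,
               ec = if (!is.null(ec_c)) tab[i, ec_c] else NA,
               dialect = dialect, annotations = ann, registry = registry),
      error = function(e) e)
    if (inherits(r, "error")) {
      if (strict) stop("row ", i, ": ", conditionMessage(r))
      warning("skipping row ", i, ": ", conditionMessage(r))
    } else {
      rules[[length(rules) + 1]] <- r
    }
  }
  new_rule_table(rules, source = if (is.character(path)) path else "")
}

#' Write a reaction-rule table as TSV
#'
#' Round-trips through [read_rule_table()]: patterns and constraints are
#' emitted in the symbols of the rules' dialect as parsed.
#'
#' @param t A `licorr_ruletable`.
#' @param path Output file path or connection.
#' @export
write_rule_table <- function(t, path) {
  render_in_dialect <- function(p, dialect) {
    txt <- render_pattern(p)
    if (dialect == "legacy") modernize_inverse(txt) else txt
  }
  rows <- lapply(t$rules, function(r) {
    base <- data.frame(
      enzyme = r$enzyme,
      substrate = render_in_dialect(r$substrate, r$dialect),
      product = render_in_dialect(r$product, r$dialect),
      constraint = {
        txt <- render_constraint(r$constraint)
        if (r$dialect == "legacy") modernize_inverse(txt) else txt
      },
      stringsAsFactors = FALSE)
    base$compartment <- r$compartment
    base$ec <- r$ec
    for (nm in names(r$annotations)) base[[nm]] <- r$annotations[[nm]]
    base
  })
  nm <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    for (miss in setdiff(nm, names(r))) r[[miss]] <- NA
    r[nm]
  }))
  drop <- vapply(out, function(col) all(is.na(col)), logical(1))
  out <- out[, !drop, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(out)
}

#' Translate legacy symbols to LiCoRR
#'
#' Applies the consensus symbol mapping: `~` to `!`, `|` to `+`, `*` to
#' `@`, and `#` count atoms to `n`; `&`, `or`, `...` and `_` are shared
#' and pass through. The output parses in the LiCoRR dialect to an
#' expression structurally equal to the legacy parse.
#'
#' @param text Legacy pattern or constraint text.
#' @param role `"pattern"` or `"constraint"` (controls whether `~` is
#'   treated as negation).
#' @return LiCoRR text.
#' @export
#' @examples
#' modernize("~Ma6", "constraint")
#' modernize("*...GNb2|Ma3", "constraint")
#' modernize("#A = 0", "constraint")
modernize <- function(text, role = c("constraint", "pattern")) {
  role <- match.arg(role)
  s <- gsub("…", "...", text)
  s <- gsub("|", "+", s, fixed = TRUE)
  s <- gsub("*", "@", s, fixed = TRUE)
  if (role == "constraint") {
    s <- gsub("~", "!", s, fixed = TRUE)
    s <- gsub("#", "n", s, fixed = TRUE)
    s <- gsub("[[:space:]]*(<=|>=|=|<|>)[[:space:]]*", "\\1", s)
  }
  s
}

# LiCoRR symbols back to the legacy dialect (used when writing legacy
# tables): the inverse of the pattern-symbol part of modernize().
modernize_inverse <- function(s) {
  s <- gsub("+", "|", s, fixed = TRUE)
  s <- gsub("@", "*", s, fixed = TRUE)
  s <- gsub("!", "~", s, fixed = TRUE)
  s <- gsub("\\bn([A-Z])", "#\\1", s)
  s
}

#' Reaction-site index of a rule instance
#'
#' The reaction site is the 0-based position of the first character at
#' which the substrate and product strings differ, both taken over the
#' sentineled canonical form.
#'
#' @param substrate_str,product_str Instantiated (sentineled) strings.
#' @return Integer index.
#' @export
#' @examples
#' compute_site("(GNb2Ma3(GNb2Ma6)Mb4GNb4GN", "(Ab4GNb2Ma3(GNb2Ma6)Mb4GNb4GN")
compute_site <- function(substrate_str, product_str) {
  if (identical(substrate_str, product_str))
    stop("substrate and product strings are identical; no reaction site")
  a <- strsplit(substrate_str, "", fixed = TRUE)[[1]]
  b <- strsplit(product_str, "", fixed = TRUE)[[1]]
  n <- min(length(a), length(b))
  if (n > 0)
    for (i in seq_len(n)) if (a[i] != b[i]) return(i - 1L)
  n
}

render_with_bindings <- function(p, bindings) {
  out <- character(0)
  bi <- 1L
  for (tk in p$tokens) {
    if (tk$type %in% wildcard_kinds) {
      out <- c(out, bindings[bi])
      bi <- bi + 1L
    } else if (tk$type == "site") {
      # zero width
    } else {
      out <- c(out, render_token(tk))
    }
  }
  paste(out, collapse = "")
}

#' Apply a reaction rule to a glycan
#'
#' Finds every substrate-pattern match, splices the wildcard bindings into
#' the product pattern, computes the reaction site as the first difference
#' between the instantiated strings, and keeps the product when the rule's
#' constraint evaluates true at that site. Products are canonicalized,
#' the glycan's conjugate is re-attached unchanged, and identical
#' (product, site) pairs are deduplicated.
#'
#' Note that an SU literal's "$" capture also transfers, so a possibly
#' modified residue keeps its modifications in the product.
#'
#' @param r A `licorr_rule`.
#' @param g Glycan or glycan string.
#' @param registry Registry.
#' @param macros Macro table for constraint expansion.
#' @return Data frame with columns `enzyme`, `site`, `product`.
#' @export
#' @examples
#' r <- new_rule("FucT3", "Ab3GNb", "Ab3(Fa4)GNb", "")
#' apply_rule(r, "Ab3GNb")
apply_rule <- function(r, g, registry = default_registry(),
                       macros = default_macros()) {
  g <- as_glycan(g, registry = registry)
  conj <- g$conjugate
  core <- new_glycan(strip_markers(g$root), dialect = g$dialect)
  S <- sentinel(serialize_glycan(core, registry))
  # "$" captures participate in splicing but are not wildcard occurrences
  # shared between substrate and product; splice them into the substrate
  # instance only.
  matches <- find_matches(r$substrate, core, registry = registry)
  results <- list()
  for (m in matches) {
    prod_bind <- transfer_bindings(r$substrate, r$product, m$bindings)
    inst <- paste0(substr(S, 1, m$start), prod_bind,
                   substr(S, m$end + 1, nchar(S)))
    site <- compute_site(S, inst)
    keep <- evaluate_constraint(r$constraint, core, site = site,
                                registry = registry, macros = macros)
    if (!keep) next
    prod_core <- sub("^\\(", "", inst)
    prod_g <- tryCatch(parse_glycan(prod_core, r$dialect, registry),
                       error = function(e) e)
    if (inherits(prod_g, "error"))
      stop("product of enzyme ", r$enzyme, " does not parse: '",
           prod_core, "' (", conditionMessage(prod_g), ")")
    prod_g$conjugate <- conj
    results[[length(results) + 1]] <-
      list(site = site, product = serialize_glycan(prod_g, registry))
  }
  if (!length(results))
    return(data.frame(enzyme = character(0), site = integer(0),
                      product = character(0), stringsAsFactors = FALSE))
  out <- data.frame(enzyme = r$enzyme,
                    site = vapply(results, function(x) as.integer(x$site),
                                  integer(1)),
                    product = vapply(results, `[[`, character(1), "product"),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("site", "product")]), , drop = FALSE]
  out <- out[order(out$site, xtfrm_c(out$product)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply every rule of a table to a glycan
#'
#' @param t A `licorr_ruletable`.
#' @inheritParams apply_rule
#' @param enzyme Optional enzyme name filter.
#' @return Data frame with columns `rule_id`, `enzyme`, `site`, `product`.
#' @export
apply_rules <- function(t, g, enzyme = NULL, registry = default_registry(),
                        macros = default_macros()) {
  out <- list()
  for (i in seq_along(t$rules)) {
    r <- t$rules[[i]]
    if (!is.null(enzyme) && !identical(r$enzyme, enzyme)) next
    res <- apply_rule(r, g, registry, macros)
    if (nrow(res)) {
      res$rule_id <- i
      out[[length(out) + 1]] <- res
    }
  }
  if (!length(out))
    return(data.frame(rule_id = integer(0), enzyme = character(0),
                      site = integer(0), product = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[c("rule_id", "enzyme", "site", "product")]
}

#' Split disjunctive constraints into separate rules
#'
#' Rewrites each rule whose constraint contains "or" as several rules with
#' a single OR-free constraint each (the one-rule-per-line convention);
#' enzyme, substrate, product, compartment and EC number are copied, and
#' row order is preserved.
#'
#' @param t A `licorr_ruletable`.
#' @return A `licorr_ruletable`.
#' @export
#' @examples
#' # a 4-way "or" becomes 4 rules
split_rules <- function(t) {
  rules <- list()
  for (r in t$rules) {
    parts <- atomize_disjunction(r$constraint)
    for (p in parts) {
      rr <- r
      rr$constraint <- p
      rules[[length(rules) + 1]] <- rr
    }
  }
  new_rule_table(rules, source = t$source)
}

# Substitute the i-th substrate wildcard binding into the i-th product
# wildcard. Bindings arrive in substrate token order and interleave "$"
# captures with wildcard bindings; both classes transfer positionally
# (the j-th "$"-carrying SU literal of the product receives the capture of
# the j-th "$" literal of the substrate).
transfer_bindings <- function(sub_p, prod_p, bindings) {
  slot_types <- function(p) {
    out <- character(0)
    for (tk in p$tokens) {
      if (tk$type %in% wildcard_kinds) out <- c(out, "wild")
      else if (tk$type == "su" && !is.null(tk$su$dollar))
        out <- c(out, "dollar")
    }
    out
  }
  st <- slot_types(sub_p)
  wild_pos <- which(st == "wild")
  dollar_pos <- which(st == "dollar")
  w <- 0L
  d <- 0L
  out <- character(0)
  for (tk in prod_p$tokens) {
    if (tk$type %in% wildcard_kinds) {
      w <- w + 1L
      out <- c(out, bindings[wild_pos[w]])
    } else if (tk$type == "su" && !is.null(tk$su$dollar)) {
      d <- d + 1L
      if (d <= length(dollar_pos)) {
        su_plain <- tk$su
        su_plain$dollar <- NULL
        out <- c(out, paste0(su_to_string(su_plain), bindings[dollar_pos[d]]))
      } else {
        out <- c(out, render_token(tk))
      }
    } else if (tk$type == "site") {
      # zero width
    } else {
      out <- c(out, render_token(tk))
    }
  }
  paste(out, collapse = "")
}
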