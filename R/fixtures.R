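#' Seeded generators and printed fixtures
#'
#' Property tests need streams of random but reproducible glycans and
#' patterns. [random_glycan()] draws canonical glycans under explicit size
#' and uncertainty parameters with a pinned Mersenne-Twister stream (the
#' caller's RNG state is untouched); [pattern_from_glycan()] cuts
#' token-aligned substrings out of a glycan's sentineled string and
#' replaces them with wildcards of a class valid for the removed text, so
#' the derived pattern is guaranteed at least one match.
#'
#' @name fixtures
NULL

#' Generator parameters
#'
#' @param seed Integer seed.
#' @param max_depth Maximum chain depth (1 gives single-residue glycans).
#' @param max_children_per_node 0-3 children per residue.
#' @param alphabet `"default"` (real monosaccharides) or `"abstract"`
#'   (single letters A-Z).
#' @param p_modification Probability that a residue carries one
#'   modification.
#' @param p_unknown_anomer Probability that a linkage anomer is "?".
#' @return A `licorr_genparams` list.
#' @export
gen_params <- function(seed = 1L, max_depth = 4L, max_children_per_node = 2L,
                       alphabet = c("default", "abstract"),
                       p_modification = 0.1, p_unknown_anomer = 0.05) {
  alphabet <- match.arg(alphabet)
  stopifnot(max_depth >= 1, max_children_per_node >= 0,
            max_children_per_node <= 3,
            p_modification >= 0, p_modification <= 1,
            p_unknown_anomer >= 0, p_unknown_anomer <= 1)
  structure(list(seed = as.integer(seed), max_depth = as.integer(max_depth),
                 max_children_per_node = as.integer(max_children_per_node),
                 alphabet = alphabet, p_modification = p_modification,
                 p_unknown_anomer = p_unknown_anomer),
            class = "licorr_genparams")
}

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a random canonical glycan
#'
#' @param params A [gen_params()] object (or an integer, taken as the
#'   seed with default parameters).
#' @param registry Registry override; defaults to the profile named in
#'   `params$alphabet`.
#' @return A canonical `licorr_glycan`.
#' @export
#' @examples
#' serialize_glycan(random_glycan(gen_params(seed = 7)))
random_glycan <- function(params = gen_params(),
                          registry = NULL) {
  if (is.numeric(params)) params <- gen_params(seed = params)
  reg <- registry %||% switch(params$alphabet,
                              default = default_registry(),
                              abstract = abstract_registry())
  codes <- reg$mono$lc_code
  mod_palette <- intersect(c("S", "P", "ME", "T"), reg$mods$lc_code)
  with_local_seed(params$seed, {
    build <- function(depth, link_pos) {
      su <- new_su(ms = sample(codes, 1))
      anomer <- if (stats::runif(1) < params$p_unknown_anomer) "?"
                else sample(c("a", "b"), 1)
      su$anomer <- anomer
      if (!is.null(link_pos)) su$pos <- as.character(link_pos)
      if (stats::runif(1) < params$p_modification && length(mod_palette))
        su$mods <- list(list(pos = sample(as.character(7:9), 1),
                             code = sample(mod_palette, 1)))
      nk <- if (depth >= params$max_depth) 0L else
        sample(0:params$max_children_per_node, 1,
               prob = c(2, rep(1, params$max_children_per_node)))
      children <- list()
      if (nk > 0) {
        positions <- sample(2:6, nk)
        for (p in positions)
          children[[length(children) + 1]] <- build(depth + 1L, p)
      }
      new_node(su, children)
    }
    root <- build(1L, NULL)
    g <- new_glycan(root)
    # canonical by re-parsing the canonical serialization
    parse_glycan(serialize_glycan(g, reg), registry = reg)
  })
}

#' Derive a pattern guaranteed to match a glycan
#'
#' Replaces 0-2 token-aligned substrings of the sentineled canonical
#' string with wildcards whose class is valid for the removed text
#' (ligand for balanced text, continuation for net-closing text, possible
#' branch for branch-shaped text, `"*"` for a single complete residue).
#'
#' @param g Canonical glycan.
#' @param seed Integer seed.
#' @param registry Registry.
#' @return A `licorr_pattern` with at least one match in `g`.
#' @export
pattern_from_glycan <- function(g, seed = 1L,
                                registry = default_registry()) {
  g <- as_glycan(g, registry = registry)
  idx <- subject_index(g, registry)
  S <- idx$S
  n <- idx$n
  # token-aligned boundaries: paren chars and SU token spans
  bounds <- c(0L, n)
  for (i in seq_len(n)) if (idx$cv[i] %in% c("(", ")")) bounds <- c(bounds, i - 1L, i)
  su_spans <- list()
  for (nm in ls(idx$tok_at)) {
    lay <- get(nm, envir = idx$tok_at)
    bounds <- c(bounds, lay$start, lay$end)
    su_spans[[length(su_spans) + 1]] <- c(lay$start, lay$end)
  }
  bounds <- sort(unique(bounds))
  with_local_seed(seed, {
    k <- sample(0:2, 1)
    chosen <- list()
    tries <- 0L
    while (length(chosen) < k && tries < 40L) {
      tries <- tries + 1L
      b <- sort(sample(bounds, 2))
      if (b[1] == b[2]) next
      if (any(vapply(chosen, function(cs)
        b[1] < cs$end && cs$start < b[2], logical(1)))) next
      txt <- substr(S, b[1] + 1, b[2])
      classes <- character(0)
      if (any(vapply(su_spans, function(sp)
        sp[1] == b[1] && sp[2] == b[2], logical(1)))) classes <- c(classes, "*")
      if (classify_substring("ligand", txt)) classes <- c(classes, "...")
      if (classify_substring("continuation", txt)) classes <- c(classes, "_")
      if (classify_substring("branch", txt)) classes <- c(classes, "+")
      if (!length(classes)) next
      chosen[[length(chosen) + 1]] <-
        list(start = b[1], end = b[2], wc = sample(classes, 1))
    }
    out <- S
    if (length(chosen)) {
      ord <- order(-vapply(chosen, function(cs) as.numeric(cs$start),
                           numeric(1)))
      for (cs in chosen[ord])
        out <- paste0(substr(out, 1, cs$start), cs$wc,
                      substr(out, cs$end + 1, nchar(out)))
    }
    parse_pattern(out, "licorr", registry)
  })
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "licorr")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)
  p
}

#' Printed worked-example fixtures
#'
#' Every worked-example string and rule table used across the package
#' tests, under stable names: the M9 high-mannose glycan, the biantennary
#' core, the galactose/fucose reactant-product pair with its
#' IUPAC-condensed forms, the branch-reordering example, the schematic
#' wildcard matrix (with expected match/no-match cells), and the three
#' reaction-rule tables (the one-row disjunctive b4GalT table, its
#' four-row split form, and the 13-rule N-glycan set).
#'
#' @return Named list of fixtures.
#' @export
paper_fixtures <- function() {
  grid <- data.frame(
    glycan = c(rep("B(C)A", 6), rep("BCA", 3), rep("E(D(C)B)A", 3)),
    pattern = c("B_A", "B...A", "B+A", "B(C_A", "B(C+A", "B(C...A",
                "B_A", "B...A", "B+A",
                "E(D_A", "E(D...A", "E(D+A"),
    expected = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                 TRUE, TRUE, FALSE,
                 TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  list(
    m9 = "Ma2Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN;Asn",
    m9_core = "Ma2Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN",
    biantennary = "GNb2Ma3(GNb2Ma6)Mb4GNb4GN",
    chitobiose_capped = "Ma3(Ma6)Mb4GNb4GN",
    table1 = list(reactant = "Ab3GNb", product = "Ab3(Fa4)GNb",
                  reactant_iupac = "Gal(β1-3)GlcNAc(β1-",
                  product_iupac = "Gal(β1-3)[Fuc(α1-4)]GlcNAc(β1-"),
    branch_reorder = list(input = "Ab4(GNb4GNb3)(GNb6)Ab4Gb",
                          canonical = "GNb4GNb3(Ab4)(GNb6)Ab4Gb"),
    fig1 = "KJ(IH)GF(D(E)(C)B)A",
    ur5 = "Ab4//Ga2Aa3",
    ur6 = "NNa6=1%|1%Ab4GNb2Ma3(1%Ab4GNb2Ma6)Mb4Gb",
    mani_rule = list(enzyme = "ManI", substrate = "(Ma2Ma", product = "(Ma",
                     constraint = "!@2Ma3(...Ma6)Ma6 & !Ga3"),
    table6 = grid,
    table7_path = fixture_path("table7_rules.tsv"),
    table8_path = fixture_path("table8_rules.tsv"),
    table9_path = fixture_path("table9_rules.tsv"))
}
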