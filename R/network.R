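#' Biosynthesis network expansion
#'
#' Starting from seed glycans, [expand_network()] repeatedly applies every
#' rule of a table to the current frontier (breadth-first closure) until no
#' new canonical product appears or a limit triggers. Node identity is the
#' canonical glycan string including any conjugate suffix. The result is
#' deterministic and independent of the order in which seeds and rules are
#' supplied: nodes and edges are kept as sets and emitted sorted, and
#' edges reference rules through a content-based canonical index.
#'
#' @name network
NULL

new_network <- function(nodes, edges, truncated = FALSE) {
  structure(list(nodes = nodes, edges = edges, truncated = truncated),
            class = "licorr_network")
}

#' @export
print.licorr_network <- function(x, ...) {
  cat("<licorr_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges", if (x$truncated) " (truncated)", "\n", sep = "")
  invisible(x)
}

rule_sort_key <- function(r) {
  paste(r$enzyme, render_pattern(r$substrate), render_pattern(r$product),
        render_constraint(r$constraint),
        if (is.na(r$compartment)) "" else r$compartment,
        sep = "\x01")
}

empty_edges <- function() {
  data.frame(substrate = character(0), product = character(0),
             enzyme = character(0), rule_id = integer(0),
             site = integer(0), stringsAsFactors = FALSE)
}

#' Expand a reaction network from seed glycans
#'
#' @param seeds Character vector of glycan strings (or list of glycans).
#' @param t A `licorr_ruletable`.
#' @param max_iterations Maximum number of breadth-first generations.
#' @param max_su Glycans with more residues than this are kept as nodes
#'   but not expanded further (repetitive elongation rules such as
#'   poly-LacNAc extension otherwise never terminate).
#' @param max_nodes Hard cap on the node count.
#' @param compartment_order Optional ordered compartment names (e.g.
#'   `c("cis", "medial", "trans")`). Rules of compartment k are applied
#'   only after the closure under compartment k-1 has stabilized; rules
#'   without a compartment participate in every stage.
#' @param registry Registry.
#' @param macros Constraint macro table.
#' @return A `licorr_network`: sorted `nodes`, an edge data frame
#'   (`substrate`, `product`, `enzyme`, `rule_id`, `site`), and a
#'   `truncated` flag set when a limit stopped the expansion.
#' @export
#' @examples
#' t <- new_rule_table(list(new_rule("FucT3", "Ab3GNb", "Ab3(Fa4)GNb", "")))
#' expand_network("Ab3GNb", t)
expand_network <- function(seeds, t, max_iterations = 25L, max_su = 30L,
                           max_nodes = 5000L,
                           compartment_order = NULL,
                           registry = default_registry(),
                           macros = default_macros()) {
  stopifnot(max_iterations >= 1, max_su >= 1, max_nodes >= 1)
  seed_keys <- vapply(seeds, function(s)
    serialize_glycan(as_glycan(s, registry = registry), registry),
    character(1))
  seed_keys <- sort(unique(seed_keys), method = "radix")

  # canonical rule order: content-sorted, so permuting table rows cannot
  # change ids or output bytes
  ord <- order(xtfrm_c(vapply(t$rules, rule_sort_key, character(1))))
  rules <- t$rules[ord]

  stages <- if (is.null(compartment_order)) list(seq_along(rules)) else {
    lapply(compartment_order, function(cp)
      which(vapply(rules, function(r)
        is.na(r$compartment) || identical(r$compartment, cp), logical(1))))
  }

  nodes <- seed_keys
  edges <- list()
  edge_keys <- character(0)
  truncated <- FALSE

  for (stage in stages) {
    frontier <- nodes
    iter <- 0L
    while (length(frontier) && iter < max_iterations) {
      iter <- iter + 1L
      new_frontier <- character(0)
      for (nk in sort(frontier, method = "radix")) {
        g <- parse_glycan(nk, registry = registry)
        if (count_residues(g, registry = registry) > max_su) next
        for (ri in stage) {
          res <- apply_rule(rules[[ri]], g, registry, macros)
          for (k in seq_len(nrow(res))) {
            prod <- res$product[k]
            if (identical(prod, nk)) next
            ek <- paste(nk, prod, ri, res$site[k], sep = "\x01")
            if (!ek %in% edge_keys) {
              edge_keys <- c(edge_keys, ek)
              edges[[length(edges) + 1]] <-
                data.frame(substrate = nk, product = prod,
                           enzyme = rules[[ri]]$enzyme, rule_id = ri,
                           site = res$site[k], stringsAsFactors = FALSE)
            }
            if (!prod %in% nodes) {
              if (length(nodes) >= max_nodes) {
                truncated <- TRUE
                next
              }
              nodes <- c(nodes, prod)
              new_frontier <- c(new_frontier, prod)
            }
          }
        }
      }
      frontier <- new_frontier
    }
    if (length(frontier)) truncated <- TRUE
  }

  edf <- if (length(edges)) do.call(rbind, edges) else empty_edges()
  edf <- edf[order(xtfrm_c(edf$substrate), xtfrm_c(edf$product),
                   edf$rule_id, edf$site), , drop = FALSE]
  rownames(edf) <- NULL
  new_network(sort(nodes, method = "radix"), edf, truncated)
}

#' Export a reaction network
#'
#' Three lossless formats: `tsv_edges` (one edge per line, isolated nodes
#' as rows with an empty product), `json`, and `graphml` (node ids are the
#' glycan strings; enzyme, rule id and site are edge attributes).
#'
#' @param n A `licorr_network`.
#' @param path Output file.
#' @param format `"tsv_edges"`, `"json"`, or `"graphml"`; inferred from
#'   the file extension when `NULL`.
#' @return `path`, invisibly.
#' @export
export_network <- function(n, path, format = NULL) {
  format <- format %||% infer_format(path)
  switch(format,
    tsv_edges = {
      edf <- n$edges
      lone <- setdiff(n$nodes, c(edf$substrate, edf$product))
      if (length(lone))
        edf <- rbind(edf, data.frame(substrate = lone, product = "",
                                     enzyme = "", rule_id = NA_integer_,
                                     site = NA_integer_,
                                     stringsAsFactors = FALSE))
      utils::write.table(edf, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
    },
    json = {
      jsonlite::write_json(list(nodes = n$nodes, edges = n$edges),
                           path, auto_unbox = FALSE, digits = NA,
                           dataframe = "columns", pretty = TRUE)
    },
    graphml = {
      doc <- xml2::xml_new_root(
        "graphml",
        xmlns = "http://graphml.graphdrawing.org/xmlns")
      for (k in list(c("enzyme", "string"), c("rule_id", "int"),
                     c("site", "int")))
        xml2::xml_add_child(doc, "key", id = k[1], `for` = "edge",
                            attr.name = k[1], attr.type = k[2])
      graph <- xml2::xml_add_child(doc, "graph", id = "G",
                                   edgedefault = "directed")
      for (nd in n$nodes)
        xml2::xml_add_child(graph, "node", id = nd)
      for (i in seq_len(nrow(n$edges))) {
        e <- xml2::xml_add_child(graph, "edge",
                                 source = n$edges$substrate[i],
                                 target = n$edges$product[i])
        xml2::xml_add_child(e, "data", key = "enzyme", n$edges$enzyme[i])
        xml2::xml_add_child(e, "data", key = "rule_id",
                            as.character(n$edges$rule_id[i]))
        xml2::xml_add_child(e, "data", key = "site",
                            as.character(n$edges$site[i]))
      }
      xml2::write_xml(doc, path)
    },
    stop("unknown format: ", format))
  invisible(path)
}

infer_format <- function(path) {
  if (grepl("\\.graphml$", path)) "graphml"
  else if (grepl("\\.json$", path)) "json"
  else "tsv_edges"
}

#' Import a reaction network written by [export_network()]
#'
#' @inheritParams export_network
#' @return A `licorr_network`.
#' @export
import_network <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  switch(format,
    tsv_edges = {
      tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c(substrate = "character",
                                              product = "character",
                                              enzyme = "character"))
      lone <- tab[!nzchar(tab$product) | is.na(tab$product), , drop = FALSE]
      edf <- tab[nzchar(tab$product) & !is.na(tab$product), , drop = FALSE]
      nodes <- sort(unique(c(edf$substrate, edf$product, lone$substrate)),
                    method = "radix")
      rownames(edf) <- NULL
      new_network(nodes, edf)
    },
    json = {
      x <- jsonlite::read_json(path, simplifyVector = TRUE)
      edf <- if (length(x$edges) && length(x$edges$substrate))
        as.data.frame(x$edges, stringsAsFactors = FALSE) else empty_edges()
      new_network(as.character(x$nodes), edf)
    },
    graphml = {
      doc <- xml2::read_xml(path)
      ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
      nodes <- xml2::xml_attr(
        xml2::xml_find_all(doc, ".//g:node", ns), "id")
      enodes <- xml2::xml_find_all(doc, ".//g:edge", ns)
      edf <- if (length(enodes)) {
        data.frame(
          substrate = xml2::xml_attr(enodes, "source"),
          product = xml2::xml_attr(enodes, "target"),
          enzyme = vapply(enodes, function(e) xml2::xml_text(
            xml2::xml_find_first(e, "./g:data[@key='enzyme']", ns)),
            character(1)),
          rule_id = as.integer(vapply(enodes, function(e) xml2::xml_text(
            xml2::xml_find_first(e, "./g:data[@key='rule_id']", ns)),
            character(1))),
          site = as.integer(vapply(enodes, function(e) xml2::xml_text(
            xml2::xml_find_first(e, "./g:data[@key='site']", ns)),
            character(1))),
          stringsAsFactors = FALSE)
      } else empty_edges()
      new_network(sort(nodes, method = "radix"), edf)
    },
    stop("unknown format: ", format))
}
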