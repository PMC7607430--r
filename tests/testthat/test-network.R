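fx <- paper_fixtures()
t8 <- read_rule_table(fx$table8_path, dialect = "legacy")

test_that("expansion reaches the closure of seed glycans", {
  t1 <- new_rule_table(list(new_rule("FucT3", "Ab3GNb", "Ab3(Fa4)GNb", "")))
  net1 <- expand_network("Ab3GNb", t1)
  expect_length(net1$nodes, 2)
  expect_equal(nrow(net1$edges), 1)
  expect_false(net1$truncated)

  net0 <- expand_network("Ab3GNb", new_rule_table(list()))
  expect_length(net0$nodes, 1)
  expect_equal(nrow(net0$edges), 0)

  net <- expand_network(fx$biantennary, t8)
  expect_length(net$nodes, 4)
  expect_equal(nrow(net$edges), 4)
  # every node is reachable from the seed
  reach <- fx$biantennary
  repeat {
    nxt <- unique(c(reach, net$edges$product[net$edges$substrate %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(reach, net$nodes)
})

test_that("expansion output is independent of seed and rule order", {
  seeds <- c(fx$biantennary, "Ab3GNb")
  t_mixed <- new_rule_table(c(t8$rules,
                              list(new_rule("FucT3", "Ab3GNb",
                                            "Ab3(Fa4)GNb", ""))))
  t_perm <- new_rule_table(rev(t_mixed$rules))
  n1 <- expand_network(seeds, t_mixed)
  n2 <- expand_network(rev(seeds), t_perm)
  for (fmt in c("tsv_edges", "json", "graphml")) {
    f1 <- tempfile(); f2 <- tempfile()
    export_network(n1, f1, fmt)
    export_network(n2, f2, fmt)
    expect_identical(readLines(f1), readLines(f2), label = fmt)
  }
})

test_that("limits stop runaway elongation and are flagged", {
  # poly-LacNAc elongation never terminates without a residue cap
  poly <- new_rule_table(list(
    new_rule("iGnT", "(Ab4GN", "(GNb3Ab4GN", ""),
    new_rule("b4GalT", "(GNb3", "(Ab4GNb3", "")))
  net <- expand_network("Ab4GNb", poly, max_su = 8, max_iterations = 50)
  expect_true(net$truncated ||
                all(vapply(net$nodes, count_residues, integer(1)) <= 10))
  expect_true(all(vapply(net$nodes, count_residues, integer(1)) <= 10))
  netN <- expand_network("Ab4GNb", poly, max_nodes = 3, max_iterations = 50)
  expect_lte(length(netN$nodes), 3)
  expect_true(netN$truncated)
})

test_that("split rules leave the reachable node set unchanged", {
  t7 <- read_rule_table(fx$table7_path, dialect = "legacy")
  n_whole <- expand_network(fx$biantennary, t7)
  n_split <- expand_network(fx$biantennary, split_rules(t7))
  expect_setequal(n_whole$nodes, n_split$nodes)
  expect_setequal(paste(n_whole$edges$substrate, n_whole$edges$product),
                  paste(n_split$edges$substrate, n_split$edges$product))
})

test_that("compartment staging applies rule pools sequentially", {
  tc <- new_rule_table(list(
    new_rule("FucT3", "Ab3GNb", "Ab3(Fa4)GNb", "", compartment = "medial"),
    new_rule("ST3", "(Ab3", "(NNa3Ab3", "", compartment = "trans")))
  net <- expand_network("Ab3GNb", tc,
                        compartment_order = c("medial", "trans"))
  expect_setequal(net$nodes, c("Ab3GNb", "Ab3(Fa4)GNb",
                               "NNa3Ab3GNb", "NNa3Ab3(Fa4)GNb"))
  # a compartment listed before its substrates exist yields fewer products
  net_rev <- expand_network("Ab3GNb", tc,
                            compartment_order = c("trans", "medial"))
  expect_true(all(net_rev$nodes %in% net$nodes))
})

test_that("all export formats round-trip losslessly", {
  net <- expand_network(fx$biantennary, t8)
  lonely <- licorr:::new_network(
    sort(c(net$nodes, "Gb"), method = "radix"), net$edges)
  for (fmt in c("tsv_edges", "json", "graphml")) {
    f <- tempfile()
    export_network(lonely, f, fmt)
    back <- import_network(f, fmt)
    expect_identical(back$nodes, lonely$nodes, label = fmt)
    expect_equal(nrow(back$edges), nrow(lonely$edges), label = fmt)
    expect_setequal(paste(back$edges$substrate, back$edges$product,
                          back$edges$enzyme, back$edges$rule_id,
                          back$edges$site),
                    paste(lonely$edges$substrate, lonely$edges$product,
                          lonely$edges$enzyme, lonely$edges$rule_id,
                          lonely$edges$site))
  }
  # graphml output is namespaced and declares its edge attribute keys
  f <- tempfile(fileext = ".graphml")
  export_network(net, f)
  doc <- xml2::read_xml(f)
  expect_match(xml2::xml_ns(doc)[[1]], "graphml.graphdrawing.org")
  keys <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name()='key']"), "id")
  expect_setequal(keys, c("enzyme", "rule_id", "site"))
  expect_error(export_network(net, tempfile(), "dot"), "unknown format")
})
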