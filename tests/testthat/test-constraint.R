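fx <- paper_fixtures()

test_that("legacy and LiCoRR constraint syntax parse to the same tree", {
  expect_equal(render_constraint(parse_constraint("~Ma6", "legacy")),
               render_constraint(parse_constraint("!Ma6")))
  expect_equal(render_constraint(parse_constraint("#A = 0", "legacy")),
               render_constraint(parse_constraint("nA=0")))
  e <- parse_constraint("(*Ab4 or (*NNa3Ab4", "legacy")
  expect_equal(e$kind, "or")
  expect_length(e$children, 2)
  expect_true(all(vapply(e$children, function(c) c$anchored, logical(1))))
  expect_equal(parse_constraint("")$kind, "empty")
  expect_equal(parse_constraint(NA)$kind, "empty")
  expect_error(parse_constraint("Ma6 &"), class = "licorr_parse_error")
})

test_that("IUPAC-condensed count atoms parse and count correctly", {
  e <- parse_constraint("nMan(a1-?)>4 & nMan(a1-?)<8")
  expect_equal(e$kind, "and")
  expect_equal(e$children[[1]]$kind, "count")
  expect_equal(e$children[[1]]$value, 4L)
  # M9 has 8 alpha-mannoses: >4 holds, <8 does not
  expect_true(evaluate_constraint("nMan(a1-?)>4", fx$m9_core))
  expect_false(evaluate_constraint("nMan(a1-?)<8", fx$m9_core))
  expect_false(evaluate_constraint(e, fx$m9_core))
  expect_true(evaluate_constraint("nMan(a1-?)=2", fx$biantennary))
})

test_that("boolean semantics follow presence of patterns in the glycan", {
  g <- fx$chitobiose_capped
  expect_false(evaluate_constraint("!Ma6", g))
  expect_true(evaluate_constraint("Ma6 & Ma3", g))
  expect_true(evaluate_constraint("Ma6 or Ab3", g))
  expect_true(evaluate_constraint("nA=0", fx$biantennary))
  expect_false(evaluate_constraint("nA=0", "Ab4GNb2Ma3(GNb2Ma6)Mb4GNb4GN"))
  expect_true(evaluate_constraint("", g))
  # count selectors are token-identity based
  expect_true(evaluate_constraint("nA=0", "ANb3ANb4Gb"))
  # negation is a complement on every fixture
  for (con in c("Ma6", "!Ma6", "nA=0", "Ab3"))
    for (gg in c(g, fx$biantennary, fx$m9_core))
      expect_equal(evaluate_constraint(paste0("!", con), gg),
                   !evaluate_constraint(con, gg))
})

test_that("site-anchored atoms bind the reaction site exactly", {
  # sites of terminal Ma2 removal on M9: 6 (upper), 13 (middle), 20 (lower)
  con <- "!@2Ma3(...Ma6)Ma6 & !Ga3"
  expect_true(evaluate_constraint(con, fx$m9_core, site = 6))
  expect_false(evaluate_constraint(con, fx$m9_core, site = 13))
  expect_true(evaluate_constraint(con, fx$m9_core, site = 20))
  expect_error(evaluate_constraint("!@2Ma3(...Ma6)Ma6", fx$m9_core),
               "without a site")
})

test_that("macros expand to pattern atoms and refuse cycles", {
  e <- expand_macros(parse_constraint("!Gnbis"))
  expect_equal(render_constraint(e), "!Ma3(GNb4)(...Ma6)Mb4")
  plain <- parse_constraint("!Ma6")
  expect_identical(render_constraint(expand_macros(plain)),
                   render_constraint(plain))
  expect_identical(render_constraint(expand_macros(expand_macros(
    parse_constraint("!Gnbis")))), render_constraint(e))
  expect_error(expand_macros(parse_constraint("!Gnx"),
                             table = c(Gnx = "Gny", Gny = "Gnx")),
               "recursive")
  expect_error(expand_macros(parse_constraint("!Nope"), table = c()),
               "unknown macro")
  # the bisecting GlcNAc macro actually recognizes a bisected glycan
  bisected <- "GNb2Ma3(GNb4)(GNb2Ma6)Mb4GNb4GN"
  expect_false(evaluate_constraint("!Gnbis", bisected))
  expect_true(evaluate_constraint("!Gnbis", fx$biantennary))
})

test_that("disjunction atomization distributes over conjunction", {
  t7 <- read_rule_table(fx$table7_path, dialect = "legacy")
  con <- t7$rules[[1]]$constraint
  parts <- atomize_disjunction(con)
  expect_length(parts, 4)
  # AND over OR distributes
  cx <- licorr:::cx
  e <- cx("and", children = list(parse_constraint("Ma6"),
                                 parse_constraint("Ab3 or Ab4")))
  parts2 <- atomize_disjunction(e)
  expect_length(parts2, 2)
  expect_true(all(vapply(parts2, function(p) p$kind == "and", logical(1))))
  expect_length(atomize_disjunction(parse_constraint("Ma6")), 1)
  # semantic equivalence: OR of parts == original, on fixture glycans
  for (gg in c(fx$biantennary, "Ab4GNb2Ma3(GNb2Ma6)Mb4GNb4GN")) {
    for (site in c(1L, 9L)) {
      whole <- evaluate_constraint(con, gg, site = site)
      split <- any(vapply(parts, evaluate_constraint, logical(1),
                          gg, site = site))
      expect_equal(whole, split)
    }
  }
})
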