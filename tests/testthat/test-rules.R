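fx <- paper_fixtures()

test_that("rule tables read with required and optional columns", {
  t8 <- read_rule_table(fx$table8_path, dialect = "legacy")
  expect_length(t8, 4)
  expect_true(all(vapply(t8$rules, function(r)
    render_pattern(r$substrate) == "(GN", logical(1))))
  expect_true(all(vapply(t8$rules, function(r)
    render_pattern(r$product) == "(Ab4GN", logical(1))))
  t9 <- read_rule_table(fx$table9_path, dialect = "licorr")
  expect_length(t9, 13)
  # the IUPAC-condensed constraint column rides along as an annotation
  expect_true("constraint_licorrice" %in% names(t9$rules[[1]]$annotations))

  hdr <- textConnection("enzyme\tsubstrate\tproduct\tconstraint")
  expect_length(read_rule_table(hdr), 0)
  bad <- textConnection("enzyme\tproduct\nx\ty")
  expect_error(read_rule_table(bad), "lacks required")
})

test_that("writing a rule table round-trips through reading", {
  t8 <- read_rule_table(fx$table8_path, dialect = "legacy")
  f <- tempfile(fileext = ".tsv")
  write_rule_table(t8, f)
  t8b <- read_rule_table(f, dialect = "legacy")
  expect_length(t8b, 4)
  sig <- function(t) lapply(t$rules, function(r)
    list(r$enzyme, render_pattern(r$substrate), render_pattern(r$product),
         render_constraint(r$constraint)))
  expect_identical(sig(t8), sig(t8b))
  # compartment column survives verbatim
  tc <- read_rule_table(textConnection(
    "enzyme\tsubstrate\tproduct\tconstraint\tcompartment\nFucT3\tAb3GNb\tAb3(Fa4)GNb\t\tmedial"))
  f2 <- tempfile(fileext = ".tsv")
  write_rule_table(tc, f2)
  expect_match(paste(readLines(f2), collapse = "\n"), "medial")
  # empty table writes a header-only file
  f3 <- tempfile(fileext = ".tsv")
  write_rule_table(licorr::new_rule_table(list()), f3)
  expect_length(readLines(f3), 1)
})

test_that("legacy symbols modernize to LiCoRR equivalents", {
  expect_equal(modernize("~Ma6"), "!Ma6")
  expect_equal(modernize("*...GNb2|Ma3"), "@...GNb2+Ma3")
  expect_equal(modernize("#A = 0"), "nA=0")
  expect_equal(modernize("~*2Ma3(…Ma6)Ma6"), "!@2Ma3(...Ma6)Ma6")
  # modernize-equivalence on every legacy constraint cell in the one-row
  # and split b4GalT tables plus the worked in-text strings
  legacy_cells <- c(
    "*...GNb2|Ma3 or*...GNb4|Ma3 or*...GNb2|Ma6 or*...GNb6|Ma6",
    "*...GNb2|Ma3", "*...GNb4|Ma3", "*...GNb2|Ma6", "*...GNb6|Ma6",
    "~Ma6", "Ma6 & Ma3", "Ma6 or Ma3", "#A = 0",
    "(*Ab4 or (*NNa3Ab4", "~*2Ma3(...Ma6)Ma6")
  for (x in legacy_cells) {
    a <- render_constraint(parse_constraint(x, "legacy"))
    b <- render_constraint(parse_constraint(modernize(x), "licorr"))
    expect_identical(a, b, label = x)
  }
  legacy_patterns <- c("(GN", "(Ab4GN", "Ma3|(Ma6)Mb4", "(...Ab4GNb")
  for (x in legacy_patterns) {
    a <- render_pattern(parse_pattern(x, "legacy"))
    b <- render_pattern(parse_pattern(modernize(x, "pattern"), "licorr"))
    expect_identical(a, b, label = x)
  }
})

test_that("the reaction site is the first differing character", {
  expect_equal(compute_site("(GNb2Ma3(GNb2Ma6)Mb4GNb4GN",
                            "(Ab4GNb2Ma3(GNb2Ma6)Mb4GNb4GN"), 1L)
  expect_error(compute_site("(Gb", "(Gb"), "identical")
  m9s <- sentinel(fx$m9_core)
  m9_minus_middle <- sentinel("Ma2Ma2Ma3(Ma3(Ma2Ma6)Ma6)Mb4GNb4GN")
  expect_equal(compute_site(m9s, m9_minus_middle), 13L)
})

test_that("rule application splices bindings and honors constraints", {
  r1 <- new_rule("FucT3", "Ab3GNb", "Ab3(Fa4)GNb", "")
  res1 <- apply_rule(r1, "Ab3GNb")
  expect_equal(res1$product, "Ab3(Fa4)GNb")
  expect_equal(res1$site, 4L)

  # one galactose per antenna under the four split constraints
  t8 <- read_rule_table(fx$table8_path, dialect = "legacy")
  res8 <- apply_rules(t8, fx$biantennary)
  expect_equal(nrow(res8), 2)
  expect_setequal(res8$product,
                  c("Ab4GNb2Ma3(GNb2Ma6)Mb4GNb4GN",
                    "GNb2Ma3(Ab4GNb2Ma6)Mb4GNb4GN"))

  # mannosidase I trims any terminal Ma2 except the middle branch
  rman <- new_rule(fx$mani_rule$enzyme, fx$mani_rule$substrate,
                   fx$mani_rule$product, fx$mani_rule$constraint)
  resm <- apply_rule(rman, fx$m9)
  expect_equal(nrow(resm), 2)
  expect_setequal(resm$product,
                  c("Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN;Asn",
                    "Ma2Ma2Ma3(Ma2Ma3(Ma6)Ma6)Mb4GNb4GN;Asn"))
  # without the site-anchored blocker all three sites react
  rfree <- new_rule("ManI", "(Ma2Ma", "(Ma", "!Ga3")
  expect_equal(nrow(apply_rule(rfree, fx$m9)), 3)

  # no substrate match, no products
  expect_equal(nrow(apply_rule(r1, "Gb")), 0)
  expect_equal(nrow(apply_rule(rman, fx$biantennary)), 0)
})

test_that("products re-parse, stay canonical, and grow by the residue delta", {
  t9 <- read_rule_table(fx$table9_path)
  for (g in c(fx$m9_core, fx$biantennary, fx$chitobiose_capped)) {
    res <- apply_rules(t9, g)
    for (prod in res$product) {
      expect_identical(canonicalize(prod), prod)
    }
    for (k in seq_len(nrow(res))) {
      r <- t9$rules[[res$rule_id[k]]]
      delta <- length(Filter(function(t) t$type == "su", r$product$tokens)) -
        length(Filter(function(t) t$type == "su", r$substrate$tokens))
      expect_equal(count_residues(res$product[k]) - count_residues(g), delta)
    }
  }
})

test_that("splitting disjunctive rules preserves the product set", {
  t7 <- read_rule_table(fx$table7_path, dialect = "legacy")
  t7s <- split_rules(t7)
  expect_length(t7s, 4)
  expect_true(all(vapply(t7s$rules, function(r)
    r$enzyme == "b4GalT", logical(1))))
  for (g in c(fx$biantennary, "Ab4GNb2Ma3(GNb2Ma6)Mb4GNb4GN",
              fx$chitobiose_capped)) {
    a <- apply_rules(t7, g)
    b <- apply_rules(t7s, g)
    expect_setequal(paste(a$product, a$site), paste(b$product, b$site))
  }
  # rules without "or" pass through unchanged
  t9 <- read_rule_table(fx$table9_path)
  expect_length(split_rules(t9), length(t9))
})

test_that("mismatched wildcard sequences are rejected", {
  expect_error(new_rule("bad", "(GNb2+Ma3", "(GNb2Ma3", ""),
               "wildcard sequences differ")
  expect_error(new_rule("bad", "...GN", "_GN", ""), "wildcard")
  expect_error(new_rule("bad", "@GN", "@Ab4GN", ""), "site is computed")
})
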