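fx <- paper_fixtures()

test_that("parsing recovers tree structure from worked examples", {
  g <- parse_glycan("Ab3GNb")
  expect_length(g$root$children, 1)
  expect_equal(g$root$su$ms, "GN")
  expect_equal(g$root$su$anomer, "b")
  expect_length(g$root$su$pos, 0)
  child <- g$root$children[[1]]
  expect_equal(child$su$ms, "A")
  expect_equal(child$su$pos, "3")

  g2 <- parse_glycan("A[2P]b3Gb")
  expect_equal(g2$root$su$ms, "G")
  expect_equal(g2$root$children[[1]]$su$mods,
               list(list(pos = "2", code = "P")))

  g3 <- parse_glycan("ANb3*A")
  expect_equal(count_residues(g3), 3L)
  expect_equal(g3$root$children[[1]]$su$ms, "*")

  expect_error(parse_glycan(""), class = "licorr_parse_error")
  expect_error(parse_glycan("A()Gb"), class = "licorr_parse_error")
  expect_error(parse_glycan("Qx3Gb"), class = "licorr_parse_error")
})

test_that("canonical serialization orders branches by attachment position", {
  expect_equal(canonicalize(fx$branch_reorder$input),
               fx$branch_reorder$canonical)
  expect_equal(canonicalize("Gb"), "Gb")
  expect_equal(canonicalize("Ab3(Fa4)GNb"), "Ab3(Fa4)GNb")
  # reordering never alters the edge multiset
  expect_equal(edge_multiset(fx$branch_reorder$input),
               edge_multiset(fx$branch_reorder$canonical))
  # positionless sibling order is preserved as written
  expect_equal(canonicalize(fx$fig1, registry = abs_reg), fx$fig1)
  expect_equal(canonicalize("E(D(C)B)A", registry = abs_reg), "E(D(C)B)A")
})

test_that("round trip and idempotence hold over random glycans", {
  for (s in 1:300) {
    g <- random_glycan(gen_params(seed = s))
    str1 <- serialize_glycan(g)
    expect_identical(serialize_glycan(parse_glycan(str1)), str1)
    expect_identical(canonicalize(str1), str1)
    expect_identical(count_residues(g),
                     length(licorr:::tokenize_glycan(str1, default_registry())) -
                       sum(strsplit(str1, "")[[1]] %in% c("(", ")")))
  }
})

test_that("conjugates split at the last top-level separator and round-trip", {
  for (s in c("Gb:C", "Ga;NY-S-C.", "GNb3Ab#4-Trifluoroacetamidophenol",
              fx$m9)) {
    expect_identical(canonicalize(s), s)
  }
  g <- parse_glycan(fx$m9)
  expect_equal(g$conjugate$sep, ";")
  expect_equal(g$conjugate$text, "Asn")
  expect_equal(count_residues(g), 11L)
})

test_that("open form is accepted only at the reducing end", {
  expect_identical(canonicalize("AbGo"), "AbGo")
  expect_identical(canonicalize("AbG[P]o"), "AbG[P]o")
  expect_error(parse_glycan("AoGb"), class = "licorr_parse_error")
})

test_that("residue counting is token-identity based", {
  expect_equal(count_residues("ANb3*A"), 3L)
  expect_equal(count_residues("Gb"), 1L)
  expect_equal(count_residues(fx$m9_core, "M"), 9L)
  expect_equal(count_residues("ANb3ANb4Gb", "A"), 0L)
  expect_equal(count_residues(fx$m9_core, "Man(a1-?)"), 8L)
  expect_equal(count_residues(fx$m9_core, "Man(a1-2)"), 4L)
  expect_error(count_residues("Gb", "ZZ"), "unregistered")
})

test_that("uncertainty enumeration is the Cartesian product of choices", {
  alts <- enumerate_alternatives(fx$ur5)
  expect_equal(vapply(alts, serialize_glycan, character(1)),
               c("Ab4Aa3", "Ga2Aa3"))
  expect_length(enumerate_alternatives("Gb"), 1)
  # fragment placement: a sialic acid on either antenna
  alts6 <- enumerate_alternatives(fx$ur6)
  expect_length(alts6, 2)
  strs <- vapply(alts6, serialize_glycan, character(1))
  expect_setequal(strs, c("NNa6Ab4GNb2Ma3(Ab4GNb2Ma6)Mb4Gb",
                          "Ab4GNb2Ma3(NNa6Ab4GNb2Ma6)Mb4Gb"))
  # "/" element sets multiply
  expect_length(enumerate_alternatives("ANb3/4Gb"), 2)
  expect_length(enumerate_alternatives("ANa/b3/4Gb"), 4)
})

test_that("repeat expansion concatenates the unit head-to-tail", {
  expect_equal(serialize_glycan(expand_repeats("{nGb4}", 3)), "Gb4Gb4Gb4")
  expect_equal(serialize_glycan(expand_repeats("{nGb4}", 1)), "Gb")
  expect_equal(serialize_glycan(expand_repeats("Gb", 5)), "Gb")
  expect_error(expand_repeats("{nGa6Ga4(-Ab3-)Ub2Ha3Ha3Ha3}", 2),
               "not supported")
  expect_identical(canonicalize("{nGb4}"), "{nGb4}")
})

test_that("validation returns diagnostics instead of raising", {
  expect_equal(nrow(validate_glycan("Ab3GNb")), 0)
  d <- validate_glycan(fx$branch_reorder$input)
  expect_equal(d$severity, "warning")
  expect_equal(d$code, "non_canonical")
  d2 <- validate_glycan("Ab3(GNb")
  expect_equal(d2$severity, "error")
  expect_equal(d2$code, "unbalanced_paren")
  expect_equal(d2$offset, 7L)
})
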