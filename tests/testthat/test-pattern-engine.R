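fx <- paper_fixtures()

test_that("the sentinel makes every branch terminal a left parenthesis", {
  expect_equal(sentinel("Ab3GNb"), "(Ab3GNb")
  expect_equal(sentinel(""), "(")
  expect_equal(sentinel(fx$biantennary), paste0("(", fx$biantennary))
})

test_that("substring classes follow the ligand/continuation/branch rules", {
  expect_true(classify_substring("ligand", "XX(XXX)XX"))
  expect_false(classify_substring("ligand", "XXX)X"))
  expect_false(classify_substring("ligand", "XX(XX"))
  expect_false(classify_substring("ligand", "X)(XX"))
  expect_true(classify_substring("continuation", "XXX)XX"))
  expect_true(classify_substring("continuation", "X)(XX)XX"))
  expect_false(classify_substring("continuation", "XX(XX"))
  expect_true(classify_substring("ligand", ""))
  expect_true(classify_substring("continuation", ""))
  expect_true(classify_substring("branch", ""))
  expect_true(classify_substring("branch", ")"))
  expect_true(classify_substring("branch", "(C)"))
  expect_true(classify_substring("branch", ")(C)"))
  expect_false(classify_substring("branch", "(("))
  expect_false(classify_substring("branch", "(C)(D)"))
  # every ligand is a continuation
  for (s in c("", "X", "(X)", "X(X)X", "((X))"))
    expect_true(classify_substring("continuation", s))
})

test_that("pattern parsing maps dialect symbols to token kinds", {
  p <- parse_pattern("(GNb2+Ma3")
  expect_equal(vapply(p$tokens, `[[`, character(1), "type"),
               c("open", "su", "branch", "su"))
  p2 <- parse_pattern("Ma3|(*_Ma6)Mb4", dialect = "legacy")
  expect_equal(vapply(p2$tokens, `[[`, character(1), "type"),
               c("su", "branch", "open", "site", "continuation", "su",
                 "close", "su"))
  expect_error(parse_pattern("@a@b"), class = "licorr_parse_error")
  # LiCoRR "*" is one whole residue, not the site
  p3 <- parse_pattern("ANb3*A")
  expect_equal(vapply(p3$tokens, `[[`, character(1), "type"),
               c("su", "any_su", "su"))
})

test_that("the terminal anchor distinguishes (GN from GN", {
  expect_length(find_matches("(GN", "Ab3GNb"), 0)
  expect_length(find_matches("GN", "Ab3GNb"), 1)
  expect_length(find_matches("(GN", fx$biantennary), 2)
  # a pattern anchored with "(" matches exactly the branch-terminal residues
  for (s in 1:25) {
    g <- random_glycan(gen_params(seed = s))
    expect_length(find_matches("(*", g), n_leaves(g))
  }
})

test_that("wildcard bindings reproduce the schematic wildcard table", {
  for (i in seq_len(nrow(fx$table6))) {
    row <- fx$table6[i, ]
    ms <- find_matches(row$pattern, row$glycan, registry = abs_reg)
    expect_equal(length(ms) > 0, row$expected,
                 label = paste(row$pattern, "on", row$glycan))
  }
  m <- find_matches("B_A", "E(D(C)B)A", registry = abs_reg)
  expect_equal(m[[1]]$bindings, ")")
  m2 <- find_matches("E(D_A", "E(D(C)B)A", registry = abs_reg)
  expect_equal(m2[[1]]$bindings, "(C)B)")
  m3 <- find_matches("B...A", "B(C)A", registry = abs_reg)
  expect_equal(m3[[1]]$bindings, "(C)")
  m4 <- find_matches("B+A", "BA", registry = abs_reg)
  expect_equal(m4[[1]]$bindings, "")
})

test_that("token-aligned literals never match inside longer codes", {
  expect_length(find_matches("A", "ANb3Gb"), 0)
  expect_length(find_matches("N", "NNa3Ab4Gb"), 0)
  expect_length(find_matches("G", "GNb2Ma3(GNb2Ma6)Mb4GNb4GN"), 0)
  # unspecified trailing elements leave characters for the next token
  m <- find_matches("(Ma2Ma", fx$m9_core)
  expect_equal(vapply(m, `[[`, integer(1), "start"), c(0L, 10L, 17L))
})

test_that("possible-modification literals match bare or modified residues", {
  expect_length(find_matches("A$GN", "A[2P]b3GNb"), 1)
  expect_length(find_matches("A$GN", "Ab3GNb"), 1)
  expect_length(find_matches("A$[2P]GN", "A[2P]b3GNb"), 1)
  expect_length(find_matches("A$[2P]GN", "Ab3GNb"), 1)
  expect_length(find_matches("A$[6S]GN", "A[2P]b3GNb"), 0)
  expect_length(find_matches("AGN", "A[2P]b3GNb"), 0)
})

test_that("matcher equals the exhaustive oracle on seeded random pairs", {
  checked <- 0L
  s <- 0L
  while (checked < 250L) {
    s <- s + 1L
    g <- random_glycan(gen_params(seed = s, max_depth = 3,
                                  p_unknown_anomer = 0))
    if (nchar(serialize_glycan(g)) + 1 > 40) next
    p <- pattern_from_glycan(g, seed = s + 10000L)
    a <- find_matches(p, g)
    b <- brute_force_matches(p, g, max_len = 40)
    expect_identical(lapply(a, unclass), lapply(b, unclass),
                     label = paste("seed", s))
    expect_gte(length(a), 1)
    # substitution soundness for every match
    for (m in a) expect_identical(splice_match(p, m), m$matched)
    checked <- checked + 1L
  }
})

test_that("every ligand match is also a continuation match", {
  for (s in 1:60) {
    g <- random_glycan(gen_params(seed = s, p_unknown_anomer = 0))
    p <- pattern_from_glycan(g, seed = s + 20000L)
    kinds <- vapply(p$tokens, `[[`, character(1), "type")
    if (!"ligand" %in% kinds) next
    q <- p
    for (k in seq_along(q$tokens))
      if (q$tokens[[k]]$type == "ligand") q$tokens[[k]]$type <- "continuation"
    expect_true(all(match_sig(find_matches(p, g)) %in%
                    match_sig(find_matches(q, g))))
  }
})

test_that("matches arrive ordered by start then bindings", {
  for (s in 1:40) {
    g <- random_glycan(gen_params(seed = s))
    p <- pattern_from_glycan(g, seed = s + 30000L)
    ms <- find_matches(p, g)
    if (length(ms) < 2) next
    starts <- vapply(ms, `[[`, integer(1), "start")
    expect_true(all(diff(starts) >= 0))
  }
})

test_that("the oracle refuses oversized subjects and fuzzy literals", {
  big <- strrep("Ab3", 30)
  expect_error(brute_force_matches("Gb", paste0(big, "Gb"), max_len = 40),
               "max_len")
  expect_error(brute_force_matches("M?3", "Ma3Gb"), "exact")
  expect_length(brute_force_matches("B...A", "B(CA", registry = abs_reg), 0)
})
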