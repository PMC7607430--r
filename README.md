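# licorr

Glycans are synthesized by the sequential, enzyme-catalyzed addition and
removal of monosaccharides, and systems-glycobiology models describe that
chemistry as *reaction rules*: string-rewriting operations over glycans
written in Linear Code, a compact linearization of the glycan tree
(`GNb2Ma3(GNb2Ma6)Mb4GNb4GN` is the biantennary N-glycan core). `licorr`
implements the consensus extension of Linear Code for reaction rules
(LiCoRR, version 1.0) for people who build or exchange glycan-synthesis
models: it parses and canonicalizes glycan strings, matches rule patterns
containing the balanced-parenthesis wildcard operators, evaluates rule
constraints, applies rules to produce product glycans, expands
biosynthesis networks from seed structures, and interconverts with the
IUPAC-condensed flavor (LiCoRRICE) and legacy rule dialects.

## The model in brief

* **Canonical form.** At every residue the child attached at the lowest
  carbon position continues the unparenthesized backbone; remaining
  children appear as parenthesized branches in ascending position, so
  `Ab4(GNb4GNb3)(GNb6)Ab4Gb` canonicalizes to
  `GNb4GNb3(Ab4)(GNb6)Ab4Gb`. String equality of canonical forms equals
  structural identity.
* **Sentinel.** Matching operates on `"(" + canonical string`, so the
  terminal end of every branch is a left parenthesis and a leading `(` in
  a pattern anchors a residue as branch-terminal: `(GN` matches only
  terminal GlcNAc, `GN` matches any.
* **Wildcards.** Ligand `...` binds any substring with all parentheses
  matched; continuation `_` binds any substring where every `(` is closed
  later (unmatched `)` allowed); possible branch `+` binds `""`, `)`,
  `(B)`, or `)(B)` for balanced `B`; `*` binds exactly one saccharide
  unit; `@` is the zero-width reaction-site anchor; `$` marks a possibly
  modified residue.
* **Rules and sites.** A rule is enzyme + substrate pattern + product
  pattern + constraint (`!` negation, `&`, `or`, count atoms `nA=0`).
  The reaction site of a rule instance is the index of the first
  character difference between the substrate and product strings;
  `@`-anchored constraint atoms must place their anchor exactly there.

## Worked example

```r
library(licorr)

canonicalize("Ab4(GNb4GNb3)(GNb6)Ab4Gb")
#> [1] "GNb4GNb3(Ab4)(GNb6)Ab4Gb"

# mannosidase I trims terminal alpha-1,2 mannose, but a site-anchored
# constraint protects the middle branch of the Man9 glycan
rman <- new_rule("ManI", "(Ma2Ma", "(Ma", "!@2Ma3(...Ma6)Ma6 & !Ga3")
apply_rule(rman, "Ma2Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN;Asn")
#>   enzyme site                                product
#> 1   ManI    6 Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN;Asn
#> 2   ManI   20 Ma2Ma2Ma3(Ma2Ma3(Ma6)Ma6)Mb4GNb4GN;Asn
```

Man9 has three terminal `Ma2` residues (sites 6, 13 and 20 of the
sentineled string); the product list shows the two permitted trims and
omits the blocked middle-branch site 13. Networks expand the same way:

```r
t8 <- read_rule_table(paper_fixtures()$table8_path, dialect = "legacy")
expand_network("GNb2Ma3(GNb2Ma6)Mb4GNb4GN", t8)
#> <licorr_network> 4 nodes, 4 edges
```

(the four nodes carry 0, 1, 1 and 2 galactoses), and conversion to
IUPAC-condensed text is one call:

```r
to_licorrice("Ab3(Fa4)GNb", greek = TRUE)
#> [1] "Gal(β1-3)[Fuc(α1-4)]GlcNAc(β1-"
```

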