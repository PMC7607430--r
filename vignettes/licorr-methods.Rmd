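---
title: "Methods: glycan reaction rules in licorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycan reaction rules in licorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(licorr)
```

## The representation

A glycan is a rooted tree of saccharide units (SUs). Each SU records a
monosaccharide code (one or two uppercase letters, e.g. `GN` for
GlcNAc), an optional stereo/ring marker (`'`, `^`, `~`), bracketed
modifications (`[2P]`), the anomer (`a`/`b`, `?` when unknown), and the
carbon position by which the SU attaches toward the reducing end. The
written string reads from the non-reducing termini (left) to the
reducing end (right); branches sit in parentheses. The package models
glycans as plain R lists (`licorr_glycan`), and all dialects (LiCoRR,
legacy, original Linear Code) share the structural syntax - they differ
only in the operator symbols used by patterns and constraints.

In-SU uncertainty is kept, not resolved: `/` element alternatives
(`ANb3/4`), `//` whole-SU alternatives, `*` unknown residues, and
numbered fragment annotations (`NNa6=1%|1%Ab4...`) survive parsing and
serialization, and `enumerate_alternatives()` expands their Cartesian
product on demand, de-duplicating after canonicalization.

## Canonical branch order

At every residue the child with the lowest known attachment position
continues the unparenthesized backbone; the remaining children follow as
parenthesized branches in ascending position. Children with unknown or
absent positions sort after all known positions, and ties among them
keep their written order. We chose stable (written-order) tie-breaking
rather than a lexicographic one deliberately: schematic glycans such as
`E(D(C)B)A`, whose abstract letters carry no positions, would otherwise
be silently rewritten, and the wildcard semantics below are defined on
the written string. For real glycans sibling positions are distinct, so
canonical string equality still coincides with structural identity;
for positionless schematics it preserves the author's layout.
Canonicalization is idempotent and never changes the multiset of
(parent, child, position) edges.

## Matching semantics

Matching always runs over the *sentineled* canonical string: an initial
`(` is prepended so the terminal end of every branch is a left
parenthesis, letting a leading `(` in a pattern demand a branch-terminal
residue. Three wildcard classes are defined purely on parenthesis
structure:

* **ligand** `...` - all parentheses matched (a fragment removable with
  one cut); includes the empty string;
* **continuation** `_` - every `(` closed later in the binding,
  unmatched `)` allowed (a path that may exit branches toward the
  root); includes the empty string;
* **possible branch** `+` - exactly `""`, `)`, `(B)`, or `)(B)` with
  `B` balanced.

Every ligand is a continuation, never the reverse. `find_matches()`
enumerates *all* start offsets and *all* binding assignments, ordered by
start and then lexicographically by bindings; downstream consumers
de-duplicate at the product level, because rule application needs every
site.

SU literals match **token-aligned**: a literal can only start where a
subject SU token starts, and its monosaccharide identity must equal the
subject token's maximal-munch code, so `A` never matches inside `AN`.
Elements a literal leaves unspecified are not consumed - the trailing
`Ma` of the pattern `(Ma2Ma` matches just the `Ma` head of an `Ma2`
token, leaving the `2` in place. That is exactly what makes string
splicing work for rules such as `(Ma2Ma -> (Ma`: the leftover `2`
merges with the product's trailing `Ma`. A `?` in a literal matches any
anomer (or any position digit) but still consumes one subject
character. A `$` flag matches the residue with any modification set
(`$[spec]` with exactly `spec` or none) and captures the covered
characters so they transfer to products.

`brute_force_matches()` is the test oracle: at every offset it tries
every substring as every wildcard's binding, keeps assignments whose
classes pass `classify_substring()` and whose concatenation reproduces
the subject substring, and applies the same ordering. It deliberately
shares almost nothing with the matcher beyond the class definitions; its
scope is exact literals (no `?`, `/`, `$`), which is all the pattern
generator emits. The suite asserts matcher/oracle identity on 1000
seeded pairs with sentineled length at most 40 - sizes chosen to keep
exhaustive enumeration honest while covering all wildcard interactions.

## Constraints and the reaction site

Constraint cells form a small boolean language: `!` binds tightest, `&`
next, the word `or` loosest; there is no parenthesized grouping
(parentheses are glycan syntax), so wider grouping is expressed by
splitting rules - `atomize_disjunction()`/`split_rules()` distribute
disjunctions into one OR-free constraint per row. Count atoms accept
LiCoRR `nA=0`, legacy `#A = 0` (whitespace ignored), and IUPAC-condensed
selectors `nMan(a1-?)>4`; counting is token-identity based, so `nA`
never counts `AN` residues. The `#` form is also tolerated in the
LiCoRR dialect because published rule tables mix the two.

The *reaction site* of a rule instance is the index of the first
character at which the instantiated substrate and product strings
differ (0-based, over the sentineled strings). A pattern atom containing
`@` is site-anchored: it is true only when some match places the anchor
exactly at the rule's site. Unanchored atoms are global presence tests.
This reproduces the published mannosidase-I behavior: with
`!@2Ma3(...Ma6)Ma6 & !Ga3`, trimming is blocked at the middle-branch
site of the Man9 glycan (site 13) and allowed at the other two terminal
sites (6 and 20).

## Rule application and networks

`apply_rule()` canonicalizes the glycan, sets the conjugate aside,
splices each substrate match's bindings positionally into the product
pattern, recomputes the site, filters by the constraint, re-parses and
canonicalizes the product, and re-attaches the conjugate. Substrate and
product must carry identical wildcard occurrence sequences - reordered
wildcards are rejected at construction because positional transfer would
be ambiguous. Duplicate (product, site) pairs collapse.

`expand_network()` is a breadth-first closure with three termination
levers: `max_iterations` (frontier generations; a rule acts on its own
product only in the next generation), `max_su` (oversized glycans stay
as nodes but are not expanded - poly-LacNAc elongation never terminates
otherwise; default 30 residues), and `max_nodes`. Truncation is flagged
on the result, never an error. Output is independent of seed and rule
order: nodes and edges are sets emitted in byte-order, and edges
reference rules through a content-sorted canonical index rather than the
input row number. When a compartment order is given (e.g. cis, medial,
trans Golgi), each compartment's rule pool runs to closure before the
next starts; rules without a compartment join every stage.

## LiCoRRICE conversion

IUPAC-condensed output writes each residue as `Name(anomer
carbon-position)` with square-bracket branches. The anomeric carbon
comes from the registry: 1 by default, 2 for Neu5Ac, Neu5Gc, Neu, KDN,
Kdo and fructose - the printed tables only ever show `a1`/`b1` sugars,
so the 2-keto convention is fixed from standard IUPAC usage. Unknown
positions render as `?`; unknown anomers as `?1-`. Modifications render
inline (`Gal3S`); stereo/ring-marked residues have no condensed
rendering and raise an error. Because IUPAC branching is not
deterministic, all three branch wildcards collapse to `...` in this
direction; reading LiCoRRICE back maps `...` to the ligand wildcard and
flags the pattern as lossy.

## Synthetic data: what it emulates and what it does not

`random_glycan()` draws rooted trees under explicit conditions: maximum
depth 4, at most 2 children per residue (so at most 15 residues),
distinct sibling attachment positions drawn from carbons 2-6, anomer
`a`/`b` with a 5% chance of `?`, and a 10% chance of one modification
per residue - sizes and rates chosen to resemble the mammalian N-glycan
strings the rule tables target while keeping exhaustive oracle checks
feasible. The stream is a pinned Mersenne-Twister; the caller's RNG
state is untouched. The generator does **not** emulate biological
branching frequencies, monosaccharide composition biases, or repeat and
fragment annotations, so passing property suites demonstrate syntactic
and algorithmic correctness, not biological realism of the sampled
glycome. `pattern_from_glycan()` cuts 0-2 token-aligned substrings out
of the sentineled string and replaces each with a wildcard class valid
for the removed text, which guarantees at least one match by
construction.

## Numerical and degenerate-input choices

* All offsets (diagnostics, match spans, sites) are 0-based character
  indices, matching the first-difference site convention.
* Parse errors are structured conditions with a machine-readable code
  and offset; `validate_glycan()` returns them as a data frame and
  reports non-canonical branch order as a warning, not an error.
* Conjugates split at the last top-level `;`, `:` or `#`; the separator
  is preserved on output, and matching ignores the conjugate entirely.
* Modification blocks canonicalize to ascending first-position order
  (`[2N,6D]`); the descending form is accepted on read.
* `{nGb4}` repeats expand by literal head-to-tail concatenation; with
  `n = 1` the dangling reducing-end position is dropped (`Gb`).
* Deterministic string ordering uses byte (C-locale) comparison
  throughout, so results do not depend on the session locale.

## Known limitations

Cyclic repeats (`c` tail markers) and `-X-` head-marked repeat units
parse but refuse expansion - their original specification is too loose
to implement faithfully. Embedded glycopeptide notation
(`PEP(AG(LY)CAN)TIDE`) is out of scope: tokenizing peptide letters
within glycan syntax is ambiguous. The oracle matcher covers exact
literals only. Rate and adjustment annotations in rule tables are
carried verbatim and never evaluated; no kinetics are modeled.
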