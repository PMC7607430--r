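Package: licorr
Title: Linear Code Reaction Rules for Glycan Biosynthesis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse, canonicalize, and interconvert glycan structures written
    in Linear Code and its consensus reaction-rule extension (LiCoRR), match
    patterns containing the ligand, continuation, and possible-branch
    wildcard operators, evaluate rule constraints with site anchoring,
    apply glycosyltransferase and glycosidase reaction rules to glycans,
    and expand biosynthesis reaction networks from seed structures.
    Includes conversion to and from the IUPAC-condensed flavor (LiCoRRICE),
    seeded random-structure generators for property testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
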