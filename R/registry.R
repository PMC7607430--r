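#' Monosaccharide, modification, and symbol registries
#'
#' A registry holds the lookup tables every other component depends on: the
#' one/two-letter Linear Code monosaccharide codes with their IUPAC names,
#' anomeric carbons, default ring forms and stereochemistry; the modification
#' codes; and the symbol map relating legacy reaction-rule dialects to the
#' LiCoRR consensus symbols. Registries are plain lists and are extended
#' functionally: [register_monosaccharide()] returns an updated copy.
#'
#' @name registry
NULL

new_registry <- function(mono, mods, symbols) {
  structure(list(mono = mono, mods = mods, symbols = symbols),
            class = "licorr_registry")
}

#' Default LiCoRR registry
#'
#' Returns the standard registry: 23 monosaccharides (Glc through ribitol,
#' including Neu5Gc), 17 modification codes, and the legacy-to-LiCoRR symbol
#' map. Sialic acids and the other 2-keto sugars (Neu5Ac, Neu5Gc, Neu, KDN,
#' Kdo, Fru) carry anomeric carbon 2; everything else links from carbon 1.
#'
#' @return A `licorr_registry` with data frames `mono`, `mods`, `symbols`.
#' @export
#' @examples
#' reg <- default_registry()
#' reg$mono[reg$mono$lc_code == "GN", "iupac_name"]
default_registry <- function() {
  if (!is.null(.registry_cache$default)) return(.registry_cache$default)
  mono <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
lc_code iupac_name anomeric_carbon ring stereo
G   Glc     1 pyranose D
A   Gal     1 pyranose D
GN  GlcNAc  1 pyranose D
AN  GalNAc  1 pyranose D
M   Man     1 pyranose D
NN  Neu5Ac  2 pyranose D
NG  Neu5Gc  2 pyranose D
N   Neu     2 pyranose D
K   KDN     2 pyranose D
W   Kdo     2 pyranose D
L   GalA    1 pyranose D
I   IdoA    1 pyranose L
H   Rha     1 pyranose L
F   Fuc     1 pyranose L
X   Xyl     1 pyranose D
B   Rib     1 pyranose D
R   Araf    1 furanose L
U   GlcA    1 pyranose D
O   All     1 pyranose D
P   Api     1 pyranose D
E   Fruf    2 furanose D
C   Asc     1 pyranose L
T   Rib-ol  1 pyranose D
')
  mods <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
lc_code iupac_name
Q   N
PE  Pe
IN  In
ME  Me
N   NAc
T   Ac
P   P
PC  Pc
PYR Pyr
S   S
SH  Sh
EP  Ep
D   d
CA  -oic
A   -amine
AO  -amide
K   -one
')
  symbols <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
role legacy_symbol licorr_symbol
negation      ~   !
and           &   &
or            or  or
continuation  _   _
ligand        ... ...
branch        |   +
site          *   @
possible_mod  NA  $
count         "#" n
fragment_div  |   |
omission      *   *
conjugate_sep ";:#" ";:#"
stereo_ring   ~   ~
')
  reg <- new_registry(mono, mods, symbols)
  .registry_cache$default <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' Abstract single-letter registry profile
#'
#' A registry in which every capital letter A-Z is an abstract
#' monosaccharide (IUPAC name equal to its code, anomeric carbon 1). Used
#' for schematic glycans such as `"E(D(C)B)A"` where the letters do not
#' denote real sugars. The modification table and symbol map are shared
#' with [default_registry()].
#'
#' @return A `licorr_registry`.
#' @export
abstract_registry <- function() {
  base <- default_registry()
  mono <- data.frame(lc_code = LETTERS, iupac_name = LETTERS,
                     anomeric_carbon = 1L, ring = "pyranose", stereo = "D",
                     stringsAsFactors = FALSE)
  new_registry(mono, base$mods, base$symbols)
}

#' Register an additional monosaccharide
#'
#' Adds a monosaccharide entry to a registry; subsequent tokenization uses
#' longest-match over the extended code table, so two-letter codes shadow
#' their one-letter prefixes automatically.
#'
#' @param registry A `licorr_registry`.
#' @param lc_code Uppercase Linear Code (1-2 letters).
#' @param iupac_name IUPAC-condensed residue name.
#' @param anomeric_carbon Carbon from which the residue forms glycosidic
#'   bonds (1 for aldoses, 2 for sialic acids and other ketoses).
#' @param ring `"pyranose"` or `"furanose"`.
#' @param stereo `"D"` or `"L"`.
#' @param overwrite Replace an existing entry instead of failing.
#' @return The updated registry.
#' @export
register_monosaccharide <- function(registry, lc_code, iupac_name = lc_code,
                                    anomeric_carbon = 1L,
                                    ring = "pyranose", stereo = "D",
                                    overwrite = FALSE) {
  stopifnot(inherits(registry, "licorr_registry"))
  if (!grepl("^[A-Z]+$", lc_code))
    stop("lc_code must be one or more uppercase letters: ", lc_code)
  hit <- registry$mono$lc_code == lc_code
  entry <- data.frame(lc_code = lc_code, iupac_name = iupac_name,
                      anomeric_carbon = as.integer(anomeric_carbon),
                      ring = ring, stereo = stereo, stringsAsFactors = FALSE)
  if (any(hit)) {
    if (!overwrite)
      stop("monosaccharide code already registered: ", lc_code,
           " (use overwrite = TRUE to replace)")
    registry$mono[hit, ] <- entry
  } else {
    registry$mono <- rbind(registry$mono, entry)
  }
  registry
}

#' Read a registry override table
#'
#' Reads a TSV with columns `lc_code`, `iupac_name`, `anomeric_carbon`,
#' `ring`, `stereo` and merges it over the default registry.
#'
#' @param path Path to a tab-separated file.
#' @param base Registry to extend (default [default_registry()]).
#' @return A `licorr_registry`.
#' @export
read_registry <- function(path, base = default_registry()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("lc_code", "iupac_name", "anomeric_carbon", "ring", "stereo")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("registry file lacks columns: ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(tab)))
    base <- register_monosaccharide(base, tab$lc_code[i], tab$iupac_name[i],
                                    tab$anomeric_carbon[i], tab$ring[i],
                                    tab$stereo[i], overwrite = TRUE)
  base
}

# Monosaccharide codes ordered longest-first for maximal-munch tokenization.
ms_codes <- function(registry) {
  codes <- registry$mono$lc_code
  codes[order(-nchar(codes), codes)]
}

mod_codes <- function(registry) {
  codes <- registry$mods$lc_code
  codes[order(-nchar(codes), codes)]
}

ms_lookup <- function(registry, lc_code) {
  i <- match(lc_code, registry$mono$lc_code)
  if (is.na(i)) return(NULL)
  as.list(registry$mono[i, ])
}

# Reverse lookup: IUPAC residue name -> lc code. Accepts both "KDN" and
# "Kdn" spellings.
ms_from_iupac <- function(registry, name) {
  i <- match(name, registry$mono$iupac_name)
  if (is.na(i) && identical(name, "Kdn"))
    i <- match("KDN", registry$mono$iupac_name)
  if (is.na(i)) return(NULL)
  registry$mono$lc_code[i]
}

iupac_names <- function(registry) {
  nm <- unique(c(registry$mono$iupac_name, "Kdn"))
  nm[order(-nchar(nm), nm)]
}

mod_from_iupac <- function(registry, name) {
  i <- match(name, registry$mods$iupac_name)
  if (is.na(i)) return(NULL)
  registry$mods$lc_code[i]
}

mod_iupac_names <- function(registry) {
  nm <- registry$mods$iupac_name
  nm[order(-nchar(nm), nm)]
}
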