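# Internal bridge to Open Babel (via ChemmineOB) and small SMILES bookkeeping
# helpers. All structure parsing, canonicalisation, fingerprinting and SMARTS
# matching go through Open Babel; the regex helpers below only tokenise atom
# symbols for fragment sizing and never interpret SMILES grammar.

# Parse a character vector of SMILES into a list of Open Babel molecule
# references. All inputs must be individually parseable; use ob_canonical()
# first on untrusted input (a failed line would silently shift the batch).
ob_refs <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L, !anyNA(smiles))
  refs <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  if (length(refs) != length(smiles)) {
    stop("Open Babel failed to parse ", length(smiles) - length(refs),
         " of ", length(smiles), " structures; canonicalise first.")
  }
  refs
}

# Canonical SMILES, one molecule per call so parse failures map to NA instead
# of shifting a batch. Strips the title field and trailing whitespace.
ob_canonical <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- try(suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", trimws(s))), silent = TRUE)
    if (inherits(out, "try-error")) return(NA_character_)
    out <- sub("[\t ].*$", "", sub("\n.*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Number of SMARTS matches per molecule (ordered mappings, as Open Babel
# counts them). `refs` from ob_refs(); reusable across patterns.
ob_smarts_count <- function(refs, smarts) {
  as.numeric(ChemmineOB::smartsSearch_OB(refs, smarts, uniqueMatches = FALSE))
}

# Elements treated as metals for curation purposes. Metalloids commonly seen
# in organic chemistry (B, Si, As, Se, Te) are deliberately not listed.
.METALS <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru",
  "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf",
  "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po",
  "Fr", "Ra", "Ac", "Th", "Pa", "U"
)

# Tokenise the atom symbols of a SMILES fragment. Bracket atoms come back as
# their element symbol; aromatic organic-subset atoms are upcased.
smiles_atom_symbols <- function(fragment) {
  tokens <- regmatches(fragment, gregexpr(
    "\\[[^]]*\\]|Cl|Br|[BCNOPSFI]|[bcnops]", fragment))[[1]]
  vapply(tokens, function(tk) {
    if (startsWith(tk, "[")) {
      m <- regmatches(tk, regexpr("[A-Z][a-z]?|[a-z]", tk))
      if (length(m) == 0L) return("")
      if (m %in% c("b", "c", "n", "o", "p", "s")) toupper(m) else m
    } else if (tk %in% c("b", "c", "n", "o", "p", "s")) {
      toupper(tk)
    } else {
      tk
    }
  }, character(1), USE.NAMES = FALSE)
}

# Heavy (non-hydrogen) atom count of a SMILES fragment.
smiles_heavy_atoms <- function(fragment) {
  sym <- smiles_atom_symbols(fragment)
  sum(sym != "H" & nzchar(sym))
}

smiles_has_metal <- function(fragment) {
  any(smiles_atom_symbols(fragment) %in% .METALS)
}

smiles_has_carbon <- function(fragment) {
  "C" %in% smiles_atom_symbols(fragment)
}

# Single bracket-atom fragment, e.g. "[Na+]", "[Cl-]".
smiles_is_single_ion <- function(fragment) {
  grepl("^\\[[^]]*\\]$", fragment)
}
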