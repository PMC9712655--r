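# Structure standardisation and library curation. Raw SMILES are
# canonicalised with Open Babel, counter-ions and solvents are stripped by a
# largest-organic-fragment rule, and metal complexes, true mixtures and
# unparseable entries are rejected with a reason.

# Common counter-ion / solvent fragments dropped when a larger organic
# fragment is present (stored canonical; computed lazily once per session).
.ALLOWLIST_RAW <- c(
  "O", "N", "CO", "CC#N", "CS(C)=O",                  # water, ammonia, MeOH, MeCN, DMSO
  "CC(=O)O", "CC(=O)[O-]", "OC=O", "[O-]C=O",        # acetic/formic acids
  "OC(=O)C(F)(F)F", "[O-]C(=O)C(F)(F)F",             # TFA
  "CS(=O)(=O)O", "CS(=O)(=O)[O-]",                   # mesylate
  "Cc1ccc(S(=O)(=O)O)cc1", "Cc1ccc(S(=O)(=O)[O-])cc1", # tosylate
  "OS(=O)(=O)O", "OP(=O)(O)O", "O[N+](=O)[O-]",      # mineral acids
  "OC(=O)C(=O)O", "OC(=O)C=CC(=O)O",                 # oxalic, maleic/fumaric
  "OC(=O)CC(O)(CC(=O)O)C(=O)O"                       # citric
)
.curation_env <- new.env(parent = emptyenv())

.allowlist_canonical <- function() {
  if (is.null(.curation_env$allow)) {
    .curation_env$allow <- unique(stats::na.omit(ob_canonical(.ALLOWLIST_RAW)))
  }
  .curation_env$allow
}

#' Standardize a raw SMILES into QSAR-ready form
#'
#' Canonicalises the structure (implicit hydrogens, library-default
#' canonical SMILES), strips counter-ion, solvent and single-atom ion
#' fragments by retaining the largest organic fragment, and rejects
#' metal-containing structures, multi-organic-fragment mixtures and
#' unparseable strings.
#'
#' A second organic fragment makes the entry a mixture when it has at least
#' 8 heavy atoms or at least half as many heavy atoms as the largest
#' fragment; smaller residual fragments are treated as formulation
#' components and dropped.
#'
#' @param smiles_raw A single SMILES string.
#' @return A list with `smiles_std` (canonical SMILES, `NA` if rejected) and
#'   `rejection_reason`, one of `"none"`, `"mixture"`,
#'   `"inorganic_or_metal"`, `"unparseable"`, `"no_structure"`.
#' @examples
#' standardize_structure("CC(=O)[O-].[Na+]")  # acetate retained
#' standardize_structure("c1ccccc1.CCO")      # rejected as mixture
#' @export
standardize_structure <- function(smiles_raw) {
  reject <- function(reason) list(smiles_std = NA_character_,
                                  rejection_reason = reason)
  if (length(smiles_raw) != 1L || is.na(smiles_raw) ||
      !nzchar(trimws(smiles_raw)))
    return(reject("unparseable"))

  can <- ob_canonical(smiles_raw)
  if (is.na(can)) return(reject("unparseable"))

  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) return(reject("no_structure"))

  info <- data.frame(
    frag = frags,
    heavy = vapply(frags, smiles_heavy_atoms, numeric(1)),
    metal = vapply(frags, smiles_has_metal, logical(1)),
    organic = vapply(frags, smiles_has_carbon, logical(1)),
    ion = vapply(frags, smiles_is_single_ion, logical(1)),
    stringsAsFactors = FALSE
  )
  saw_metal <- any(info$metal)

  # drop bare single-atom ions (Na+, Cl-, ...) outright
  info <- info[!(info$ion & info$heavy <= 1L), , drop = FALSE]

  organics <- info[info$organic & !info$metal, , drop = FALSE]
  if (nrow(organics) == 0L)
    return(reject(if (saw_metal) "inorganic_or_metal" else "no_structure"))

  # organometallic main fragment (metal bonded within an organic fragment)
  if (any(info$organic & info$metal)) return(reject("inorganic_or_metal"))

  if (nrow(organics) > 1L) {
    # strip listed counter-ions/solvents while something else remains
    allowed <- organics$frag %in% .allowlist_canonical()
    if (any(!allowed)) organics <- organics[!allowed, , drop = FALSE]
  }
  if (nrow(organics) > 1L) {
    o <- organics[order(-organics$heavy), , drop = FALSE]
    if (o$heavy[2] >= 8 || o$heavy[2] >= 0.5 * o$heavy[1])
      return(reject("mixture"))
    organics <- o[1, , drop = FALSE]
  }
  # any leftover non-organic multi-atom fragment with a metal was caught
  # above; remaining inorganics (e.g. sulfate) are dropped silently

  kept <- organics$frag[which.max(organics$heavy)]
  # a fragment of a canonical SMILES is not guaranteed canonical on its
  # own, so re-canonicalise unless the whole input was kept
  std <- if (identical(kept, can)) can else ob_canonical(kept)
  if (is.na(std)) return(reject("unparseable"))
  list(smiles_std = std, rejection_reason = "none")
}

#' Curate a chemical library
#'
#' Applies [standardize_structure()] to every record, preserving input
#' order, and tallies rejections by reason.
#'
#' @param records Data frame with at least columns `id` (unique) and
#'   `smiles`; typically the `records` element of a synthetic library or a
#'   table read with [read_library_csv()].
#' @return A list of class `curated_library`: `curated` (data frame id,
#'   smiles_std for accepted records), `rejected` (id, smiles,
#'   rejection_reason), and `report` (named rejection tally).
#' @export
curate_library <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  if (anyDuplicated(records$id))
    stop("duplicate chemical id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  if (nrow(records) == 0L) {
    return(structure(list(
      curated = data.frame(id = character(0), smiles_std = character(0),
                           stringsAsFactors = FALSE),
      rejected = data.frame(id = character(0), smiles = character(0),
                            rejection_reason = character(0),
                            stringsAsFactors = FALSE),
      report = integer(0)), class = "curated_library"))
  }
  std <- lapply(records$smiles, standardize_structure)
  reason <- vapply(std, `[[`, character(1), "rejection_reason")
  smi <- vapply(std, `[[`, character(1), "smiles_std")
  ok <- reason == "none"
  curated <- data.frame(id = records$id[ok], smiles_std = smi[ok],
                        stringsAsFactors = FALSE)
  rejected <- data.frame(id = records$id[!ok], smiles = records$smiles[!ok],
                         rejection_reason = reason[!ok],
                         stringsAsFactors = FALSE)
  report <- table(factor(reason[!ok],
                         levels = c("mixture", "inorganic_or_metal",
                                    "unparseable", "no_structure")))
  structure(list(curated = curated, rejected = rejected,
                 report = c(report)),
            class = "curated_library")
}

#' @export
print.curated_library <- function(x, ...) {
  cat("Curated library:", nrow(x$curated), "QSAR-ready structures,",
      nrow(x$rejected), "rejected\n")
  rej <- x$report[x$report > 0]
  if (length(rej))
    cat("Rejections:", paste(names(rej), rej, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Read a chemical library CSV
#'
#' Expects columns `id`, `smiles` and optionally `casrn`, `name` (the
#' layout written by [write_library()]).
#'
#' @param path CSV file path.
#' @return Data frame of records.
#' @export
read_library_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(df)))
    stop("library CSV must contain 'id' and 'smiles' columns")
  df
}

#' Inactive-pool bookkeeping for QSAR endpoint sets
#'
#' Computes the size of the inactive pool used for a QSAR endpoint model:
#' chemicals tested minus actives minus the groups excluded for uncertain
#' activity (borderline actives and single-dose-only responders).
#'
#' @param n_total Chemicals tested in the assay.
#' @param n_active Actives in concentration-response for the endpoint.
#' @param n_borderline Borderline actives excluded from both classes.
#' @param n_single_dose Single-dose-only responders excluded from both
#'   classes.
#' @return The inactive pool size (integer).
#' @export
qsar_inactive_pool <- function(n_total, n_active, n_borderline,
                               n_single_dose) {
  counts <- c(n_total, n_active, n_borderline, n_single_dose)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("all counts must be non-negative numbers")
  out <- n_total - n_active - n_borderline - n_single_dose
  if (out < 0) stop("excluded groups exceed the total set size")
  as.integer(out)
}
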