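# Chemotype (binary substructure feature) handling: loading an externally
# computed chemotype matrix, a built-in SMARTS-defined chemotype fallback,
# per-chemotype chi-squared enrichment of an active set against the full
# tested background, and co-occurrence networks of significant chemotypes.

# Built-in chemotype vocabulary (SMARTS). A small substructure vocabulary
# mirroring the feature families most often flagged for steroidogenesis
# activity: benzene, phenol, aromatic and primary/secondary amines,
# triazine, aryl halide, phosphorothioate/dithioate, aromatic-alkane
# chains, naphthalene, biphenyl and sulfonyl groups.
.BUILTIN_CHEMOTYPES <- c(
  ring_aromatic_benzene       = "c1ccccc1",
  bond_COH_phenol             = "[OX2H][c]",
  bond_CN_amine_aromatic      = "[NX3;!$(N=*)]c1ccccc1",
  bond_CN_amine_primary       = "[NX3H2][#6]",
  bond_CN_amine_secondary     = "[NX3H1]([#6])[#6]",
  ring_hetero_triazine        = "c1ncncn1",
  bond_CX_halide_aromatic     = "[F,Cl,Br,I][c]",
  bond_PS_phosphorothioate    = "[PX4](=[SX1])",
  chain_aromatic_alkane       = "[CX4][c]",
  ring_aromatic_naphthalene   = "c1ccc2ccccc2c1",
  ring_aromatic_biphenyl      = "c1ccc(-c2ccccc2)cc1",
  bond_sulfonyl               = "[SX4](=O)(=O)"
)

#' Built-in chemotype vocabulary
#'
#' @return Named character vector of SMARTS patterns, one per built-in
#'   chemotype.
#' @export
builtin_chemotypes <- function() .BUILTIN_CHEMOTYPES

#' Match built-in chemotypes against curated structures
#'
#' Binary chemical x chemotype matrix by SMARTS substructure matching
#' (deterministic).
#'
#' @param curated A `curated_library`, or a data frame with `id` and
#'   `smiles_std`, or a named character vector of SMILES.
#' @return Object of class `chemotype_matrix`: list with `ids`, `flags`
#'   (binary matrix, chemicals x chemotypes), `source = "builtin_smarts"`.
#' @export
match_builtin_chemotypes <- function(curated) {
  if (inherits(curated, "curated_library")) curated <- curated$curated
  if (is.data.frame(curated)) {
    smiles <- stats::setNames(curated$smiles_std, curated$id)
  } else {
    smiles <- curated
    if (is.null(names(smiles)))
      names(smiles) <- as.character(seq_along(smiles))
  }
  refs <- ob_refs(smiles)
  flags <- vapply(.BUILTIN_CHEMOTYPES, function(patt)
    as.integer(ob_smarts_count(refs, patt) > 0), integer(length(smiles)))
  if (length(smiles) == 1L) flags <- matrix(flags, nrow = 1,
                                            dimnames = list(NULL, names(.BUILTIN_CHEMOTYPES)))
  rownames(flags) <- names(smiles)
  structure(list(ids = names(smiles), flags = flags,
                 source = "builtin_smarts"),
            class = "chemotype_matrix")
}

#' Load a chemotype matrix from a batch-search export
#'
#' Reads a TSV/CSV with an identifier column followed by binary chemotype
#' columns (the layout of a ToxPrint batch-search export from the EPA
#' chemicals dashboard).
#'
#' @param path File path; tab- or comma-separated, with header.
#' @param id_column Name of the identifier column (default: first column).
#' @return A `chemotype_matrix` with `source = "external_file"`.
#' @export
load_chemotype_matrix <- function(path, id_column = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chemotype file needs an id column plus flags")
  if (is.null(id_column)) id_column <- names(df)[1]
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids))
    stop("duplicate chemical id(s) in chemotype file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  flags <- as.matrix(df[, setdiff(names(df), id_column), drop = FALSE])
  bad <- which(matrix(!(flags %in% c(0, 1)), nrow(flags)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary chemotype value at row %d, column '%s'",
                 bad[1, 1], colnames(flags)[bad[1, 2]]))
  if (anyDuplicated(colnames(flags)))
    stop("duplicate chemotype column names")
  storage.mode(flags) <- "integer"
  rownames(flags) <- ids
  structure(list(ids = ids, flags = flags, source = "external_file"),
            class = "chemotype_matrix")
}

#' @export
print.chemotype_matrix <- function(x, ...) {
  cat("Chemotype matrix:", length(x$ids), "chemicals x", ncol(x$flags),
      "chemotypes (", x$source, ")\n")
  cat(sprintf("Mean chemotypes per chemical: %.1f\n", mean(rowSums(x$flags))))
  invisible(x)
}

.p_tier <- function(p) {
  ifelse(is.na(p), "-",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "-"))))
}

#' Chemotype enrichment of an active set against the tested background
#'
#' For every chemotype, a Pearson chi-squared test (two-sided, no
#' continuity correction) on the 2 x 2 table of (active vs non-active) x
#' (has vs lacks chemotype), where the background is the full tested set
#' including the actives. Rows are ordered by ascending p-value.
#' Chemotypes present in no chemical (or all chemicals) of the background
#' are untestable and flagged. Significance tiers: `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05. `reported` flags chemotypes covering more than
#' 20% of the active set. A Benjamini-Hochberg adjusted p-value is emitted
#' alongside for transparency but does not drive the tiers.
#'
#' @param matrix A `chemotype_matrix` covering all background ids.
#' @param active_ids Identifiers of the active set (non-empty, subset of
#'   `background_ids`).
#' @param background_ids Identifiers of the full tested set; defaults to
#'   all chemicals in the matrix.
#' @return Data frame of class `enrichment_rows`: chemotype, count_active,
#'   prevalence_active, count_background, prevalence_background, chi2,
#'   p_value, p_adjusted, tier, reported, untestable, low_expected (any
#'   expected count < 5).
#' @export
chemotype_enrichment <- function(matrix, active_ids,
                                 background_ids = matrix$ids) {
  stopifnot(inherits(matrix, "chemotype_matrix"))
  if (length(active_ids) == 0L) stop("empty active set")
  if (!all(active_ids %in% background_ids))
    stop("active ids must be a subset of background ids")
  if (!all(background_ids %in% matrix$ids))
    stop("chemotype matrix does not cover all background ids")
  fl <- matrix$flags[background_ids, , drop = FALSE]
  is_act <- background_ids %in% active_ids
  n_act <- sum(is_act); n_bg <- length(background_ids)

  rows <- lapply(colnames(fl), function(ct) {
    has <- fl[, ct] == 1L
    a_with <- sum(has & is_act)
    na_with <- sum(has & !is_act)
    tab <- rbind(c(a_with, n_act - a_with),
                 c(na_with, (n_bg - n_act) - na_with))
    untestable <- sum(has) == 0L || sum(has) == n_bg
    if (untestable) {
      chi2 <- NA_real_; p <- NA_real_; low_exp <- NA
    } else {
      ht <- suppressWarnings(stats::chisq.test(t(tab), correct = FALSE))
      chi2 <- unname(ht$statistic); p <- ht$p.value
      low_exp <- any(ht$expected < 5)
    }
    data.frame(chemotype = ct, count_active = a_with,
               prevalence_active = a_with / n_act,
               count_background = a_with + na_with,
               prevalence_background = (a_with + na_with) / n_bg,
               chi2 = chi2, p_value = p,
               reported = (a_with / n_act) > 0.20,
               untestable = untestable,
               low_expected = low_exp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  testable <- !out$untestable
  out$p_adjusted[testable] <- stats::p.adjust(out$p_value[testable], "BH")
  out$tier <- .p_tier(out$p_value)
  out <- out[order(out$p_value, method = "radix", na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_rows", class(out))
  out
}

#' Co-occurrence network of significant chemotypes
#'
#' Builds a weighted undirected graph whose nodes are the chemotypes
#' enriched (or depleted) at `p_cutoff`, annotated with their active-set
#' counts; an edge joins two chemotypes with weight equal to the number of
#' active chemicals carrying both, and zero-weight edges are omitted.
#'
#' @param matrix The `chemotype_matrix` used for the enrichment.
#' @param enrichment An [chemotype_enrichment()] result on that matrix.
#' @param active_ids The active set used for the enrichment.
#' @param p_cutoff Significance cutoff for node inclusion, default 0.01.
#' @return An `igraph` graph; vertex attribute `count_active`, edge
#'   attribute `weight`.
#' @export
cooccurrence_network <- function(matrix, enrichment, active_ids,
                                 p_cutoff = 0.01) {
  stopifnot(inherits(matrix, "chemotype_matrix"),
            inherits(enrichment, "enrichment_rows"))
  sig <- enrichment$chemotype[!enrichment$untestable &
                                !is.na(enrichment$p_value) &
                                enrichment$p_value < p_cutoff]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (length(sig) == 0L) return(g)
  fl <- matrix$flags[matrix$ids %in% active_ids, sig, drop = FALSE]
  co <- crossprod(fl)
  counts <- diag(co)
  edges <- NULL
  if (length(sig) > 1L) {
    prs <- utils::combn(sig, 2)
    w <- co[cbind(match(prs[1, ], colnames(co)),
                  match(prs[2, ], colnames(co)))]
    keep <- w > 0
    if (any(keep))
      edges <- data.frame(from = prs[1, keep], to = prs[2, keep],
                          weight = w[keep], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0),
                                   weight = numeric(0)) else edges,
    directed = FALSE,
    vertices = data.frame(name = sig, count_active = unname(counts[sig]),
                          stringsAsFactors = FALSE))
  g
}

#' Write a chemotype network to disk
#'
#' @param g Graph from [cooccurrence_network()].
#' @param graphml_path,edges_path Output paths (GraphML and edge-list CSV);
#'   either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(g, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.csv(el, edges_path, row.names = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}
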