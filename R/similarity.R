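# MACCS fingerprints, Tanimoto similarity, reference-hormone similarity
# profiles, applicability-domain scoring and classical-MDS projection of
# similarity matrices.

#' MACCS substructure fingerprints
#'
#' Computes 166-key MACCS fingerprints (Open Babel implementation) for a
#' vector of curated SMILES. Deterministic for a given canonical structure.
#'
#' @param smiles Character vector of curated SMILES; names (or `ids`) become
#'   fingerprint names.
#' @param ids Optional identifiers, defaults to `names(smiles)`.
#' @return A named list of class `maccs_fp_set`; each element is an integer
#'   vector of set key indices in 1..166.
#' @export
maccs_fingerprints <- function(smiles, ids = names(smiles)) {
  if (length(smiles) == 0L) stop("empty structure set")
  can <- ob_canonical(smiles)
  if (anyNA(can))
    stop("unparseable structure(s) at position(s): ",
         paste(utils::head(which(is.na(can)), 5), collapse = ", "),
         "; curate the library first")
  fp <- ChemmineOB::fingerprint_OB(ob_refs(can), "MACCS")
  if (!is.matrix(fp)) fp <- matrix(fp, nrow = 1)
  bits <- lapply(seq_len(nrow(fp)), function(i) which(fp[i, ] > 0))
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  names(bits) <- ids
  structure(bits, class = "maccs_fp_set")
}

#' @rdname maccs_fingerprints
#' @param smi A single SMILES string.
#' @export
maccs_fingerprint <- function(smi) {
  maccs_fingerprints(smi, ids = "query")[[1]]
}

#' Tanimoto similarity between two fingerprints
#'
#' |A intersect B| / |A union B|. Two empty fingerprints are defined to
#' have similarity 0 (conservative dissimilarity).
#'
#' @param a,b Integer vectors of set key indices (elements of a
#'   [maccs_fingerprints()] result).
#' @return Similarity score in [0, 1]; 1 means identical key sets.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps A `maccs_fp_set`.
#' @return Symmetric matrix with unit diagonal (for non-empty
#'   fingerprints).
#' @export
tanimoto_matrix <- function(fps) {
  n <- length(fps)
  # bit-matrix formulation: intersections via crossprod
  M <- matrix(0L, nrow = n, ncol = 166)
  for (i in seq_len(n)) M[i, fps[[i]]] <- 1L
  inter <- tcrossprod(M)
  sizes <- rowSums(M)
  uni <- outer(sizes, sizes, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  dimnames(S) <- list(names(fps), names(fps))
  S
}

#' Similarity profile of a library against a reference structure
#'
#' Tanimoto score of every library chemical against a reference fingerprint
#' (e.g. estradiol or progesterone), with the profile mean and standard
#' deviation.
#'
#' @param fps A `maccs_fp_set` for the library.
#' @param reference A single fingerprint (integer key vector).
#' @param reference_id Label for the reference.
#' @return An object of class `similarity_profile`: list with `scores`
#'   (data frame id, score), `mean`, `sd`, `reference_id`.
#' @export
similarity_profile <- function(fps, reference, reference_id = "reference") {
  if (length(fps) == 0L) stop("empty library")
  sc <- vapply(fps, tanimoto, numeric(1), b = reference)
  structure(list(scores = data.frame(id = names(fps), score = unname(sc),
                                     stringsAsFactors = FALSE),
                 mean = mean(sc), sd = stats::sd(sc),
                 reference_id = reference_id),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("Similarity profile vs %s: %.2f +/- %.2f over %d chemicals\n",
              x$reference_id, x$mean,
              ifelse(is.na(x$sd), 0, x$sd), nrow(x$scores)))
  invisible(x)
}

#' Applicability-domain score of a query against a training set
#'
#' Scores how well a query chemical is covered by the training chemical
#' space. The default (`"nearest"`) is the Tanimoto similarity to the
#' nearest training chemical, so training members score 1 and structural
#' outliers score near 0; predictions with scores below ~0.75 should be
#' treated with caution. The `"minimum"` variant (similarity to the
#' farthest training chemical) is exposed for completeness but is close to
#' 0 for any query against a diverse training set.
#'
#' @param query A single fingerprint.
#' @param training A `maccs_fp_set` (non-empty).
#' @param method `"nearest"` (default) or `"minimum"`.
#' @return Score in [0, 1].
#' @export
ad_score <- function(query, training, method = c("nearest", "minimum")) {
  method <- match.arg(method)
  if (length(training) == 0L) stop("empty training set")
  sims <- vapply(training, tanimoto, numeric(1), b = query)
  if (method == "nearest") max(sims) else min(sims)
}

#' Classical MDS projection of a similarity matrix
#'
#' Projects chemicals into two dimensions by classical multidimensional
#' scaling of the distance matrix 1 - similarity. Signs are fixed so the
#' largest-magnitude loading of each axis is positive, making the output
#' deterministic up to that convention.
#'
#' @param S Square symmetric similarity matrix with unit diagonal.
#' @return Data frame with `id`, `x`, `y`.
#' @export
mds_projection <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S) ||
      max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix must be square and symmetric")
  D <- 1 - S
  k <- min(2L, nrow(S) - 1L)
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = k))
  if (!is.matrix(xy) || ncol(xy) == 0L)   # degenerate: coincident points
    xy <- matrix(0, nrow(S), 2L)
  while (ncol(xy) < 2L) xy <- cbind(xy, 0)
  for (j in 1:2) {
    if (abs(min(xy[, j])) > abs(max(xy[, j]))) xy[, j] <- -xy[, j]
  }
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(S)))
  data.frame(id = ids, x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}

# Reference hormone structures (as depicted on the EPA dashboard records).
.REFERENCE_SMILES <- c(
  estradiol = "C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1CC[C@@H]2O",
  progesterone = "CC(=O)[C@H]1CC[C@H]2[C@@H]3CCC4=CC(=O)CC[C@]4(C)[C@H]3CC[C@]12C"
)

#' Reference hormone structures
#'
#' SMILES of estradiol (CASRN 50-28-2) and progesterone (CASRN 57-83-0),
#' the endogenous reference hormones for similarity profiling.
#'
#' @return Named character vector of SMILES.
#' @export
reference_hormones <- function() .REFERENCE_SMILES
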