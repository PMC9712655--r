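# 1D/2D molecular descriptor computation and the two-stage descriptor
# selection: (i) removal of null-variance and near-constant columns,
# (ii) correlation clustering at |r| > 0.9 with one seeded representative
# per cluster.
#
# Descriptor families: constitutional counts, aromatic composition,
# topological indices (Wiener, Harary, Zagreb, Narumi harmonic,
# eccentricity-based), Kier-Hall connectivity chi indices (simple, valence
# and 6-ring cyclic), Basak information content, Burden-matrix eigenvalue
# (BCUT) descriptors, electrotopological state sums, and physicochemical
# properties from Open Babel (logP, TPSA, molar refractivity, H-bond
# counts). Graphs are taken from Open Babel's kekulised connection table;
# aromaticity from Hueckel ring perception (ChemmineR).

.ELEM <- list(
  mass = c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
           F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81,
           Si = 28.085, H = 1.008),
  vdw_r = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47,
            Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10, H = 1.20),
  zv = c(C = 4, N = 5, O = 6, S = 6, P = 5, F = 7, Cl = 7, Br = 7, I = 7,
         B = 3, Si = 4, H = 1),
  quantum_n = c(C = 2, N = 2, O = 2, F = 2, B = 2, S = 3, P = 3, Cl = 3,
                Si = 3, Br = 4, I = 5, H = 1)
)

.elem_lookup <- function(table, elems, default) {
  out <- unname(table[elems])
  out[is.na(out)] <- default
  out
}

# implicit hydrogen count per heavy atom from the kekulised bond-order sum
.implicit_h <- function(elems, bondsum) {
  vapply(seq_along(elems), function(i) {
    e <- elems[i]; b <- bondsum[i]
    val <- switch(e,
                  C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
                  B = 3, Si = 4,
                  S = c(2, 4, 6)[which(c(2, 4, 6) >= b)[1]],
                  P = c(3, 5)[which(c(3, 5) >= b)[1]],
                  b)
    if (is.na(val)) val <- b
    max(0, val - b)
  }, numeric(1))
}

# descriptors for one molecule given its atom elements, bond table and
# perceived rings; `props` is the corresponding prop_OB row
.mol_descriptors <- function(elems, bonds, ringinfo, props, n_rot) {
  nA <- length(elems)
  nB <- if (is.null(bonds)) 0L else nrow(bonds)
  counts <- c(
    nHeavy = nA,
    nC = sum(elems == "C"), nN = sum(elems == "N"), nO = sum(elems == "O"),
    nS = sum(elems == "S"), nP = sum(elems == "P"),
    nHalogen = sum(elems %in% c("F", "Cl", "Br", "I"))
  )

  deg <- numeric(nA)
  bondsum <- numeric(nA)
  if (nB > 0) {
    for (k in seq_len(nB)) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1
      bondsum[i] <- bondsum[i] + o; bondsum[j] <- bondsum[j] + o
    }
  }
  nH <- .implicit_h(elems, bondsum)

  # rings
  ring_sets <- ringinfo$rings
  aromatic <- ringinfo$aromatic
  ar_rings <- ring_sets[aromatic]
  ar_atoms <- unique(unlist(ar_rings))
  ar_bond_keys <- unique(unlist(lapply(ar_rings, function(r) {
    nxt <- c(r[-1], r[1])
    paste(pmin(r, nxt), pmax(r, nxt))
  })))
  # substituted aromatic carbon (aasC): aromatic C, heavy degree 3, member
  # of exactly one aromatic ring
  ar_member_count <- tabulate(as.integer(unlist(ar_rings)), nbins = nA)
  aasC <- which(elems == "C" & seq_len(nA) %in% ar_atoms &
                  deg == 3 & ar_member_count == 1)

  # topology (single-fragment guaranteed by curation)
  if (nA > 1 && nB > 0) {
    g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < nA) g <- igraph::add_vertices(g, nA - igraph::vcount(g))
    D <- igraph::distances(g)
    D[!is.finite(D)] <- nA
    ecc <- apply(D, 1, max)
    wiener <- sum(D) / 2
    harary <- sum(1 / D[upper.tri(D)])
    diam <- max(ecc); rad <- min(ecc)
  } else {
    D <- matrix(0, nA, nA)
    ecc <- 0; wiener <- 0; harary <- 0; diam <- 0; rad <- 0
  }

  zagreb1 <- sum(deg^2)
  zagreb2 <- if (nB > 0) sum(deg[bonds[, 1]] * deg[bonds[, 2]]) else 0
  hato <- if (all(deg > 0)) nA / sum(1 / deg) else 0
  n_multiple <- if (nB > 0) sum(bonds[, 3] >= 2) else 0
  ui <- log2(1 + n_multiple)
  ecc_conn <- sum(deg * ecc)

  # connectivity chi indices
  zv <- .elem_lookup(.ELEM$zv, elems, 4)
  dv <- pmax(zv - nH, 1e-6)
  chi0 <- sum(ifelse(deg > 0, 1 / sqrt(deg), 0))
  chi0v <- sum(1 / sqrt(dv))
  chi1 <- if (nB > 0) sum(1 / sqrt(deg[bonds[, 1]] * deg[bonds[, 2]])) else 0
  chi1v <- if (nB > 0) sum(1 / sqrt(dv[bonds[, 1]] * dv[bonds[, 2]])) else 0
  chi2 <- 0
  if (nB > 0) {
    adj <- vector("list", nA)
    for (k in seq_len(nB)) {
      adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], bonds[k, 2])
      adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], bonds[k, 1])
    }
    for (j in seq_len(nA)) {
      nb <- adj[[j]]
      if (length(nb) >= 2) {
        prs <- utils::combn(nb, 2)
        chi2 <- chi2 + sum(1 / sqrt(deg[prs[1, ]] * deg[j] * deg[prs[2, ]]))
      }
    }
  }
  six_rings <- ring_sets[vapply(ring_sets, length, integer(1)) == 6]
  chi6ch <- sum(vapply(six_rings,
                       function(r) prod(1 / sqrt(deg[r])), numeric(1)))

  # Basak information content via neighbourhood refinement
  ic <- function(classes) {
    p <- table(classes) / length(classes)
    -sum(p * log2(p))
  }
  cls <- paste(elems, nH)
  ic0 <- ic(cls)
  for (it in 1:2) {
    cls_new <- vapply(seq_len(nA), function(i) {
      nb <- if (nB > 0) sort(cls[adj_of(bonds, i)]) else character(0)
      paste(cls[i], paste(nb, collapse = "|"))
    }, character(1))
    cls <- cls_new
    if (it == 1) ic1 <- ic(cls)
  }
  ic2 <- ic(cls)

  # Burden-matrix eigenvalue descriptors
  bcut <- function(diagw) {
    if (nA == 1) return(c(diagw, diagw))
    B <- matrix(0.001, nA, nA)
    if (nB > 0) for (k in seq_len(nB)) {
      w <- 0.1 * bonds[k, 3]
      B[bonds[k, 1], bonds[k, 2]] <- w
      B[bonds[k, 2], bonds[k, 1]] <- w
    }
    diag(B) <- diagw
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    c(min(ev), max(ev))
  }
  mw_diag <- .elem_lookup(.ELEM$mass, elems, 30) / .ELEM$mass[["C"]]
  vr <- .elem_lookup(.ELEM$vdw_r, elems, 1.7)
  vv_diag <- (4 / 3) * pi * vr^3 / ((4 / 3) * pi * .ELEM$vdw_r[["C"]]^3)
  bm <- bcut(mw_diag); bv <- bcut(vv_diag)

  # electrotopological state
  qn <- .elem_lookup(.ELEM$quantum_n, elems, 3)
  I <- ifelse(deg > 0, ((2 / qn)^2 * dv + 1) / deg, 0)
  S <- I
  if (nA > 1) {
    for (i in seq_len(nA)) {
      S[i] <- I[i] + sum((I[i] - I[-i]) / (D[i, -i] + 1)^2)
    }
  }

  mw <- props[["MW"]]; logp <- props[["logP"]]
  hba <- props[["HBA1"]]; hbd <- props[["HBD"]]
  lipinski <- sum(mw > 500, logp > 5, hbd > 5, hba > 10)

  c(counts,
    nRings = max(0, nB - nA + 1),
    nRotBond = n_rot,
    ArAtomCount = length(ar_atoms),
    ArBondCount = length(ar_bond_keys),
    Cfrag17 = length(aasC),
    Zagreb1 = zagreb1, Zagreb2 = zagreb2,
    Wiener = wiener, Harary = harary,
    Diameter = diam, Radius = rad, EccConn = ecc_conn,
    Hato = hato, UI = ui,
    Chi0 = chi0, Chi1 = chi1, Chi2 = chi2,
    Chi0v = chi0v, Chi1v = chi1v, Chi6ch = chi6ch,
    IC0 = ic0, IC1 = ic1, IC2 = ic2,
    Bcutm1 = bm[1], Bcutm2 = bm[2], Bcutv1 = bv[1], Bcutv2 = bv[2],
    SsTot = sum(S), SEStatefrag17 = sum(S[aasC]),
    SsO = sum(S[elems == "O"]), SsN = sum(S[elems == "N"]),
    Smax = if (nA) max(S) else 0, Smin = if (nA) min(S) else 0,
    MW = mw, logP = logp, TPSA = props[["TPSA"]], MR = props[["MR"]],
    HBA = hba, HBD = hbd,
    LipinskiViolations = lipinski)
}

adj_of <- function(bonds, i) {
  c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
}

#' Compute the 1D/2D descriptor matrix for a curated library
#'
#' One row per chemical over the package's 1D/2D descriptor families (see
#' the file-level description). Structures must be curated
#' ([curate_library()]): single-fragment, metal-free, canonical SMILES.
#' Any descriptor that fails on a chemical is imputed with the column
#' median; a column failing on more than 10% of chemicals is dropped.
#'
#' @param curated A `curated_library` or a data frame with columns `id` and
#'   `smiles_std`.
#' @return An object of class `descriptor_matrix`: list with `ids`,
#'   `values` (numeric matrix, rownames = ids), `provenance` (named vector,
#'   `"computed"` or `"external"`), and `smiles` (named by id, used
#'   downstream for fingerprints).
#' @export
compute_descriptor_matrix <- function(curated) {
  if (inherits(curated, "curated_library")) curated <- curated$curated
  stopifnot(is.data.frame(curated),
            all(c("id", "smiles_std") %in% names(curated)))
  if (nrow(curated) == 0L) stop("empty curated set")
  ids <- curated$id
  smiles <- curated$smiles_std

  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids)))
  ringinfo_all <- ChemmineR::rings(sdf, upper = 6, type = "all", arom = TRUE,
                                   inner = FALSE)
  refs <- ob_refs(smiles)
  props <- ChemmineOB::prop_OB(refs)
  n_rot <- ob_smarts_count(refs, "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]") / 2

  n <- length(ids)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elems <- sub("_.*$", "", rownames(ab))
    keep <- elems != "H"
    elems <- elems[keep]
    bonds <- NULL
    if (!is.null(bb) && nrow(bb) > 0) {
      bonds <- cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]),
                     as.numeric(bb[, 3]))
    }
    ri <- if (n == 1) ringinfo_all else ringinfo_all[[i]]
    ring_sets <- lapply(ri$RINGS, function(r)
      as.integer(sub("^.*_", "", r)))
    ringinfo <- list(rings = ring_sets,
                     aromatic = if (length(ring_sets))
                       as.logical(ri$AROMATIC) else logical(0))
    rows[[i]] <- tryCatch(
      .mol_descriptors(elems, bonds, ringinfo, props[i, , drop = FALSE],
                       n_rot[i]),
      error = function(e) NULL)
  }
  template <- rows[[which(!vapply(rows, is.null, logical(1)))[1]]]
  if (is.null(template)) stop("descriptor computation failed on every chemical")
  values <- t(vapply(rows, function(r) {
    if (is.null(r)) rep(NA_real_, length(template)) else r
  }, numeric(length(template))))
  rownames(values) <- ids
  colnames(values) <- names(template)

  # impute residual failures with the column median; drop mostly-failed cols
  frac_na <- colMeans(is.na(values))
  values <- values[, frac_na <= 0.10, drop = FALSE]
  for (j in seq_len(ncol(values))) {
    nas <- is.na(values[, j])
    if (any(nas)) values[nas, j] <- stats::median(values[, j], na.rm = TRUE)
  }

  structure(list(ids = ids, values = values,
                 provenance = stats::setNames(rep("computed", ncol(values)),
                                              colnames(values)),
                 smiles = stats::setNames(smiles, ids)),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("Descriptor matrix:", length(x$ids), "chemicals x", ncol(x$values),
      "descriptors (", sum(x$provenance == "external"), "external )\n")
  invisible(x)
}

#' Merge externally computed descriptors
#'
#' Appends id-keyed external descriptor columns (e.g. predicted
#' physicochemical properties) to a computed descriptor matrix. Chemicals
#' absent from the external table are imputed with the column median.
#'
#' @param mat A `descriptor_matrix`.
#' @param table Data frame with an `id` column and numeric descriptor
#'   columns; ids must be a subset of `mat$ids`.
#' @return The extended `descriptor_matrix`; new columns are flagged
#'   `provenance = "external"`.
#' @export
merge_external_descriptors <- function(mat, table) {
  stopifnot(inherits(mat, "descriptor_matrix"), is.data.frame(table))
  if (ncol(table) <= 1L || nrow(table) == 0L) return(mat)
  if (!"id" %in% names(table)) stop("external table must have an 'id' column")
  unknown <- setdiff(table$id, mat$ids)
  if (length(unknown))
    stop("external table contains unknown id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  newcols <- setdiff(names(table), "id")
  clash <- intersect(newcols, colnames(mat$values))
  if (length(clash))
    stop("descriptor name collision: ", paste(clash, collapse = ", "))
  ext <- matrix(NA_real_, nrow = length(mat$ids), ncol = length(newcols),
                dimnames = list(mat$ids, newcols))
  ext[match(table$id, mat$ids), ] <- as.matrix(table[, newcols, drop = FALSE])
  for (j in seq_len(ncol(ext))) {
    nas <- is.na(ext[, j])
    if (any(nas)) ext[nas, j] <- stats::median(ext[, j], na.rm = TRUE)
  }
  mat$values <- cbind(mat$values, ext)
  mat$provenance <- c(mat$provenance,
                      stats::setNames(rep("external", length(newcols)),
                                      newcols))
  mat
}

#' Remove uninformative descriptors
#'
#' Drops descriptors with null variance and descriptors whose most frequent
#' value covers more than 90% of the chemicals (strictly more; a descriptor
#' constant for exactly 90% of the set is retained).
#'
#' @param mat A `descriptor_matrix` with at least two chemicals.
#' @param near_constant_fraction Modal-frequency cutoff, default 0.90.
#' @return List with the filtered `matrix` and a `report` (lists
#'   `dropped_null_variance`, `dropped_near_constant`).
#' @export
remove_uninformative <- function(mat, near_constant_fraction = 0.90) {
  stopifnot(inherits(mat, "descriptor_matrix"))
  if (length(mat$ids) < 2L) stop("need at least two chemicals")
  v <- apply(mat$values, 2, stats::var)
  null_var <- colnames(mat$values)[v == 0 | !is.finite(v)]
  modal_frac <- apply(mat$values, 2, function(x)
    max(table(x)) / length(x))
  near_const <- setdiff(
    colnames(mat$values)[modal_frac > near_constant_fraction], null_var)
  keep <- setdiff(colnames(mat$values), c(null_var, near_const))
  if (length(keep) == 0L)
    stop("descriptor selection removed every column")
  mat$values <- mat$values[, keep, drop = FALSE]
  mat$provenance <- mat$provenance[keep]
  list(matrix = mat,
       report = list(dropped_null_variance = null_var,
                     dropped_near_constant = near_const,
                     near_constant_fraction = near_constant_fraction))
}

#' Correlation-based descriptor clustering and selection
#'
#' Clusters descriptors as connected components of the graph whose edges
#' connect pairs with |Pearson r| > `threshold`, then keeps one randomly
#' selected representative per cluster (seeded draw). Anti-correlated
#' descriptors are treated as redundant (absolute correlation).
#'
#' Note the contract is component-based: two retained descriptors are in
#' different components, but a retained pair may exceed the threshold only
#' through a dropped mediator; what is guaranteed is one representative per
#' component.
#'
#' @param mat A `descriptor_matrix` that already passed
#'   [remove_uninformative()].
#' @param threshold Absolute-correlation threshold, default 0.9.
#' @param seed Integer seed for the representative draw.
#' @return List with the reduced `matrix` and a `report` of class
#'   `selection_report` (`correlation_clusters`: list of name sets with the
#'   representative first; `threshold`; `seed`).
#' @export
correlation_cluster_select <- function(mat, threshold = 0.9, seed = 1L) {
  stopifnot(inherits(mat, "descriptor_matrix"))
  cors <- suppressWarnings(stats::cor(mat$values))
  cors[!is.finite(cors)] <- 0
  adj <- abs(cors) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  clusters <- split(colnames(mat$values), comp)
  reps <- vapply(clusters, function(cl) {
    if (length(cl) == 1L) cl else sample(cl, 1L)
  }, character(1))
  keep <- colnames(mat$values)[colnames(mat$values) %in% reps]
  clusters <- lapply(clusters, function(cl)
    c(intersect(cl, reps), setdiff(cl, reps)))
  mat$values <- mat$values[, keep, drop = FALSE]
  mat$provenance <- mat$provenance[keep]
  report <- structure(list(correlation_clusters = unname(clusters),
                           threshold = threshold, seed = seed),
                      class = "selection_report")
  list(matrix = mat, report = report)
}

#' Z-score standardisation of a descriptor matrix
#'
#' Centers and scales every descriptor; the scaler is kept so query sets
#' can be transformed with the training parameters
#' ([apply_standardization()]).
#'
#' @param mat A `descriptor_matrix`.
#' @return The matrix with standardised `values` and a `scaler` element
#'   (`center`, `scale`).
#' @export
standardize_descriptors <- function(mat) {
  stopifnot(inherits(mat, "descriptor_matrix"))
  ctr <- colMeans(mat$values)
  scl <- apply(mat$values, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  mat$values <- scale(mat$values, center = ctr, scale = scl)
  attr(mat$values, "scaled:center") <- NULL
  attr(mat$values, "scaled:scale") <- NULL
  mat$scaler <- list(center = ctr, scale = scl)
  mat
}

#' Apply a stored standardisation to a query descriptor matrix
#'
#' @param mat A `descriptor_matrix` over (at least) the scaler's
#'   descriptors.
#' @param scaler The `scaler` element of a [standardize_descriptors()]
#'   result.
#' @return The matrix restricted to the scaler's descriptors, standardised
#'   with the stored center and scale.
#' @export
apply_standardization <- function(mat, scaler) {
  stopifnot(inherits(mat, "descriptor_matrix"))
  miss <- setdiff(names(scaler$center), colnames(mat$values))
  if (length(miss))
    stop("query matrix is missing descriptor(s): ",
         paste(miss, collapse = ", "))
  mat$values <- scale(mat$values[, names(scaler$center), drop = FALSE],
                      center = scaler$center, scale = scaler$scale)
  attr(mat$values, "scaled:center") <- NULL
  attr(mat$values, "scaled:scale") <- NULL
  mat$provenance <- mat$provenance[names(scaler$center)]
  mat$scaler <- scaler
  mat
}
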