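test_that("aromatic and ring descriptors match hand counts", {
  mat <- compute_descriptor_matrix(
    data.frame(id = c("benzene", "ethane", "toluene", "naphthalene"),
               smiles_std = c("c1ccccc1", "CC", "Cc1ccccc1",
                              "c1ccc2ccccc2c1")))
  v <- mat$values
  expect_equal(unname(v["benzene", "ArBondCount"]), 6)
  expect_equal(unname(v["benzene", "ArAtomCount"]), 6)
  # benzene 6-ring cyclic chi: all degrees 2 -> (1/sqrt(2))^6
  expect_equal(unname(v["benzene", "Chi6ch"]), (1 / sqrt(2))^6)
  expect_equal(unname(v["ethane", "ArBondCount"]), 0)
  expect_equal(unname(v["ethane", "Chi6ch"]), 0)
  expect_equal(unname(v["ethane", "nRings"]), 0)
  # toluene: one substituted aromatic carbon
  expect_equal(unname(v["toluene", "Cfrag17"]), 1)
  # naphthalene: 11 aromatic bonds, 10 atoms, fusion carbons not aasC
  expect_equal(unname(v["naphthalene", "ArBondCount"]), 11)
  expect_equal(unname(v["naphthalene", "Cfrag17"]), 0)
  # Wiener index of ethane = 1
  expect_equal(unname(v["ethane", "Wiener"]), 1)
})

test_that("descriptor matrices are complete (no missing values)", {
  mat <- small_descriptors()
  expect_false(anyNA(mat$values))
  expect_equal(rownames(mat$values), mat$ids)
  expect_true(all(mat$provenance == "computed"))
})

test_that("external descriptor merge appends flagged columns", {
  mat <- compute_descriptor_matrix(
    data.frame(id = c("a", "b"), smiles_std = c("CCO", "CCCO")))
  ext <- data.frame(id = c("a", "b"), LogVP_pred = c(-1.2, -2.0),
                    BP_pred = c(78, 97))
  merged <- merge_external_descriptors(mat, ext)
  expect_equal(ncol(merged$values), ncol(mat$values) + 2)
  expect_equal(unname(merged$provenance[c("LogVP_pred", "BP_pred")]),
               c("external", "external"))
  # empty table: unchanged
  expect_identical(merge_external_descriptors(mat, data.frame(id = character(0))),
                   mat)
  # unknown id: error
  expect_error(merge_external_descriptors(mat,
                                          data.frame(id = "zz", X = 1)),
               "unknown id")
  # collision with existing name: error
  expect_error(merge_external_descriptors(mat,
                                          data.frame(id = "a", MW = 1)),
               "collision")
})

test_that("uninformative filter drops null-variance and >90% constant", {
  base <- compute_descriptor_matrix(
    data.frame(id = sprintf("c%d", 1:5),
               smiles_std = c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC")))
  # craft columns with known modal frequencies on 100 rows
  fake <- base
  n <- 100
  fake$values <- cbind(
    informative = c(seq_len(n)),
    constant = rep(5, n),
    const91 = c(rep(5, 91), 101:109),
    const90 = c(rep(5, 90), 101:110))
  fake$ids <- sprintf("x%03d", seq_len(n))
  rownames(fake$values) <- fake$ids
  fake$provenance <- stats::setNames(rep("computed", 4),
                                     colnames(fake$values))
  out <- remove_uninformative(fake)
  expect_equal(out$report$dropped_null_variance, "constant")
  expect_equal(out$report$dropped_near_constant, "const91")
  expect_setequal(colnames(out$matrix$values), c("informative", "const90"))
})

test_that("correlation clustering keeps one representative per component", {
  n <- 50
  set.seed(9)
  x <- rnorm(n)
  vals <- cbind(a = x, b = x, c = -x + rnorm(n, sd = 0.01),
                d = rnorm(n), e = rnorm(n))
  mat <- structure(list(ids = sprintf("m%d", 1:n), values = vals,
                        provenance = stats::setNames(rep("computed", 5),
                                                     colnames(vals))),
                   class = "descriptor_matrix")
  rownames(mat$values) <- mat$ids
  out <- correlation_cluster_select(mat, threshold = 0.9, seed = 1)
  kept <- colnames(out$matrix$values)
  # a, b, c are one component (|r| > 0.9, anti-correlation counts)
  expect_equal(sum(kept %in% c("a", "b", "c")), 1)
  expect_true(all(c("d", "e") %in% kept))
  # every cluster has exactly one representative, marked first
  reps <- vapply(out$report$correlation_clusters, `[`, character(1), 1)
  expect_setequal(reps, kept)
  # determinism given seed
  out2 <- correlation_cluster_select(mat, threshold = 0.9, seed = 1)
  expect_identical(colnames(out2$matrix$values), kept)
})

test_that("selection is idempotent on an already-selected matrix", {
  sel1 <- correlation_cluster_select(
    remove_uninformative(small_descriptors())$matrix, seed = 7)
  sel2 <- correlation_cluster_select(
    remove_uninformative(sel1$matrix)$matrix, seed = 7)
  expect_identical(colnames(sel2$matrix$values),
                   colnames(sel1$matrix$values))
})

test_that("standardisation round-trips through the stored scaler", {
  std <- small_selected_std()
  expect_equal(unname(colMeans(std$values)),
               rep(0, ncol(std$values)), tolerance = 1e-12)
  expect_equal(unname(apply(std$values, 2, sd)),
               rep(1, ncol(std$values)), tolerance = 1e-12)
  raw <- correlation_cluster_select(
    remove_uninformative(small_descriptors())$matrix, seed = 7)$matrix
  again <- apply_standardization(raw, std$scaler)
  expect_equal(again$values, std$values)
})
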