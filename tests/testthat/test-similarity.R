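test_that("MACCS fingerprints are deterministic, sparse for methane", {
  fp1 <- maccs_fingerprint("C")
  fp2 <- maccs_fingerprint("C")
  expect_identical(fp1, fp2)
  expect_lte(length(fp1), 3)
  refs <- maccs_fingerprints(reference_hormones())
  expect_true(all(unlist(refs) >= 1) && all(unlist(refs) <= 166))
  expect_false(setequal(refs$estradiol, refs$progesterone))
  expect_error(maccs_fingerprints("not-a-smiles((("), "unparseable")
})

test_that("tanimoto has the set-overlap semantics", {
  expect_equal(tanimoto(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(integer(0), integer(0)), 0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 2 / 4)
  # symmetry on random key sets
  set.seed(1)
  for (i in 1:20) {
    a <- sample(166, sample(30, 1))
    b <- sample(166, sample(30, 1))
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0)
    expect_lte(tanimoto(a, b), 1)
    expect_equal(tanimoto(a, a), 1)
  }
})

test_that("estradiol vs progesterone similarity matches the known value", {
  refs <- maccs_fingerprints(reference_hormones())
  s <- tanimoto(refs$estradiol, refs$progesterone)
  expect_equal(round(s, 2), 0.58)
  # the two hormones share the sterol core: high but not identical
  expect_gt(s, 0.5)
  expect_lt(s, 1)
})

test_that("tanimoto_matrix agrees with pairwise calls", {
  lib <- c(a = "c1ccccc1", b = "Cc1ccccc1", c = "CCO")
  fps <- maccs_fingerprints(lib)
  S <- tanimoto_matrix(fps)
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(S["a", "b"], tanimoto(fps$a, fps$b))
  expect_equal(S["a", "c"], tanimoto(fps$a, fps$c))
})

test_that("similarity profiles summarise per-chemical scores", {
  fps <- maccs_fingerprints(c(x = "c1ccccc1", y = "c1ccccc1"))
  prof <- similarity_profile(fps, fps$x, "self")
  expect_equal(prof$mean, 1)
  expect_equal(prof$sd, 0)
  # mean of hand-made scores
  prof2 <- similarity_profile(
    maccs_fingerprints(c(p = "CCO", q = "CCCCO")),
    maccs_fingerprint("CCO"))
  expect_equal(prof2$mean, mean(prof2$scores$score))
  expect_error(similarity_profile(structure(list(), class = "maccs_fp_set"),
                                  fps$x), "empty")
})

test_that("AD score is nearest-neighbour similarity, 1 for members", {
  lib <- small_curated()$curated[1:25, ]
  fps <- maccs_fingerprints(stats::setNames(lib$smiles_std, lib$id))
  for (i in c(1, 10, 25)) {
    expect_equal(ad_score(fps[[i]], fps), 1)
  }
  # disjoint query scores 0
  train <- list(a = c(10, 20, 30))
  class(train) <- "maccs_fp_set"
  expect_equal(ad_score(c(40, 50), train), 0)
  # minimum variant is never above the nearest-neighbour score
  q <- fps[[3]]
  expect_lte(ad_score(q, fps, method = "minimum"),
             ad_score(q, fps, method = "nearest"))
  expect_error(ad_score(q, structure(list(), class = "maccs_fp_set")),
               "empty")
})

test_that("classical MDS reproduces planted 2D configurations", {
  # two chemicals at similarity 0.5 -> points 0.5 apart
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  xy <- mds_projection(S2)
  expect_equal(dist(as.matrix(xy[, c("x", "y")]))[1], 0.5,
               tolerance = 1e-9)
  # identical chemicals coincide
  S1 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  xy1 <- mds_projection(S1)
  expect_equal(xy1$x[1], xy1$x[2], tolerance = 1e-9)
  # 4 planted points: distances recovered within 1e-6
  pts <- matrix(c(0, 0, 0.4, 0, 0, 0.3, 0.4, 0.3), ncol = 2, byrow = TRUE)
  D <- as.matrix(dist(pts))
  S <- 1 - D
  dimnames(S) <- list(letters[1:4], letters[1:4])
  proj <- mds_projection(S)
  Dhat <- as.matrix(dist(proj[, c("x", "y")]))
  expect_equal(unname(Dhat), unname(D), tolerance = 1e-6)
  expect_error(mds_projection(matrix(c(1, 0.2, 0.8, 1), 2)), "symmetric")
})
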