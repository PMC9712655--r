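test_that("built-in chemotype matching flags known substructures", {
  cm <- match_builtin_chemotypes(c(
    phenol = "Oc1ccccc1",
    atrazine = "CCNc1nc(Cl)nc(NC(C)C)n1",
    ethane = "CC",
    parathion_like = "CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-]"))
  fl <- cm$flags
  expect_equal(unname(fl["phenol", c("ring_aromatic_benzene",
                                     "bond_COH_phenol",
                                     "ring_hetero_triazine")]),
               c(1L, 1L, 0L))
  expect_equal(unname(fl["atrazine", "ring_hetero_triazine"]), 1L)
  expect_equal(unname(fl["ethane", ]), rep(0L, ncol(fl)))
  expect_equal(unname(fl["parathion_like", "bond_PS_phosphorothioate"]), 1L)
  expect_true(all(fl %in% c(0L, 1L)))
})

test_that("chemotype files are validated on load", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("DTXSID\tct_a\tct_b", "id1\t1\t0", "id2\t0\t1", "id3\t1\t1"),
             path)
  cm <- load_chemotype_matrix(path)
  expect_equal(length(cm$ids), 3)
  expect_equal(ncol(cm$flags), 2)
  expect_equal(cm$source, "external_file")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("DTXSID\tct_a", "id1\t2"), bad)
  expect_error(load_chemotype_matrix(bad), "non-binary")
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("DTXSID\tct_a", "id1\t1", "id1\t0"), dup)
  expect_error(load_chemotype_matrix(dup), "duplicate")
})

test_that("chi-squared enrichment matches a brute-force oracle", {
  set.seed(31)
  for (i in 1:50) {
    # random 2x2 with all margins positive
    a <- sample(1:30, 1); b <- sample(1:30, 1)
    c <- sample(1:30, 1); d <- sample(1:30, 1)
    ht <- suppressWarnings(stats::chisq.test(matrix(c(a, b, c, d), 2),
                                             correct = FALSE))
    oracle <- chisq2x2_oracle(a, b, c, d)
    expect_equal(unname(ht$statistic), oracle$stat, tolerance = 1e-9)
    expect_equal(ht$p.value, oracle$p, tolerance = 1e-9)
  }
})

test_that("enrichment reproduces the triazine worked example", {
  # 11 of 182 actives carry the chemotype vs 19 of 1925 tested overall
  ids <- sprintf("c%04d", 1:1925)
  active <- ids[1:182]
  flags <- matrix(0L, 1925, 1, dimnames = list(ids, "triazine"))
  flags[c(1:11, 183:190), 1] <- 1L   # 11 active + 8 non-active carriers
  cm <- structure(list(ids = ids, flags = flags, source = "external_file"),
                  class = "chemotype_matrix")
  enr <- chemotype_enrichment(cm, active)
  expect_lt(enr$p_value[1], 0.001)
  expect_equal(enr$tier[1], "***")
  expect_equal(enr$count_active[1], 11)
  expect_equal(enr$count_background[1], 19)
  # agrees with the independent oracle on the same table
  oracle <- chisq2x2_oracle(11, 171, 8, 1735)
  expect_equal(enr$chi2[1], oracle$stat, tolerance = 1e-9)
})

test_that("flat and absent chemotypes are handled", {
  ids <- sprintf("c%02d", 1:40)
  flags <- cbind(equal = rep(c(1L, 0L), 20),
                 absent = rep(0L, 40),
                 everywhere = rep(1L, 40))
  rownames(flags) <- ids
  cm <- structure(list(ids = ids, flags = flags, source = "external_file"),
                  class = "chemotype_matrix")
  enr <- chemotype_enrichment(cm, ids[seq(1, 40, by = 2)])  # all carriers
  flat <- enr[enr$chemotype == "absent", ]
  expect_true(flat$untestable)
  expect_equal(flat$tier, "-")
  expect_true(enr[enr$chemotype == "everywhere", "untestable"])
  expect_error(chemotype_enrichment(cm, character(0)), "empty")
  expect_error(chemotype_enrichment(cm, "zz"), "subset")
})

test_that("tiers follow the p-value cutpoints", {
  expect_equal(steroqsar:::.p_tier(c(5e-4, 5e-3, 0.03, 0.2, NA)),
               c("***", "**", "*", "-", "-"))
})

test_that("co-occurrence network counts shared active chemicals", {
  ids <- sprintf("c%02d", 1:60)
  active <- ids[1:20]
  flags <- cbind(A = c(rep(1L, 18), rep(0L, 42)),
                 B = c(rep(1L, 15), rep(0L, 45)),
                 C = rep(c(1L, 0L), 30))
  rownames(flags) <- ids
  cm <- structure(list(ids = ids, flags = flags, source = "external_file"),
                  class = "chemotype_matrix")
  enr <- chemotype_enrichment(cm, active)
  g <- cooccurrence_network(cm, enr, active, p_cutoff = 0.01)
  expect_true(all(igraph::V(g)$name %in% c("A", "B")))
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    # edge weight = actives carrying both = 15; bounded by node counts
    expect_equal(w, 15)
    expect_lte(w, min(igraph::V(g)$count_active))
  }
  # no significant chemotypes -> empty graph
  enr0 <- enr
  enr0$p_value <- 0.9
  g0 <- cooccurrence_network(cm, enr0, active)
  expect_equal(igraph::vcount(g0), 0)
})

test_that("planted-motif libraries rank the motif first", {
  lib <- small_library()
  cm <- match_builtin_chemotypes(small_curated())
  act <- lib$labels$id[lib$labels$active == 1]
  enr <- chemotype_enrichment(cm, act)
  # the strong motif (triazine, OR = 8) tops the ranking; the primary-amine
  # chemotype follows as a structural implication of the aminotriazine
  # fragment, and the weaker phenol motif (OR = 4) is next at this n
  expect_equal(enr$chemotype[1], "ring_hetero_triazine")
  expect_lt(enr$p_value[1], 0.001)
  expect_true("bond_COH_phenol" %in% enr$chemotype[1:3])
  # mean chemotypes per chemical is reported by the print method
  expect_output(print(cm), "Mean chemotypes per chemical")
})
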