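test_that("generic scaffolds collapse substituted/heteroaromatic rings to carbocycles", {
  res <- generic_scaffold(c("Cc1ccccc1", "c1ccncc1", "CCO"))
  expect_equal(res[1], "C1CCCCC1")
  expect_equal(res[2], "C1CCCCC1")  # heteroatom converted to carbon
  expect_true(is.na(res[3]))        # acyclic -> no framework
})

test_that("scaffold transformation is idempotent and strips linkers' side chains", {
  smis <- c("CCOc1ccc(cc1)C(=O)Nc1ccccn1",   # two rings + amide linker
            "Cc1ccc2[nH]c(C)cc2c1",          # decorated indole
            "O=C(O)C1CCN(CC1)Cc1ccsc1")
  s1 <- generic_scaffold(smis)
  expect_false(anyNA(s1))
  s2 <- generic_scaffold(s1)
  expect_equal(s1, s2)
  # scaffolds contain only sp3 carbon: no heteroatoms, no bond-order marks
  expect_false(any(grepl("[nosNOS=#]", s1)))
})

test_that("invalid SMILES are rejected by the scaffold transform", {
  expect_error(generic_scaffold(c("CCO", "][")), "invalid SMILES")
})

test_that("tanimoto matches set arithmetic and its corner cases", {
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_error(tanimoto(c(0, 0), c(0, 0)), "undefined")
})

test_that("tanimoto is symmetric, identity-discriminating, and 1-T is metric-like", {
  set.seed(21)
  for (i in 1:25) {
    x <- rbinom(24, 1, 0.4); y <- rbinom(24, 1, 0.4); z <- rbinom(24, 1, 0.4)
    if (sum(x) == 0 || sum(y) == 0 || sum(z) == 0) next
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_equal(tanimoto(x, y) == 1, all(x == y))
    # Soergel distance 1-T satisfies the triangle inequality
    expect_lte(1 - tanimoto(x, z),
               (1 - tanimoto(x, y)) + (1 - tanimoto(y, z)) + 1e-12)
  }
})

test_that("nearest-neighbor similarities handle duplicates, pairs, and unknown ids", {
  fp <- structure(
    rbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 1L, 0L, 0L), c = c(0L, 0L, 1L, 1L)),
    class = c("structural_fp", "matrix", "array")
  )
  colnames(fp) <- paste0("bit", 1:4)
  nn <- nearest_neighbor_similarities(c("a", "b", "c"), fp)
  expect_equal(unname(nn[c("a", "b")]), c(1, 1))  # duplicated molecule
  expect_equal(unname(nn["c"]), 0)
  nn2 <- nearest_neighbor_similarities(c("a", "c"), fp)
  expect_equal(unname(nn2["a"]), unname(nn2["c"]))  # N=2 symmetry
  expect_error(nearest_neighbor_similarities("a", fp), "at least two")
  expect_error(nearest_neighbor_similarities(c("a", "zz"), fp), "zz")
})

test_that("a tight chemical series sits right of a diverse selection in NN similarity", {
  w <- small_world()
  fp <- build_structural_fp(w$compounds)
  same <- w$compounds$entries$compound_id[w$chemotype == 1][1:20]
  set.seed(8)
  diverse <- vapply(1:6, function(ct) {
    sample(w$compounds$entries$compound_id[w$chemotype == ct], 1)
  }, "")
  expect_gt(median(nearest_neighbor_similarities(same, fp)),
            median(nearest_neighbor_similarities(diverse, fp)))
})

test_that("Venn regions agree with brute-force membership on enumerated sets", {
  A <- c("s1", "s2"); B <- "s2"; C <- c("s2", "s3")
  reg <- bashfp:::venn_regions(A, B, C)
  expect_equal(unname(reg["c_only"]), 1)
  expect_equal(unname(reg["abc"]), 1)
  expect_equal(sum(reg), length(union(A, union(B, C))))

  set.seed(31)
  pool <- sprintf("sc%02d", 1:12)
  for (i in 1:20) {
    A <- sample(pool, sample(0:8, 1)); B <- sample(pool, sample(0:8, 1))
    C <- sample(pool, sample(0:8, 1))
    reg <- bashfp:::venn_regions(A, B, C)
    u <- union(A, union(B, C))
    expect_equal(sum(reg), length(u))
    brute <- table(factor(paste0(
      ifelse(u %in% A, "a", ""), ifelse(u %in% B, "b", ""),
      ifelse(u %in% C, "c", "")
    ), levels = c("a", "b", "c", "ab", "ac", "bc", "abc")))
    expect_equal(unname(reg[c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc")]),
                 as.numeric(brute))
  }
})

test_that("scaffold reports count unique frameworks per fold and average regions", {
  ids <- sprintf("CPD%05d", 1:6)
  tab <- compound_table(ids, c("Cc1ccccc1", "CCc1ccccc1",   # same framework
                               "c1ccc2ccccc2c1",            # naphthalene
                               "C1CCNCC1", "CCO", "CCCC"))  # acyclic excluded
  selections <- list(
    bash = list(ids[1:4], ids[1:3]),
    htsfp = list(ids[3:6], ids[4:5]),
    ecfp = list(ids[1:2], ids[1:2])
  )
  rep_s <- scaffold_sets(selections, tab)
  # fold 1: bash yields {C6 carbocycle, naphthalene framework} -- benzene and
  # piperidine collapse to the same generic scaffold; acyclics are dropped
  expect_equal(unname(rep_s$set_sizes[1, ]), c(2, 2, 1))
  expect_equal(unname(rep_s$set_sizes[2, ]), c(2, 1, 1))
  for (f in 1:2) {
    expect_equal(sum(rep_s$regions[f, ]),
                 length(Reduce(union, lapply(rep_s$per_fold_sets, `[[`, f))))
  }
  expect_equal(rep_s$region_means, colMeans(rep_s$regions))
  # identical sets -> everything in the triple region
  same <- list(m1 = list(ids[1:3]), m2 = list(ids[1:3]), m3 = list(ids[1:3]))
  rep2 <- scaffold_sets(same, tab)
  expect_equal(unname(rep2$regions[1, "abc"]), 2)
  expect_equal(sum(rep2$regions[1, ]), 2)
})

test_that("rank comparison partitions the hybrid top list into quadrants", {
  mk_cv <- function(scores, labels, ids) {
    structure(list(predictions = data.frame(
      compound_id = ids, fold = 1L, label = labels, probability = scores,
      rank = rank_predictions(scores, ids), stringsAsFactors = FALSE
    ), k = 1L, config = rf_config("custom")), class = "cv_result")
  }
  ids <- sprintf("c%02d", 1:10)
  labels <- rep(c(1L, 0L), 5)
  bash <- mk_cv(seq(1, 0.1, length.out = 10), labels, ids)
  ecfp <- mk_cv(c(0.9, 0.1, 0.8, 0.2, 0.7, 0.3, 0.6, 0.4, 0.5, 0.05), labels, ids)
  htsfp <- mk_cv(rev(seq(1, 0.1, length.out = 10)), labels, ids)
  rc <- rank_comparison(bash, ecfp, htsfp, top_n = 3)
  expect_equal(sum(rc$quadrants), 3)
  expect_equal(nrow(rc$table), 3)
  # c01: ecfp rank 1 (top), htsfp rank 10 (outside) -> ecfp_only
  row1 <- rc$table[rc$table$compound_id == "c01", ]
  expect_equal(row1$ecfp_rank, 1L)
  expect_gt(row1$htsfp_rank, 3)
  expect_gte(rc$quadrants[["ecfp_only"]], 1)
  # mismatched universes are rejected
  other <- mk_cv(runif(9), labels[1:9], ids[1:9])
  expect_error(rank_comparison(bash, other, htsfp), "different compound universes")
})
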