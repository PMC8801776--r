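# Neighbor-joining, multiple alignment distances and bootstrap support.

additive_matrix_abcd <- function() {
  # tree ((A:1,B:2):1,(C:3,D:4)) with internal edge 1
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  d
}

test_that("NJ recovers topology and branch lengths from additive input", {
  d <- additive_matrix_abcd()
  tr <- build_nj_tree(d)
  # the AB|CD split is present and path lengths reproduce the matrix
  expect_true(same_split_sets(phylo_splits(tr),
                              list(sort(c("C", "D")))))
  coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(unname(coph), unname(d), tolerance = 1e-8)
})

test_that("three taxa give the unique unrooted topology", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- build_nj_tree(d)
  expect_equal(sort(tr$tip.label), c("x", "y", "z"))
  coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(unname(coph), unname(d), tolerance = 1e-8)
})

test_that("NJ is invariant to input taxon ordering", {
  set.seed(51)
  ref_tree <- ape::rtree(6, br = function(n) runif(n, 0.5, 2))
  d <- ape::cophenetic.phylo(ref_tree)
  tr1 <- build_nj_tree(d)
  perm <- sample(rownames(d))
  tr2 <- build_nj_tree(d[perm, perm])
  expect_true(same_split_sets(phylo_splits(tr1), phylo_splits(tr2)))
  expect_equal(ape::dist.topo(tr1, tr2), structure(0, names = "PH85"),
               ignore_attr = TRUE)
})

test_that("NJ agrees with the reference NJ implementation", {
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    ref_tree <- ape::rtree(n, br = function(k) runif(k, 0.2, 2))
    d <- ape::cophenetic.phylo(ref_tree)
    # mild perturbation away from perfect additivity
    noise <- matrix(runif(n * n, -0.01, 0.01), n)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    dn <- d + noise
    tr <- build_nj_tree(dn)
    ref <- ape::nj(as.dist(dn))
    expect_equal(ape::dist.topo(tr, ref), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
  }
})

test_that("NJ equals brute-force minimum evolution on additive input", {
  set.seed(53)
  for (n in c(5, 6)) {
    ref_tree <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- ape::cophenetic.phylo(ref_tree)
    nj_splits <- phylo_splits(build_nj_tree(d))
    me_splits <- oracle_me_splits(d)
    # canonicalise oracle splits to the same leaf-1 convention
    expect_true(same_split_sets(nj_splits, me_splits))
  }
})

test_that("conflict-free informative columns give 100% support", {
  # 60 columns supporting AB|CD plus shared invariant columns
  colA <- strsplit(paste(rep("A", 60), collapse = ""), "")[[1]]
  colC <- strsplit(paste(rep("C", 60), collapse = ""), "")[[1]]
  inv <- strsplit(paste(rep("MKVLWG", 10), collapse = ""), "")[[1]]
  msa <- c(A = paste(c(colA, inv), collapse = ""),
           B = paste(c(colA, inv), collapse = ""),
           C = paste(c(colC, inv), collapse = ""),
           D = paste(c(colC, inv), collapse = ""))
  # perturb single taxa so that all four tips are distinct
  substr(msa[["B"]], 61, 61) <- "P"
  substr(msa[["D"]], 62, 62) <- "P"
  tr <- bootstrap_support(msa, replicates = 100, seed = 5)
  internal <- suppressWarnings(as.numeric(tr$node.label))
  internal <- internal[!is.na(internal)]
  expect_true(all(internal == 100))
})

test_that("bootstrap supports are deterministic for a fixed seed", {
  set.seed(54)
  res <- cached_pipeline()
  genome <- res$stages$genome
  ids <- names(genome$proteins)[1:8]
  msa <- align_msa(genome$proteins[ids])
  t1 <- bootstrap_support(msa, replicates = 50, seed = 9)
  t2 <- bootstrap_support(msa, replicates = 50, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("random noise columns leave the three resolutions unsettled", {
  set.seed(55)
  sims <- replicate(150, {
    mat <- matrix(sample(c("A", "C", "D", "E", "F"), 4 * 40, replace = TRUE),
                  nrow = 4, dimnames = list(c("a", "b", "c", "d"), NULL))
    msa <- setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
    tr <- suppressWarnings(bootstrap_support(msa, replicates = 20,
                                             seed = sample.int(1e6, 1)))
    s <- suppressWarnings(as.numeric(tr$node.label))
    split <- phylo_splits(tr)
    c(sup = mean(s[!is.na(s)]),
      res = paste(split[[1]], collapse = ""))
  })
  sup <- as.numeric(sims["sup", ])
  # with no phylogenetic signal each of the three resolutions is picked
  # about equally often ...
  freq <- table(factor(sims["res", ], levels = c("bc", "bd", "cd"))) / 150
  expect_true(all(freq > 0.15 & freq < 0.55))
  # ... and the winning split is supported far below the conflict-free
  # level of 100 (but at least as often as chance would give it)
  expect_gt(mean(sup, na.rm = TRUE), 100 / 3)
  expect_lt(mean(sup, na.rm = TRUE), 95)
})

test_that("msa distances equal pairwise-deletion mismatch correction", {
  msa <- c(x = "MKV-LA", y = "MKVWLA", z = "MQV-LC")
  d <- msa_distances(msa)
  # x vs z: 5 shared columns, 2 mismatches
  p <- 2 / 5
  expect_equal(d["x", "z"], -log(1 - p - 0.2 * p^2), tolerance = 1e-12)
  expect_equal(d["x", "y"], 0)
  expect_true(isSymmetric(d))
})
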