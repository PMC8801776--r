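# Duplicate-pair calling, tandem/segmental typing, segment assignment
# and pair location categories.

toy_identity <- function(ids, values) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  for (v in values) m[v[[1]], v[[2]]] <- m[v[[2]], v[[1]]] <- v[[3]]
  m
}

test_that("calling is inclusive at the threshold and exempts homeologs", {
  ids <- c("a1", "b1", "c1", "d1")
  m <- toy_identity(ids, list(
    list("a1", "b1", 95),    # same homeolog group, cross subgenome
    list("a1", "c1", 90.0),  # boundary pair
    list("a1", "d1", 89.9),
    list("c1", "d1", 30)))
  groups <- data.frame(gene_id = ids,
                       subfamily = "SEP",
                       subgenome = c("A", "B", "A", "A"),
                       group_id = c("HG001", "HG001", NA, NA),
                       support = 99, status = "balanced",
                       stringsAsFactors = FALSE)
  pairs <- call_duplicates(m, groups, threshold = 90)
  keys <- pair_key(pairs$gene_a, pairs$gene_b)
  expect_true(pair_key("a1", "c1") %in% keys)    # inclusive >= 90
  expect_false(pair_key("a1", "d1") %in% keys)   # 89.9 below
  expect_false(pair_key("a1", "b1") %in% keys)   # homeologous
  expect_true(pairs$boundary[keys == pair_key("a1", "c1")])
  expect_equal(attr(pairs, "n_genes"), 2)
})

test_that("same-subgenome pairs within a group are still callable", {
  ids <- c("a1", "a2", "b1")
  m <- toy_identity(ids, list(list("a1", "a2", 96), list("a1", "b1", 96),
                              list("a2", "b1", 93)))
  groups <- data.frame(gene_id = ids, subfamily = "SEP",
                       subgenome = c("A", "A", "B"),
                       group_id = "HG001", support = 99,
                       status = "balanced", stringsAsFactors = FALSE)
  pairs <- call_duplicates(m, groups)
  keys <- pair_key(pairs$gene_a, pairs$gene_b)
  expect_true(pair_key("a1", "a2") %in% keys)
  expect_false(pair_key("a1", "b1") %in% keys)
  expect_false(pair_key("a2", "b1") %in% keys)
})

test_that("raising the threshold never adds pairs", {
  res <- cached_pipeline()
  im <- identity_matrix(res$stages$genome$cds[1:20])
  groups <- res$stages$groups
  n_pairs <- vapply(c(85, 90, 95, 99), function(th) {
    nrow(call_duplicates(im, groups, threshold = th))
  }, numeric(1))
  expect_true(all(diff(n_pairs) <= 0))
})

test_that("duplication type follows chromosome placement", {
  ann <- make_annotation(c("x", "y", "z", "u"),
                         c("3B", "3B", "3D", "U"))
  expect_equal(classify_dup_type(list(gene_a = "x", gene_b = "y"), ann),
               "tandem")
  expect_equal(classify_dup_type(list(gene_a = "x", gene_b = "z"), ann),
               "segmental")
  expect_equal(classify_dup_type(list(gene_a = "x", gene_b = "u"), ann),
               "unplaced")
  # resolution via an inferred chromosome
  expect_equal(classify_dup_type(list(gene_a = "x", gene_b = "u"), ann,
                                 resolved = c(u = "3B")), "tandem")
})

test_that("unplaced chromosomes are inferred from unanimous partners", {
  ann <- make_annotation(c("u1", "p1", "p2", "p3", "q1"),
                         c("U", "3B", "3B", "3B", "3A"))
  pairs <- data.frame(gene_a = c("u1", "u1", "u1"),
                      gene_b = c("p1", "p2", "p3"),
                      stringsAsFactors = FALSE)
  res <- infer_unplaced_chromosome("u1", pairs, ann)
  expect_equal(res$chromosome, "3B")
  expect_true(res$inferred)
  # conflicting partners: no inference
  pairs2 <- rbind(pairs, data.frame(gene_a = "u1", gene_b = "q1"))
  expect_true(is.na(infer_unplaced_chromosome("u1", pairs2, ann)$chromosome))
  # no placed partners: no inference
  pairs3 <- data.frame(gene_a = "u1", gene_b = "u1")
  expect_true(is.na(infer_unplaced_chromosome("u1", pairs3, ann)$chromosome))
})

test_that("segment assignment uses the gene midpoint", {
  smap <- toy_segment_map("1A")
  ann <- make_annotation(c("early", "mid", "late"), rep("1A", 3),
                         start = c(2, 45, 90), end = c(8, 55, 99))
  expect_equal(assign_segment("early", ann, smap)$segment, "R1")
  expect_equal(assign_segment("early", ann, smap)$zone, "distal")
  expect_equal(assign_segment("mid", ann, smap)$segment, "C")
  expect_equal(assign_segment("mid", ann, smap)$zone, "central")
  expect_equal(assign_segment("late", ann, smap)$segment, "R3")
  # out-of-range midpoint errors
  bad <- make_annotation("far", "1A", start = 500, end = 600)
  expect_error(assign_segment("far", bad, smap), "outside")
})

test_that("pair location categories combine the two zones", {
  smap <- toy_segment_map("1A")
  ann <- make_annotation(c("r1", "r3", "c", "r2a"), rep("1A", 4),
                         start = c(2, 90, 45, 20), end = c(8, 99, 55, 30))
  cat_of <- function(a, b) {
    locate_pair_category(list(gene_a = a, gene_b = b), ann, smap)
  }
  expect_equal(cat_of("r1", "r3"), "distal_telomeric")
  expect_equal(cat_of("r1", "c"), "sub_telomeric")
  expect_equal(cat_of("r2a", "c"), "proximal")
})

test_that("planted duplicates are recovered with correct labels", {
  res <- cached_pipeline()
  truth <- res$stages$genome$truth
  pairs <- res$stages$duplicates
  called <- pair_key(pairs$gene_a, pairs$gene_b)
  planted <- pair_key(truth$duplicate_pairs$gene_a,
                      truth$duplicate_pairs$gene_b)
  expect_true(all(planted %in% called))
  m <- match(planted, called)
  expect_equal(pairs$dup_type[m], truth$duplicate_pairs$mode)
  # every called pair has exactly one type
  expect_true(all(pairs$dup_type %in% c("tandem", "segmental", "unplaced")))
  # planted tandem pairs share a chromosome, segmental pairs never do
  ann <- res$stages$genome$annotation
  chr <- setNames(ann$chromosome, ann$gene_id)
  same_chr <- chr[truth$duplicate_pairs$gene_a] ==
    chr[truth$duplicate_pairs$gene_b]
  expect_equal(unname(same_chr), truth$duplicate_pairs$mode == "tandem")
})

test_that("chromosome density table counts genes per Mbp", {
  ann <- make_annotation(c("a", "b", "c"), c("1A", "1A", "1B"))
  dens <- chromosome_density(ann, c(`1A` = 2e6, `1B` = 1e6))
  expect_equal(dens$n_genes, c(2, 1))
  expect_equal(dens$density, c(1, 1))
})
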