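# Homeolog group detection from supported clades and balance reporting.

toy_tree <- function(newick) ape::read.tree(text = newick)

toy_assignments <- function(ids, subfamily = "SEP") {
  data.frame(gene_id = ids, subfamily = rep_len(subfamily, length(ids)),
             stringsAsFactors = FALSE)
}

test_that("a supported single-subfamily clade forms a balanced group", {
  # root node first, then the (gA,gB,gD) clade with support 98
  tr <- toy_tree("((gA:1,gB:1,gD:1)98:1,(out1:1,out2:1)95:1)100;")
  ann <- make_annotation(c("gA", "gB", "gD", "out1", "out2"),
                         c("1A", "1B", "1D", "2A", "2B"))
  asn <- rbind(toy_assignments(c("gA", "gB", "gD"), "SEP"),
               toy_assignments(c("out1", "out2"), "SVP"))
  groups <- detect_homeolog_groups(tr, asn, ann, support_threshold = 90)
  g <- groups[groups$gene_id %in% c("gA", "gB", "gD"), ]
  expect_equal(unique(g$group_id), g$group_id[1])
  expect_false(any(is.na(g$group_id)))
  expect_true(all(g$status == "balanced"))
})

test_that("clades at or below the support threshold stay undetermined", {
  tr <- toy_tree("((gA:1,gB:1,gD:1)85:1,(out1:1,out2:1)95:1)100;")
  ann <- make_annotation(c("gA", "gB", "gD", "out1", "out2"),
                         c("1A", "1B", "1D", "2A", "2B"))
  asn <- rbind(toy_assignments(c("gA", "gB", "gD"), "SEP"),
               toy_assignments(c("out1", "out2"), "SVP"))
  groups <- detect_homeolog_groups(tr, asn, ann, support_threshold = 90)
  g <- groups[groups$gene_id %in% c("gA", "gB", "gD"), ]
  expect_true(all(g$status == "undetermined"))
  # strict inequality: support exactly 90 is not enough
  tr90 <- toy_tree("((gA:1,gB:1,gD:1)90:1,(out1:1,out2:1)95:1)100;")
  g90 <- detect_homeolog_groups(tr90, asn, ann, support_threshold = 90)
  expect_true(all(g90$status[g90$gene_id %in% c("gA", "gB", "gD")] ==
                    "undetermined"))
})

test_that("cross-subfamily clades never become groups", {
  tr <- toy_tree("((gA:1,gB:1,hD:1)99:1,(out1:1,out2:1)95:1)100;")
  ann <- make_annotation(c("gA", "gB", "hD", "out1", "out2"),
                         c("1A", "1B", "1D", "2A", "2B"))
  asn <- rbind(toy_assignments(c("gA", "gB"), "SEP"),
               toy_assignments("hD", "SOC1"),
               toy_assignments(c("out1", "out2"), "SVP"))
  groups <- detect_homeolog_groups(tr, asn, ann)
  expect_true(all(is.na(groups$group_id[groups$gene_id %in%
                                          c("gA", "gB")])) ||
                !any(groups$gene_id[!is.na(groups$group_id)] %in% "hD"))
  # gA+gB alone may group; hD must not join them
  gid_ab <- groups$group_id[groups$gene_id %in% c("gA", "gB")]
  gid_h <- groups$group_id[groups$gene_id == "hD"]
  expect_false(isTRUE(gid_h %in% gid_ab[!is.na(gid_ab)]))
})

test_that("balance classification follows the subgenome sets", {
  expect_equal(classify_balance(c("A", "B", "D")), "balanced")
  expect_equal(classify_balance(c("A", "B", "D", "A")), "balanced")
  expect_equal(classify_balance(c("A", "B")), "unbalanced")
  expect_equal(classify_balance("A"), "unbalanced")
  expect_equal(classify_balance(c("U", "U")), "undetermined")
})

test_that("raising the support threshold never resolves more genes", {
  res <- cached_pipeline()
  tr <- res$stages$trees[[1]]
  asn <- res$stages$assignments
  ann <- res$stages$genome$annotation
  thresholds <- c(50, 70, 90, 99)
  resolved <- vapply(thresholds, function(th) {
    g <- detect_homeolog_groups(tr, asn, ann, support_threshold = th)
    sum(g$status != "undetermined")
  }, numeric(1))
  expect_true(all(diff(resolved) <= 0))
})

test_that("balance report reproduces constructed subfamily rows", {
  # an Malpha-style configuration: 33 balanced members + 20 unbalanced
  groups <- data.frame(
    gene_id = sprintf("g%02d", 1:53),
    subfamily = "Malpha",
    subgenome = c(rep(c("A", "B", "D"), 11), rep(c("A", "B"), 10)),
    group_id = c(rep(sprintf("HG%03d", 1:11), each = 3),
                 rep(sprintf("HG%03d", 12:21), each = 2)),
    support = 99,
    status = c(rep("balanced", 33), rep("unbalanced", 20)),
    stringsAsFactors = FALSE)
  rep1 <- balance_report(groups)
  expect_equal(rep1$total, 53)
  expect_equal(rep1$balanced, 33)
  expect_equal(rep1$unbalanced, 20)
  expect_equal(rep1$duplications, "Absent")
  # duplications despite fully balanced homeologs get the exception flag
  groups2 <- groups[groups$status == "balanced", ]
  dups <- data.frame(gene_a = "g01", gene_b = "g04")
  rep2 <- balance_report(groups2, dups)
  expect_equal(rep2$duplications, "Present")
  expect_true(rep2$exception)
  # unbalanced subfamily with duplications: present, no exception
  rep3 <- balance_report(groups, dups)
  expect_equal(rep3$duplications, "Present")
  expect_false(rep3$exception)
})

test_that("planted triads and balance labels are fully recovered", {
  res <- cached_pipeline()
  truth <- res$stages$genome$truth
  groups <- res$stages$groups
  hom <- truth$genes[truth$genes$role == "homeolog", ]
  by_triad <- split(hom$gene_id, hom$triad_id)
  recovered <- vapply(by_triad, function(ids) {
    g <- groups$group_id[match(ids, groups$gene_id)]
    !any(is.na(g)) && length(unique(g)) == 1
  }, logical(1))
  expect_true(all(recovered))
  expected <- truth$triads$expected_status[match(hom$triad_id,
                                                 truth$triads$triad_id)]
  observed <- groups$status[match(hom$gene_id, groups$gene_id)]
  expect_equal(observed, expected)
})
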