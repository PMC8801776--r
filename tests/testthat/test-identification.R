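# Domain profile scanning, candidate bookkeeping, architecture and
# protein statistics.

test_that("profile consensus attains the maximal window score", {
  mp <- mads_profile()
  hit <- scan_domain(mp$consensus, mp)
  expect_true(hit$hit)
  expect_equal(hit$start, 1L)
  # the consensus is the argmax of its own PSSM column by column
  expect_equal(hit$score, sum(apply(mp$pssm, 2, max)))
  # embedded in flanking sequence the same window wins
  set.seed(41)
  flank <- paste(sample(rownames(mp$pssm), 25, replace = TRUE),
                 collapse = "")
  hit2 <- scan_domain(paste0(flank, mp$consensus, flank), mp)
  expect_equal(hit2$start, 26L)
  expect_equal(hit2$score, hit$score)
})

test_that("scan score equals brute-force maximum over all windows", {
  mp <- mads_profile()
  set.seed(42)
  prot <- paste(sample(rownames(mp$pssm), 150, replace = TRUE),
                collapse = "")
  res <- strsplit(prot, "")[[1]]
  brute <- max(vapply(seq_len(length(res) - mp$length + 1), function(w) {
    sum(mp$pssm[cbind(match(res[w:(w + mp$length - 1)],
                            rownames(mp$pssm)), seq_len(mp$length))])
  }, numeric(1)))
  expect_equal(scan_domain(prot, mp)$score, brute)
})

test_that("reversed consensus scores below the shuffled-null threshold", {
  mp <- mads_profile()
  rev_cons <- paste(rev(strsplit(mp$consensus, "")[[1]]), collapse = "")
  hit <- scan_domain(rev_cons, mp)
  expect_false(hit$hit)
  expect_lt(hit$score, mp$threshold)
})

test_that("proteins shorter than the profile yield a too-short no-hit", {
  mp <- mads_profile()
  hit <- scan_domain("MKVLAWTTTTPPPPGGGGSS", mp)
  expect_false(hit$hit)
  expect_equal(hit$reason, "too_short")
  expect_true(is.na(hit$score))
})

test_that("candidate merging keeps pooled totals and unions separate", {
  # disjoint lists sized like the published searches
  dom <- list(MADS = sprintf("m%03d", 1:281), KBOX = sprintf("k%03d", 1:131))
  kw <- sprintf("q%03d", 1:300)
  merged <- merge_candidates(dom, kw)
  expect_equal(merged$pooled_total, 712)
  expect_equal(merged$n_union, 712)
  # identical lists collapse in the union but not the pooled total
  same <- merge_candidates(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same$pooled_total, 4)
  expect_equal(same$n_union, 2)
  empty <- merge_candidates(list(character(0)), character(0))
  expect_equal(empty$pooled_total, 0)
})

test_that("redundancy filter keeps unique high-confidence genes", {
  ann <- make_annotation(sprintf("g%02d", 1:10), rep("1A", 10),
                         confidence = c(rep("high", 7), rep("low", 3)))
  res <- filter_nonredundant(sprintf("g%02d", 1:10), ann)
  expect_equal(length(res$retained), 7)
  # duplicate ids collapse to one record
  res2 <- filter_nonredundant(c("g01", "g01", "g02"), ann)
  expect_equal(res2$retained, c("g01", "g02"))
  # unknown candidates warn and are excluded
  expect_warning(res3 <- filter_nonredundant(c("g01", "nope"), ann),
                 "absent")
  expect_equal(res3$retained, "g01")
  expect_true("nope" %in% res3$excluded$gene_id)
})

test_that("architecture follows the two-domain truth table", {
  expect_equal(classify_architecture(TRUE, FALSE), "MADS_ONLY")
  expect_equal(classify_architecture(TRUE, TRUE), "MADS_K")
  expect_equal(classify_architecture(FALSE, TRUE), "K_ONLY")
  expect_equal(classify_architecture(FALSE, FALSE), "NONE")
})

test_that("architecture counts partition the synthetic gene set", {
  res <- cached_pipeline()
  report <- res$stages$identification
  truth <- res$stages$genome$truth$genes
  expect_equal(nrow(report), nrow(truth))
  expect_equal(sum(table(report$architecture)), nrow(report))
  # generated MIKC genes carry both domains, M-type genes only MADS
  arch <- setNames(report$architecture, report$gene_id)
  expect_true(all(arch[truth$gene_id[truth$superclade == "MIKC"]] ==
                    "MADS_K"))
  expect_true(all(arch[truth$gene_id[truth$superclade == "M"]] ==
                    "MADS_ONLY"))
})

test_that("molecular weight uses average masses plus one water", {
  st <- compute_protein_stats("G")
  expect_equal(st$mw_kda, (57.0519 + 18.0153) / 1000, tolerance = 1e-9)
  expect_equal(st$length, 1)
  # acidic sequence has acidic pI
  expect_lt(compute_protein_stats("DDDDD")$pi, 7)
  expect_gt(compute_protein_stats("KKKKK")$pi, 7)
  expect_warning(compute_protein_stats("GXG"), "unknown")
})

test_that("pI responds monotonically to charged residues", {
  base <- "MKVLAWTTGS"
  pi0 <- compute_protein_stats(base)$pi
  expect_gte(compute_protein_stats(paste0(base, "K"))$pi, pi0)
  expect_gte(compute_protein_stats(paste0(base, "R"))$pi, pi0)
  expect_lte(compute_protein_stats(paste0(base, "D"))$pi, pi0)
  expect_lte(compute_protein_stats(paste0(base, "E"))$pi, pi0)
})
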