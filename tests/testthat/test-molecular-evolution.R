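# Nei-Gojobori site/difference counting, Jukes-Cantor correction,
# dating and selection classification.

test_that("site fractions match direct single-mutant enumeration", {
  expect_equal(unname(ng_sites("TTT")["s"]), 1 / 3)
  expect_equal(unname(ng_sites("TTT")["n"]), 8 / 3)
  expect_equal(unname(ng_sites("ATG")["s"]), 0)
  # every codon of a 4-fold degenerate family has a fully synonymous
  # third position
  for (codon in c("GGG", "GGC", "GTA", "CTC", "CCG", "ACT", "GCA", "CGT")) {
    muts <- sapply(c("A", "C", "G", "T"), function(b) {
      v <- strsplit(codon, "")[[1]]
      v[3] <- b
      paste(v, collapse = "")
    })
    expect_true(unname(ng_sites(codon)["s"]) >= 1)
  }
  # random subset against the oracle (full sweep runs in the
  # acceptance suite)
  set.seed(11)
  for (codon in sample(SENSE, 25)) {
    expect_equal(unname(ng_sites(codon)), unname(oracle_ng_sites(codon)),
                 tolerance = 1e-12)
  }
})

test_that("pathway-averaged differences match exhaustive enumeration", {
  expect_equal(unname(ng_differences("GTT", "GTA")), c(1, 0))
  expect_equal(unname(ng_differences("TTT", "TTA")), c(0, 1))
  expect_equal(unname(ng_differences("AAA", "AAA")), c(0, 0))
  set.seed(12)
  for (k in 1:60) {
    pair <- sample(SENSE, 2)
    expect_equal(unname(ng_differences(pair[1], pair[2])),
                 unname(oracle_ng_diffs(pair[1], pair[2])),
                 tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction and omega follow the closed form", {
  # identical sequences
  aln <- list(a = c("ATG", "GCT", "TTT"), b = c("ATG", "GCT", "TTT"))
  est <- compute_kaks(aln)
  expect_equal(est$Ks, 0)
  expect_equal(est$Ka, 0)
  expect_true(is.na(est$omega))
  expect_equal(classify_selection(est), "undefined")
  # ps = 0.05 -> Ks = -(3/4) log(1 - 0.2/3)
  expect_equal(-(3 / 4) * log(1 - (4 / 3) * 0.05), 0.051745,
               tolerance = 1e-4)
  # engineered alignment: only synonymous third-position changes
  a <- rep("GGA", 20)
  b <- c(rep("GGC", 2), rep("GGA", 18))
  est2 <- compute_kaks(list(a = a, b = b))
  expect_equal(est2$Sd, 2)
  expect_equal(est2$Nd, 0)
  expect_equal(est2$Ks, -(3 / 4) * log(1 - (4 / 3) * (2 / est2$S)))
  expect_equal(est2$Ka, 0)
})

test_that("site counts conserve S + N = 3 x codons and are symmetric", {
  set.seed(13)
  for (rep in 1:10) {
    a <- sample(SENSE, 40, replace = TRUE)
    b <- sample(SENSE, 40, replace = TRUE)
    est <- compute_kaks(list(a = a, b = b))
    expect_equal(est$S + est$N, 3 * est$n_codons, tolerance = 1e-9)
    est_rev <- compute_kaks(list(a = b, b = a))
    expect_equal(est$Sd, est_rev$Sd)
    expect_equal(est$Nd, est_rev$Nd)
    expect_equal(est$Ks, est_rev$Ks)
  }
})

test_that("saturated proportions are flagged rather than corrected", {
  # force ps far beyond the JC-correctable range with third positions
  a <- rep("CGA", 40)
  b <- rep("CGC", 40)  # every codon one synonymous difference
  est <- compute_kaks(list(a = a, b = b))
  # ps = 40/S; S about 60 -> fine, now make it extreme by tiny S
  a2 <- c("ATG", "TGG")  # S = 0 for both codons
  expect_true(is.na(suppressWarnings(compute_kaks(list(a = a2, b = a2))$ps)) ||
                compute_kaks(list(a = a2, b = a2))$S == 0)
})

test_that("back-translation masks exactly the gapped codon columns", {
  cds_a <- "ATGGCTTTTGGA"      # M A F G
  cds_b <- "ATGTTTGGA"         # M F G
  aln <- align_global("MAFG", "MFG")
  ca <- backtranslate_and_mask(aln, cds_a, cds_b)
  expect_equal(length(ca$a), 3)
  expect_equal(ca$n_dropped, 1)
  expect_equal(ca$a, c("ATG", "TTT", "GGA"))
  expect_equal(ca$b, c("ATG", "TTT", "GGA"))
  # gapless pair retains everything
  aln2 <- list(a = "MAFG", b = "MAFG")
  ca2 <- backtranslate_and_mask(aln2, cds_a, cds_a)
  expect_equal(length(ca2$a), 4)
  expect_equal(ca2$n_dropped, 0)
  # random indel patterns: retained count equals a direct column scan
  set.seed(14)
  for (rep in 1:5) {
    n <- 12
    aa <- sample(SENSE, n, replace = TRUE)
    keep_a <- sort(sample(n, n - 2))
    keep_b <- sort(sample(n, n - 2))
    prot <- function(codons) {
      paste(GC_TABLE[codons], collapse = "")
    }
    pa <- prot(aa[keep_a])
    pb <- prot(aa[keep_b])
    al <- align_global(pa, pb)
    ca3 <- backtranslate_and_mask(al, paste(aa[keep_a], collapse = ""),
                                  paste(aa[keep_b], collapse = ""))
    ga <- strsplit(al$a, "")[[1]]
    gb <- strsplit(al$b, "")[[1]]
    expect_equal(length(ca3$a), sum(ga != "-" & gb != "-"))
  }
})

test_that("translation mismatch is reported with the offending codon", {
  aln <- list(a = "MA", b = "MA")
  expect_error(backtranslate_and_mask(aln, "ATGGCT", "ATGTTT"),
               "codon 2")
})

test_that("divergence dating follows T = Ks / 2r", {
  expect_equal(divergence_time(0.013, 6.5e-9), 1.0, tolerance = 1e-12)
  expect_identical(divergence_time(0), 0)
  expect_equal(divergence_time(0.13), 10.0)
  expect_equal(divergence_time(c(0.013, 0.026)), c(1, 2))
})

test_that("selection classes follow the omega rule", {
  expect_equal(classify_selection(1.2), "positive")
  expect_equal(classify_selection(0.2), "purifying")
  expect_equal(classify_selection(1), "neutral")
  expect_equal(classify_selection(NA_real_), "undefined")
})

test_that("superclade summary yields quartiles and selection fractions", {
  est <- data.frame(
    gene_a = c("m1", "m2", "m3", "k1", "k2"),
    gene_b = c("x", "x", "x", "x", "x"),
    Ks = c(0.02, 0.04, 0.06, 0.2, 0.4),
    omega = c(1.5, 0.5, 0.5, 0.3, 0.3),
    T_mya = c(1, 2, 3, 10, 20))
  sc <- c(m1 = "M", m2 = "M", m3 = "M", k1 = "MIKC", k2 = "MIKC")
  out <- summarize_by_superclade(est, sc)
  m <- out[out$superclade == "M", ]
  expect_equal(m$Ks_median, 0.04)
  expect_equal(m$positive_pct, 100 / 3)
  k <- out[out$superclade == "MIKC", ]
  expect_equal(k$positive_pct, 0)
  # identical estimates collapse the quartiles
  est2 <- est[c(1, 1, 1), ]
  out2 <- summarize_by_superclade(est2, sc)
  expect_equal(out2$Ks_q1, out2$Ks_q3)
})
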