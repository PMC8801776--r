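# Shared fixtures. The default synthetic pipeline run is expensive, so
# it is computed once per test session and reused.

.fixture_cache <- new.env(parent = emptyenv())

cached_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    cfg <- pipeline_config(mode = "synthetic", seed = 42)
    .fixture_cache$pipeline <- suppressWarnings(run_pipeline(cfg))
  }
  .fixture_cache$pipeline
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

split_codons_for_test <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# tiny annotation table builder
make_annotation <- function(gene_id, chromosome, start = 1000,
                            end = 2000, subgenome = NULL,
                            confidence = "high") {
  if (is.null(subgenome)) {
    subgenome <- ifelse(grepl("U", chromosome), "U",
                        substr(chromosome, nchar(chromosome),
                               nchar(chromosome)))
  }
  data.frame(gene_id = gene_id, chromosome = chromosome,
             subgenome = subgenome,
             start = rep_len(start, length(gene_id)),
             end = rep_len(end, length(gene_id)),
             strand = "+", confidence = rep_len(confidence, length(gene_id)),
             stringsAsFactors = FALSE)
}

# segment map for one chromosome of length 100 (units arbitrary):
# R1 1-15, R2a 16-40, C 41-60, R2b 61-85, R3 86-100
toy_segment_map <- function(chromosomes) {
  do.call(rbind, lapply(chromosomes, function(cc) {
    data.frame(chromosome = cc,
               segment = c("R1", "R2a", "C", "R2b", "R3"),
               start = c(1, 16, 41, 61, 86),
               end = c(15, 40, 60, 85, 100),
               stringsAsFactors = FALSE)
  }))
}

published_counts_report <- function() {
  # the published genome-wide counts for the wheat family, as a partial
  # report: 300 genes, 128 M + 172 MIKC, 16 subfamilies, architecture
  # 167/125/8, candidate searches 281 + 131 + 300 = 712
  subfam <- c(Malpha = 53, Mbeta = 28, Mgamma = 47,
              AP1 = 9, AP3 = 6, PI = 6, `AG/STK` = 12, SEP = 28,
              AGL6 = 3, AGL12 = 6, AGL17 = 31, Bsister = 19,
              MIKCstar = 27, OsMADS32 = 3, SOC1 = 13, SVP = 9)
  table1 <- data.frame(
    subfamily = names(subfam),
    total = unname(subfam),
    balanced = c(33, 10, 26, 9, 6, 6, 12, 25, 3, 6, 22, 10, 21, 3, 12, 9),
    unbalanced = c(20, 18, 21, 0, 0, 0, 0, 3, 0, 0, 9, 9, 6, 0, 1, 0),
    undetermined = 0)
  list(
    total_genes = 300,
    superclade_counts = c(M = 128, MIKC = 172),
    subfamily_counts = subfam,
    subfamily_superclade = setNames(superclade_of(names(subfam)),
                                    names(subfam)),
    architecture_counts = c(MADS_ONLY = 167, MADS_K = 125, K_ONLY = 8),
    candidates = list(source_sizes = c(MADS = 281, KBOX = 131,
                                       keyword = 300),
                      pooled_total = 712, n_union = 300),
    balance_table = table1)
}
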