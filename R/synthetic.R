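# Synthetic allohexaploid genome generator. Produces a toy A/B/D genome
# for the gene family - annotation, CDS, proteins, segment map - with
# complete ground truth (triad membership, balance labels, planted
# duplications, expression clusters) so that every downstream stage can
# be scored exactly.

#' Construct and validate a synthetic genome specification
#'
#' @param triads Data frame with `subfamily` and `subgenomes` (comma
#'   separated subset of `"A,B,D"`, e.g. `"A,B"` for a triad missing
#'   its D copy).
#' @param duplications Data frame with `subfamily`,
#'   `mode` (`"tandem"`/`"segmental"`), `target_ks`, `target_omega`
#'   (may have zero rows).
#' @param chromosome_lengths Named numeric vector of chromosome lengths
#'   in bp; names end in the subgenome letter (e.g. `"3A"`).
#' @param segment_fractions Four strictly increasing fractions in (0,1)
#'   placing the R1/R2a, R2a/C, C/R2b and R2b/R3 breakpoints on every
#'   chromosome.
#' @param master_seed Integer master seed; all downstream randomness
#'   derives from it.
#' @return Validated list of class `genome_spec`.
#' @export
genome_spec <- function(triads, duplications = NULL,
                        chromosome_lengths = NULL,
                        segment_fractions = c(0.15, 0.40, 0.60, 0.85),
                        master_seed = 1) {
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- setNames(
      rep(1e8, 21),
      paste0(rep(1:7, each = 3), c("A", "B", "D")))
  }
  if (length(chromosome_lengths) == 0L) {
    stop("configuration error: no chromosomes defined", call. = FALSE)
  }
  if (length(segment_fractions) != 4L ||
      any(diff(segment_fractions) <= 0) ||
      any(segment_fractions <= 0) || any(segment_fractions >= 1)) {
    stop("configuration error: segment breakpoints must be four strictly ",
         "increasing fractions within the chromosome", call. = FALSE)
  }
  stopifnot(is.data.frame(triads), nrow(triads) >= 1,
            all(c("subfamily", "subgenomes") %in% names(triads)))
  pats <- strsplit(triads$subgenomes, ",", fixed = TRUE)
  if (any(lengths(pats) == 0L) ||
      !all(unlist(pats) %in% c("A", "B", "D"))) {
    stop("configuration error: every triad pattern must be a non-empty ",
         "subset of A,B,D", call. = FALSE)
  }
  if (is.null(duplications)) {
    duplications <- data.frame(subfamily = character(0), mode = character(0),
                               target_ks = numeric(0),
                               target_omega = numeric(0))
  }
  if (nrow(duplications) > 0) {
    stopifnot(all(duplications$mode %in% c("tandem", "segmental")))
    if (any(duplications$target_ks < 0) || any(duplications$target_omega < 0)) {
      stop("configuration error: target_ks and target_omega must be >= 0",
           call. = FALSE)
    }
    if (!all(duplications$subfamily %in% triads$subfamily)) {
      stop("configuration error: duplication subfamily without any triad",
           call. = FALSE)
    }
  }
  unknown <- setdiff(unique(triads$subfamily), names(subfamily_superclades()))
  if (length(unknown) > 0) {
    stop("unknown subfamily: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- list(triads = triads, duplications = duplications,
              chromosome_lengths = chromosome_lengths,
              segment_fractions = segment_fractions,
              master_seed = master_seed)
  class(out) <- "genome_spec"
  out
}

#' Default synthetic genome specification
#'
#' Twenty triads spread over eight subfamilies with a mixture of
#' balanced and unbalanced subgenome patterns, plus ten tandem and ten
#' segmental planted duplications at Ks = 0.05, omega = 0.3 (mild
#' purifying selection, comfortably above the 90% identity calling
#' threshold).
#'
#' @param master_seed Integer master seed.
#' @return A `genome_spec`.
#' @export
default_genome_spec <- function(master_seed = 1) {
  triads <- data.frame(
    subfamily = c("Malpha", "Malpha", "Malpha", "Mbeta", "Mbeta",
                  "Mgamma", "Mgamma", "Mgamma", "AGL17", "AGL17", "AGL17",
                  "Bsister", "Bsister", "MIKCstar", "MIKCstar", "MIKCstar",
                  "SEP", "SEP", "SOC1", "SOC1"),
    subgenomes = c("A,B,D", "A,B,D", "A,B", "A,B,D", "A",
                   "A,B,D", "B,D", "A,B,D", "A,B,D", "A,B,D", "D",
                   "A,B,D", "A,B", "A,B,D", "A,B,D", "A,B,D",
                   "A,B,D", "B,D", "A,B,D", "A,B,D"),
    stringsAsFactors = FALSE)
  dup_sf <- c("Malpha", "Malpha", "Mbeta", "Mgamma", "AGL17", "AGL17",
              "Bsister", "MIKCstar", "SEP", "SOC1")
  duplications <- data.frame(
    subfamily = rep(dup_sf, 2),
    mode = rep(c("tandem", "segmental"), each = 10),
    target_ks = 0.05,
    target_omega = 0.3,
    stringsAsFactors = FALSE)
  genome_spec(triads = triads, duplications = duplications,
              master_seed = master_seed)
}

# Random protein segment (used for linkers/tails of reference proteins).
random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Substitute a fraction of residues of a protein at random positions.
perturb_protein <- function(protein, fraction) {
  res <- str_chars(protein)
  n_mut <- round(fraction * length(res))
  if (n_mut > 0) {
    pos <- sample(length(res), n_mut)
    res[pos] <- vapply(res[pos], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1)
    }, character(1))
  }
  paste(res, collapse = "")
}

# Back-translate a protein with uniformly random synonymous codons.
backtranslate <- function(protein) {
  gc <- genetic_code()
  by_aa <- split(names(gc), gc)
  codons <- vapply(str_chars(protein), function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Synthetic labelled reference exemplar set
#'
#' One exemplar protein (and a backing CDS) per subfamily, standing in
#' for curated Arabidopsis/rice subfamily exemplars. Each exemplar
#' carries the MADS domain (a lightly perturbed copy of the packaged
#' profile consensus); MIKC-type exemplars additionally carry a K-box
#' domain. Linkers and C-terminal tails are subfamily-specific, which
#' drives subfamily separation in alignments.
#'
#' @param seed RNG seed; the default yields the canonical packaged set.
#' @return Data frame: id, subfamily, superclade, protein, cds.
#' @export
reference_set <- function(seed = 20603) {
  map <- subfamily_superclades()
  mads_cons <- mads_profile()$consensus
  kbox_cons <- kbox_profile()$consensus
  with_seed(seed, {
    rows <- lapply(names(map), function(sf) {
      domain <- perturb_protein(mads_cons, 0.08)
      if (map[[sf]] == "MIKC") {
        protein <- paste0(domain, random_protein(25),
                          perturb_protein(kbox_cons, 0.08),
                          random_protein(40))
      } else {
        protein <- paste0(domain, random_protein(30))
      }
      data.frame(id = paste0("REF_", sf), subfamily = sf,
                 superclade = map[[sf]], protein = protein,
                 cds = backtranslate(protein), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Mutate a coding sequence towards target Ks and omega
#'
#' Introduces synonymous and nonsynonymous single-nucleotide codon
#' changes so that Nei-Gojobori estimates on (input, output) approach
#' the targets. Change counts are obtained by inverting the
#' Jukes-Cantor correction (`p = 3/4 (1 - exp(-4/3 K))`) and scaling by
#' the sequence's site counts; changes are drawn from precomputed
#' synonymous/nonsynonymous mutant sets, so no internal stop codon can
#' arise and the reading frame is preserved.
#'
#' @param cds Coding sequence (length divisible by 3, no internal
#'   stops).
#' @param target_ks Target synonymous substitution rate (>= 0).
#' @param target_omega Target Ka/Ks ratio (>= 0).
#' @param seed RNG seed.
#' @return Mutated coding sequence.
#' @export
mutate_cds <- function(cds, target_ks, target_omega, seed = 1) {
  stopifnot(target_ks >= 0, target_omega >= 0)
  codons <- split_codons(toupper(cds))
  gc <- genetic_code()
  aa <- gc[codons]
  if (any(aa[-length(aa)] == "*")) {
    stop("sequence error: internal stop codon", call. = FALSE)
  }
  if (target_ks == 0) return(cds)
  muts <- codon_mutants()
  sites <- codon_site_table()
  coding <- which(aa != "*")
  S <- sum(sites[codons[coding], "s"])
  N <- sum(sites[codons[coding], "n"])
  target_ka <- target_omega * target_ks
  ps <- 0.75 * (1 - exp(-4 / 3 * target_ks))
  pn <- 0.75 * (1 - exp(-4 / 3 * target_ka))
  with_seed(seed, {
    frac_round <- function(x) floor(x) + (runif(1) < (x - floor(x)))
    n_syn <- frac_round(ps * S)
    n_non <- frac_round(pn * N)
    pool_of <- function(codon, class) {
      unlist(lapply(muts[[codon]], `[[`, class), use.names = FALSE)
    }
    apply_changes <- function(codons, n, class, avoid = integer(0)) {
      changed <- integer(0)
      candidates <- coding[vapply(codons[coding], function(cc) {
        length(pool_of(cc, class)) > 0
      }, logical(1))]
      candidates <- setdiff(candidates, avoid)
      n <- min(n, length(candidates))
      if (n > 0) {
        changed <- sample(candidates, n)
        for (i in changed) {
          opts <- pool_of(codons[i], class)
          codons[i] <- opts[sample.int(length(opts), 1)]
        }
      }
      list(codons = codons, changed = changed)
    }
    syn <- apply_changes(codons, n_syn, "syn")
    non <- apply_changes(syn$codons, n_non, "nonsyn", avoid = syn$changed)
    paste(non$codons, collapse = "")
  })
}

# Build the per-chromosome segment map from lengths and fractions.
make_segment_map <- function(chromosome_lengths, segment_fractions) {
  segs <- c("R1", "R2a", "C", "R2b", "R3")
  rows <- lapply(names(chromosome_lengths), function(cc) {
    len <- chromosome_lengths[[cc]]
    bp <- floor(segment_fractions * len)
    if (any(diff(bp) <= 0) || bp[4] >= len) {
      stop("configuration error: breakpoints not strictly increasing ",
           "within chromosome ", cc, call. = FALSE)
    }
    starts <- c(1, bp + 1)
    ends <- c(bp, len)
    data.frame(chromosome = cc, segment = segs, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic allohexaploid genome with ground truth
#'
#' Builds subfamily ancestor CDS from the reference exemplars, derives
#' per-triad ancestors and subgenome copies by seeded codon mutation,
#' plants tandem (same chromosome) and segmental (different chromosome,
#' same subgenome) duplicates at the requested Ks/omega, and places
#' every gene at coordinates consistent with a declared chromosome
#' segment. Deterministic for a fixed `master_seed`.
#'
#' @param spec A `genome_spec`.
#' @return List of class `synthetic_genome` with `annotation` (gene_id,
#'   chromosome, subgenome, start, end, strand, confidence,
#'   description), `cds` and `proteins` (named character vectors),
#'   `segment_map`, `chromosome_lengths`, `refs` (reference exemplars)
#'   and `truth` (genes, triads, duplicate_pairs tables).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  seed <- spec$master_seed
  refs <- reference_set()
  segment_map <- make_segment_map(spec$chromosome_lengths,
                                  spec$segment_fractions)
  chroms <- names(spec$chromosome_lengths)
  groups_avail <- sort(unique(sub("[ABDU]$", "", chroms)))
  segs <- c("R1", "R2a", "C", "R2b", "R3")

  gene_rows <- list()
  cds_list <- list()
  truth_genes <- list()
  truth_pairs <- list()
  triad_rows <- list()
  counter <- 0L

  next_id <- function() {
    counter <<- counter + 1L
    sprintf("SYNG%04d", counter)
  }

  place_gene <- function(chromosome, len_bp, segment = NULL, after = NULL) {
    smap <- segment_map[segment_map$chromosome == chromosome, ]
    if (is.null(segment)) segment <- sample(segs, 1)
    srow <- smap[smap$segment == segment, ]
    if (!is.null(after)) {
      start <- after + 1000
      if (start + len_bp - 1 > srow$end) start <- srow$start + 500
    } else {
      start <- srow$start + floor(runif(1) * (srow$end - srow$start - len_bp))
    }
    list(segment = segment, start = start, end = start + len_bp - 1)
  }

  # subfamily ancestors derived from the reference exemplars
  sfs <- unique(spec$triads$subfamily)
  ancestors <- with_seed(derive_seed(seed, "ancestors"), {
    setNames(lapply(sfs, function(sf) {
      ref_cds <- refs$cds[refs$subfamily == sf]
      mutate_cds(ref_cds, target_ks = 0.15, target_omega = 0.5,
                 seed = derive_seed(seed, paste0("anc", sf)))
    }), sfs)
  })

  with_seed(derive_seed(seed, "genes"), {
    for (t in seq_len(nrow(spec$triads))) {
      sf <- spec$triads$subfamily[t]
      pattern <- strsplit(spec$triads$subgenomes[t], ",")[[1]]
      triad_id <- sprintf("TRI%03d", t)
      triad_anc <- mutate_cds(ancestors[[sf]], target_ks = 0.25,
                              target_omega = 0.5,
                              seed = derive_seed(seed, paste0("tri", t)))
      grp <- sample(groups_avail, 1)
      triad_rows[[t]] <- data.frame(
        triad_id = triad_id, subfamily = sf,
        pattern = spec$triads$subgenomes[t],
        expected_status = if (all(c("A", "B", "D") %in% pattern)) {
          "balanced"
        } else {
          "unbalanced"
        },
        stringsAsFactors = FALSE)
      for (sg in pattern) {
        gid <- next_id()
        cds <- mutate_cds(triad_anc, target_ks = 0.015, target_omega = 0.3,
                          seed = derive_seed(seed, paste0("mem", t, sg)))
        chromosome <- paste0(grp, sg)
        if (!chromosome %in% chroms) chromosome <- sample(chroms, 1)
        loc <- place_gene(chromosome, nchar(cds))
        cds_list[[gid]] <- cds
        gene_rows[[gid]] <- data.frame(
          gene_id = gid, chromosome = chromosome, subgenome = sg,
          start = loc$start, end = loc$end,
          strand = sample(c("+", "-"), 1), confidence = "high",
          description = "MADS-box transcription factor-like protein",
          stringsAsFactors = FALSE)
        truth_genes[[gid]] <- data.frame(
          gene_id = gid, subfamily = sf, superclade = superclade_of(sf),
          triad_id = triad_id, subgenome = sg, chromosome = chromosome,
          segment = loc$segment, role = "homeolog",
          source_gene = NA_character_, stringsAsFactors = FALSE)
      }
    }

    # planted duplications
    if (nrow(spec$duplications) > 0) {
      for (d in seq_len(nrow(spec$duplications))) {
        sf <- spec$duplications$subfamily[d]
        mode <- spec$duplications$mode[d]
        sf_genes <- names(truth_genes)[vapply(truth_genes, function(x) {
          x$subfamily == sf && x$role == "homeolog"
        }, logical(1))]
        src <- sf_genes[1 + (d - 1L) %% length(sf_genes)]
        src_row <- gene_rows[[src]]
        gid <- next_id()
        cds <- mutate_cds(cds_list[[src]],
                          target_ks = spec$duplications$target_ks[d],
                          target_omega = spec$duplications$target_omega[d],
                          seed = derive_seed(seed, paste0("dup", d)))
        if (mode == "tandem") {
          chromosome <- src_row$chromosome
          loc <- place_gene(chromosome, nchar(cds),
                            segment = truth_genes[[src]]$segment,
                            after = src_row$end)
        } else {
          sg <- src_row$subgenome
          cand <- setdiff(chroms[endsWith(chroms, sg)], src_row$chromosome)
          chromosome <- if (length(cand)) sample(cand, 1) else src_row$chromosome
          loc <- place_gene(chromosome, nchar(cds))
        }
        cds_list[[gid]] <- cds
        gene_rows[[gid]] <- data.frame(
          gene_id = gid, chromosome = chromosome,
          subgenome = src_row$subgenome,
          start = loc$start, end = loc$end,
          strand = sample(c("+", "-"), 1), confidence = "high",
          description = "MADS-box transcription factor-like protein",
          stringsAsFactors = FALSE)
        truth_genes[[gid]] <- data.frame(
          gene_id = gid, subfamily = sf,
          superclade = superclade_of(sf),
          triad_id = truth_genes[[src]]$triad_id,
          subgenome = src_row$subgenome, chromosome = chromosome,
          segment = loc$segment, role = "duplicate", source_gene = src,
          stringsAsFactors = FALSE)
        truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
          gene_a = src, gene_b = gid, mode = mode,
          target_ks = spec$duplications$target_ks[d],
          target_omega = spec$duplications$target_omega[d],
          stringsAsFactors = FALSE)
      }
    }
  })

  annotation <- do.call(rbind, unname(gene_rows))
  cds <- unlist(cds_list)
  proteins <- vapply(cds, translate_cds, character(1))
  names(proteins) <- names(cds)
  truth <- list(genes = do.call(rbind, unname(truth_genes)),
                triads = do.call(rbind, triad_rows),
                duplicate_pairs = if (length(truth_pairs)) {
                  do.call(rbind, truth_pairs)
                } else {
                  data.frame(gene_a = character(0), gene_b = character(0),
                             mode = character(0), target_ks = numeric(0),
                             target_omega = numeric(0))
                })
  out <- list(annotation = annotation, cds = cds, proteins = proteins,
              segment_map = segment_map,
              chromosome_lengths = spec$chromosome_lengths,
              refs = refs, truth = truth)
  class(out) <- "synthetic_genome"
  out
}

#' Generate a synthetic log2-TPM expression matrix with planted clusters
#'
#' Each cluster has its own per-condition mean profile with additive
#' Gaussian noise. A configurable fraction of genes is silent: their
#' values are all negative on the log2 scale, exercising the
#' "log2 TPM < 0 means not expressed" rule; when `fraction_silent > 0`
#' the last cluster is the silent one.
#'
#' @param gene_ids Character vector of gene ids (matrix rows).
#' @param k_true Number of planted clusters (>= 1, including the silent
#'   cluster when present).
#' @param n_conditions Number of conditions (columns), default 16
#'   mirroring the stress condition groups I-XVI.
#' @param noise_sd Additive noise standard deviation.
#' @param fraction_silent Fraction of genes in the all-negative silent
#'   cluster.
#' @param separation Spread of cluster mean profiles.
#' @param seed RNG seed.
#' @return List with `matrix` (genes x conditions) and `labels` (named
#'   integer ground-truth clusters).
#' @export
generate_expression <- function(gene_ids, k_true = 5, n_conditions = 16,
                                noise_sd = 0.5, fraction_silent = 0,
                                separation = 3, seed = 1) {
  n <- length(gene_ids)
  if (k_true < 1) stop("configuration error: k_true must be >= 1",
                       call. = FALSE)
  if (k_true > n) {
    stop("configuration error: k_true exceeds the number of genes",
         call. = FALSE)
  }
  stopifnot(fraction_silent >= 0, fraction_silent <= 1)
  with_seed(seed, {
    means <- matrix(runif(k_true * n_conditions, 0.5, 0.5 + 2 * separation),
                    nrow = k_true)
    n_silent <- round(fraction_silent * n)
    if (n_silent > 0) {
      means[k_true, ] <- runif(n_conditions, -3, -1.5)
    }
    labels <- if (n_silent > 0) {
      c(rep(k_true, n_silent),
        rep_len(seq_len(max(k_true - 1, 1)), n - n_silent))
    } else {
      rep_len(seq_len(k_true), n)
    }
    labels <- sample(labels)
    mat <- means[labels, , drop = FALSE] +
      matrix(rnorm(n * n_conditions, sd = noise_sd), nrow = n)
    if (n_silent > 0) {
      silent <- labels == k_true
      mat[silent, ] <- pmin(mat[silent, ], -0.01)
    }
    dimnames(mat) <- list(gene_ids, sprintf("cond%02d", seq_len(n_conditions)))
    list(matrix = mat, labels = setNames(labels, gene_ids))
  })
}
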