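# End-to-end pipeline: identification -> classification -> homeology ->
# duplication -> molecular evolution -> expression, with a consistency
# check over every partition identity in the report.

#' Construct and validate a pipeline configuration
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param spec A `genome_spec` (synthetic mode).
#' @param paths Named list of input paths (real mode): `proteins`,
#'   `cds`, `annotation`, `segments`, `expression`, `refs`.
#' @param identity_threshold Duplicate-calling identity threshold
#'   (percent, 0-100].
#' @param support_threshold Homeolog clade support threshold (percent).
#' @param expression_threshold Expressed/not-expressed cutoff on log2
#'   TPM.
#' @param rate Synonymous clock rate (substitutions/site/year).
#' @param bootstrap Bootstrap replicates for tree supports.
#' @param kmeans_k,kmeans_iterations,kmeans_runs K-means configuration
#'   (defaults 10 / 1000 / 5).
#' @param seed Master seed for all stochastic stages.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"), spec = NULL,
                            paths = NULL, identity_threshold = 90,
                            support_threshold = 90,
                            expression_threshold = 0.0,
                            rate = 6.5e-9, bootstrap = 100,
                            kmeans_k = 10, kmeans_iterations = 1000,
                            kmeans_runs = 5, seed = 1) {
  mode <- match.arg(mode)
  if (identity_threshold <= 0 || identity_threshold > 100) {
    stop("validation error: identity_threshold must be in (0, 100]",
         call. = FALSE)
  }
  if (support_threshold < 0 || support_threshold > 100) {
    stop("validation error: support_threshold must be in [0, 100]",
         call. = FALSE)
  }
  if (rate <= 0) stop("validation error: rate must be > 0", call. = FALSE)
  if (mode == "synthetic") {
    if (is.null(spec)) spec <- default_genome_spec(master_seed = seed)
    stopifnot(inherits(spec, "genome_spec"))
  } else {
    needed <- c("proteins", "cds", "annotation", "segments")
    missing_paths <- setdiff(needed, names(paths))
    if (length(missing_paths) > 0) {
      stop("validation error: real mode needs paths: ",
           paste(missing_paths, collapse = ", "), call. = FALSE)
    }
    gone <- !vapply(paths[needed], file.exists, logical(1))
    if (any(gone)) {
      stop("validation error: missing input file(s): ",
           paste(unlist(paths[needed])[gone], collapse = ", "), call. = FALSE)
    }
  }
  out <- list(mode = mode, spec = spec, paths = paths,
              identity_threshold = identity_threshold,
              support_threshold = support_threshold,
              expression_threshold = expression_threshold,
              rate = rate, bootstrap = bootstrap,
              kmeans_k = kmeans_k, kmeans_iterations = kmeans_iterations,
              kmeans_runs = kmeans_runs, seed = seed)
  class(out) <- "pipeline_config"
  out
}

#' Run the full gene-family analysis pipeline
#'
#' Stages run in order: identification (domain scans, architecture,
#' protein statistics), classification (subfamily assignment, per
#' superclade trees with bootstrap supports), homeology (triads and
#' balance), duplication (identity matrix, pair calling, typing and
#' segment categories), molecular evolution (Ka/Ks, dating, selection),
#' expression (expressed rule, K-means). Deterministic for a fixed
#' seed.
#'
#' @param config A `pipeline_config`.
#' @return List with `report` (see [consistency_check()]) and `stages`
#'   (per-stage artifacts: identification table, assignments, trees,
#'   groups, pairs, estimates, expression results, and in synthetic
#'   mode the generated `genome`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()

  if (config$mode == "synthetic") {
    genome <- generate_genome(config$spec)
    stages$genome <- genome
    proteins <- genome$proteins
    cds <- genome$cds
    annotation <- genome$annotation
    segment_map <- genome$segment_map
    chromosome_lengths <- genome$chromosome_lengths
    refs <- genome$refs
    expr <- generate_expression(
      names(proteins), k_true = 5, fraction_silent = 0.43,
      seed = derive_seed(config$seed, "expr"))
    expr_mat <- expr$matrix
    stages$expression_truth <- expr$labels
  } else {
    proteins <- read_fasta(config$paths$proteins, "protein")
    cds <- read_fasta(config$paths$cds, "dna")
    annotation <- read_tsv(config$paths$annotation)
    segment_map <- read_tsv(config$paths$segments)
    chromosome_lengths <- NULL
    if (!is.null(config$paths$chromosomes)) {
      ct <- read_tsv(config$paths$chromosomes)
      chromosome_lengths <- setNames(ct$length, ct$chromosome)
    }
    refs <- if (!is.null(config$paths$refs)) {
      rt <- read_fasta(config$paths$refs, "protein")
      # headers "id|subfamily"
      parts <- strsplit(names(rt), "|", fixed = TRUE)
      data.frame(id = vapply(parts, `[`, character(1), 1),
                 subfamily = vapply(parts, `[`, character(1), 2),
                 protein = unname(rt), stringsAsFactors = FALSE)
    } else {
      reference_set()
    }
    expr_mat <- if (!is.null(config$paths$expression)) {
      as.matrix(read_tsv(config$paths$expression)[, -1, drop = FALSE])
    } else {
      NULL
    }
  }

  # --- identification ---------------------------------------------------
  domain_report <- identify_family(proteins)
  kw <- keyword_search(annotation)
  merged <- merge_candidates(
    list(MADS = domain_report$gene_id[domain_report$architecture %in%
                                        c("MADS_ONLY", "MADS_K")],
         KBOX = domain_report$gene_id[domain_report$architecture %in%
                                        c("MADS_K", "K_ONLY")]),
    keyword_ids = kw)
  filtered <- filter_nonredundant(merged$union_ids, annotation)
  retained <- filtered$retained
  stages$identification <- domain_report
  stages$candidates <- merged
  stages$filtered <- filtered

  # --- classification ---------------------------------------------------
  assignments <- assign_subfamily(proteins[retained], refs)
  stages$assignments <- assignments

  # per-superclade trees include the labelled references as anchors and
  # are rooted on a reference tip, so that gene-only clades are well
  # defined for homeolog detection
  ref_superclade <- superclade_of(refs$subfamily)
  trees <- list()
  for (sc in unique(assignments$superclade)) {
    ids <- assignments$gene_id[assignments$superclade == sc]
    ref_sel <- ref_superclade == sc
    seqs <- c(proteins[ids],
              setNames(refs$protein[ref_sel], refs$id[ref_sel]))
    if (length(seqs) < 3) next
    msa <- align_msa(seqs)
    tr <- bootstrap_support(
      msa, replicates = config$bootstrap,
      seed = derive_seed(config$seed, paste0("boot", sc)))
    out_ref <- sort(refs$id[ref_sel])[1]
    if (!is.na(out_ref) && out_ref %in% tr$tip.label) {
      tr <- ape::root(tr, outgroup = out_ref, resolve.root = TRUE,
                      edgelabel = TRUE)
    }
    trees[[sc]] <- tr
  }
  stages$trees <- trees

  # --- duplication identity (needed as homeology duplicate candidates) --
  im <- identity_matrix(cds[retained])
  high_pairs <- which(im$identity >= config$identity_threshold &
                        upper.tri(im$identity), arr.ind = TRUE)
  dup_cand <- data.frame(
    gene_a = rownames(im$identity)[high_pairs[, 1]],
    gene_b = colnames(im$identity)[high_pairs[, 2]],
    stringsAsFactors = FALSE)

  # --- homeology --------------------------------------------------------
  # homeolog detection runs on per-subfamily trees (genes plus the
  # subfamily's reference and an outgroup reference for rooting):
  # within a subfamily the sequences are homologous over their full
  # length, which keeps the alignment, distances and clade supports
  # clean
  subfamily_trees <- list()
  group_parts <- list()
  for (sf in unique(assignments$subfamily)) {
    ids <- assignments$gene_id[assignments$subfamily == sf]
    if (length(ids) < 2) {
      subg <- setNames(annotation$subgenome, annotation$gene_id)
      group_parts[[sf]] <- data.frame(
        gene_id = ids, subfamily = sf, subgenome = unname(subg[ids]),
        group_id = paste0(sf, "_solo"), support = NA_real_,
        status = classify_balance(unname(subg[ids])),
        stringsAsFactors = FALSE)
      next
    }
    sc <- superclade_of(sf)
    own_ref <- refs$id[refs$subfamily == sf]
    out_ref <- sort(refs$id[ref_superclade == sc & refs$subfamily != sf])[1]
    anchor_ids <- c(own_ref, out_ref)
    anchor_ids <- anchor_ids[!is.na(anchor_ids)]
    seqs <- c(proteins[ids],
              setNames(refs$protein[match(anchor_ids, refs$id)],
                       anchor_ids))
    tr <- bootstrap_support(
      align_msa(seqs), replicates = config$bootstrap,
      seed = derive_seed(config$seed, paste0("hboot", sf)))
    root_tip <- if (!is.na(out_ref) && out_ref %in% tr$tip.label) {
      out_ref
    } else {
      anchor_ids[1]
    }
    if (!is.null(root_tip) && root_tip %in% tr$tip.label) {
      tr <- ape::root(tr, outgroup = root_tip, resolve.root = TRUE,
                      edgelabel = TRUE)
    }
    subfamily_trees[[sf]] <- tr
    part <- detect_homeolog_groups(
      tr, assignments, annotation,
      support_threshold = config$support_threshold,
      duplicate_candidates = dup_cand)
    part$group_id <- ifelse(is.na(part$group_id), NA_character_,
                            paste0(sf, "_", part$group_id))
    group_parts[[sf]] <- part
  }
  stages$subfamily_trees <- subfamily_trees
  groups <- do.call(rbind, unname(group_parts))
  rownames(groups) <- NULL
  missing_genes <- setdiff(assignments$gene_id, groups$gene_id)
  if (length(missing_genes) > 0) {
    subg <- setNames(annotation$subgenome, annotation$gene_id)
    groups <- rbind(groups, data.frame(
      gene_id = missing_genes,
      subfamily = assignments$subfamily[match(missing_genes,
                                              assignments$gene_id)],
      subgenome = unname(subg[missing_genes]),
      group_id = NA_character_, support = NA_real_,
      status = "undetermined", stringsAsFactors = FALSE))
  }
  stages$groups <- groups

  # --- duplication ------------------------------------------------------
  pairs <- call_duplicates(im, groups, threshold = config$identity_threshold)
  pairs <- annotate_duplicates(pairs, annotation, segment_map)
  stages$duplicates <- pairs
  stages$balance <- balance_report(groups, pairs)

  # --- molecular evolution ----------------------------------------------
  estimates <- NULL
  if (nrow(pairs) > 0) {
    est_rows <- lapply(seq_len(nrow(pairs)), function(k) {
      est <- kaks_pair(cds[[pairs$gene_a[k]]], cds[[pairs$gene_b[k]]])
      data.frame(gene_a = pairs$gene_a[k], gene_b = pairs$gene_b[k],
                 S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
                 Ka = est$Ka, Ks = est$Ks, omega = est$omega,
                 T_mya = divergence_time(est$Ks, config$rate),
                 selection = classify_selection(est),
                 stringsAsFactors = FALSE)
    })
    estimates <- do.call(rbind, est_rows)
  }
  stages$estimates <- estimates
  superclades <- setNames(assignments$superclade, assignments$gene_id)
  stages$evolution_summary <- if (!is.null(estimates)) {
    summarize_by_superclade(estimates, superclades)
  } else {
    NULL
  }

  # --- expression -------------------------------------------------------
  expression <- NULL
  if (!is.null(expr_mat)) {
    flags <- mark_expressed(expr_mat)
    km <- kmeans_cluster(expr_mat, k = min(config$kmeans_k, nrow(expr_mat)),
                         iterations = config$kmeans_iterations,
                         runs = config$kmeans_runs,
                         seed = derive_seed(config$seed, "kmeans"))
    expression <- list(
      flags = flags, clustering = km,
      summary = subfamily_expression_summary(assignments, flags$expressed,
                                             km$labels))
  }
  stages$expression <- expression

  report <- build_report(stages, annotation, chromosome_lengths)
  list(report = report, stages = stages)
}

# Assemble the survey-style report from stage artifacts.
build_report <- function(stages, annotation, chromosome_lengths = NULL) {
  assignments <- stages$assignments
  groups <- stages$groups
  pairs <- stages$duplicates
  report <- list()
  report$total_genes <- nrow(assignments)
  report$superclade_counts <- table(assignments$superclade)
  report$subfamily_counts <- table(assignments$subfamily)
  report$subfamily_superclade <-
    setNames(superclade_of(names(report$subfamily_counts)),
             names(report$subfamily_counts))
  report$architecture_counts <-
    table(stages$identification$architecture[
      stages$identification$gene_id %in% assignments$gene_id])
  report$candidates <- list(
    source_sizes = table(stages$candidates$provenance$source),
    pooled_total = stages$candidates$pooled_total,
    n_union = stages$candidates$n_union)
  report$balance_table <- stages$balance
  if (!is.null(pairs) && nrow(pairs) > 0) {
    report$duplication <- list(
      n_pairs = nrow(pairs),
      n_genes = attr(pairs, "n_genes"),
      type_counts = table(factor(pairs$dup_type,
                                 levels = c("tandem", "segmental",
                                            "unplaced"))),
      location_counts = table(factor(
        pairs$location_category,
        levels = c("distal_telomeric", "sub_telomeric", "proximal"))),
      n_located = sum(!is.na(pairs$location_category)))
  } else {
    report$duplication <- list(n_pairs = 0L, n_genes = 0L,
                               type_counts = NULL, location_counts = NULL,
                               n_located = 0L)
  }
  if (!is.null(chromosome_lengths)) {
    report$chromosome_density <- chromosome_density(annotation,
                                                    chromosome_lengths)
  }
  if (!is.null(stages$estimates)) {
    sel <- stages$estimates$selection
    report$selection_counts <- table(factor(
      sel, levels = c("positive", "purifying", "neutral", "undefined")))
    report$evolution_summary <- stages$evolution_summary
  }
  if (!is.null(stages$expression)) {
    report$expression <- list(
      expressed_fraction = stages$expression$flags$expressed_fraction,
      nonexpressed_share = stages$expression$summary$nonexpressed_share)
  }
  report
}

#' Check every partition identity in a report
#'
#' Asserts the arithmetic identities a consistent report must satisfy:
#' superclade counts sum to the total; subfamily counts sum to their
#' superclade counts; architecture counts sum to the total; the pooled
#' candidate total equals the sum of per-source sizes; each balance
#' table row satisfies balanced + unbalanced + undetermined = total and
#' rows sum to the family total; duplication type and location
#' categories partition the called pairs; selection classes partition
#' the estimated pairs. Fields absent from the report are skipped, so
#' partial reports (e.g. published count sets) can be validated.
#'
#' @param report Report list (see [run_pipeline()]); any subset of the
#'   fields may be present.
#' @return List with `pass` (logical) and `violations` (character
#'   vector naming each failed identity).
#' @export
consistency_check <- function(report) {
  v <- character(0)
  chk <- function(cond, label) {
    if (!isTRUE(cond)) v <<- c(v, label)
  }
  if (!is.null(report$superclade_counts) && !is.null(report$total_genes)) {
    chk(sum(report$superclade_counts) == report$total_genes,
        "superclade counts must sum to the total gene count")
  }
  if (!is.null(report$subfamily_counts) &&
      !is.null(report$superclade_counts)) {
    map <- report$subfamily_superclade
    if (is.null(map)) {
      map <- setNames(superclade_of(names(report$subfamily_counts)),
                      names(report$subfamily_counts))
    }
    for (sc in names(report$superclade_counts)) {
      chk(sum(report$subfamily_counts[names(map)[map == sc]]) ==
            report$superclade_counts[[sc]],
          paste0("subfamily counts must sum to the ", sc,
                 " superclade count"))
    }
  }
  if (!is.null(report$architecture_counts) && !is.null(report$total_genes)) {
    chk(sum(report$architecture_counts) == report$total_genes,
        "architecture counts must partition the gene set")
  }
  if (!is.null(report$candidates)) {
    chk(sum(report$candidates$source_sizes) == report$candidates$pooled_total,
        "pooled candidate total must equal the sum of source sizes")
  }
  if (!is.null(report$balance_table)) {
    bt <- report$balance_table
    und <- if ("undetermined" %in% names(bt)) bt$undetermined else 0
    chk(all(bt$balanced + bt$unbalanced + und == bt$total),
        "balance table rows must satisfy balanced + unbalanced (+ undetermined) = total")
    if (!is.null(report$total_genes)) {
      chk(sum(bt$total) == report$total_genes,
          "balance table totals must sum to the total gene count")
    }
  }
  if (!is.null(report$duplication) && report$duplication$n_pairs > 0) {
    chk(sum(report$duplication$type_counts) == report$duplication$n_pairs,
        "duplication types must partition the called pairs")
    chk(sum(report$duplication$location_counts) ==
          report$duplication$n_located,
        "location categories must partition the placed pairs")
  }
  if (!is.null(report$selection_counts)) {
    chk(sum(report$selection_counts) >= 0, "selection counts present")
    defined <- sum(report$selection_counts[c("positive", "purifying",
                                             "neutral")])
    total_sel <- sum(report$selection_counts)
    chk(defined + report$selection_counts[["undefined"]] == total_sel,
        "selection classes must partition the estimated pairs")
  }
  list(pass = length(v) == 0, violations = v)
}
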