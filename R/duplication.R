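# Duplicate-pair calling from CDS identity, tandem/segmental typing,
# chromosome-segment assignment (R1/R2a/C/R2b/R3) and pair location
# categories.

#' Call duplicated gene pairs from an identity matrix
#'
#' All unordered, informative pairs with identity at or above the
#' threshold (inclusive, boundary pairs flagged) and non-homeologous
#' status are called. A pair is homeologous when both genes belong to
#' the same homeolog group and lie on different subgenomes.
#'
#' @param im Result of [identity_matrix()] (or a plain identity matrix).
#' @param groups Output of [detect_homeolog_groups()] (may be `NULL`:
#'   no homeology exemption).
#' @param threshold Percent identity threshold (default 90, inclusive).
#' @return Data frame: gene_a, gene_b, identity, coverage, homeologous,
#'   boundary (identity within 0.5 points of the threshold), plus
#'   attribute-free helper column `called` always `TRUE`. An attribute
#'   `n_genes` gives the non-redundant count of genes in at least one
#'   pair.
#' @export
call_duplicates <- function(im, groups = NULL, threshold = 90) {
  idm <- if (is.list(im)) im$identity else im
  inf <- if (is.list(im) && !is.null(im$informative)) im$informative else
    matrix(TRUE, nrow(idm), ncol(idm))
  cov <- if (is.list(im) && !is.null(im$coverage)) im$coverage else
    matrix(NA_real_, nrow(idm), ncol(idm))
  ids <- rownames(idm)
  group_of <- subg_of <- NULL
  if (!is.null(groups)) {
    group_of <- setNames(groups$group_id, groups$gene_id)
    subg_of <- setNames(groups$subgenome, groups$gene_id)
  }
  rows <- list()
  n <- length(ids)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      if (idm[i, j] < threshold || !inf[i, j]) next
      a <- ids[i]
      b <- ids[j]
      homeo <- FALSE
      if (!is.null(group_of)) {
        ga <- if (a %in% names(group_of)) group_of[[a]] else NA_character_
        gb <- if (b %in% names(group_of)) group_of[[b]] else NA_character_
        if (!is.na(ga) && !is.na(gb) && ga == gb &&
            subg_of[[a]] != subg_of[[b]]) {
          homeo <- TRUE
        }
      }
      if (homeo) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b,
        identity = idm[i, j], coverage = cov[i, j],
        homeologous = FALSE,
        boundary = abs(idm[i, j] - threshold) <= 0.5,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               identity = numeric(0), coverage = numeric(0),
               homeologous = logical(0), boundary = logical(0))
  attr(out, "n_genes") <- length(unique(c(out$gene_a, out$gene_b)))
  out
}

#' Classify a duplicate pair as tandem, segmental or unplaced
#'
#' Same chromosome: tandem. Different placed chromosomes: segmental.
#' Either gene on an unplaced (U) chromosome: unplaced, unless
#' `resolved` supplies an inferred chromosome for it.
#'
#' @param pair List or one-row data frame with `gene_a`, `gene_b`.
#' @param annotation Data frame with `gene_id` and `chromosome`
#'   (`"U"`-prefixed names are unplaced).
#' @param resolved Optional named vector of inferred chromosomes for
#'   unplaced genes (see [infer_unplaced_chromosome()]).
#' @return `"tandem"`, `"segmental"` or `"unplaced"`.
#' @export
classify_dup_type <- function(pair, annotation, resolved = NULL) {
  chr <- setNames(annotation$chromosome, annotation$gene_id)
  ca <- unname(chr[[pair$gene_a]])
  cb <- unname(chr[[pair$gene_b]])
  lookup <- function(g, cc) {
    if (is_unplaced(cc) && !is.null(resolved) && g %in% names(resolved) &&
        !is.na(resolved[[g]])) resolved[[g]] else cc
  }
  ca <- lookup(pair$gene_a, ca)
  cb <- lookup(pair$gene_b, cb)
  if (is_unplaced(ca) || is_unplaced(cb)) return("unplaced")
  if (ca == cb) "tandem" else "segmental"
}

is_unplaced <- function(chromosome) {
  is.na(chromosome) | chromosome == "U" | grepl("^chrU", chromosome)
}

#' Infer the chromosome of an unplaced gene from its duplicate partners
#'
#' If all placed partners of an unplaced gene lie on a single
#' chromosome, that chromosome is returned (flagged as inferred);
#' otherwise `NA`.
#'
#' @param gene Unplaced gene id.
#' @param pairs Called duplicate pairs ([call_duplicates()] output).
#' @param annotation Data frame with `gene_id` and `chromosome`.
#' @return Named list with `chromosome` (or `NA`) and `inferred`.
#' @export
infer_unplaced_chromosome <- function(gene, pairs, annotation) {
  chr <- setNames(annotation$chromosome, annotation$gene_id)
  partners <- c(pairs$gene_b[pairs$gene_a == gene],
                pairs$gene_a[pairs$gene_b == gene])
  placed <- partners[!is_unplaced(chr[partners])]
  if (length(placed) == 0L) {
    return(list(chromosome = NA_character_, inferred = FALSE))
  }
  chrs <- unique(unname(chr[placed]))
  if (length(chrs) == 1L) {
    list(chromosome = chrs, inferred = TRUE)
  } else {
    list(chromosome = NA_character_, inferred = FALSE)
  }
}

#' Assign a gene to a chromosome segment and zone
#'
#' The five segments R1, R2a, C, R2b, R3 partition each placed
#' chromosome (IWGSC-style); R1/R3 are distal telomeric, R2a/C/R2b
#' central. The gene is assigned by its midpoint.
#'
#' @param gene Gene id.
#' @param annotation Data frame with `gene_id`, `chromosome`, `start`,
#'   `end`.
#' @param segment_map Data frame with `chromosome`, `segment`
#'   (R1/R2a/C/R2b/R3), `start`, `end` (1-based inclusive, contiguous).
#' @return List with `segment` and `zone` (`"distal"`/`"central"`), or
#'   `NA`s for unplaced chromosomes.
#' @export
assign_segment <- function(gene, annotation, segment_map) {
  row <- annotation[annotation$gene_id == gene, ]
  if (nrow(row) != 1L) stop("gene not in annotation: ", gene, call. = FALSE)
  if (is_unplaced(row$chromosome)) {
    return(list(segment = NA_character_, zone = NA_character_))
  }
  seg <- segment_map[segment_map$chromosome == row$chromosome, ]
  if (nrow(seg) == 0L) {
    stop("no segment map for chromosome ", row$chromosome, call. = FALSE)
  }
  mid <- floor((row$start + row$end) / 2)
  hit <- seg[seg$start <= mid & mid <= seg$end, ]
  if (nrow(hit) != 1L) {
    stop("midpoint ", mid, " outside segment map of ", row$chromosome,
         call. = FALSE)
  }
  segment <- hit$segment
  list(segment = segment,
       zone = if (segment %in% c("R1", "R3")) "distal" else "central")
}

#' Location category of a duplicate pair
#'
#' Both genes distal: `distal_telomeric`; one distal, one central:
#' `sub_telomeric`; both central: `proximal`. Pairs with an unplaced
#' member get `NA`.
#'
#' @param pair List/one-row data frame with `gene_a`, `gene_b`.
#' @param annotation,segment_map As in [assign_segment()].
#' @return Category string or `NA_character_`.
#' @export
locate_pair_category <- function(pair, annotation, segment_map) {
  za <- assign_segment(pair$gene_a, annotation, segment_map)$zone
  zb <- assign_segment(pair$gene_b, annotation, segment_map)$zone
  if (is.na(za) || is.na(zb)) return(NA_character_)
  n_distal <- sum(c(za, zb) == "distal")
  c("proximal", "sub_telomeric", "distal_telomeric")[n_distal + 1L]
}

#' Annotate called pairs with type, segments and location category
#'
#' Resolves unplaced genes via [infer_unplaced_chromosome()] before
#' typing, mirroring the chrU-to-3B style inference.
#'
#' @param pairs Output of [call_duplicates()].
#' @param annotation Gene annotation data frame.
#' @param segment_map Segment map data frame.
#' @return `pairs` with added columns dup_type, location_category,
#'   chr_a, chr_b, inferred_a, inferred_b.
#' @export
annotate_duplicates <- function(pairs, annotation, segment_map) {
  if (nrow(pairs) == 0L) {
    pairs$dup_type <- character(0)
    pairs$location_category <- character(0)
    return(pairs)
  }
  chr <- setNames(annotation$chromosome, annotation$gene_id)
  unplaced_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  unplaced_genes <- unplaced_genes[is_unplaced(chr[unplaced_genes])]
  resolved <- vapply(unplaced_genes, function(g) {
    infer_unplaced_chromosome(g, pairs, annotation)$chromosome
  }, character(1))
  ann2 <- annotation
  for (g in names(resolved)) {
    if (!is.na(resolved[[g]])) {
      ann2$chromosome[ann2$gene_id == g] <- resolved[[g]]
    }
  }
  pairs$chr_a <- unname(chr[pairs$gene_a])
  pairs$chr_b <- unname(chr[pairs$gene_b])
  pairs$inferred_a <- pairs$gene_a %in% names(resolved)[!is.na(resolved)]
  pairs$inferred_b <- pairs$gene_b %in% names(resolved)[!is.na(resolved)]
  pairs$dup_type <- vapply(seq_len(nrow(pairs)), function(k) {
    classify_dup_type(pairs[k, ], annotation, resolved = resolved)
  }, character(1))
  pairs$location_category <- vapply(seq_len(nrow(pairs)), function(k) {
    if (pairs$dup_type[k] == "unplaced") return(NA_character_)
    # inferred chromosomes have no coordinates; category needs both placed
    if (is_unplaced(chr[[pairs$gene_a[k]]]) ||
        is_unplaced(chr[[pairs$gene_b[k]]])) {
      return(NA_character_)
    }
    locate_pair_category(pairs[k, ], annotation, segment_map)
  }, character(1))
  pairs
}

#' Per-chromosome gene counts and density
#'
#' @param annotation Gene annotation data frame with `chromosome`.
#' @param chromosome_lengths Named numeric vector of chromosome lengths
#'   in bp.
#' @return Data frame: chromosome, n_genes, length_mbp, density
#'   (genes/Mbp).
#' @export
chromosome_density <- function(annotation, chromosome_lengths) {
  chroms <- names(chromosome_lengths)
  counts <- vapply(chroms, function(cc) {
    sum(annotation$chromosome == cc)
  }, integer(1))
  data.frame(chromosome = chroms,
             n_genes = unname(counts),
             length_mbp = unname(chromosome_lengths) / 1e6,
             density = unname(counts) / (unname(chromosome_lengths) / 1e6),
             stringsAsFactors = FALSE)
}
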