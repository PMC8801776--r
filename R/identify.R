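# Family identification: candidate merging, redundancy filtering, domain
# architecture classification and protein statistics.

# Average residue masses (Da) and the mass of one water molecule.
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

# EMBOSS pKa values for ionizable groups.
.PKA <- list(nterm = 8.6, cterm = 3.6,
             positive = c(K = 10.8, R = 12.5, H = 6.5),
             negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

#' Merge candidate gene lists from multiple searches
#'
#' Pools candidate ids from domain searches and a keyword search, keeping
#' the survey-style bookkeeping: the pooled total is the sum of the list
#' sizes (overlaps counted multiply), reported separately from the
#' distinct-id union.
#'
#' @param domain_lists Named list of character vectors of gene ids (one
#'   per domain search).
#' @param keyword_ids Character vector of gene ids from the keyword
#'   search.
#' @return List with `pooled_total`, `union_ids`, `n_union` and a
#'   `provenance` data frame (gene_id, source).
#' @export
merge_candidates <- function(domain_lists, keyword_ids = character(0)) {
  if (is.null(names(domain_lists))) {
    names(domain_lists) <- paste0("domain", seq_along(domain_lists))
  }
  all_lists <- c(domain_lists, list(keyword = keyword_ids))
  prov <- do.call(rbind, lapply(names(all_lists), function(src) {
    ids <- all_lists[[src]]
    if (length(ids) == 0L) return(NULL)
    data.frame(gene_id = ids, source = src, stringsAsFactors = FALSE)
  }))
  if (is.null(prov)) {
    prov <- data.frame(gene_id = character(0), source = character(0))
  }
  union_ids <- unique(prov$gene_id)
  list(pooled_total = nrow(prov), union_ids = union_ids,
       n_union = length(union_ids), provenance = prov)
}

#' Case-insensitive keyword search over annotation descriptions
#'
#' @param annotation Annotation data frame with `gene_id` and a text
#'   column (default `description`).
#' @param keyword Literal substring to match (default `"MADS"`).
#' @param column Text column to search.
#' @return Character vector of matching gene ids.
#' @export
keyword_search <- function(annotation, keyword = "MADS",
                           column = "description") {
  if (!column %in% names(annotation)) return(character(0))
  hit <- grepl(keyword, annotation[[column]], ignore.case = TRUE, fixed = FALSE)
  annotation$gene_id[hit]
}

#' Filter candidates to high-confidence, non-redundant gene models
#'
#' Keeps candidates annotated as high confidence, collapsing duplicate
#' ids to one record. Candidates missing from the annotation are excluded
#' with a warning.
#'
#' @param candidate_ids Character vector of candidate gene ids (may
#'   contain duplicates).
#' @param annotation Annotation data frame with `gene_id` and
#'   `confidence` (`"high"`/`"low"`).
#' @return List with `retained` (character vector of unique high
#'   confidence ids, annotation order) and `excluded` data frame
#'   (gene_id, reason).
#' @export
filter_nonredundant <- function(candidate_ids, annotation) {
  ids <- unique(candidate_ids)
  known <- ids %in% annotation$gene_id
  excluded <- data.frame(gene_id = character(0), reason = character(0))
  if (any(!known)) {
    warning(sum(!known), " candidate id(s) absent from annotation; excluded")
    excluded <- rbind(excluded, data.frame(gene_id = ids[!known],
                                           reason = "not_annotated"))
    ids <- ids[known]
  }
  conf <- annotation$confidence[match(ids, annotation$gene_id)]
  low <- conf != "high"
  if (any(low)) {
    excluded <- rbind(excluded, data.frame(gene_id = ids[low],
                                           reason = "low_confidence"))
  }
  retained <- ids[!low]
  retained <- annotation$gene_id[annotation$gene_id %in% retained]
  list(retained = retained, excluded = excluded)
}

#' Classify domain architecture from MADS and K-box scan results
#'
#' @param mads_hit,kbox_hit `domain_hit` results from [scan_domain()]
#'   with the two packaged profiles (or logicals).
#' @return One of `"MADS_ONLY"`, `"MADS_K"`, `"K_ONLY"`, `"NONE"`.
#' @export
classify_architecture <- function(mads_hit, kbox_hit) {
  m <- if (is.logical(mads_hit)) mads_hit else isTRUE(mads_hit$hit)
  k <- if (is.logical(kbox_hit)) kbox_hit else isTRUE(kbox_hit$hit)
  if (m && k) "MADS_K" else if (m) "MADS_ONLY" else if (k) "K_ONLY" else "NONE"
}

# Net charge of a protein at a given pH (Henderson-Hasselbalch over the
# termini and ionizable side chains).
protein_charge <- function(counts, ph) {
  pos <- 1 / (1 + 10^(ph - .PKA$nterm))
  for (res in names(.PKA$positive)) {
    pos <- pos + counts[[res]] / (1 + 10^(ph - .PKA$positive[[res]]))
  }
  neg <- 1 / (1 + 10^(.PKA$cterm - ph))
  for (res in names(.PKA$negative)) {
    neg <- neg + counts[[res]] / (1 + 10^(.PKA$negative[[res]] - ph))
  }
  pos - neg
}

#' Protein length, molecular weight and isoelectric point
#'
#' Molecular weight uses average residue masses plus one water molecule,
#' reported in kDa. The isoelectric point is the pH at which the net
#' charge (EMBOSS pKa set) crosses zero, located by bisection to
#' `|charge| < 1e-4`. Unknown residues are excluded from both with a
#' warning.
#'
#' @param protein Amino-acid sequence.
#' @return List with `length` (residues, including unknowns), `mw_kda`
#'   and `pi`.
#' @export
#' @examples
#' compute_protein_stats("G")$mw_kda  # 0.0750672 kDa
compute_protein_stats <- function(protein) {
  res <- str_chars(toupper(protein))
  known <- res %in% names(.AA_MASS)
  if (any(!known)) {
    warning(sum(!known), " unknown residue(s) excluded from MW/pI")
  }
  res_known <- res[known]
  mw <- (sum(.AA_MASS[res_known]) + .WATER_MASS) / 1000
  counts <- as.list(table(factor(res_known, levels = names(.AA_MASS))))
  lo <- 0
  hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    ch <- protein_charge(counts, mid)
    if (abs(ch) < 1e-4 || (hi - lo) < 1e-8) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  list(length = length(res), mw_kda = mw, pi = mid)
}

#' Identify family members and build the gene report
#'
#' Scans every protein with the MADS and K-box profiles, classifies the
#' domain architecture and computes protein statistics.
#'
#' @param proteins Named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @param mads,kbox Domain profiles (defaults: packaged profiles).
#' @return Data frame with one row per protein: gene_id, mads_score,
#'   mads_start, kbox_score, architecture, length, mw_kda, pi.
#' @export
identify_family <- function(proteins, mads = mads_profile(),
                            kbox = kbox_profile()) {
  if (is(proteins, "AAStringSet")) proteins <- as.character(proteins)
  rows <- lapply(names(proteins), function(id) {
    p <- proteins[[id]]
    mh <- scan_domain(p, mads)
    kh <- scan_domain(p, kbox)
    st <- suppressWarnings(compute_protein_stats(p))
    data.frame(gene_id = id,
               mads_score = mh$score, mads_start = mh$start %||% NA_integer_,
               kbox_score = kh$score,
               architecture = classify_architecture(mh, kh),
               length = st$length, mw_kda = st$mw_kda, pi = st$pi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
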