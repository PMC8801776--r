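# Pairwise global alignment (Needleman-Wunsch with affine gaps) via
# Biostrings, plus CDS identity used by the duplication caller.

#' Global pairwise alignment with affine gap penalties
#'
#' End-gap-penalized (Needleman-Wunsch) alignment. Proteins are scored
#' with BLOSUM62 by default; nucleotide sequences with a +1/-1
#' match/mismatch matrix.
#'
#' @param a,b Sequences (character scalars).
#' @param type `"protein"` or `"dna"`.
#' @param substitution_matrix Scoring matrix name or matrix; default
#'   BLOSUM62 for proteins.
#' @param gap_open,gap_extend Gap opening/extension penalties (positive).
#' @param match,mismatch Nucleotide scores when `type = "dna"`.
#' @return List of class `alignment_pair` with gapped rows `a`, `b` and
#'   the alignment `score`.
#' @export
align_global <- function(a, b, type = c("protein", "dna"),
                         substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5,
                         match = 1, mismatch = -1) {
  type <- match.arg(type)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (type == "protein") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  } else {
    sm <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = sm,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  }
  out <- list(a = as.character(Biostrings::alignedPattern(pa)),
              b = as.character(Biostrings::alignedSubject(pa)),
              score = Biostrings::score(pa))
  class(out) <- "alignment_pair"
  out
}

# Column-wise identity of a gapped pair, excluding terminal gap columns
# from the denominator; internal gap columns count as mismatches.
aligned_identity <- function(ga, gb) {
  ca <- str_chars(ga)
  cb <- str_chars(gb)
  stopifnot(length(ca) == length(cb))
  nongap <- ca != "-" & cb != "-"
  if (!any(nongap)) {
    return(list(identity = NA_real_, aligned_columns = 0L))
  }
  # terminal gap columns: leading/trailing runs where either row is gapped
  first <- which(nongap)[1]
  last <- max(which(nongap))
  keep <- seq(first, last)
  matches <- sum(ca[keep] == cb[keep] & nongap[keep])
  list(identity = 100 * matches / length(keep),
       aligned_columns = length(keep))
}

#' Percent identity and coverage of two coding sequences
#'
#' Globally aligns two CDS (match +1, mismatch -1, affine gaps) and
#' reports percent identity over the aligned columns excluding terminal
#' gap columns (internal gaps count as mismatches), together with the
#' aligned-overlap coverage relative to the shorter sequence. Pairs with
#' coverage below `min_overlap` are flagged uninformative, standing in
#' for a database-size-dependent E-value filter.
#'
#' @param a,b Coding sequences.
#' @param min_overlap Minimum aligned-overlap fraction of the shorter
#'   sequence for the pair to be informative.
#' @param gap_open,gap_extend Gap penalties for the nucleotide alignment.
#' @return List with `identity` (percent), `coverage` (fraction) and
#'   `informative` (logical).
#' @export
cds_identity <- function(a, b, min_overlap = 0.5,
                         gap_open = 5, gap_extend = 2) {
  aln <- align_global(a, b, type = "dna",
                      gap_open = gap_open, gap_extend = gap_extend)
  id <- aligned_identity(aln$a, aln$b)
  cov <- id$aligned_columns / min(nchar(a), nchar(b))
  list(identity = id$identity, coverage = min(cov, 1),
       informative = cov >= min_overlap)
}

#' All-against-all CDS identity matrix
#'
#' Alignments for all unordered pairs run in one batched
#' `pairwiseAlignment` call; identity and coverage are then computed
#' column-wise per pair exactly as in [cds_identity()].
#'
#' @param cds Named character vector (or `DNAStringSet`) of coding
#'   sequences.
#' @param min_overlap Passed to [cds_identity()].
#' @param gap_open,gap_extend Gap penalties for the nucleotide
#'   alignments.
#' @return List with symmetric matrices `identity` (percent, diagonal
#'   100) and `coverage`, and logical matrix `informative`.
#' @export
identity_matrix <- function(cds, min_overlap = 0.5,
                            gap_open = 5, gap_extend = 2,
                            screen_identity = 80) {
  if (is(cds, "DNAStringSet")) cds <- as.character(cds)
  n <- length(cds)
  ids <- names(cds)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("cds must be uniquely named", call. = FALSE)
  }
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  cov <- matrix(1, n, n, dimnames = list(ids, ids))
  inf <- matrix(TRUE, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    pairs <- which(upper.tri(idm), arr.ind = TRUE)
    set <- Biostrings::DNAStringSet(cds)
    sm <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE)
    # screening stage: batched alignment scores; with +1/-1 scoring and
    # positive gap costs, score/L_min bounds the achievable identity, so
    # pairs whose score proxy falls well below the region of interest
    # (default proxy < 80%, i.e. far from any 90% call) skip the exact
    # column-wise identity computation -- the same role the E-value
    # prefilter plays in BLAST-based protocols
    scores <- Biostrings::pairwiseAlignment(
      set[pairs[, 1]], set[pairs[, 2]], substitutionMatrix = sm,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global",
      scoreOnly = TRUE)
    lmin <- pmin(nchar(cds)[pairs[, 1]], nchar(cds)[pairs[, 2]])
    proxy <- 100 * (scores / lmin + 1) / 2
    keep <- proxy >= screen_identity
    idm[pairs] <- idm[pairs[, 2:1, drop = FALSE]] <- pmax(pmin(proxy, 99), 0)
    if (any(keep)) {
      kp <- pairs[keep, , drop = FALSE]
      pa <- Biostrings::pairwiseAlignment(
        set[kp[, 1]], set[kp[, 2]], substitutionMatrix = sm,
        gapOpening = gap_open, gapExtension = gap_extend, type = "global")
      ga <- as.character(Biostrings::alignedPattern(pa))
      gb <- as.character(Biostrings::alignedSubject(pa))
      for (k in seq_len(nrow(kp))) {
        i <- kp[k, 1]
        j <- kp[k, 2]
        res <- aligned_identity(ga[k], gb[k])
        cvr <- res$aligned_columns / min(nchar(cds[[i]]), nchar(cds[[j]]))
        idm[i, j] <- idm[j, i] <- res$identity
        cov[i, j] <- cov[j, i] <- min(cvr, 1)
        inf[i, j] <- inf[j, i] <- cvr >= min_overlap
      }
    }
  }
  list(identity = idm, coverage = cov, informative = inf)
}

# Batched global-alignment scores of many queries against one subject
# (protein, BLOSUM62 by default); used where only scores are needed.
batch_scores <- function(queries, subject, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global",
    scoreOnly = TRUE)
}
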