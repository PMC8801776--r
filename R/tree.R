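# Distance-based phylogenetics: Kimura-corrected protein distances,
# center-star progressive multiple alignment, neighbor-joining with a
# deterministic tie-break, and Felsenstein bootstrap supports.

#' Kimura-corrected protein distance from a pairwise alignment
#'
#' With p the mismatch fraction over ungapped columns, the distance is
#' `d = -log(1 - p - 0.2 p^2)`. Saturated pairs (argument <= 0) return
#' `Inf`.
#'
#' @param aln An `alignment_pair` (or list with gapped rows `a`, `b`).
#' @return Distance (substitutions per site); `Inf` if saturated.
#' @export
protein_distance <- function(aln) {
  ca <- str_chars(aln$a)
  cb <- str_chars(aln$b)
  ungapped <- ca != "-" & cb != "-"
  if (!any(ungapped)) {
    stop("no ungapped columns: distance undefined", call. = FALSE)
  }
  p <- mean(ca[ungapped] != cb[ungapped])
  arg <- 1 - p - 0.2 * p^2
  if (arg <= 0) Inf else -log(arg)
}

# Character matrix (taxa x columns) from a list/vector of gapped rows.
msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  mat <- do.call(rbind, strsplit(unname(unlist(msa)), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  mat
}

#' Pairwise Kimura distances from a multiple alignment
#'
#' Mismatch fractions use pairwise deletion (columns ungapped in both
#' rows), then the Kimura correction of [protein_distance()].
#'
#' @param msa Named character vector of equal-length gapped sequences, or
#'   a character matrix (taxa x columns).
#' @return Symmetric distance matrix.
#' @export
msa_distances <- function(msa) {
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  taxa <- rownames(mat)
  # crossprod trick over residue indicator matrices
  nongap <- (mat != "-") * 1
  shared <- tcrossprod(nongap)
  letters_used <- setdiff(unique(as.vector(mat)), "-")
  matches <- matrix(0, n, n)
  for (a in letters_used) {
    ind <- (mat == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  p <- 1 - matches / shared
  arg <- 1 - p - 0.2 * p^2
  d <- matrix(Inf, n, n)
  ok <- is.finite(arg) & arg > 0
  d[ok] <- -log(arg[ok])
  diag(d) <- 0
  dimnames(d) <- list(taxa, taxa)
  d
}

# Merge gap patterns: given the master gapped center row and a new
# pairwise alignment of the (ungapped) center with a sequence, return the
# updated MSA including the new row (classic center-star merge).
merge_into_msa <- function(msa_rows, center_gapped, pair_center, pair_new) {
  mc <- str_chars(center_gapped)   # center as currently in the MSA
  pc <- str_chars(pair_center)     # center in the new pairwise alignment
  pn <- str_chars(pair_new)
  i <- 1L  # position in mc
  j <- 1L  # position in pc
  out_cols_old <- integer(0)  # source column in old MSA (NA = new gap col)
  out_new <- character(0)     # residue of the new row per output column
  n_old <- length(mc)
  n_pair <- length(pc)
  while (i <= n_old || j <= n_pair) {
    ci <- if (i <= n_old) mc[i] else NULL
    cj <- if (j <= n_pair) pc[j] else NULL
    if (!is.null(ci) && ci == "-" && (is.null(cj) || cj != "-")) {
      # gap column already in MSA, center absent here
      out_cols_old <- c(out_cols_old, i)
      out_new <- c(out_new, "-")
      i <- i + 1L
    } else if (!is.null(cj) && cj == "-") {
      # new sequence inserts relative to center: new all-gap column
      out_cols_old <- c(out_cols_old, NA_integer_)
      out_new <- c(out_new, pn[j])
      j <- j + 1L
    } else if (!is.null(ci) && !is.null(cj)) {
      # both advance over the same center residue
      out_cols_old <- c(out_cols_old, i)
      out_new <- c(out_new, pn[j])
      i <- i + 1L
      j <- j + 1L
    } else if (!is.null(ci)) {
      out_cols_old <- c(out_cols_old, i)
      out_new <- c(out_new, "-")
      i <- i + 1L
    } else {
      out_cols_old <- c(out_cols_old, NA_integer_)
      out_new <- c(out_new, pn[j])
      j <- j + 1L
    }
  }
  updated <- lapply(msa_rows, function(row) {
    chars <- str_chars(row)
    paste(ifelse(is.na(out_cols_old), "-", chars[pmax(out_cols_old, 1L)]),
          collapse = "")
  })
  updated[[length(updated) + 1L]] <- paste(out_new, collapse = "")
  updated
}

#' Center-star progressive multiple alignment
#'
#' Picks the center sequence maximising the total pairwise alignment
#' score against all others, then merges the pairwise alignments to the
#' center with once-a-gap-always-a-gap column propagation. Adequate for
#' the family-level alignments used here; it is not a full progressive
#' profile aligner.
#'
#' @param seqs Named character vector of protein sequences.
#' @param ... Passed to [align_global()].
#' @return Named character vector of gapped rows (equal length), in the
#'   input order.
#' @export
align_msa <- function(seqs, ...) {
  if (is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  if (n == 2) {
    aln <- align_global(seqs[[1]], seqs[[2]], ...)
    return(setNames(c(aln$a, aln$b), names(seqs)))
  }
  # center selection by total batched alignment score
  score_mat <- vapply(seq_len(n), function(j) {
    batch_scores(unname(seqs), seqs[[j]])
  }, numeric(n))
  diag(score_mat) <- 0
  center <- which.max(rowSums(score_mat))
  others <- setdiff(seq_len(n), center)
  # full alignments of every other sequence to the center, one call
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(seqs[others])),
    Biostrings::AAString(seqs[[center]]),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  gnew <- as.character(Biostrings::alignedPattern(pa))
  gcen <- as.character(Biostrings::alignedSubject(pa))
  msa_rows <- list(seqs[[center]])
  order_added <- center
  for (k in seq_along(others)) {
    msa_rows <- merge_into_msa(msa_rows, msa_rows[[1]], gcen[k], gnew[k])
    order_added <- c(order_added, others[k])
  }
  out <- unlist(msa_rows)
  names(out) <- names(seqs)[order_added]
  out[names(seqs)]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with deterministic tie-breaking
#' (among minimal Q values, the lexicographically smallest taxon-name
#' pair is joined). Negative branch lengths are clamped to zero. On an
#' additive matrix the generating topology and branch lengths are
#' recovered.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  stopifnot(n >= 3)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # working Newick fragment and representative name per active node
  frag <- labels
  key <- labels  # lexicographic representative for tie-breaks
  active <- d
  rownames(active) <- colnames(active) <- NULL
  fmt <- function(x) formatC(max(x, 0), format = "g", digits = 10)
  while (nrow(active) > 3) {
    m <- nrow(active)
    r <- rowSums(active)
    q <- (m - 2) * active - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pair_keys)[1], ]
    i <- pick[1]
    j <- pick[2]
    vi <- active[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- active[i, j] - vi
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",",
                       frag[j], ":", fmt(vj), ")")
    new_key <- min(key[i], key[j])
    new_d <- (active[i, ] + active[j, ] - active[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    active <- rbind(cbind(active[keep, keep, drop = FALSE], new_d[keep]),
                    c(new_d[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }
  # join the final three nodes at an internal node
  dd <- active
  v1 <- (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2
  v2 <- (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2
  v3 <- (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
  ord <- order(key)
  vs <- c(v1, v2, v3)[ord]
  fr <- frag[ord]
  newick <- paste0("(", fr[1], ":", fmt(vs[1]), ",", fr[2], ":", fmt(vs[2]),
                   ",", fr[3], ":", fmt(vs[3]), ");")
  ape::read.tree(text = newick)
}

# Bootstrap-resample alignment columns and rebuild the NJ tree.
nj_from_columns <- function(mat, cols) {
  sub <- mat[, cols, drop = FALSE]
  d <- msa_distances(sub)
  # guard against saturated/undefined distances in resamples
  finite_max <- max(d[is.finite(d)], 0)
  d[!is.finite(d)] <- finite_max * 1.5 + 1
  build_nj_tree(d)
}

#' Neighbor-joining tree with Felsenstein bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `replicates` times; the support of each
#' internal edge is the percentage of replicate trees containing its
#' bipartition, stored in `node.label`.
#'
#' @param msa Named character vector of gapped rows (from [align_msa()]).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed; supports are deterministic given the seed.
#' @return An `ape::phylo` with percent supports in `node.label`.
#' @export
bootstrap_support <- function(msa, replicates = 100, seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  mat <- msa_matrix(msa)
  if (ncol(mat) < 2) stop("alignment needs >= 2 columns", call. = FALSE)
  main <- nj_from_columns(mat, seq_len(ncol(mat)))
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      nj_from_columns(mat, sample.int(ncol(mat), replace = TRUE))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / replicates, 1)
  main
}
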