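# Superclade / subfamily classification against a labelled reference set
# and the FLC-vs-MIKC* diagnostic-residue test.

#' The 16 recognised subfamilies and their superclades
#'
#' Three M-type subfamilies (Malpha, Mbeta, Mgamma) and thirteen
#' MIKC-type subfamilies.
#'
#' @return Named character vector mapping subfamily to superclade.
#' @export
subfamily_superclades <- function() {
  c(Malpha = "M", Mbeta = "M", Mgamma = "M",
    AP1 = "MIKC", AP3 = "MIKC", PI = "MIKC", `AG/STK` = "MIKC",
    SEP = "MIKC", AGL6 = "MIKC", AGL12 = "MIKC", AGL17 = "MIKC",
    Bsister = "MIKC", MIKCstar = "MIKC", OsMADS32 = "MIKC",
    SOC1 = "MIKC", SVP = "MIKC")
}

#' Superclade implied by a subfamily label
#'
#' @param subfamily Subfamily name(s).
#' @return `"M"` or `"MIKC"` per element.
#' @export
superclade_of <- function(subfamily) {
  map <- subfamily_superclades()
  out <- unname(map[subfamily])
  if (anyNA(out)) {
    stop("unknown subfamily: ",
         paste(unique(subfamily[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Assign genes to subfamilies by nearest labelled reference
#'
#' Aligns each query against every reference exemplar with
#' [align_global()] and assigns the subfamily of the best-scoring
#' reference; the superclade is implied by the subfamily. Score ties
#' between different subfamily labels are flagged ambiguous with both
#' labels reported. The result does not depend on the ordering of the
#' reference set.
#'
#' @param proteins Named character vector of query proteins.
#' @param refs Data frame with columns `id`, `subfamily` and `protein`
#'   (see [reference_set()]).
#' @param tree Optional `ape::phylo` with supports in `node.label`
#'   containing both queries and references; if given, `support` is the
#'   support of the smallest clade joining the gene and its nearest
#'   reference.
#' @param ... Passed to [align_global()].
#' @return Data frame: gene_id, superclade, subfamily, nearest_ref,
#'   score, ambiguous, support.
#' @export
assign_subfamily <- function(proteins, refs, tree = NULL, ...) {
  stopifnot(all(c("id", "subfamily", "protein") %in% names(refs)))
  # canonical reference order so that assignment is order-invariant
  refs <- refs[order(refs$id), , drop = FALSE]
  # score all queries against each reference in one batched call
  score_mat <- vapply(seq_len(nrow(refs)), function(k) {
    batch_scores(unname(unlist(proteins)), refs$protein[k], ...)
  }, numeric(length(proteins)))
  if (is.null(dim(score_mat))) score_mat <- matrix(score_mat, nrow = 1)
  rownames(score_mat) <- names(proteins)
  rows <- lapply(names(proteins), function(id) {
    scores <- score_mat[id, ]
    best <- max(scores)
    tied <- which(scores >= best - 1e-9)
    labels <- sort(unique(refs$subfamily[tied]))
    nearest <- refs$id[tied[order(refs$id[tied])][1]]
    support <- NA_real_
    if (!is.null(tree)) {
      support <- clade_support(tree, id, nearest)
    }
    data.frame(gene_id = id,
               superclade = superclade_of(labels[1]),
               subfamily = labels[1],
               nearest_ref = nearest,
               score = best,
               ambiguous = length(labels) > 1,
               ambiguous_with = if (length(labels) > 1) {
                 paste(labels[-1], collapse = ",")
               } else {
                 NA_character_
               },
               support = support,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Support of the smallest clade containing both tips, from node.label.
clade_support <- function(tree, tip_a, tip_b) {
  ia <- match(tip_a, tree$tip.label)
  ib <- match(tip_b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) return(NA_real_)
  mrca <- ape::getMRCA(tree, c(ia, ib))
  if (is.null(mrca) || is.null(tree$node.label)) return(NA_real_)
  lab <- tree$node.label[mrca - ape::Ntip(tree)]
  suppressWarnings(as.numeric(lab))
}

#' FLC-vs-MIKC* diagnostic residue test
#'
#' MADS-domain alignment positions 30, 34 and 50 separate FLC-like
#' sequences, which carry (E, Q, A/G/S), from MIKC*-like sequences,
#' which carry (K, E, P). Anything else - including a gap at a
#' diagnostic position - is indeterminate.
#'
#' @param residues Character vector of length 3: the residues at
#'   positions 30, 34 and 50 of the reference MADS-domain alignment
#'   frame.
#' @return List with `call` (`"FLC_like"`, `"MIKCstar_like"` or
#'   `"indeterminate"`) and `reason`.
#' @export
diagnose_flc <- function(residues) {
  stopifnot(length(residues) == 3)
  r <- toupper(residues)
  if (any(r == "-")) {
    return(list(call = "indeterminate", reason = "gap at diagnostic position"))
  }
  if (r[1] == "E" && r[2] == "Q" && r[3] %in% c("A", "G", "S")) {
    list(call = "FLC_like", reason = "E/Q/(A|G|S) signature")
  } else if (r[1] == "K" && r[2] == "E" && r[3] == "P") {
    list(call = "MIKCstar_like", reason = "K/E/P signature")
  } else {
    list(call = "indeterminate", reason = "matches neither signature")
  }
}

#' Extract the FLC diagnostic residues from a protein
#'
#' Locates the MADS domain with [scan_domain()] and reads the residues at
#' domain positions 30, 34 and 50 (the packaged MADS profile defines the
#' coordinate frame).
#'
#' @param protein Amino-acid sequence.
#' @param profile MADS domain profile (default: packaged).
#' @return Character vector of length 3, or `NA`s when no domain hit.
#' @export
flc_residues <- function(protein, profile = mads_profile()) {
  hit <- scan_domain(protein, profile)
  if (!hit$hit) return(rep(NA_character_, 3))
  res <- str_chars(protein)
  pos <- hit$start + c(30, 34, 50) - 1L
  ifelse(pos <= length(res), res[pos], NA_character_)
}
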