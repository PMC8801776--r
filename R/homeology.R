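# Homeolog detection from supported tree clades and subgenome labels,
# and subfamily balance classification (Table 1-style reporting).

#' Detect homeologous groups from supported single-subfamily clades
#'
#' Scans the tree for maximal clades with bootstrap support strictly
#' above `support_threshold` whose leaves all carry one subfamily label
#' and at most one gene per subgenome beyond duplicate candidates
#' (same-subgenome members are admitted only when linked by
#' `duplicate_candidates`, which prevents two distinct triads of one
#' subfamily from merging into a single group). Each accepted clade
#' becomes a homeolog group.
#'
#' Leftover genes are assessed individually: a gene whose smallest
#' supported ancestral clade contains no other unresolved gene of its
#' subfamily is confidently isolated and forms a singleton group
#' (typically classified unbalanced); all other leftover genes have
#' status `undetermined`.
#'
#' @param tree `ape::phylo` with percent supports in `node.label` (tips
#'   are gene ids; tips absent from `assignments` are ignored).
#' @param assignments Data frame with `gene_id` and `subfamily`.
#' @param annotation Data frame with `gene_id` and `subgenome`
#'   (`"A"`, `"B"`, `"D"` or `"U"`).
#' @param support_threshold Percent support required (strict >; default
#'   90, the rule used for wheat homeolog calling).
#' @param duplicate_candidates Optional data frame with `gene_a`,
#'   `gene_b`: high-identity pairs that may share a subgenome within a
#'   group (e.g. all pairs at or above the duplication identity
#'   threshold). When `NULL`, groups admit at most one gene per
#'   subgenome.
#' @return Data frame with one row per gene: gene_id, subfamily,
#'   subgenome, group_id (`NA` if undetermined), support, status
#'   (`balanced`/`unbalanced`/`undetermined`).
#' @export
detect_homeolog_groups <- function(tree, assignments, annotation,
                                   support_threshold = 90,
                                   duplicate_candidates = NULL) {
  genes <- intersect(tree$tip.label, assignments$gene_id)
  subfam <- setNames(assignments$subfamily, assignments$gene_id)
  subg <- setNames(annotation$subgenome, annotation$gene_id)
  if (anyNA(subg[genes])) {
    stop("missing subgenome label for: ",
         paste(genes[is.na(subg[genes])], collapse = ", "), call. = FALSE)
  }
  dup_key <- character(0)
  if (!is.null(duplicate_candidates) && nrow(duplicate_candidates) > 0) {
    dup_key <- paste(pmin(duplicate_candidates$gene_a, duplicate_candidates$gene_b),
                     pmax(duplicate_candidates$gene_a, duplicate_candidates$gene_b))
  }
  linked <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% dup_key

  ntip <- ape::Ntip(tree)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  pp <- ape::prop.part(tree)
  clades <- lapply(seq_len(tree$Nnode), function(node) tree$tip.label[pp[[node]]])

  subgenome_ok <- function(members) {
    placed <- members[subg[members] != "U"]
    for (s in unique(subg[placed])) {
      ms <- placed[subg[placed] == s]
      if (length(ms) > 1L) {
        # every extra member must be a duplicate candidate of another
        ok <- vapply(ms, function(g) {
          any(linked(rep(g, length(ms) - 1L), setdiff(ms, g)))
        }, logical(1))
        if (!all(ok)) return(FALSE)
      }
    }
    TRUE
  }

  cand <- list()
  for (node in seq_len(tree$Nnode)) {
    tips <- clades[[node]]
    members <- tips[tips %in% genes]
    if (length(members) < 2L || length(members) != length(tips)) next
    sup <- supports[node]
    if (is.na(sup) || !(sup > support_threshold)) next
    if (length(unique(subfam[members])) != 1L) next
    if (!subgenome_ok(members)) next
    cand[[length(cand) + 1L]] <- list(members = members, support = sup)
  }
  # keep maximal candidates (largest first, no overlaps)
  accepted <- list()
  if (length(cand) > 0) {
    sizes <- vapply(cand, function(x) length(x$members), integer(1))
    cand <- cand[order(-sizes)]
    taken <- character(0)
    for (cl in cand) {
      if (any(cl$members %in% taken)) next
      accepted[[length(accepted) + 1L]] <- cl
      taken <- c(taken, cl$members)
    }
  }
  grouped <- unlist(lapply(accepted, `[[`, "members")) %||% character(0)

  # singleton resolution for leftover genes
  leftover <- setdiff(genes, grouped)
  singleton <- character(0)
  if (length(leftover) > 0) {
    # node sets sorted by clade size so the smallest supported ancestor
    # is found first
    node_order <- order(lengths(clades))
    for (g in leftover) {
      anc_nodes <- node_order[vapply(node_order, function(nd) {
        g %in% clades[[nd]]
      }, logical(1))]
      placed_ok <- FALSE
      for (nd in anc_nodes) {
        sup <- supports[nd]
        if (is.na(sup) || !(sup > support_threshold)) next
        others <- setdiff(clades[[nd]], g)
        same_sf <- others[others %in% genes & subfam[others] == subfam[g]]
        placed_ok <- all(same_sf %in% grouped)
        break
      }
      if (placed_ok) singleton <- c(singleton, g)
    }
  }

  rows <- data.frame(gene_id = genes,
                     subfamily = unname(subfam[genes]),
                     subgenome = unname(subg[genes]),
                     group_id = NA_character_,
                     support = NA_real_,
                     status = "undetermined",
                     stringsAsFactors = FALSE)
  k <- 0L
  for (cl in accepted) {
    k <- k + 1L
    gid <- sprintf("HG%03d", k)
    sel <- rows$gene_id %in% cl$members
    rows$group_id[sel] <- gid
    rows$support[sel] <- cl$support
    rows$status[sel] <- classify_balance(rows$subgenome[sel])
  }
  for (g in singleton) {
    k <- k + 1L
    sel <- rows$gene_id == g
    rows$group_id[sel] <- sprintf("HG%03d", k)
    rows$status[sel] <- classify_balance(rows$subgenome[sel])
  }
  rows
}

#' Classify the subgenome balance of a homeolog group
#'
#' Balanced means at least one copy on each of the A, B and D
#' subgenomes; unbalanced means a copy is missing from one or two
#' subgenomes. Groups placed only on unassigned chromosomes (U) are
#' undetermined.
#'
#' @param subgenomes Character vector of member subgenomes.
#' @return `"balanced"`, `"unbalanced"` or `"undetermined"`.
#' @export
classify_balance <- function(subgenomes) {
  stopifnot(length(subgenomes) >= 1)
  placed <- setdiff(unique(subgenomes), "U")
  if (length(placed) == 0L) return("undetermined")
  if (all(c("A", "B", "D") %in% placed)) "balanced" else "unbalanced"
}

#' Table 1-style balance report per subfamily
#'
#' Counts genes by homeolog status per subfamily and flags whether
#' duplicate pairs were called in the subfamily. Subfamilies with
#' duplications despite fully balanced homeologs get an exception flag
#' (the AP3-style annotation).
#'
#' @param groups Output of [detect_homeolog_groups()].
#' @param duplicates Data frame of called pairs with columns `gene_a`,
#'   `gene_b` (may be `NULL` or empty).
#' @return Data frame per subfamily: total, balanced, unbalanced,
#'   undetermined, duplications (`"Present"`/`"Absent"`), exception
#'   (logical).
#' @export
balance_report <- function(groups, duplicates = NULL) {
  split_g <- split(groups, groups$subfamily)
  dup_genes <- character(0)
  if (!is.null(duplicates) && nrow(duplicates) > 0) {
    dup_genes <- unique(c(duplicates$gene_a, duplicates$gene_b))
  }
  rows <- lapply(names(split_g), function(sf) {
    g <- split_g[[sf]]
    has_dup <- any(g$gene_id %in% dup_genes)
    data.frame(subfamily = sf,
               total = nrow(g),
               balanced = sum(g$status == "balanced"),
               unbalanced = sum(g$status == "unbalanced"),
               undetermined = sum(g$status == "undetermined"),
               duplications = if (has_dup) "Present" else "Absent",
               exception = has_dup && sum(g$status == "unbalanced") == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
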