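# Genetic-code tables shared by the molecular-evolution module and the
# synthetic-genome mutation model. All tables are built once per session
# and cached in a package-local environment.

.codon_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' @noRd
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_codon <- function(codon) {
  unname(genetic_code()[codon])
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds A coding sequence (character scalar, length divisible by 3).
#'   A terminal stop codon, if present, is dropped from the translation.
#' @return Amino-acid sequence as a character scalar.
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(toupper(cds))
  aa <- genetic_code()[codons]
  if (anyNA(aa)) {
    stop("CDS contains non-ACGT codons: ",
         paste(unique(codons[is.na(aa)]), collapse = ", "), call. = FALSE)
  }
  if (length(aa) > 1L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    stop("CDS contains an internal stop codon", call. = FALSE)
  }
  paste(aa, collapse = "")
}

# For every sense codon, the single-nucleotide mutant codons at each
# position, split into synonymous / nonsynonymous / stop classes.
codon_mutants <- function() {
  if (!is.null(.codon_cache$mutants)) return(.codon_cache$mutants)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (codon in sense_codons()) {
    aa <- gc[[codon]]
    per_pos <- vector("list", 3L)
    for (pos in 1:3) {
      chars <- str_chars(codon)
      muts <- vapply(setdiff(bases, chars[pos]), function(b) {
        chars2 <- chars
        chars2[pos] <- b
        paste(chars2, collapse = "")
      }, character(1))
      cls <- ifelse(gc[muts] == "*", "stop",
                    ifelse(gc[muts] == aa, "syn", "nonsyn"))
      per_pos[[pos]] <- split(unname(muts), factor(cls, levels = c("syn", "nonsyn", "stop")))
    }
    out[[codon]] <- per_pos
  }
  .codon_cache$mutants <- out
  out
}

# Nei-Gojobori site fractions per sense codon (s, n with s + n = 3).
# At each position the synonymous fraction is counted over the non-stop
# single-nucleotide mutants, excluding mutations to stop codons from the
# denominator (SNAP convention).
codon_site_table <- function() {
  if (!is.null(.codon_cache$sites)) return(.codon_cache$sites)
  muts <- codon_mutants()
  tab <- t(vapply(names(muts), function(codon) {
    s <- 0
    for (pos in 1:3) {
      nsyn <- length(muts[[codon]][[pos]]$syn)
      nvalid <- nsyn + length(muts[[codon]][[pos]]$nonsyn)
      if (nvalid > 0L) s <- s + nsyn / nvalid
    }
    c(s = s, n = 3 - s)
  }, numeric(2)))
  .codon_cache$sites <- tab
  tab
}

# Pathway-averaged synonymous/nonsynonymous difference counts for every
# ordered pair of sense codons (cached 61 x 61 matrices). Pathways through
# stop codons are excluded; when every minimal pathway passes through a
# stop (possible for 2-3 differences), all pathways are used with steps
# to/from stop codons counted as nonsynonymous.
codon_diff_tables <- function() {
  if (!is.null(.codon_cache$diffs)) return(.codon_cache$diffs)
  gc <- genetic_code()
  codons <- sense_codons()
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- matrix(0, n, n, dimnames = list(codons, codons))

  step_class <- function(from, to) {
    # one mutational step; stop codons count as a distinct "amino acid"
    if (gc[[from]] == gc[[to]]) "syn" else "nonsyn"
  }
  path_counts <- function(a, b, positions) {
    # enumerate all orderings of the differing positions
    perms <- if (length(positions) == 1L) {
      list(positions)
    } else if (length(positions) == 2L) {
      list(positions, rev(positions))
    } else {
      list(positions[c(1, 2, 3)], positions[c(1, 3, 2)], positions[c(2, 1, 3)],
           positions[c(2, 3, 1)], positions[c(3, 1, 2)], positions[c(3, 2, 1)])
    }
    a_chars <- str_chars(a)
    b_chars <- str_chars(b)
    res <- lapply(perms, function(ord) {
      cur <- a_chars
      s <- 0L
      ns <- 0L
      blocked <- FALSE
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- b_chars[pos]
        from <- paste(cur, collapse = "")
        to <- paste(nxt, collapse = "")
        if (gc[[to]] == "*" && to != b) blocked <- TRUE
        if (step_class(from, to) == "syn") s <- s + 1L else ns <- ns + 1L
        cur <- nxt
      }
      list(s = s, ns = ns, blocked = blocked)
    })
    ok <- !vapply(res, `[[`, logical(1), "blocked")
    use <- if (any(ok)) res[ok] else res
    c(sd = mean(vapply(use, `[[`, integer(1), "s")),
      nd = mean(vapply(use, `[[`, integer(1), "ns")))
  }

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      a <- codons[i]
      b <- codons[j]
      pos <- which(str_chars(a) != str_chars(b))
      counts <- path_counts(a, b, pos)
      sd[i, j] <- sd[j, i] <- counts[["sd"]]
      nd[i, j] <- nd[j, i] <- counts[["nd"]]
    }
  }
  .codon_cache$diffs <- list(sd = sd, nd = nd)
  .codon_cache$diffs
}
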