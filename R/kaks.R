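# Molecular evolution: Nei-Gojobori (1986) pathway method with
# Jukes-Cantor correction, duplication dating (T = Ks / 2r) and selection
# classification. This mirrors the method popularised by the SNAP program:
# equal pathway weighting, stop-codon pathways excluded, site counts
# averaged between the two sequences.

#' Nei-Gojobori synonymous/nonsynonymous site fractions of a codon
#'
#' Counts, for each codon position, the fraction of single-nucleotide
#' mutations that are synonymous, excluding mutations to stop codons from
#' the denominator. The synonymous (s) and nonsynonymous (n) site counts
#' always satisfy s + n = 3.
#'
#' @param codon A sense codon (3-letter ACGT string).
#' @return Named numeric vector `c(s =, n =)`.
#' @export
#' @examples
#' ng_sites("TTT")  # s = 1/3: only TTT->TTC is synonymous
ng_sites <- function(codon) {
  codon <- toupper(codon)
  tab <- codon_site_table()
  if (!codon %in% rownames(tab)) {
    stop("not a sense codon: ", codon, call. = FALSE)
  }
  tab[codon, ]
}

#' Pathway-averaged substitution differences between two codons
#'
#' Averages synonymous and nonsynonymous difference counts over all
#' minimal mutational pathways between two sense codons, with equal
#' weighting. Pathways passing through a stop codon are excluded; if every
#' pathway is blocked the average falls back to all pathways with
#' stop-involving steps counted as nonsynonymous.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd =, nd =)`.
#' @export
ng_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  tabs <- codon_diff_tables()
  if (!codon_a %in% rownames(tabs$sd) || !codon_b %in% rownames(tabs$sd)) {
    stop("not a sense codon: ", codon_a, " / ", codon_b, call. = FALSE)
  }
  c(sd = tabs$sd[codon_a, codon_b], nd = tabs$nd[codon_a, codon_b])
}

#' Back-translate a protein alignment onto CDS pairs and mask gap codons
#'
#' Maps the gap pattern of a pairwise protein alignment onto the two
#' coding sequences and drops every codon column containing a gap in
#' either sequence, yielding a gap-free codon alignment.
#'
#' @param aln An `alignment_pair` from [align_global()] over the two
#'   translated proteins, or a list with gapped sequences `a` and `b`.
#' @param cds_a,cds_b Ungapped coding sequences whose translations match
#'   the ungapped alignment rows (a terminal stop codon is tolerated).
#' @return List of class `codon_alignment` with codon vectors `a`, `b`
#'   (equal length, gap-free) and `n_dropped`, the number of masked codon
#'   columns.
#' @export
backtranslate_and_mask <- function(aln, cds_a, cds_b) {
  ga <- str_chars(aln$a)
  gb <- str_chars(aln$b)
  if (length(ga) != length(gb)) {
    stop("gapped alignment rows differ in length", call. = FALSE)
  }
  cod_a <- split_codons(toupper(cds_a))
  cod_b <- split_codons(toupper(cds_b))
  gc <- genetic_code()
  if (gc[[cod_a[length(cod_a)]]] == "*") cod_a <- cod_a[-length(cod_a)]
  if (gc[[cod_b[length(cod_b)]]] == "*") cod_b <- cod_b[-length(cod_b)]
  ia <- cumsum(ga != "-")
  ib <- cumsum(gb != "-")
  if (max(ia) != length(cod_a) || max(ib) != length(cod_b)) {
    stop("protein alignment is inconsistent with CDS lengths (",
         max(ia), " vs ", length(cod_a), " codons; ",
         max(ib), " vs ", length(cod_b), " codons)", call. = FALSE)
  }
  # verify translations column by column, naming the offending codon
  for (k in seq_along(ga)) {
    if (ga[k] != "-" && ga[k] != "X" && gc[[cod_a[ia[k]]]] != ga[k]) {
      stop("codon ", ia[k], " of sequence a (", cod_a[ia[k]],
           ") does not translate to aligned residue '", ga[k], "'",
           call. = FALSE)
    }
    if (gb[k] != "-" && gb[k] != "X" && gc[[cod_b[ib[k]]]] != gb[k]) {
      stop("codon ", ib[k], " of sequence b (", cod_b[ib[k]],
           ") does not translate to aligned residue '", gb[k], "'",
           call. = FALSE)
    }
  }
  keep <- ga != "-" & gb != "-"
  out <- list(a = cod_a[ia[keep]], b = cod_b[ib[keep]],
              n_dropped = sum(!keep))
  class(out) <- "codon_alignment"
  out
}

#' Ka/Ks estimation by the Nei-Gojobori pathway method
#'
#' Computes synonymous and nonsynonymous site counts (averaged between the
#' two sequences), pathway-averaged difference counts, the proportions
#' ps = Sd/S and pn = Nd/N, and Jukes-Cantor-corrected rates
#' `K = -(3/4) log(1 - (4/3) p)`. Saturated proportions (argument of the
#' logarithm <= 0) leave the corresponding rate `NA` with a flag.
#'
#' @param aln A `codon_alignment` from [backtranslate_and_mask()], or a
#'   list with equal-length gap-free codon vectors `a` and `b`.
#' @return List of class `evolution_estimate` with elements `S`, `N`,
#'   `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`, `omega`, `saturated`,
#'   `n_codons`.
#' @export
compute_kaks <- function(aln) {
  a <- toupper(aln$a)
  b <- toupper(aln$b)
  stopifnot(length(a) == length(b))
  sense <- sense_codons()
  keep <- a %in% sense & b %in% sense
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) {
    stop("no retained sense codons in alignment", call. = FALSE)
  }
  sites <- codon_site_table()
  S <- (sum(sites[a, "s"]) + sum(sites[b, "s"])) / 2
  N <- (sum(sites[a, "n"]) + sum(sites[b, "n"])) / 2
  tabs <- codon_diff_tables()
  idx <- cbind(match(a, rownames(tabs$sd)), match(b, colnames(tabs$sd)))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(c(NA_real_, NA))
    arg <- 1 - (4 / 3) * p
    if (arg <= 0) c(NA_real_, TRUE) else c(-(3 / 4) * log(arg), FALSE)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  omega <- if (!is.na(ks[1]) && ks[1] > 0 && !is.na(ka[1])) ka[1] / ks[1] else NA_real_
  out <- list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
              Ks = ks[1], Ka = ka[1], omega = omega,
              saturated = isTRUE(ks[2] == 1) || isTRUE(ka[2] == 1),
              n_codons = length(a))
  class(out) <- "evolution_estimate"
  out
}

#' Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper: translates both CDS, aligns the proteins globally,
#' back-translates and masks gapped codon columns, and estimates Ka/Ks.
#'
#' @param cds_a,cds_b Coding sequences (character scalars).
#' @param ... Passed to [align_global()].
#' @return An `evolution_estimate` (see [compute_kaks()]).
#' @export
kaks_pair <- function(cds_a, cds_b, ...) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  aln <- align_global(pa, pb, ...)
  compute_kaks(backtranslate_and_mask(aln, cds_a, cds_b))
}

#' Divergence time of a duplication event
#'
#' Applies the molecular-clock dating formula `T = Ks / (2 r)`, reported
#' in million years (MYA). The default clock rate is
#' `r = 6.5e-9` substitutions per synonymous site per year, the value
#' commonly used for grasses.
#'
#' @param ks Synonymous substitution rate (substitutions per synonymous
#'   site); may be a vector. `NA` propagates.
#' @param rate Clock rate in substitutions/synonymous site/year.
#' @return Divergence time in MYA.
#' @export
#' @examples
#' divergence_time(0.013)  # 1 MYA
divergence_time <- function(ks, rate = 6.5e-9) {
  stopifnot(rate > 0)
  ks / (2 * rate) * 1e-6
}

#' Classify the mode of selection from a Ka/Ks ratio
#'
#' @param estimate An `evolution_estimate`, or a numeric omega value.
#' @return One of `"positive"` (omega > 1), `"purifying"` (omega < 1),
#'   `"neutral"` (omega == 1) or `"undefined"` (omega undefined, e.g.
#'   Ks = 0).
#' @export
classify_selection <- function(estimate) {
  omega <- if (is.numeric(estimate)) estimate else estimate$omega
  if (length(omega) != 1L || is.na(omega)) return("undefined")
  if (omega > 1) "positive" else if (omega < 1) "purifying" else "neutral"
}

#' Superclade-level evolution summary
#'
#' Summarises Ks, Ka/Ks and divergence time per superclade (M vs MIKC)
#' with quartiles, and reports the percentage of defined-omega pairs under
#' positive selection (omega > 1), as used to contrast evolution rates of
#' M-type and MIKC-type genes.
#'
#' @param estimates Data frame with one row per duplicate pair and columns
#'   `Ks`, `omega`, `T_mya` plus a gene-id column named by `by`.
#' @param superclades Named character vector mapping gene id to
#'   superclade (`"M"`/`"MIKC"`); a pair is attributed to the superclade
#'   of its first gene (pairs are subfamily-specific by construction).
#' @param by Column of `estimates` holding the gene id used for lookup.
#' @return Data frame with one row per superclade: quartiles of Ks,
#'   omega and T, `n_pairs`, `n_defined_omega` and `positive_pct`.
#' @export
summarize_by_superclade <- function(estimates, superclades, by = "gene_a") {
  cls <- unname(superclades[estimates[[by]]])
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " pair(s) without superclade assignment omitted")
  }
  out <- lapply(split(estimates, cls), function(df) {
    q <- function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      unname(quantile(x, c(0.25, 0.5, 0.75)))
    }
    qs <- q(df$Ks)
    qo <- q(df$omega)
    qt <- q(df$T_mya)
    defined <- !is.na(df$omega)
    data.frame(
      n_pairs = nrow(df),
      Ks_q1 = qs[1], Ks_median = qs[2], Ks_q3 = qs[3],
      omega_q1 = qo[1], omega_median = qo[2], omega_q3 = qo[3],
      T_q1 = qt[1], T_median = qt[2], T_q3 = qt[3],
      T_mean = mean(df$T_mya, na.rm = TRUE),
      n_defined_omega = sum(defined),
      positive_pct = if (any(defined)) 100 * mean(df$omega[defined] > 1) else NA_real_
    )
  })
  res <- do.call(rbind, out)
  res <- cbind(superclade = names(out), res)
  rownames(res) <- NULL
  res
}
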