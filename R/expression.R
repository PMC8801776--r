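# Expression analysis: the expressed / not-expressed rule on log2-TPM
# matrices, K-means clustering (Lloyd's algorithm, best of several
# seeded restarts) and subfamily-level summaries.

#' Flag expressed genes in a log2-TPM matrix
#'
#' A gene is expressed iff its maximum over conditions exceeds 0.0 on
#' the log2-TPM scale; genes never rising above 0.0 are "no or very low
#' expression". The observed minimum and maximum among expressed values
#' are reported so real-data runs can be compared with published ranges.
#'
#' @param mat Numeric matrix, genes x conditions (log2 TPM; may be
#'   negative).
#' @return List with `expressed` (named logical), `expressed_fraction`,
#'   `expressed_min`, `expressed_max`.
#' @export
mark_expressed <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 1 || nrow(mat) < 1) {
    stop("expression matrix must have at least one gene and condition",
         call. = FALSE)
  }
  mx <- apply(mat, 1, max)
  expressed <- mx > 0.0
  vals <- mat[expressed, , drop = FALSE]
  vals <- vals[vals > 0.0]
  list(expressed = expressed,
       expressed_fraction = mean(expressed),
       expressed_min = if (length(vals)) min(vals) else NA_real_,
       expressed_max = if (length(vals)) max(vals) else NA_real_)
}

# One Lloyd run from a given seed; returns labels, centers, wcss and the
# per-iteration WCSS trace (asserted non-increasing).
lloyd_run <- function(mat, k, iterations, seed) {
  n <- nrow(mat)
  centers <- with_seed(seed, mat[sample.int(n, k), , drop = FALSE])
  labels <- integer(n)
  trace <- numeric(0)
  assign_wcss <- function(centers) {
    # squared Euclidean distances to each center
    d2 <- vapply(seq_len(nrow(centers)), function(j) {
      rowSums(sweep(mat, 2, centers[j, ], `-`)^2)
    }, numeric(n))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = n)
    lab <- max.col(-d2, ties.method = "first")
    list(labels = lab, wcss = sum(d2[cbind(seq_len(n), lab)]))
  }
  for (iter in seq_len(iterations)) {
    as1 <- assign_wcss(centers)
    labels <- as1$labels
    trace <- c(trace, as1$wcss)
    # empty clusters are re-seeded from the farthest point
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        d2_own <- rowSums((mat - centers[labels, , drop = FALSE])^2)
        far <- which.max(d2_own)
        centers[j, ] <- mat[far, ]
        labels[far] <- j
      }
    }
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- labels == j
      if (any(sel)) new_centers[j, ] <- colMeans(mat[sel, , drop = FALSE])
    }
    if (all(abs(new_centers - centers) < 1e-12)) break
    centers <- new_centers
  }
  final <- assign_wcss(centers)
  trace <- c(trace, final$wcss)
  if (any(diff(trace) > 1e-8 * max(1, trace[1]))) {
    stop("internal error: WCSS increased across Lloyd iterations")
  }
  list(labels = final$labels, centers = centers, wcss = final$wcss,
       trace = trace)
}

#' K-means clustering of expression profiles
#'
#' Lloyd's algorithm with Euclidean distance on matrix rows, run
#' `runs` times from seeds derived from the master seed; the run with
#' the lowest within-cluster sum of squares wins. Defaults follow the
#' K = 10, 1,000 iterations, 5 runs configuration used for the wheat
#' stress-expression clustering. Empty clusters are re-seeded from the
#' point farthest from its current center.
#'
#' @param mat Numeric matrix, genes x conditions.
#' @param k Number of clusters (>= 1, <= number of genes).
#' @param iterations Maximum Lloyd iterations per run.
#' @param runs Number of seeded restarts.
#' @param seed Master seed.
#' @return List with `labels` (named integer), `centers`, `wcss`,
#'   `run_wcss` (per-run best WCSS) and `trace` (WCSS per iteration of
#'   the winning run).
#' @export
kmeans_cluster <- function(mat, k = 10, iterations = 1000, runs = 5,
                           seed = 1) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (nrow(mat) < k) {
    stop("fewer genes (", nrow(mat), ") than clusters (", k, ")",
         call. = FALSE)
  }
  run_res <- lapply(seq_len(runs), function(r) {
    lloyd_run(mat, k, iterations, derive_seed(seed, paste0("kmeans", r)))
  })
  wcss <- vapply(run_res, `[[`, numeric(1), "wcss")
  best <- run_res[[which.min(wcss)]]
  labels <- setNames(best$labels, rownames(mat))
  list(labels = labels, centers = best$centers, wcss = best$wcss,
       run_wcss = wcss, trace = best$trace)
}

#' Subfamily-level expression summary
#'
#' Per subfamily: expressed / not-expressed counts and cluster
#' composition; per superclade: the share of all non-expressed genes,
#' the quantity behind "most non-expressed genes are M-type" style
#' statements.
#'
#' @param assignments Data frame with `gene_id`, `subfamily`,
#'   `superclade`.
#' @param expressed Named logical vector from [mark_expressed()].
#' @param labels Named cluster labels from [kmeans_cluster()] (optional).
#' @return List with `by_subfamily` (data frame), `nonexpressed_share`
#'   (named numeric per superclade, percent) and `cluster_table`
#'   (subfamily x cluster counts, or `NULL`).
#' @export
subfamily_expression_summary <- function(assignments, expressed,
                                         labels = NULL) {
  genes <- assignments$gene_id
  ex <- expressed[genes]
  sf <- assignments$subfamily
  by_sf <- do.call(rbind, lapply(split(seq_along(genes), sf), function(ix) {
    data.frame(n = length(ix),
               expressed = sum(ex[ix]),
               not_expressed = sum(!ex[ix]))
  }))
  by_sf <- cbind(subfamily = rownames(by_sf), by_sf)
  rownames(by_sf) <- NULL
  non_ex <- genes[!ex]
  share <- if (length(non_ex) > 0) {
    tab <- table(assignments$superclade[match(non_ex, genes)])
    100 * as.numeric(tab) / length(non_ex)
  } else {
    numeric(0)
  }
  names(share) <- if (length(non_ex) > 0) {
    names(table(assignments$superclade[match(non_ex, genes)]))
  } else {
    character(0)
  }
  cluster_table <- NULL
  if (!is.null(labels)) {
    cluster_table <- table(subfamily = sf, cluster = labels[genes])
  }
  list(by_subfamily = by_sf, nonexpressed_share = share,
       cluster_table = cluster_table)
}
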