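# Independent oracles used to validate the package implementations.
# These deliberately share no code with the package internals.

GC_TABLE <- as.character(Biostrings::GENETIC_CODE)
names(GC_TABLE) <- names(Biostrings::GENETIC_CODE)
SENSE <- names(GC_TABLE)[GC_TABLE != "*"]

# --- Nei-Gojobori site counting by direct enumeration -------------------
oracle_ng_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (b in bases) {
      v <- strsplit(codon, "")[[1]]
      if (v[pos] == b) next
      v[pos] <- b
      mut <- paste(v, collapse = "")
      if (GC_TABLE[[mut]] == "*") next
      valid <- valid + 1
      if (GC_TABLE[[mut]] == GC_TABLE[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# --- pathway enumeration for codon differences --------------------------
perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

oracle_ng_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- perms_of(pos)
  res <- lapply(paths, function(ord) {
    cur <- strsplit(a, "")[[1]]
    tgt <- strsplit(b, "")[[1]]
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (GC_TABLE[[nxt]] == "*" && nxt != b) blocked <- TRUE
      if (GC_TABLE[[prev]] == GC_TABLE[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  use <- if (any(ok)) res[ok] else res
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

# --- exhaustive global alignment of tiny strings ------------------------
# Enumerates every possible alignment (monotone column sequence) and
# scores it with affine gaps (cost = open + extend * run length), the
# same convention as the package aligner.
oracle_best_alignment <- function(a, b, subst, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  score_cols <- function(cols) {
    s <- 0
    run <- 0
    for (k in seq_len(nrow(cols))) {
      if (cols[k, 1] == 0 || cols[k, 2] == 0) {
        run <- run + 1
      } else {
        if (run > 0) s <- s - gap_open - gap_extend * run
        run <- 0
        s <- s + subst[av[cols[k, 1]], bv[cols[k, 2]]]
      }
    }
    if (run > 0) s <- s - gap_open - gap_extend * run
    s
  }
  recurse <- function(i, j, cols) {
    if (i > length(av) && j > length(bv)) {
      if (nrow(cols) > 0) best <<- max(best, score_cols(cols))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1, j + 1, rbind(cols, c(i, j)))
    }
    if (i <= length(av)) recurse(i + 1, j, rbind(cols, c(i, 0)))
    if (j <= length(bv)) recurse(i, j + 1, rbind(cols, c(0, j)))
  }
  recurse(1, 1, matrix(0, 0, 2))
  best
}

# --- brute-force minimum-evolution tree search --------------------------
# Enumerates all unrooted binary topologies on n taxa (sequential leaf
# insertion), fits branch lengths by ordinary least squares and returns
# the splits of the minimum total-length topology.
enumerate_topologies <- function(n) {
  # edges as two-column matrices; leaves 1..n, internal nodes n+1, ...
  start <- matrix(c(n + 1, 1, n + 1, 2, n + 1, 3), ncol = 2, byrow = TRUE)
  tops <- list(list(edges = start, next_node = n + 2))
  for (leaf in seq(4, length.out = max(0, n - 3))) {
    new_tops <- list()
    for (tp in tops) {
      for (e in seq_len(nrow(tp$edges))) {
        ed <- tp$edges
        u <- ed[e, 1]
        v <- ed[e, 2]
        mid <- tp$next_node
        ed2 <- rbind(ed[-e, , drop = FALSE],
                     c(u, mid), c(mid, v), c(mid, leaf))
        new_tops[[length(new_tops) + 1]] <-
          list(edges = ed2, next_node = mid + 1)
      }
    }
    tops <- new_tops
  }
  tops
}

topo_paths <- function(edges, n) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(setNames(nodes, nodes), function(u) {
    c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1])
  })
  edge_id <- function(u, v) {
    which((edges[, 1] == u & edges[, 2] == v) |
            (edges[, 1] == v & edges[, 2] == u))
  }
  path_edges <- function(from, to) {
    # BFS on the tree
    prev <- setNames(rep(NA_integer_, length(nodes)), nodes)
    queue <- from
    seen <- as.character(from)
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      if (u == to) break
      for (w in adj[[as.character(u)]]) {
        if (!(as.character(w) %in% seen)) {
          seen <- c(seen, as.character(w))
          prev[as.character(w)] <- u
          queue <- c(queue, w)
        }
      }
    }
    path <- integer(0)
    cur <- to
    while (cur != from) {
      p <- prev[[as.character(cur)]]
      path <- c(path, edge_id(p, cur))
      cur <- p
    }
    path
  }
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (k in seq_len(nrow(pairs))) {
    A[k, path_edges(pairs[k, 1], pairs[k, 2])] <- 1
  }
  list(pairs = pairs, A = A)
}

topo_splits <- function(edges, n, labels) {
  # for each internal edge, the leaf set on one side (canonical: the
  # side not containing the lexicographically smallest label)
  ref_label <- min(labels)
  splits <- list()
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]
    v <- edges[e, 2]
    if (u <= n || v <= n) next
    ed2 <- edges[-e, , drop = FALSE]
    reach <- function(start) {
      seen <- start
      repeat {
        nb <- unique(c(ed2[ed2[, 1] %in% seen, 2],
                       ed2[ed2[, 2] %in% seen, 1]))
        newly <- setdiff(nb, seen)
        if (length(newly) == 0) break
        seen <- c(seen, newly)
      }
      seen
    }
    side <- intersect(reach(u), seq_len(n))
    if (ref_label %in% labels[side]) side <- setdiff(seq_len(n), side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      splits[[length(splits) + 1]] <- sort(labels[side])
    }
  }
  splits
}

oracle_me_splits <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  dv <- d[t(combn(n, 2))]
  best_len <- Inf
  best_splits <- NULL
  for (tp in enumerate_topologies(n)) {
    tpath <- topo_paths(tp$edges, n)
    A <- tpath$A
    b <- solve(crossprod(A), crossprod(A, dv))
    len <- sum(b)
    if (len < best_len - 1e-10) {
      best_len <- len
      best_splits <- topo_splits(tp$edges, n, labels)
    }
  }
  best_splits
}

# splits of an ape tree in the same canonical form
phylo_splits <- function(tree) {
  n <- ape::Ntip(tree)
  ref_label <- min(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- list()
  for (k in seq_along(pp)) {
    side <- tree$tip.label[pp[[k]]]
    other <- setdiff(tree$tip.label, side)
    if (ref_label %in% side) side <- other
    if (length(side) >= 2 && length(side) <= n - 2) {
      out[[length(out) + 1]] <- sort(side)
    }
  }
  unique(out)
}

same_split_sets <- function(a, b) {
  fa <- sort(vapply(a, paste, character(1), collapse = "|"))
  fb <- sort(vapply(b, paste, character(1), collapse = "|"))
  identical(unique(fa), unique(fb))
}
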