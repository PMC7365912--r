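# Naive reference implementations used as independent oracles. These favor
# transparency over speed: ancestor lists, all-pairs scans, exhaustive
# recursion.

# ancestor list (self first, then up to the root) per node of a phylo tree
oracle_ancestors <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  parent <- integer(n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  lapply(seq_len(n), function(v) {
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  })
}

# reconciliation by first principles: mapping = deepest common entry of the
# species ancestor lists of all descendant tip species; duplication = maps
# like a child; losses from ancestor-list length differences (origination
# charged from the species root)
oracle_reconcile <- function(gene_phy, sp_phy) {
  g_anc <- oracle_ancestors(gene_phy)
  s_anc <- oracle_ancestors(sp_phy)
  gn_tip <- length(gene_phy$tip.label)
  gn <- gn_tip + gene_phy$Nnode
  sp_of_tip <- match(sub("\\|.*$", "", gene_phy$tip.label), sp_phy$tip.label)
  g_parent <- integer(gn)
  g_parent[gene_phy$edge[, 2]] <- gene_phy$edge[, 1]
  desc_tips <- lapply(seq_len(gn), function(v)
    which(vapply(seq_len(gn_tip), function(t) v %in% g_anc[[t]], TRUE)))
  mapping <- vapply(seq_len(gn), function(v)
    Reduce(intersect, s_anc[sp_of_tip[desc_tips[[v]]]])[1], 0L)
  children <- lapply(seq_len(gn), function(v) which(g_parent == v))
  dup <- vapply(seq_len(gn), function(v)
    length(children[[v]]) > 0L && any(mapping[children[[v]]] == mapping[v]),
    TRUE)
  s_root <- setdiff(sp_phy$edge[, 1], sp_phy$edge[, 2])[1]
  losses <- 0L
  for (v in seq_len(gn)) {
    p <- g_parent[v]
    if (p == 0L) {
      losses <- losses + (length(s_anc[[mapping[v]]]) - length(s_anc[[s_root]]))
    } else if (mapping[p] != mapping[v]) {
      d <- length(s_anc[[mapping[v]]]) - length(s_anc[[mapping[p]]])
      losses <- losses + d - 1L + as.integer(dup[p])
    }
  }
  list(mapping = mapping, dup = dup,
       duplications = sum(dup), losses = losses)
}

# random rooted binary gene tree over a species set, tips "species|gN"
random_gene_tree <- function(n_leaves, species) {
  phy <- ape::rtree(n_leaves, rooted = TRUE)
  phy$edge.length <- NULL
  phy$tip.label <- paste0(sample(species, n_leaves, replace = TRUE),
                          "|g", seq_len(n_leaves))
  phy
}

# all-pairs union-find clustering: any two genes on one sequence whose
# intergenic gap is within the window end up in one component
oracle_cluster_partition <- function(genes, window) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (genes$seq_id[i] != genes$seq_id[j]) next
      gap <- max(genes$start[i], genes$start[j]) -
             min(genes$end[i], genes$end[j]) - 1L
      if (gap <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  unname(split(genes$gene_id, comp))
}

# random non-overlapping gene layout: intergenic gaps drawn around the
# clustering threshold so both cluster and singleton cases arise
random_layout <- function(n, n_chrom = 3L) {
  seqs <- sort(sample(seq_len(n_chrom), n, replace = TRUE))
  lens <- sample(2000:9000, n, replace = TRUE)
  start <- integer(n)
  for (s in unique(seqs)) {
    i <- which(seqs == s)
    gaps <- sample.int(500000L, length(i), replace = TRUE)
    start[i] <- cumsum(gaps + c(0L, lens[i][-length(i)]))
  }
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             seq_id = sprintf("chr%d", seqs),
             start = start, end = start + lens - 1L,
             stringsAsFactors = FALSE)
}

# exhaustive search for the longest valid anchor chain (either orientation)
oracle_max_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0L
  for (orient in c(1L, -1L)) {
    rec <- function(last, count) {
      if (count > best) best <<- count
      for (nx in seq_len(n)) {
        ok <- if (last == 0L) TRUE else {
          da <- ra[nx] - ra[last]
          db <- orient * (rb[nx] - rb[last])
          da >= 1L && da <= max_gap && db >= 1L && db <= max_gap
        }
        if (ok) rec(nx, count + 1L)
      }
    }
    rec(0L, 0L)
  }
  best
}

# exhaustive best total score of ordered, non-overlapping candidate windows
# (one window per motif at most, motifs in fixed order)
oracle_best_ordered_score <- function(cand, n_motifs = 6L) {
  rec <- function(mi, min_start) {
    if (mi > n_motifs) return(0)
    best <- rec(mi + 1L, min_start)
    rows <- which(cand$motif_i == mi & cand$start >= min_start)
    for (r in rows) {
      best <- max(best, cand$score[r] + rec(mi + 1L, cand$end[r] + 1L))
    }
    best
  }
  rec(1L, 1L)
}

# candidate windows for one sequence under the packaged scoring (naive loop)
oracle_candidates <- function(seq, seeds, score_frac = 0.25) {
  aa <- strsplit(seq, "")[[1]]
  out <- list()
  for (mi in seq_len(nrow(seeds))) {
    pwm <- nlrtrace:::seed_pwm(seeds[mi, ])
    w <- seeds$width[mi]
    thr <- score_frac * sum(apply(pwm, 2, max))
    for (s in seq_len(nchar(seq) - w + 1L)) {
      sc <- 0
      for (k in seq_len(w)) {
        row <- match(aa[s + k - 1L], rownames(pwm))
        if (!is.na(row)) sc <- sc + pwm[row, k]
      }
      if (sc >= thr) {
        out[[length(out) + 1L]] <- data.frame(motif_i = mi, start = s,
                                              end = s + w - 1L, score = sc)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(motif_i = integer(0), start = integer(0), end = integer(0),
               score = numeric(0))
}
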