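# Simplified collinearity detection (anchor chaining over gene-rank
# dot-plots) and duplicate-type classification (tandem / dispersed /
# WGD-segmental), mirroring the MCScanX duplicate_gene_classifier hierarchy.

#' Gene ranks along each sequence
#'
#' Ranks genes by start position within each (genome, sequence); ranks are
#' the gene-order coordinates used by the collinearity chainer.
#'
#' @param genes data.frame with `gene_id`, `genome_id`, `seq_id`, `start`.
#' @return `genes` with an integer `rank` column added (NA for genes with a
#'   missing `seq_id`, i.e. unanchored genes).
#' @export
gene_ranks <- function(genes) {
  genes$rank <- NA_integer_
  anchored <- !is.na(genes$seq_id)
  key <- paste(genes$genome_id[anchored], genes$seq_id[anchored], sep = "\r")
  for (k in unique(key)) {
    i <- which(anchored)[key == k]
    genes$rank[i[order(genes$start[i])]] <- seq_along(i)
  }
  genes
}

#' Find collinear blocks by anchor chaining
#'
#' Anchors are homolog pairs whose two genes are both rank-anchored. For each
#' pair of sequences, maximal chains of anchors are found by dynamic
#' programming over the rank dot-plot: consecutive anchors must be within
#' `max_gap` ranks on both axes and strictly monotone (increasing on both for
#' "same" orientation, decreasing on the second for "inverted"). Chains with
#' at least `min_anchors` anchors are reported; overlapping chains are
#' resolved greedily by descending anchor count (each anchor is used once).
#'
#' @param genes rank-annotated gene table from [gene_ranks()].
#' @param pairs homolog pairs (`gene_a`, `gene_b`, `score`).
#' @param min_anchors minimum anchors per reported block (default 5, the
#'   MCScanX default).
#' @param max_gap maximum rank gap between consecutive anchors (default 25,
#'   the MCScanX default).
#' @return list with `blocks` (data.frame: `block_id`, `genome_a`, `seq_a`,
#'   `genome_b`, `seq_b`, `n_anchors`, `orientation`) and `anchors`
#'   (data.frame: `block_id`, `gene_a`, `gene_b`, `rank_a`, `rank_b`).
#' @export
find_collinear_blocks <- function(genes, pairs, min_anchors = 5,
                                  max_gap = 25) {
  gi <- match(pairs$gene_a, genes$gene_id)
  gj <- match(pairs$gene_b, genes$gene_id)
  ok <- !is.na(gi) & !is.na(gj) & !is.na(genes$rank[gi]) & !is.na(genes$rank[gj])
  empty <- list(
    blocks = data.frame(block_id = character(0), genome_a = character(0),
                        seq_a = character(0), genome_b = character(0),
                        seq_b = character(0), n_anchors = integer(0),
                        orientation = character(0)),
    anchors = data.frame(block_id = character(0), gene_a = character(0),
                         gene_b = character(0), rank_a = integer(0),
                         rank_b = integer(0)))
  if (!any(ok)) return(empty)
  gi <- gi[ok]; gj <- gj[ok]
  # orient each anchor so (genome_a, seq_a) <= (genome_b, seq_b); on the same
  # sequence keep rank_a < rank_b so mirror-image chains are not duplicated
  key_i <- paste(genes$genome_id[gi], genes$seq_id[gi], sep = "\r")
  key_j <- paste(genes$genome_id[gj], genes$seq_id[gj], sep = "\r")
  swap <- key_i > key_j | (key_i == key_j & genes$rank[gi] > genes$rank[gj])
  a <- ifelse(swap, gj, gi); b <- ifelse(swap, gi, gj)
  anc <- data.frame(
    gene_a = genes$gene_id[a], gene_b = genes$gene_id[b],
    genome_a = genes$genome_id[a], seq_a = genes$seq_id[a],
    genome_b = genes$genome_id[b], seq_b = genes$seq_id[b],
    rank_a = genes$rank[a], rank_b = genes$rank[b],
    stringsAsFactors = FALSE)
  blocks <- list(); anchors_out <- list(); bid <- 0L
  for (grp in split(anc, paste(anc$genome_a, anc$seq_a, anc$genome_b,
                               anc$seq_b, sep = "\r"))) {
    grp <- grp[order(grp$rank_a, grp$rank_b), , drop = FALSE]
    avail <- rep(TRUE, nrow(grp))
    repeat {
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- chain_anchors(grp[avail, , drop = FALSE], orient, max_gap)
        if (!is.null(ch) && (is.null(best) || length(ch$idx) >
                             length(best$idx))) {
          ch$which <- which(avail)[ch$idx]
          best <- ch
        }
      }
      if (is.null(best) || length(best$idx) < min_anchors) break
      bid <- bid + 1L
      id <- sprintf("block%03d", bid)
      sel <- grp[best$which, , drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = id, genome_a = sel$genome_a[1], seq_a = sel$seq_a[1],
        genome_b = sel$genome_b[1], seq_b = sel$seq_b[1],
        n_anchors = nrow(sel), orientation = best$orient,
        stringsAsFactors = FALSE)
      anchors_out[[bid]] <- data.frame(
        block_id = id, gene_a = sel$gene_a, gene_b = sel$gene_b,
        rank_a = sel$rank_a, rank_b = sel$rank_b, stringsAsFactors = FALSE)
      avail[best$which] <- FALSE
    }
  }
  if (bid == 0L) return(empty)
  list(blocks = do.call(rbind, blocks), anchors = do.call(rbind, anchors_out))
}

# longest chain (by anchor count) under the gap/monotonicity constraints;
# anchors come sorted by (rank_a, rank_b)
chain_anchors <- function(anc, orient, max_gap) {
  n <- nrow(anc)
  if (n == 0L) return(NULL)
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- anc$rank_a[i] - anc$rank_a[j]
      db <- if (orient == "same") anc$rank_b[i] - anc$rank_b[j]
            else anc$rank_b[j] - anc$rank_b[i]
      if (da >= 1L && da <= max_gap && db >= 1L && db <= max_gap &&
          len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  idx <- integer(0)
  while (i != 0L) { idx <- c(i, idx); i <- prev[i] }
  list(idx = idx, orient = orient)
}

#' Classify NBS-gene duplication types
#'
#' Priority order per gene: "unanchored" when the gene has no chromosome;
#' "WGD/segmental" when it is an anchor of a within-genome collinear block;
#' "tandem" when it has a homolog on the same sequence within
#' `tandem_max_rank_gap` ranks; "dispersed" when it has any other homolog.
#' Genes with no homolog at all are called dispersed with no evidence and
#' flagged `singleton_origin`.
#'
#' @param nbs_genes rank-annotated gene table (one genome) restricted to NBS
#'   genes; unanchored genes have `seq_id` NA.
#' @param pairs within-genome homolog pairs.
#' @param blocks result of [find_collinear_blocks()] run within the genome.
#' @param tandem_max_rank_gap maximum rank difference for a tandem call
#'   (default 1 = adjacent genes).
#' @return list with `calls` (data.frame: `gene_id`, `type`, `evidence`,
#'   `singleton_origin`) and `summary` (from [duptype_summary()]).
#' @export
classify_duplication_types <- function(nbs_genes, pairs, blocks,
                                       tandem_max_rank_gap = 1) {
  anchor_genes <- unique(c(blocks$anchors$gene_a, blocks$anchors$gene_b))
  anchor_block <- c(stats::setNames(blocks$anchors$block_id,
                                    blocks$anchors$gene_a),
                    stats::setNames(blocks$anchors$block_id,
                                    blocks$anchors$gene_b))
  loc <- stats::setNames(seq_len(nrow(nbs_genes)), nbs_genes$gene_id)
  partner <- function(g) {
    i <- which(pairs$gene_a == g | pairs$gene_b == g)
    if (!length(i)) return(character(0))
    ifelse(pairs$gene_a[i] == g, pairs$gene_b[i], pairs$gene_a[i])
  }
  rows <- lapply(seq_len(nrow(nbs_genes)), function(i) {
    g <- nbs_genes[i, ]
    singleton <- FALSE
    if (is.na(g$seq_id)) {
      type <- "unanchored"; evidence <- NA_character_
    } else if (g$gene_id %in% anchor_genes) {
      type <- "WGD/segmental"; evidence <- unname(anchor_block[g$gene_id])
    } else {
      mates <- partner(g$gene_id)
      j <- match(mates, nbs_genes$gene_id)
      same_seq <- !is.na(j) & !is.na(nbs_genes$seq_id[j]) &
        nbs_genes$seq_id[j] == g$seq_id &
        abs(nbs_genes$rank[j] - g$rank) <= tandem_max_rank_gap
      if (any(same_seq)) {
        type <- "tandem"; evidence <- mates[which(same_seq)[1]]
      } else if (length(mates)) {
        type <- "dispersed"; evidence <- mates[1]
      } else {
        type <- "dispersed"; evidence <- NA_character_; singleton <- TRUE
      }
    }
    data.frame(gene_id = g$gene_id, type = type, evidence = evidence,
               singleton_origin = singleton, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  list(calls = calls, summary = duptype_summary(calls))
}

#' Summary of duplication-type calls
#'
#' Counts and percentages (of all NBS genes, rounded half-up to 1 decimal)
#' per duplication type, in the fixed order tandem, dispersed,
#' WGD/segmental, unanchored.
#'
#' @param calls data.frame with a `type` column (or the `calls` element from
#'   [classify_duplication_types()]).
#' @return data.frame: `type`, `n`, `pct`.
#' @export
duptype_summary <- function(calls) {
  types <- c("tandem", "dispersed", "WGD/segmental", "unanchored")
  n <- vapply(types, function(t) sum(calls$type == t), 0L)
  data.frame(type = types, n = unname(n),
             pct = round_half_up(100 * unname(n) / max(1L, nrow(calls)), 1),
             stringsAsFactors = FALSE)
}

#' Syntenic NBS gene pairs between two genomes
#'
#' Restricts cross-genome block anchors to pairs where both genes are NBS
#' genes and labels each pair by the cluster/singleton status of its two
#' ends. NBS genes that lie inside the rank span of a block on their own
#' genome but have no syntenic NBS partner are counted as presence/absence
#' polymorphic ("private").
#'
#' @param blocks cross-genome result of [find_collinear_blocks()].
#' @param genes rank-annotated gene table covering both genomes.
#' @param nbs_ids character vector of NBS gene ids (both genomes).
#' @param clusters_a,clusters_b results of [assign_clusters()] for the two
#'   genomes (used for the cluster/singleton end labels).
#' @return list with `pairs` (data.frame: `gene_a`, `gene_b`, `block_id`,
#'   `form`) and `n_private` (named vector: private NBS genes per genome).
#' @export
syntenic_nbs_pairs <- function(blocks, genes, nbs_ids, clusters_a,
                               clusters_b) {
  clustered <- c(
    unlist(strsplit(clusters_a$clusters$members, ",")),
    unlist(strsplit(clusters_b$clusters$members, ",")))
  status <- function(g) if (g %in% clustered) "cluster" else "singleton"
  anc <- blocks$anchors
  both_nbs <- anc$gene_a %in% nbs_ids & anc$gene_b %in% nbs_ids
  sel <- anc[both_nbs, , drop = FALSE]
  form <- vapply(seq_len(nrow(sel)), function(i) {
    ends <- sort(c(status(sel$gene_a[i]), status(sel$gene_b[i])))
    paste(ends, collapse = "-to-")
  }, "")
  pairs <- data.frame(gene_a = sel$gene_a, gene_b = sel$gene_b,
                      block_id = sel$block_id,
                      form = if (nrow(sel)) form else character(0),
                      stringsAsFactors = FALSE)
  # private NBS genes: inside a block's rank span on their genome, but in no
  # syntenic NBS pair
  in_pair <- unique(c(pairs$gene_a, pairs$gene_b))
  spans <- list()
  for (id in unique(anc$block_id)) {
    ba <- anc[anc$block_id == id, ]
    g1 <- genes$genome_id[match(ba$gene_a[1], genes$gene_id)]
    g2 <- genes$genome_id[match(ba$gene_b[1], genes$gene_id)]
    s1 <- genes$seq_id[match(ba$gene_a[1], genes$gene_id)]
    s2 <- genes$seq_id[match(ba$gene_b[1], genes$gene_id)]
    spans[[length(spans) + 1L]] <- data.frame(
      genome = g1, seq = s1, lo = min(ba$rank_a), hi = max(ba$rank_a))
    spans[[length(spans) + 1L]] <- data.frame(
      genome = g2, seq = s2, lo = min(ba$rank_b), hi = max(ba$rank_b))
  }
  n_private <- stats::setNames(integer(0), character(0))
  if (length(spans)) {
    spans <- do.call(rbind, spans)
    nbs <- genes[genes$gene_id %in% nbs_ids & !is.na(genes$rank), ]
    private <- vapply(seq_len(nrow(nbs)), function(i) {
      if (nbs$gene_id[i] %in% in_pair) return(FALSE)
      any(spans$genome == nbs$genome_id[i] & spans$seq == nbs$seq_id[i] &
          spans$lo <= nbs$rank[i] & nbs$rank[i] <= spans$hi)
    }, TRUE)
    n_private <- tapply(private, nbs$genome_id, sum)
    n_private <- stats::setNames(as.integer(n_private), names(n_private))
  }
  list(pairs = pairs, n_private = n_private)
}
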