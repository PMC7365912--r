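# Chromosomal cluster assignment for NBS-encoding genes: two neighboring
# genes on one chromosome within the distance window belong to one cluster.

#' Assign NBS genes to clusters and singletons
#'
#' Genes are sorted by start position within each chromosome; two neighbors
#' join the same cluster when their distance is at most `window` (inclusive
#' at exactly `window`), and clusters are the transitive closure of that
#' relation. Remaining genes are singletons. All input genes must be
#' chromosome-anchored; drop unanchored scaffolds beforehand.
#'
#' @param genes data.frame with columns `gene_id`, `seq_id`, `start`, `end`.
#' @param window distance threshold in bp (default 250000, i.e. 250 kb).
#' @param distance_mode `"gap"` (default) measures the intergenic gap
#'   `start(next) - end(prev) - 1`; `"start"` measures start-to-start
#'   distance `start(next) - start(prev)`.
#' @return list with `clusters` (data.frame: `cluster_id`, `seq_id`,
#'   `n_genes`, `span`, `members` comma-joined in start order) and
#'   `singletons` (character vector of gene ids).
#' @export
assign_clusters <- function(genes, window = 250000,
                            distance_mode = c("gap", "start")) {
  distance_mode <- match.arg(distance_mode)
  if (nrow(genes) == 0L) {
    return(list(clusters = data.frame(cluster_id = character(0),
                                      seq_id = character(0),
                                      n_genes = integer(0), span = integer(0),
                                      members = character(0)),
                singletons = character(0)))
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids")
  genes <- genes[order(genes$seq_id, genes$start, genes$end), , drop = FALSE]
  clusters <- list(); singletons <- character(0); k <- 0L
  for (chrom in unique(genes$seq_id)) {
    g <- genes[genes$seq_id == chrom, , drop = FALSE]
    n <- nrow(g)
    if (n == 1L) { singletons <- c(singletons, g$gene_id); next }
    d <- if (distance_mode == "gap") g$start[-1] - g$end[-n] - 1
         else g$start[-1] - g$start[-n]
    joined <- d <= window
    grp <- cumsum(c(TRUE, !joined))
    for (members in split(seq_len(n), grp)) {
      if (length(members) == 1L) {
        singletons <- c(singletons, g$gene_id[members])
      } else {
        k <- k + 1L
        clusters[[k]] <- data.frame(
          cluster_id = sprintf("%s_cl%02d", chrom, sum(
            vapply(clusters, function(cl) cl$seq_id == chrom, TRUE)) + 1L),
          seq_id = chrom, n_genes = length(members),
          span = g$end[members[length(members)]] - g$start[members[1]] + 1L,
          members = paste(g$gene_id[members], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = character(0), seq_id = character(0),
               n_genes = integer(0), span = integer(0), members = character(0))
  list(clusters = clusters, singletons = singletons)
}

#' Cluster organization statistics
#'
#' Summary in the shape of a genome-organization table: anchored loci and
#' genes, singleton and clustered loci, the clustered/singleton gene ratio,
#' mean cluster size, number of large (>= 10 gene) clusters, and the largest
#' cluster. Ratio and mean are rounded half-up to 2 decimals; with no
#' singletons the ratio is `Inf`, with no clusters the mean is `NA`.
#'
#' @param assignment result of [assign_clusters()].
#' @return one-row data.frame of statistics.
#' @export
cluster_statistics <- function(assignment) {
  cl <- assignment$clusters
  n_clustered_genes <- sum(cl$n_genes)
  n_singletons <- length(assignment$singletons)
  largest <- if (nrow(cl)) which.max(cl$n_genes) else NA_integer_
  data.frame(
    n_anchored_loci = nrow(cl) + n_singletons,
    n_anchored_genes = n_clustered_genes + n_singletons,
    n_singleton_loci = n_singletons,
    n_clustered_loci = nrow(cl),
    n_clustered_genes = n_clustered_genes,
    clustered_singleton_ratio = if (n_clustered_genes == 0L) 0 else
      if (n_singletons == 0L) Inf else
        round_half_up(n_clustered_genes / n_singletons, 2),
    mean_genes_per_cluster = if (nrow(cl) == 0L) NA_real_ else
      round_half_up(n_clustered_genes / nrow(cl), 2),
    n_clusters_ge10 = sum(cl$n_genes >= 10L),
    largest_cluster_size = if (is.na(largest)) 0L else cl$n_genes[largest],
    largest_cluster_seq = if (is.na(largest)) NA_character_ else
      cl$seq_id[largest],
    stringsAsFactors = FALSE)
}

#' Per-chromosome, per-subclass gene counts
#'
#' @param genes data.frame with `seq_id` and `subclass` columns (classified,
#'   anchored genes).
#' @param chromosomes optional character vector of chromosomes to report;
#'   chromosomes with no NBS gene keep an all-zero row.
#' @return data.frame: one row per chromosome with one column per subclass
#'   plus a `total` column, and a final "total" row.
#' @export
chromosome_distribution <- function(genes, chromosomes = NULL) {
  if (is.null(chromosomes)) chromosomes <- sort(unique(genes$seq_id))
  tab <- table(factor(genes$seq_id, levels = chromosomes),
               factor(genes$subclass, levels = SUBCLASSES))
  out <- as.data.frame.matrix(tab)
  out <- cbind(seq_id = rownames(out), out, total = rowSums(out))
  rownames(out) <- NULL
  rbind(out, data.frame(seq_id = "total", TNL = sum(out$TNL),
                        CNL = sum(out$CNL), RNL = sum(out$RNL),
                        total = sum(out$total)))
}
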