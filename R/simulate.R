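# Synthetic-data generators. Every generator is deterministic under a fixed
# seed and returns ground-truth labels alongside the data, so every analysis
# stage can be tested against known truth without external downloads.

#' Simulate a gene family by birth-death along a species tree
#'
#' Each gene copy evolves independently along every species-tree branch under
#' a continuous-time birth-death process (exponential waiting times;
#' duplication with rate `dup_rate`, loss with rate `loss_rate`); copies
#' surviving to a speciation node continue into both child branches. The
#' returned gene trees are pruned to extant genes (extinct subtrees and
#' pass-through nodes removed). Leaves are labelled `"species|geneN"`.
#'
#' @param species_tree rooted binary `phylo`; branch lengths default to 1
#'   where absent.
#' @param dup_rate,loss_rate per-branch rates (events per copy per unit
#'   time); a scalar, or a named vector keyed by the branch's child node
#'   label.
#' @param root_copies number of independent gene copies at the species root.
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with `trees` (list of newick strings, one per root copy with
#'   extant descendants), `leaf_map` (data.frame `leaf`, `species`),
#'   `extinct` (TRUE when no gene survived) and `truth`: per-branch
#'   `duplications` and `losses` (named by the branch's child node, all
#'   events counted, including in extinct subtrees), per-node `copies`
#'   (lineages reaching each species node) and `copies_surviving` (those
#'   with at least one extant descendant).
#' @export
simulate_gene_family <- function(species_tree = default_species_tree(),
                                 dup_rate = 0.1, loss_rate = 0.1,
                                 root_copies = 1L, seed = NULL) {
  stopifnot(all(dup_rate >= 0), all(loss_rate >= 0), root_copies >= 1L)
  if (!is.null(seed)) set.seed(seed)
  st <- species_index(species_tree)
  blen <- rep(1, st$n)
  if (!is.null(species_tree$edge.length)) {
    blen[species_tree$edge[, 2]] <- species_tree$edge.length
  }
  expand_rate <- function(r) {
    if (is.null(names(r))) rep(r[1], st$n)
    else {
      out <- rep(0, st$n)
      out[match(names(r), st$label)] <- r
      out
    }
  }
  lam <- expand_rate(dup_rate); mu <- expand_rate(loss_rate)
  env <- new.env(parent = emptyenv())
  env$dups <- stats::setNames(numeric(st$n), st$label)
  env$losses <- stats::setNames(numeric(st$n), st$label)
  env$copies <- stats::setNames(numeric(st$n), st$label)
  env$copies_surviving <- stats::setNames(numeric(st$n), st$label)
  env$gene_i <- 0L
  evolve <- function(sp, t_left) {   # one lineage along the branch above sp
    total <- lam[sp] + mu[sp]
    t <- if (total > 0) stats::rexp(1, total) else Inf
    if (t >= t_left) return(arrive(sp))
    if (stats::runif(1) < lam[sp] / total) {
      env$dups[sp] <- env$dups[sp] + 1
      a <- evolve(sp, t_left - t)
      b <- evolve(sp, t_left - t)
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      list(kids = list(a, b))
    } else {
      env$losses[sp] <- env$losses[sp] + 1
      NULL
    }
  }
  arrive <- function(sp) {           # one lineage reaching species node sp
    env$copies[sp] <- env$copies[sp] + 1
    kids <- st$children[[sp]]
    res <- if (length(kids) == 0L) {
      env$gene_i <- env$gene_i + 1L
      list(label = paste0(st$label[sp], "|gene", env$gene_i))
    } else {
      a <- evolve(kids[1], blen[kids[1]])
      b <- evolve(kids[2], blen[kids[2]])
      if (is.null(a) && is.null(b)) NULL
      else if (is.null(a)) b
      else if (is.null(b)) a
      else list(kids = list(a, b))
    }
    if (!is.null(res))
      env$copies_surviving[sp] <- env$copies_surviving[sp] + 1
    res
  }
  to_newick <- function(node) {
    if (!is.null(node$label)) return(node$label)
    paste0("(", paste(vapply(node$kids, to_newick, ""), collapse = ","), ")")
  }
  collect_leaves <- function(node) {
    if (!is.null(node$label)) return(node$label)
    unlist(lapply(node$kids, collect_leaves))
  }
  roots <- lapply(seq_len(root_copies), function(i) arrive(st$root))
  roots <- Filter(Negate(is.null), roots)
  trees <- lapply(roots, function(r) paste0(
    if (is.null(r$label)) to_newick(r) else paste0("(", r$label, ")"), ";"))
  leaves <- unlist(lapply(roots, collect_leaves))
  leaf_map <- data.frame(leaf = if (is.null(leaves)) character(0) else leaves,
                         species = if (is.null(leaves)) character(0) else
                           sub("\\|.*$", "", leaves),
                         stringsAsFactors = FALSE)
  list(trees = trees, leaf_map = leaf_map, extinct = length(roots) == 0L,
       truth = list(duplications = env$dups, losses = env$losses,
                    copies = env$copies,
                    copies_surviving = env$copies_surviving))
}

#' Simulate a chromosomal gene layout with clusters and singletons
#'
#' Places cluster loci and singleton loci round-robin across chromosomes.
#' Within a cluster consecutive genes are separated by an intergenic gap of
#' exactly `intra_gap` bp; consecutive loci are separated by `inter_gap` bp.
#' With `intra_gap < window < inter_gap` the 250-kb cluster rule recovers the
#' constructed partition exactly.
#'
#' @param n_clusters number of cluster loci (default 39).
#' @param cluster_sizes integer vector of cluster sizes (length
#'   `n_clusters`); default draws `2 + rpois(1.4)` genes per cluster.
#' @param n_singletons number of singleton loci (default 44).
#' @param n_chromosomes number of chromosomes (default 15).
#' @param intra_gap intergenic gap within clusters, bp (default 200000).
#' @param inter_gap gap between consecutive loci, bp (default 300000).
#' @param gene_length gene span in bp (default 6000).
#' @param seed integer seed.
#' @return list with `genes` (gene-model data.frame as from [read_gff3()])
#'   and `truth` (data.frame: `gene_id`, `seq_id`, `locus_type`
#'   "clustered"/"singleton", `cluster_id`).
#' @export
simulate_genome_layout <- function(n_clusters = 39, cluster_sizes = NULL,
                                   n_singletons = 44, n_chromosomes = 15,
                                   intra_gap = 200000, inter_gap = 300000,
                                   gene_length = 6000, seed = NULL) {
  stopifnot(intra_gap < inter_gap)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cluster_sizes)) {
    cluster_sizes <- if (n_clusters > 0)
      2L + stats::rpois(n_clusters, 1.4) else integer(0)
  }
  stopifnot(length(cluster_sizes) == n_clusters, all(cluster_sizes >= 2L))
  loci <- c(lapply(seq_len(n_clusters), function(i)
              list(type = "clustered", size = cluster_sizes[i], id = i)),
            lapply(seq_len(n_singletons), function(i)
              list(type = "singleton", size = 1L, id = NA_integer_)))
  if (length(loci) == 0L) {
    return(list(genes = data.frame(), truth = data.frame()))
  }
  loci <- loci[sample.int(length(loci))]
  pos <- rep(10000, n_chromosomes)
  rows <- list(); gid <- 0L
  for (k in seq_along(loci)) {
    chrom <- (k - 1L) %% n_chromosomes + 1L
    lc <- loci[[k]]
    for (j in seq_len(lc$size)) {
      gid <- gid + 1L
      start <- pos[chrom]
      end <- start + gene_length - 1L
      rows[[gid]] <- data.frame(
        gene_id = sprintf("simg%04d", gid), genome_id = "simgenome",
        seq_id = sprintf("chr%02d", chrom), start = start, end = end,
        strand = sample(c("+", "-"), 1), cds_length = round(gene_length / 2),
        gene_length = gene_length,
        locus_type = lc$type,
        cluster_id = if (is.na(lc$id)) NA_character_ else
          sprintf("true_cl%03d", lc$id),
        stringsAsFactors = FALSE)
      pos[chrom] <- end + (if (j < lc$size) intra_gap else inter_gap) + 1L
    }
  }
  all_rows <- do.call(rbind, rows)
  list(genes = all_rows[, c("gene_id", "genome_id", "seq_id", "start", "end",
                            "strand", "cds_length", "gene_length")],
       truth = all_rows[, c("gene_id", "seq_id", "locus_type", "cluster_id")])
}

# letters string for a (subclass, category) combination
category_letters <- function(subclass, category) {
  x <- substr(subclass, 1, 1)
  switch(category,
         intact = paste0(x, "NL"),
         NL = "NL",
         N = "N",
         Other = c(CNL = "CNLCNL", TNL = "TNTN", RNL = "RNRN")[[subclass]],
         { stopifnot(category == paste0(x, "N")); paste0(x, "N") })
}

#' Simulate domain-hit tables with known architectures
#'
#' Generates per-gene ordered domain hits realizing a chosen count of genes
#' per (subclass, structural category). Each architecture letter emits one
#' domain hit except LRR, which emits a short run of consecutive LRR hits to
#' exercise adjacent-repeat collapsing. E-values are drawn below 1e-6.
#' Truncated (N/NL) genes carry no N-terminal domain, so the true subclass is
#' also emitted as a neighbor hint.
#'
#' @param counts data.frame with columns `subclass`, `category`, `n`;
#'   defaults to the X. sorbifolium column of the family table (180 genes).
#' @param seed integer seed.
#' @return list with `hits` (domain-hit data.frame), `hints` (data.frame
#'   `gene_id`, `subclass` for N/NL genes) and `truth` (data.frame:
#'   `gene_id`, `subclass`, `category`, `letters`).
#' @export
simulate_architectures <- function(counts = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(counts)) {
    counts <- data.frame(
      subclass = rep(c("TNL", "CNL", "RNL"), each = 5),
      category = c("intact", "TN", "NL", "N", "Other",
                   "intact", "CN", "NL", "N", "Other",
                   "intact", "RN", "NL", "N", "Other"),
      n = c(24, 0, 5, 3, 0, 55, 27, 45, 18, 1, 2, 0, 0, 0, 0))
  }
  dom_of <- c(T = "TIR", C = "CC", R = "RPW8", N = "NBS", L = "LRR")
  dom_len <- c(TIR = 120L, CC = 60L, RPW8 = 80L, NBS = 250L, LRR = 25L)
  hits <- list(); truth <- list(); hints <- list(); gid <- 0L
  for (i in seq_len(nrow(counts))) {
    if (counts$n[i] == 0) next
    sc <- counts$subclass[i]; cat <- counts$category[i]
    letters <- category_letters(sc, cat)
    for (r in seq_len(counts$n[i])) {
      gid <- gid + 1L
      gene <- sprintf("arch_g%04d", gid)
      pos <- 1L + sample.int(20L, 1)
      hrows <- list()
      for (ch in strsplit(letters, "")[[1]]) {
        dom <- dom_of[[ch]]
        reps <- if (ch == "L") 2L + sample.int(3L, 1) else 1L
        for (rr in seq_len(reps)) {
          hrows[[length(hrows) + 1L]] <- data.frame(
            gene_id = gene, domain_label = dom, ali_start = pos,
            ali_end = pos + dom_len[[dom]] - 1L,
            evalue = 10^-(6 + stats::runif(1) * 6),
            stringsAsFactors = FALSE)
          pos <- pos + dom_len[[dom]] + 5L + sample.int(10L, 1)
        }
      }
      hits[[gid]] <- do.call(rbind, hrows)
      truth[[gid]] <- data.frame(gene_id = gene, subclass = sc,
                                 category = cat, letters = letters,
                                 stringsAsFactors = FALSE)
      if (letters %in% c("N", "NL")) {
        hints[[length(hints) + 1L]] <- data.frame(gene_id = gene,
                                                  subclass = sc,
                                                  stringsAsFactors = FALSE)
      }
    }
  }
  list(hits = if (length(hits)) do.call(rbind, hits) else
         data.frame(gene_id = character(0), domain_label = character(0),
                    ali_start = integer(0), ali_end = integer(0),
                    evalue = numeric(0)),
       hints = if (length(hints)) do.call(rbind, hints) else
         data.frame(gene_id = character(0), subclass = character(0)),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(gene_id = character(0), subclass = character(0),
                    category = character(0), letters = character(0)))
}

#' Simulate NBS-domain sequences with planted motif signatures
#'
#' Builds one sequence per gene: random flanks and spacers around the six
#' motif consensi of the gene's subclass (from [motif_seeds()]), padded to at
#' least `min_length` residues, then applies per-position substitution noise
#' (each residue is replaced by a uniform draw from the 19 other amino acids
#' with probability `noise_rate`).
#'
#' @param n named integer vector: sequences per subclass (default
#'   `c(CNL = 300, TNL = 150, RNL = 50)`, CNL-dominant as in real NBS gene
#'   families).
#' @param noise_rate per-position substitution probability (default 0.2).
#' @param seeds seed table from [motif_seeds()].
#' @param min_length minimum sequence length (default 190).
#' @param seed integer seed.
#' @return list with `seqs` (named character vector), `truth` (named
#'   subclass vector) and `planted` (data.frame: `seq_id`, `motif`, `start`
#'   of each planted motif).
#' @export
simulate_motif_alignment <- function(n = c(CNL = 300, TNL = 150, RNL = 50),
                                     noise_rate = 0.2, seeds = motif_seeds(),
                                     min_length = 190, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(n) %in% SUBCLASSES), noise_rate >= 0, noise_rate <= 1)
  rand_aa <- function(k) paste(sample(AA_ALPHABET, k, replace = TRUE),
                               collapse = "")
  seqs <- character(0); truth <- character(0); planted <- list()
  for (sc in names(n)) {
    for (i in seq_len(n[[sc]])) {
      id <- sprintf("%s_seq%04d", sc, i)
      parts <- rand_aa(10L + sample.int(6L, 1))
      starts <- integer(nrow(seeds))
      for (mi in seq_len(nrow(seeds))) {
        starts[mi] <- nchar(parts) + 1L
        spacer <- rand_aa(18L + sample.int(10L, 1))
        parts <- paste0(parts, seeds[[sc]][mi],
                        if (mi < nrow(seeds)) spacer else "")
      }
      if (nchar(parts) < min_length) {
        parts <- paste0(parts, rand_aa(min_length - nchar(parts)))
      }
      if (noise_rate > 0) {
        ch <- strsplit(parts, "")[[1]]
        hit <- stats::runif(length(ch)) < noise_rate
        if (any(hit)) {
          ch[hit] <- vapply(ch[hit], function(a)
            sample(setdiff(AA_ALPHABET, a), 1), "")
          parts <- paste(ch, collapse = "")
        }
      }
      seqs[id] <- parts
      truth[id] <- sc
      planted[[id]] <- data.frame(seq_id = id, motif = seeds$motif,
                                  start = starts, stringsAsFactors = FALSE)
    }
  }
  list(seqs = seqs, truth = truth, planted = do.call(rbind, planted))
}

#' Simulate two genomes with tandem, segmental and dispersed duplicates
#'
#' Builds a base genome ("genomeA") of background genes on `n_chromosomes`
#' chromosomes, then plants NBS-gene duplication features in rank slots
#' spaced more than `max_gap` apart so features cannot chain into each other:
#' tandem arrays (adjacent homologous NBS genes), segmental blocks (a run of
#' `segmental_size` genes, alternating NBS/background, duplicated to another
#' chromosome with one homolog pair per gene), dispersed NBS copies (a
#' single homolog at a distant locus), one NBS gene with no homolog at all,
#' and unanchored NBS genes. A second genome ("genomeB") carries one ortholog
#' per genome-A gene in the same order (cross-genome pairs), except for
#' `n_missing_orthologs` NBS genes deleted from genomeB to create
#' presence/absence polymorphism.
#'
#' @param genes_per_chrom background genes per chromosome (default 300).
#' @param n_chromosomes chromosomes in each genome (default 2).
#' @param n_tandem_arrays number of tandem arrays (default 4).
#' @param tandem_size genes per tandem array (default 2).
#' @param n_segmental_blocks number of segmentally duplicated runs
#'   (default 1).
#' @param segmental_size genes per segmental run (default 6; keep at or
#'   above the chainer's `min_anchors`).
#' @param n_dispersed number of dispersed duplicate pairs (default 4).
#' @param n_unanchored NBS genes without a chromosome (default 2).
#' @param n_missing_orthologs NBS genes absent from genomeB (default 2).
#' @param max_gap the chainer rank gap the slot spacing must exceed
#'   (default 25).
#' @param seed integer seed.
#' @return list with `genes` (rank-annotated gene table, both genomes),
#'   `pairs_within` (genomeA homolog pairs), `pairs_cross` (genomeA-genomeB
#'   ortholog pairs), `nbs_ids` (character vector over both genomes), `truth`
#'   (data.frame: `gene_id`, `type` for every genomeA NBS gene) and
#'   `truth_forms` (data.frame: `gene_a`, `gene_b`, `form` for the expected
#'   syntenic NBS pairs).
#' @export
simulate_synteny <- function(genes_per_chrom = 300, n_chromosomes = 2,
                             n_tandem_arrays = 4, tandem_size = 2,
                             n_segmental_blocks = 1, segmental_size = 6,
                             n_dispersed = 4, n_unanchored = 2,
                             n_missing_orthologs = 2, max_gap = 25,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slot_width <- max(segmental_size, tandem_size) + 2L
  spacing <- max_gap + slot_width + 2L
  slots <- expand.grid(
    base = seq(5L, genes_per_chrom - slot_width, by = spacing),
    chrom = seq_len(n_chromosomes))
  # slots are consumed round-robin across chromosomes so paired features land
  # on different chromosomes
  slots <- slots[order(slots$base, slots$chrom), ]
  needed <- n_tandem_arrays + 2L * n_segmental_blocks + 2L * n_dispersed + 1L
  if (nrow(slots) < needed)
    stop("not enough rank slots; increase genes_per_chrom")
  slot_i <- 0L
  take_slot <- function() {
    slot_i <<- slot_i + 1L
    slots[slot_i, ]
  }
  # background genome A
  gene_tab <- list()
  for (c in seq_len(n_chromosomes)) {
    for (r in seq_len(genes_per_chrom)) {
      gene_tab[[length(gene_tab) + 1L]] <- data.frame(
        gene_id = sprintf("gA_c%d_%03d", c, r), genome_id = "genomeA",
        seq_id = sprintf("chrA%d", c), start = r * 10000L,
        end = r * 10000L + 3000L, slot_rank = r, nbs = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  ga <- do.call(rbind, gene_tab)
  rownames(ga) <- paste(ga$seq_id, ga$slot_rank)
  mark_nbs <- function(chrom, ranks) {
    ga[paste(sprintf("chrA%d", chrom), ranks), "nbs"] <<- TRUE
    ga$gene_id[match(paste(sprintf("chrA%d", chrom), ranks),
                     rownames(ga))]
  }
  pairs_within <- list(); truth <- list()
  # tandem arrays
  for (i in seq_len(n_tandem_arrays)) {
    s <- take_slot()
    ids <- mark_nbs(s$chrom, s$base + seq_len(tandem_size) - 1L)
    for (j in seq_len(tandem_size - 1L)) {
      pairs_within[[length(pairs_within) + 1L]] <- data.frame(
        gene_a = ids[j], gene_b = ids[j + 1L], score = 200,
        stringsAsFactors = FALSE)
    }
    for (id in ids) truth[[length(truth) + 1L]] <-
      data.frame(gene_id = id, type = "tandem", stringsAsFactors = FALSE)
  }
  # segmental blocks: source run duplicated onto another chromosome slot
  for (i in seq_len(n_segmental_blocks)) {
    src <- take_slot(); dst <- take_slot()
    src_ranks <- src$base + seq_len(segmental_size) - 1L
    dst_ranks <- dst$base + seq_len(segmental_size) - 1L
    nbs_pos <- seq(1L, segmental_size, by = 2L)   # alternate NBS/background
    src_ids <- ga$gene_id[match(paste(sprintf("chrA%d", src$chrom),
                                      src_ranks), rownames(ga))]
    dst_ids <- ga$gene_id[match(paste(sprintf("chrA%d", dst$chrom),
                                      dst_ranks), rownames(ga))]
    mark_nbs(src$chrom, src_ranks[nbs_pos])
    mark_nbs(dst$chrom, dst_ranks[nbs_pos])
    for (j in seq_len(segmental_size)) {
      pairs_within[[length(pairs_within) + 1L]] <- data.frame(
        gene_a = src_ids[j], gene_b = dst_ids[j], score = 300,
        stringsAsFactors = FALSE)
    }
    for (id in c(src_ids[nbs_pos], dst_ids[nbs_pos]))
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = id, type = "WGD/segmental", stringsAsFactors = FALSE)
  }
  # dispersed duplicates
  for (i in seq_len(n_dispersed)) {
    src <- take_slot(); dst <- take_slot()
    a <- mark_nbs(src$chrom, src$base)
    b <- mark_nbs(dst$chrom, dst$base)
    pairs_within[[length(pairs_within) + 1L]] <- data.frame(
      gene_a = a, gene_b = b, score = 150, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(gene_id = a, type = "dispersed",
                                              stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(gene_id = b, type = "dispersed",
                                              stringsAsFactors = FALSE)
  }
  # one NBS gene with no homolog (singleton origin)
  s <- take_slot()
  lone <- mark_nbs(s$chrom, s$base)
  truth[[length(truth) + 1L]] <- data.frame(gene_id = lone,
                                            type = "dispersed",
                                            stringsAsFactors = FALSE)
  # unanchored NBS genes
  for (i in seq_len(n_unanchored)) {
    id <- sprintf("gA_un_%02d", i)
    ga <- rbind(ga, data.frame(gene_id = id, genome_id = "genomeA",
                               seq_id = NA_character_, start = NA_integer_,
                               end = NA_integer_, slot_rank = NA_integer_,
                               nbs = TRUE, row.names = id,
                               stringsAsFactors = FALSE))
    truth[[length(truth) + 1L]] <- data.frame(gene_id = id,
                                              type = "unanchored",
                                              stringsAsFactors = FALSE)
  }
  # genome B: one ortholog per anchored genome-A gene, same order, minus a
  # few NBS genes (presence/absence polymorphism)
  gb <- ga[!is.na(ga$seq_id), , drop = FALSE]
  gb$genome_id <- "genomeB"
  gb$seq_id <- sub("chrA", "chrB", gb$seq_id)
  orig <- gb$gene_id
  gb$gene_id <- sub("^gA_", "gB_", gb$gene_id)
  nbs_a_anchored <- ga$gene_id[ga$nbs & !is.na(ga$seq_id)]
  drop_b <- utils::head(sub("^gA_", "gB_", nbs_a_anchored),
                        n_missing_orthologs)
  keep <- !gb$gene_id %in% drop_b
  pairs_cross <- data.frame(gene_a = orig[keep], gene_b = gb$gene_id[keep],
                            score = 500, stringsAsFactors = FALSE)
  gb <- gb[keep, , drop = FALSE]
  genes <- rbind(ga, gb)
  genes <- gene_ranks(genes[, c("gene_id", "genome_id", "seq_id", "start",
                                "end", "nbs")])
  nbs_ids <- genes$gene_id[genes$nbs]
  truth <- do.call(rbind, truth)
  # expected syntenic-NBS-pair forms: an NBS gene is "cluster" when its
  # nearest NBS neighbor on the chromosome is within 250 kb (tandem arrays
  # and segmental runs; isolated NBS genes are singletons)
  cl_status <- function(sub) {
    vapply(seq_len(nrow(sub)), function(i) {
      same <- sub[sub$seq_id == sub$seq_id[i] & sub$gene_id != sub$gene_id[i], ]
      if (nrow(same) == 0L) return("singleton")
      gap <- pmax(same$start, sub$start[i]) - pmin(same$end, sub$end[i]) - 1L
      if (any(gap <= 250000L)) "cluster" else "singleton"
    }, "")
  }
  nbs_tab <- genes[genes$nbs & !is.na(genes$seq_id), ]
  status <- stats::setNames(unlist(lapply(split(nbs_tab, nbs_tab$genome_id),
                                          cl_status)),
                            unlist(lapply(split(nbs_tab, nbs_tab$genome_id),
                                          function(x) x$gene_id)))
  cr <- pairs_cross[pairs_cross$gene_a %in% nbs_ids &
                    pairs_cross$gene_b %in% nbs_ids, ]
  truth_forms <- data.frame(
    gene_a = cr$gene_a, gene_b = cr$gene_b,
    form = vapply(seq_len(nrow(cr)), function(i)
      paste(sort(c(status[cr$gene_a[i]], status[cr$gene_b[i]])),
            collapse = "-to-"), ""),
    stringsAsFactors = FALSE)
  if (length(pairs_within) == 0L) {
    pairs_within <- list(data.frame(gene_a = character(0),
                                    gene_b = character(0),
                                    score = numeric(0)))
  }
  list(genes = genes, pairs_within = do.call(rbind, pairs_within),
       pairs_cross = pairs_cross, nbs_ids = nbs_ids, truth = truth,
       truth_forms = truth_forms)
}
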