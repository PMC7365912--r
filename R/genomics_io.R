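#' Read gene models from a GFF3 file
#'
#' Parses gene, mRNA and CDS features and returns one row per gene. The gene
#' is identified by the `ID` attribute of its `gene` feature. For genes with
#' several transcripts, the transcript with the longest summed CDS represents
#' the gene, so `cds_length` is the CDS length of the longest-CDS isoform.
#' Coordinates are 1-based and inclusive throughout.
#'
#' @param path path to a GFF3 file.
#' @param genome_id genome identifier stored with every gene.
#' @return a data.frame with columns `gene_id`, `genome_id`, `seq_id`,
#'   `start`, `end`, `strand`, `cds_length`, `gene_length`.
#' @export
read_gff3 <- function(path, genome_id) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) {
    return(data.frame(gene_id = character(0), genome_id = character(0),
                      seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      cds_length = integer(0), gene_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  gene_id <- as.character(genes$ID)
  if (anyNA(gene_id)) stop("gene feature without an ID attribute")
  if (anyDuplicated(gene_id)) stop("duplicated gene IDs in ", path)

  # map every CDS segment up to its gene, via mRNA parents when present
  mrna <- gr[type %in% c("mRNA", "transcript")]
  mrna_gene <- if (length(mrna)) {
    stats::setNames(vapply(S4Vectors::mcols(mrna)$Parent, function(p)
      as.character(p)[1], ""), as.character(mrna$ID))
  } else character(0)

  cds <- gr[type == "CDS"]
  cds_by_tx <- new.env(parent = emptyenv())
  if (length(cds)) {
    par <- S4Vectors::mcols(cds)$Parent
    w <- GenomicRanges::width(cds)
    for (i in seq_along(cds)) {
      for (p in as.character(par[[i]])) {
        cds_by_tx[[p]] <- (if (is.null(cds_by_tx[[p]])) 0L else cds_by_tx[[p]]) + w[i]
      }
    }
  }
  # per-gene longest transcript CDS sum; CDS may also point straight at a gene
  cds_length <- integer(length(gene_id))
  names(cds_length) <- gene_id
  for (tx in ls(cds_by_tx)) {
    g <- if (tx %in% names(mrna_gene)) mrna_gene[[tx]] else tx
    if (g %in% gene_id) cds_length[g] <- max(cds_length[g], cds_by_tx[[tx]])
  }
  if (any(cds_length == 0L)) {
    warning("gene(s) with no CDS feature: ",
            paste(gene_id[cds_length == 0L], collapse = ", "))
  }
  out <- data.frame(
    gene_id = gene_id,
    genome_id = genome_id,
    seq_id = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    cds_length = as.integer(unname(cds_length)),
    stringsAsFactors = FALSE
  )
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  out$gene_length <- out$end - out$start + 1L
  bad <- out$cds_length > out$gene_length
  if (any(bad)) stop("CDS longer than gene for: ",
                     paste(out$gene_id[bad], collapse = ", "))
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits one `gene` feature per row plus a single `CDS` child of length
#' `cds_length` so that [read_gff3()] round-trips all fields.
#'
#' @param genes data.frame as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- genes[order(genes$seq_id, genes$start), , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(paste(g$seq_id, "nlrtrace", "gene", g$start, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
    if (g$cds_length > 0L) {
      writeLines(paste(g$seq_id, "nlrtrace", "CDS", g$start,
                       g$start + g$cds_length - 1L, ".", g$strand, "0",
                       paste0("ID=", g$gene_id, ".cds;Parent=", g$gene_id),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a domain-hit table
#'
#' Reads a TSV with columns `gene_id`, `domain_label`, `ali_start`, `ali_end`,
#' `evalue` (Pfam/CDD-style evidence). Rows with an E-value above the
#' threshold are dropped, rows with an unknown domain label are rejected with
#' a warning, and the result is sorted by gene and alignment start.
#'
#' @param path path to the TSV file.
#' @param evalue_threshold maximum E-value retained (default `1e-4`).
#' @return data.frame of domain hits.
#' @export
read_domain_hits <- function(path, evalue_threshold = 1e-4) {
  cols <- c("gene_id", "domain_label", "ali_start", "ali_end", "evalue")
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(hits) == 0L && ncol(hits) < 5L) {
    hits <- data.frame(gene_id = character(0), domain_label = character(0),
                       ali_start = integer(0), ali_end = integer(0),
                       evalue = numeric(0), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(cols, names(hits))
  if (length(missing_cols)) stop("domain-hit table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  hits <- hits[cols]
  unknown <- !hits$domain_label %in% names(DOMAIN_LETTERS)
  if (any(unknown)) {
    warning("rejecting ", sum(unknown), " hit(s) with unknown domain label: ",
            paste(unique(hits$domain_label[unknown]), collapse = ", "))
    hits <- hits[!unknown, , drop = FALSE]
  }
  if (any(hits$ali_start > hits$ali_end)) stop("hit with ali_start > ali_end")
  hits <- hits[hits$evalue <= evalue_threshold, , drop = FALSE]
  hits <- hits[order(hits$gene_id, hits$ali_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read a newick tree
#'
#' @param path path to a newick file (single tree).
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in '", path, "'")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a tree in newick format
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a homolog-pair table
#'
#' Reads a TSV with columns `gene_a`, `gene_b`, `score`. Pairs are unordered:
#' each is normalised so `gene_a < gene_b` and duplicates are collapsed
#' (keeping the best score). Self-pairs are dropped with a warning.
#'
#' @param path path to the TSV file.
#' @return data.frame of unique unordered pairs.
#' @export
read_homolog_pairs <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(p))) stop("homolog-pair table needs columns ",
                                     paste(need, collapse = ", "))
  normalize_pairs(p[need])
}

normalize_pairs <- function(p) {
  self <- p$gene_a == p$gene_b
  if (any(self)) {
    warning("dropping ", sum(self), " self pair(s)")
    p <- p[!self, , drop = FALSE]
  }
  a <- pmin(p$gene_a, p$gene_b)
  b <- pmax(p$gene_a, p$gene_b)
  p <- data.frame(gene_a = a, gene_b = b, score = p$score,
                  stringsAsFactors = FALSE)
  p <- p[order(p$gene_a, p$gene_b, -p$score), , drop = FALSE]
  p <- p[!duplicated(p[c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Read a leaf-to-species map
#'
#' Two-column TSV (`leaf`, `species`) mapping gene-tree leaf labels to
#' species-tree tips. When no map file is used, leaf labels of the form
#' `"species|gene"` are parsed directly (see [leaf_species()]).
#'
#' @param path path to the TSV file.
#' @return named character vector, species keyed by leaf label.
#' @export
read_leaf_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(m) < 2L) stop("leaf map needs two columns (leaf, species)")
  stats::setNames(as.character(m[[2]]), as.character(m[[1]]))
}

#' Species of gene-tree leaves
#'
#' Resolves each leaf label to its species, either through an explicit map or
#' by the `"species|gene"` naming convention.
#'
#' @param labels character vector of leaf labels.
#' @param leaf_map optional named character vector (from [read_leaf_map()]).
#' @return character vector of species ids, same length as `labels`.
#' @export
leaf_species <- function(labels, leaf_map = NULL) {
  if (!is.null(leaf_map)) {
    miss <- setdiff(labels, names(leaf_map))
    if (length(miss)) stop("leaf(s) missing from leaf map: ",
                           paste(miss, collapse = ", "))
    return(unname(leaf_map[labels]))
  }
  no_bar <- !grepl("|", labels, fixed = TRUE)
  if (any(no_bar)) stop("leaf label(s) not of the form 'species|gene' and no ",
                        "leaf map given: ", paste(labels[no_bar], collapse = ", "))
  sub("\\|.*$", "", labels)
}

#' Write a stage report
#'
#' Writes a data.frame as TSV and, optionally, a named list as a JSON summary
#' next to it.
#'
#' @param table data.frame to write (TSV, no quoting).
#' @param path output TSV path.
#' @param summary optional named list written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, summary = NULL) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary)) {
    jsonlite::write_json(summary, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# half-up decimal rounding, matching how the source tables print percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
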