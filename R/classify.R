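# Domain-architecture classification: TNL / CNL / RNL subclasses and the
# intact / XN / NL / N / Other structural categories.

DOMAIN_LETTERS <- c(TIR = "T", CC = "C", RPW8 = "R", NBS = "N", LRR = "L")
SUBCLASSES <- c("TNL", "CNL", "RNL")

collapse_runs <- function(letters) {
  if (nchar(letters) == 0L) return(letters)
  ch <- strsplit(letters, "")[[1]]
  keep <- c(TRUE, ch[-1] != ch[-length(ch)])
  paste(ch[keep], collapse = "")
}

#' Build a domain-architecture string for one gene
#'
#' Maps ordered domain hits to architecture letters (TIR->T, CC->C, RPW8->R,
#' NBS->N, LRR->L). When two hits overlap by at least half the shorter hit,
#' only the lower-E-value hit is kept. Maximal runs of the same letter are
#' then collapsed to one (so three consecutive LRR hits read "L", but
#' interleaved repeats such as "CNLCNL" are preserved).
#'
#' @param hits data.frame of domain hits for a single gene, with columns
#'   `gene_id`, `domain_label`, `ali_start`, `ali_end`, `evalue`.
#' @param overlap_frac overlap fraction (of the shorter hit) above which two
#'   hits conflict; default 0.5.
#' @return a list of class `nlr_architecture` with `gene_id`, `raw_letters`,
#'   `letters` (collapsed); subclass and category are filled by
#'   [assign_subclass()].
#' @seealso [assign_subclass()], [classify_genes()]
#' @export
build_architecture <- function(hits, overlap_frac = 0.5) {
  stopifnot(length(unique(hits$gene_id)) == 1L)
  bad <- !hits$domain_label %in% names(DOMAIN_LETTERS)
  if (any(bad)) stop("unknown domain label(s): ",
                     paste(unique(hits$domain_label[bad]), collapse = ", "))
  # overlap resolution: consider hits best-E-value first, drop any hit that
  # overlaps an already-kept hit by >= overlap_frac of the shorter one
  hits <- hits[order(hits$evalue, hits$ali_start), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(hits))) {
    conflict <- FALSE
    for (j in kept) {
      ov <- min(hits$ali_end[i], hits$ali_end[j]) -
            max(hits$ali_start[i], hits$ali_start[j]) + 1L
      shorter <- min(hits$ali_end[i] - hits$ali_start[i],
                     hits$ali_end[j] - hits$ali_start[j]) + 1L
      if (ov >= overlap_frac * shorter) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- c(kept, i)
  }
  hits <- hits[kept, , drop = FALSE]
  hits <- hits[order(hits$ali_start, hits$ali_end), , drop = FALSE]
  raw <- paste(DOMAIN_LETTERS[hits$domain_label], collapse = "")
  if (!grepl("N", raw)) {
    stop(errorCondition(
      paste0("gene '", hits$gene_id[1], "' has no NBS domain hit: ",
             "not an NBS-encoding gene"),
      class = c("nlrtrace_not_nbs", "error", "condition")))
  }
  structure(list(gene_id = hits$gene_id[1], raw_letters = raw,
                 letters = collapse_runs(raw),
                 subclass = NA_character_, category = NA_character_),
            class = "nlr_architecture")
}

#' Assign subclass and structural category to an architecture
#'
#' Subclass follows the N-terminal domain: any TIR letter gives TNL, else
#' RPW8 gives RNL, else CC gives CNL. Truncated genes (letters "N" or "NL")
#' carry no N-terminal evidence; they take the `neighbor_hint` subclass (the
#' closest-relative strategy) when provided, and default to CNL otherwise.
#' Category is "intact" for exactly X+"NL" (X in T/C/R), "TN"/"CN"/"RN" for
#' X+"N", "NL", "N", and "Other" for anything else. Architectures carrying
#' both TIR and RPW8 are flagged: category "Other", subclass from the first
#' N-terminal letter, with a warning.
#'
#' @param arch an `nlr_architecture` from [build_architecture()].
#' @param neighbor_hint optional subclass ("TNL"/"CNL"/"RNL") of the gene's
#'   nearest phylogenetic/similarity neighbor, used for N/NL genes.
#' @return the architecture with `subclass` and `category` filled.
#' @export
assign_subclass <- function(arch, neighbor_hint = NULL) {
  letters <- arch$letters
  stopifnot(nchar(letters) > 0L, grepl("N", letters))
  has <- function(x) grepl(x, letters)
  conflict <- has("T") && has("R")
  if (conflict) {
    warning("gene '", arch$gene_id, "': architecture '", letters,
            "' carries both TIR and RPW8; classifying by the first ",
            "N-terminal letter")
    first_nterm <- regmatches(letters, regexpr("[TRC]", letters))
    arch$subclass <- c(T = "TNL", R = "RNL", C = "CNL")[[first_nterm]]
  } else if (has("T")) arch$subclass <- "TNL"
  else if (has("R")) arch$subclass <- "RNL"
  else if (has("C")) arch$subclass <- "CNL"
  else {
    arch$subclass <- if (!is.null(neighbor_hint) && !is.na(neighbor_hint)) {
      stopifnot(neighbor_hint %in% SUBCLASSES)
      neighbor_hint
    } else "CNL"
  }
  x <- substr(arch$subclass, 1, 1)   # T, C or R
  arch$category <-
    if (conflict) "Other"
    else if (letters == paste0(x, "NL")) "intact"
    else if (letters == paste0(x, "N")) paste0(x, "N")
    else if (letters == "NL") "NL"
    else if (letters == "N") "N"
    else "Other"
  arch
}

#' Classify a set of genes from their domain hits
#'
#' Runs [build_architecture()] and [assign_subclass()] over every gene in a
#' domain-hit table. Genes without an NBS hit are skipped with a warning.
#'
#' @param hits domain-hit data.frame (several genes), as from
#'   [read_domain_hits()].
#' @param hints optional data.frame (`gene_id`, `subclass`) of
#'   nearest-neighbor subclass hints for truncated genes.
#' @return data.frame with columns `gene_id`, `raw_letters`, `letters`,
#'   `subclass`, `category`.
#' @export
classify_genes <- function(hits, hints = NULL) {
  hint_of <- if (is.null(hints)) character(0) else
    stats::setNames(hints$subclass, hints$gene_id)
  rows <- lapply(split(hits, hits$gene_id), function(h) {
    arch <- tryCatch(build_architecture(h), nlrtrace_not_nbs = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(arch)) return(NULL)
    hint <- if (arch$gene_id %in% names(hint_of)) hint_of[[arch$gene_id]] else NULL
    arch <- assign_subclass(arch, hint)
    data.frame(gene_id = arch$gene_id, raw_letters = arch$raw_letters,
               letters = arch$letters, subclass = arch$subclass,
               category = arch$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene_id = character(0),
                                      raw_letters = character(0),
                                      letters = character(0),
                                      subclass = character(0),
                                      category = character(0))
  rownames(out) <- NULL
  out
}

#' Family summary of NBS-encoding genes
#'
#' Per-genome counts of genes by subclass and structural category, subclass
#' proportions (percent of NBS genes), the proportion of NBS genes among all
#' protein-coding genes, and mean gene/CDS lengths. Percentages are rounded
#' half-up to 2 decimals and mean lengths to whole base pairs.
#'
#' @param classification data.frame from [classify_genes()], plus a
#'   `genome_id` column (added here as `"genome"` if absent).
#' @param genes optional gene-model data.frame (from [read_gff3()]) supplying
#'   `gene_length` and `cds_length` per gene.
#' @param total_protein_coding optional named integer vector: number of
#'   annotated protein-coding genes per genome.
#' @return list with data.frames `by_subclass` (genome, subclass, n, pct),
#'   `by_category` (genome, subclass, category, n) and `totals` (genome,
#'   n_nbs, pct_protein_coding, mean_gene_length, mean_cds_length).
#' @export
summarize_family <- function(classification, genes = NULL,
                             total_protein_coding = NULL) {
  cls <- classification
  if (!"genome_id" %in% names(cls)) {
    cls$genome_id <- rep("genome", nrow(cls))
  }
  genomes <- unique(cls$genome_id)
  if (nrow(cls) == 0L) {
    return(list(
      by_subclass = data.frame(genome_id = character(0), subclass = character(0),
                               n = integer(0), pct = numeric(0)),
      by_category = data.frame(genome_id = character(0), subclass = character(0),
                               category = character(0), n = integer(0)),
      totals = data.frame(genome_id = character(0), n_nbs = integer(0),
                          pct_protein_coding = numeric(0),
                          mean_gene_length = numeric(0),
                          mean_cds_length = numeric(0))))
  }
  by_cat <- as.data.frame(table(genome_id = cls$genome_id,
                                subclass = cls$subclass,
                                category = cls$category),
                          stringsAsFactors = FALSE)
  names(by_cat)[names(by_cat) == "Freq"] <- "n"
  by_sub <- stats::aggregate(n ~ genome_id + subclass, by_cat, sum)
  tot <- stats::aggregate(n ~ genome_id, by_sub, sum)
  names(tot)[2] <- "n_nbs"
  by_sub$pct <- round_half_up(
    100 * by_sub$n / tot$n_nbs[match(by_sub$genome_id, tot$genome_id)], 2)

  tot$pct_protein_coding <- NA_real_
  if (!is.null(total_protein_coding)) {
    tpc <- total_protein_coding[tot$genome_id]
    ok <- !is.na(tpc) & tpc > 0
    tot$pct_protein_coding[ok] <- round_half_up(100 * tot$n_nbs[ok] / tpc[ok], 2)
    if (any(!ok)) warning("no protein-coding total for genome(s): ",
                          paste(tot$genome_id[!ok], collapse = ", "))
  }
  tot$mean_gene_length <- NA_real_
  tot$mean_cds_length <- NA_real_
  if (!is.null(genes)) {
    m <- merge(cls["gene_id"], genes, by = "gene_id")
    if (nrow(m)) {
      mg <- stats::aggregate(cbind(gene_length, cds_length) ~ genome_id, m, mean)
      idx <- match(tot$genome_id, mg$genome_id)
      tot$mean_gene_length <- round_half_up(mg$gene_length[idx])
      tot$mean_cds_length <- round_half_up(mg$cds_length[idx])
    }
  }
  list(by_subclass = by_sub[order(by_sub$genome_id, by_sub$subclass), ],
       by_category = by_cat[by_cat$n > 0 | TRUE, ][order(by_cat$genome_id,
                                                         by_cat$subclass,
                                                         by_cat$category), ],
       totals = tot)
}
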