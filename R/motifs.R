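# The six conserved NBS-domain motifs (N- to C-terminal order): P-loop,
# Kinase-2, Kinase-3, RNBS-C, GLPL, RNBS-D. Seeded scanning with packaged
# consensus seeds, per-subclass position-frequency profiles, and
# subclass-diagnostic residue detection.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
MOTIF_ORDER <- c("P-loop", "Kinase-2", "Kinase-3", "RNBS-C", "GLPL", "RNBS-D")

#' Packaged motif consensus seeds
#'
#' Per-motif, per-subclass consensus sequences for the six conserved NBS
#' motifs. Widths are fixed per motif (P-loop 9, Kinase-2 8, Kinase-3 8,
#' RNBS-C 8, GLPL 6, RNBS-D 11); position indices in all diagnostics are
#' 1-based within these seeds. The seeds carry the subclass signatures:
#' serine at P-loop position 4 in RNL, the TNL-specific aspartate at the
#' final Kinase-2 position, tryptophan at RNBS-C position 7 in CNL, and the
#' RNBS-D signatures (glutamate at position 2 in RNL, cysteine at position 7
#' in CNL, phenylalanine at position 11 in TNL); RNBS-D, the least conserved
#' motif, additionally differs between all three subclasses at position 5.
#'
#' @return data.frame with columns `motif`, `width`, `CNL`, `TNL`, `RNL`.
#' @export
motif_seeds <- function() {
  data.frame(
    motif = MOTIF_ORDER,
    width = c(9L, 8L, 8L, 8L, 6L, 11L),
    CNL = c("GMGGLGKTT", "LLVLDDVW", "GSRIIITT", "SFDENEWL", "GLPLAL",
            "LADKGICPKLL"),
    TNL = c("GMGGLGKTT", "LLVLDDVD", "GSRIIITT", "SFDENELL", "GLPLAL",
            "LADKYISPKLF"),
    RNL = c("GMGSLGKTT", "LLVLDDVW", "GSRIIITT", "SFDENELL", "GLPLAL",
            "LEDKNISPKLL"),
    stringsAsFactors = FALSE)
}

#' Published subclass-diagnostic residues
#'
#' The packaged default diagnostic set: tryptophan (W) at RNBS-C position 7
#' and cysteine (C) at RNBS-D position 7 for CNL; phenylalanine (F) at
#' RNBS-D position 11 and the terminal Kinase-2 aspartate (D, position 8) for
#' TNL; serine (S) at P-loop position 4 and glutamic acid (E) at RNBS-D
#' position 2 for RNL.
#'
#' @return data.frame with columns `motif`, `position`, `residue`,
#'   `subclass`.
#' @export
default_diagnostics <- function() {
  data.frame(
    motif = c("RNBS-C", "RNBS-D", "RNBS-D", "Kinase-2", "P-loop", "RNBS-D"),
    position = c(7L, 7L, 11L, 8L, 4L, 2L),
    residue = c("W", "C", "F", "D", "S", "E"),
    subclass = c("CNL", "CNL", "TNL", "TNL", "RNL", "RNL"),
    stringsAsFactors = FALSE)
}

# scanning PWM for one motif: average of the subclass consensi, each giving
# probability `p_match` to its consensus residue; log-odds vs uniform 1/20
seed_pwm <- function(seed_row, p_match = 0.7) {
  width <- seed_row$width
  mat <- matrix(0, nrow = 20L, ncol = width, dimnames = list(AA_ALPHABET))
  for (sc in SUBCLASSES) {
    ch <- strsplit(seed_row[[sc]], "")[[1]]
    for (j in seq_len(width)) {
      p <- rep((1 - p_match) / 19, 20L)
      p[match(ch[j], AA_ALPHABET)] <- p_match
      mat[, j] <- mat[, j] + p / length(SUBCLASSES)
    }
  }
  log(mat / (1 / 20))
}

#' Scan sequences for the six conserved NBS motifs
#'
#' Scores every window of each sequence against a log-odds matrix built from
#' the packaged consensus seeds (uniform background). Per sequence at most
#' one occurrence per motif is reported; occurrences are constrained to the
#' canonical N-to-C motif order by dynamic programming over the candidate
#' windows (maximizing total score subject to ordered, non-overlapping
#' placement). Motifs with no window above the score threshold are reported
#' absent. Sequences shorter than `min_length` residues (default 190, under
#' two-thirds of a regular NBS domain) are excluded.
#'
#' @param seqs named character vector of amino-acid sequences (or an
#'   `AAStringSet`); alignment gaps (`-`) are removed before scanning.
#' @param seeds seed table from [motif_seeds()].
#' @param min_length minimum sequence length retained.
#' @param score_frac threshold as a fraction of each motif's maximum
#'   attainable score (default 0.25).
#' @return data.frame of occurrences: `seq_id`, `motif`, `start`, `end`,
#'   `score`, `match`. Sequences skipped by the length filter are listed in
#'   attribute `"skipped"`.
#' @export
scan_motifs <- function(seqs, seeds = motif_seeds(), min_length = 190,
                        score_frac = 0.25) {
  if (inherits(seqs, "AAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- vapply(seqs, function(s) gsub("-", "", s, fixed = TRUE), "")
  skipped <- names(seqs)[nchar(seqs) < min_length]
  seqs <- seqs[nchar(seqs) >= min_length]
  pwms <- lapply(seq_len(nrow(seeds)), function(i) seed_pwm(seeds[i, ]))
  names(pwms) <- seeds$motif
  thresholds <- vapply(pwms, function(m) score_frac * sum(apply(m, 2, max)), 0)

  res <- lapply(names(seqs), function(id) {
    aa <- match(strsplit(seqs[[id]], "")[[1]], AA_ALPHABET)
    n <- length(aa)
    # candidate windows per motif
    cands <- lapply(seq_len(nrow(seeds)), function(mi) {
      w <- seeds$width[mi]
      if (n < w) return(NULL)
      starts <- seq_len(n - w + 1L)
      pos <- outer(starts - 1L, seq_len(w), `+`)
      vals <- matrix(pwms[[mi]][cbind(as.vector(aa[pos]),
                                      rep(seq_len(w), each = length(starts)))],
                     nrow = length(starts))
      sc <- rowSums(vals, na.rm = TRUE)
      keep <- which(sc >= thresholds[mi])
      if (!length(keep)) return(NULL)
      data.frame(motif_i = mi, start = starts[keep], score = sc[keep])
    })
    cand <- do.call(rbind, cands)
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    cand$end <- cand$start + seeds$width[cand$motif_i] - 1L
    # DP: best-scoring chain of candidates, motif indices strictly
    # increasing, windows non-overlapping and in order
    m <- nrow(cand)
    ord <- order(cand$motif_i, cand$start)
    cand <- cand[ord, , drop = FALSE]
    best <- cand$score
    prev <- rep(0L, m)
    for (i in seq_len(m)) {
      for (j in seq_len(i - 1L)) {
        if (cand$motif_i[j] < cand$motif_i[i] &&
            cand$end[j] < cand$start[i] &&
            best[j] + cand$score[i] > best[i]) {
          best[i] <- best[j] + cand$score[i]
          prev[i] <- j
        }
      }
    }
    chain <- integer(0)
    i <- which.max(best)
    while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
    picked <- cand[chain, , drop = FALSE]
    data.frame(seq_id = id, motif = seeds$motif[picked$motif_i],
               start = picked$start, end = picked$end, score = picked$score,
               match = substring(seqs[[id]], picked$start, picked$end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(seq_id = character(0), motif = character(0),
                                      start = integer(0), end = integer(0),
                                      score = numeric(0), match = character(0),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Build per-subclass motif profiles and detect diagnostic residues
#'
#' For every (motif, subclass) with at least one occurrence, builds a
#' position-frequency matrix (20 amino acids x motif width, pseudocount
#' added, columns normalized to 1). A position is diagnostic for a subclass
#' when that subclass's modal residue has frequency >= `modal_min` and
#' differs from the modal residues of both other subclasses.
#'
#' @param occurrences data.frame from [scan_motifs()].
#' @param subclasses named character vector: subclass per `seq_id`.
#' @param pseudocount per-residue pseudocount (default 0.01).
#' @param modal_min minimum modal frequency for a diagnostic call (default
#'   0.5).
#' @return list with `profiles` (nested list `profiles[[motif]][[subclass]]`
#'   of matrices) and `diagnostics` (data.frame: `motif`, `position`,
#'   `residue`, `subclass`, `modal_frequency`).
#' @export
build_profiles <- function(occurrences, subclasses, pseudocount = 0.01,
                           modal_min = 0.5) {
  occ <- occurrences
  occ$subclass <- subclasses[occ$seq_id]
  if (anyNA(occ$subclass)) stop("occurrence(s) with unknown subclass")
  present <- unique(occ$subclass)
  absent <- setdiff(SUBCLASSES, present)
  if (length(absent)) warning("no occurrences for subclass(es): ",
                              paste(absent, collapse = ", "),
                              "; profiles omitted")
  profiles <- list()
  for (m in intersect(MOTIF_ORDER, unique(occ$motif))) {
    for (sc in present) {
      hits <- occ$match[occ$motif == m & occ$subclass == sc]
      if (!length(hits)) next
      w <- nchar(hits[1])
      mat <- matrix(pseudocount, nrow = 20L, ncol = w,
                    dimnames = list(AA_ALPHABET, NULL))
      for (h in hits) {
        idx <- match(strsplit(h, "")[[1]], AA_ALPHABET)
        ok <- !is.na(idx)
        mat[cbind(idx[ok], seq_len(w)[ok])] <-
          mat[cbind(idx[ok], seq_len(w)[ok])] + 1
      }
      profiles[[m]][[sc]] <- sweep(mat, 2, colSums(mat), "/")
    }
  }
  diag_rows <- list()
  for (m in names(profiles)) {
    scs <- names(profiles[[m]])
    if (length(scs) < 3L) next
    w <- ncol(profiles[[m]][[1]])
    for (pos in seq_len(w)) {
      modal <- vapply(scs, function(sc) {
        col <- profiles[[m]][[sc]][, pos]
        names(which.max(col))
      }, "")
      freq <- vapply(scs, function(sc) max(profiles[[m]][[sc]][, pos]), 0)
      for (sc in scs) {
        others <- setdiff(scs, sc)
        if (freq[sc] >= modal_min && all(modal[others] != modal[sc])) {
          diag_rows[[length(diag_rows) + 1L]] <- data.frame(
            motif = m, position = pos, residue = unname(modal[sc]),
            subclass = sc, modal_frequency = unname(freq[sc]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(motif = character(0), position = integer(0),
               residue = character(0), subclass = character(0),
               modal_frequency = numeric(0))
  list(profiles = profiles, diagnostics = diagnostics)
}

#' Predict subclass from motif signatures
#'
#' Majority vote over matched diagnostic residues: each diagnostic whose
#' residue is found at its motif position in the sequence's occurrence votes
#' for its subclass; the subclass with the most votes wins, ties or zero
#' matches give "ambiguous".
#'
#' @param occurrences data.frame from [scan_motifs()] (may cover many
#'   sequences).
#' @param diagnostics data.frame of diagnostic residues, e.g.
#'   [default_diagnostics()] or the learned set from [build_profiles()].
#' @return data.frame: `seq_id`, `prediction`, `votes_CNL`, `votes_TNL`,
#'   `votes_RNL`.
#' @export
predict_subclass_from_motifs <- function(occurrences, diagnostics) {
  ids <- unique(occurrences$seq_id)
  rows <- lapply(ids, function(id) {
    occ <- occurrences[occurrences$seq_id == id, , drop = FALSE]
    votes <- stats::setNames(numeric(3), SUBCLASSES)
    for (i in seq_len(nrow(diagnostics))) {
      d <- diagnostics[i, ]
      j <- match(d$motif, occ$motif)
      if (is.na(j)) next
      if (substr(occ$match[j], d$position, d$position) == d$residue) {
        votes[d$subclass] <- votes[d$subclass] + 1
      }
    }
    top <- max(votes)
    pred <- if (top == 0 || sum(votes == top) > 1L) "ambiguous" else
      names(votes)[which.max(votes)]
    data.frame(seq_id = id, prediction = pred, votes_CNL = votes[["CNL"]],
               votes_TNL = votes[["TNL"]], votes_RNL = votes[["RNL"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(seq_id = character(0),
                                      prediction = character(0),
                                      votes_CNL = numeric(0),
                                      votes_TNL = numeric(0),
                                      votes_RNL = numeric(0))
  rownames(out) <- NULL
  out
}
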