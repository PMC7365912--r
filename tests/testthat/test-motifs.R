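test_that("a sequence built from the seed consensi matches all six motifs in order", {
  sim <- simulate_motif_alignment(n = c(CNL = 5, TNL = 5, RNL = 5),
                                  noise_rate = 0, seed = 12)
  occ <- scan_motifs(sim$seqs)
  expect_equal(sort(unique(occ$motif)), sort(nlrtrace:::MOTIF_ORDER))
  m <- merge(occ[c("seq_id", "motif", "start")], sim$planted,
             by = c("seq_id", "motif"))
  expect_equal(nrow(m), nrow(sim$planted))   # every planted motif found
  expect_equal(m$start.x, m$start.y)         # at the planted position
  # order constraint: starts increase along the canonical motif order
  for (occ_i in split(occ, occ$seq_id)) {
    ord <- match(occ_i$motif, nlrtrace:::MOTIF_ORDER)
    expect_true(all(diff(occ_i$start[order(ord)]) > 0))
  }
})

test_that("sequences under 190 residues are excluded", {
  seqs <- c(short = strrep("A", 100), ok = simulate_motif_alignment(
    n = c(CNL = 1), noise_rate = 0, seed = 1)$seqs[[1]])
  occ <- scan_motifs(seqs)
  expect_equal(attr(occ, "skipped"), "short")
  expect_false("short" %in% occ$seq_id)
})

test_that("ordered-placement DP attains the exhaustive optimum", {
  set.seed(77)
  seeds <- motif_seeds()
  sim <- simulate_motif_alignment(n = c(CNL = 4, TNL = 3, RNL = 3),
                                  noise_rate = 0.25, seed = 99)
  occ <- scan_motifs(sim$seqs)
  for (id in names(sim$seqs)) {
    cand <- oracle_candidates(sim$seqs[[id]], seeds)
    best <- oracle_best_ordered_score(cand)
    got <- sum(occ$score[occ$seq_id == id])
    expect_equal(got, best, tolerance = 1e-9, info = id)
  }
})

test_that("profiles normalize per position and detect planted diagnostics", {
  # 90% tryptophan at RNBS-C position 7 in CNL, leucine elsewhere
  mk <- function(sub, res7, n) {
    data.frame(seq_id = sprintf("%s_%02d", sub, seq_len(n)), motif = "RNBS-C",
               start = 1L, end = 8L, score = 1,
               match = paste0("SFDENE", res7, "L"), stringsAsFactors = FALSE)
  }
  occ <- rbind(mk("CNL", "W", 18), mk("CNL", "L", 2),
               mk("TNL", "L", 10), mk("RNL", "L", 10))
  subs <- stats::setNames(sub("_.*", "", occ$seq_id), occ$seq_id)
  prof <- build_profiles(occ, subs)
  for (sc in c("CNL", "TNL", "RNL")) {
    expect_equal(colSums(prof$profiles[["RNBS-C"]][[sc]]), rep(1, 8),
                 tolerance = 1e-9)
    expect_true(all(prof$profiles[["RNBS-C"]][[sc]] > 0))  # pseudocount
  }
  d <- prof$diagnostics
  expect_true(any(d$motif == "RNBS-C" & d$position == 7 & d$residue == "W" &
                  d$subclass == "CNL"))
  # identical positions are never diagnostic
  expect_false(any(d$position == 1))
})

test_that("profile building is deterministic for a fixed seed", {
  run <- function() {
    sim <- simulate_motif_alignment(n = c(CNL = 15, TNL = 10, RNL = 8),
                                    noise_rate = 0.2, seed = 55)
    occ <- scan_motifs(sim$seqs)
    build_profiles(occ, sim$truth)
  }
  expect_identical(run(), run())
})

test_that("published signatures drive subclass prediction", {
  occ_for <- function(id, ploop4 = "G", k2_8 = "W", rnbsc7 = "E",
                      rnbsd2 = "A", rnbsd7 = "X", rnbsd11 = "L") {
    data.frame(
      seq_id = id,
      motif = c("P-loop", "Kinase-2", "RNBS-C", "RNBS-D"),
      start = c(1L, 30L, 60L, 90L), end = c(9L, 37L, 67L, 100L), score = 1,
      match = c(paste0("GMG", ploop4, "LGKTT"),
                paste0("LLVLDDV", k2_8),
                paste0("SFDENE", rnbsc7, "L"),
                paste0("L", rnbsd2, "DKGI", rnbsd7, "PKL", rnbsd11)),
      stringsAsFactors = FALSE)
  }
  d <- default_diagnostics()
  # S at P-loop 4 and E at RNBS-D 2: RNL
  p <- predict_subclass_from_motifs(occ_for("s1", ploop4 = "S", rnbsd2 = "E"), d)
  expect_equal(p$prediction, "RNL")
  # F at RNBS-D 11: TNL
  p <- predict_subclass_from_motifs(occ_for("s2", rnbsd11 = "F"), d)
  expect_equal(p$prediction, "TNL")
  # W at RNBS-C 7 and C at RNBS-D 7: CNL
  p <- predict_subclass_from_motifs(occ_for("s3", rnbsc7 = "W", rnbsd7 = "C"), d)
  expect_equal(p$prediction, "CNL")
  # no diagnostic matched: ambiguous
  p <- predict_subclass_from_motifs(occ_for("s4"), d)
  expect_equal(p$prediction, "ambiguous")
  # one vote each for two subclasses: ambiguous
  p <- predict_subclass_from_motifs(occ_for("s5", ploop4 = "S", rnbsd11 = "F"), d)
  expect_equal(p$prediction, "ambiguous")
})

test_that("noise-free simulated alignments are classified perfectly", {
  sim <- simulate_motif_alignment(n = c(CNL = 12, TNL = 8, RNL = 6),
                                  noise_rate = 0, seed = 3)
  occ <- scan_motifs(sim$seqs)
  prof <- build_profiles(occ, sim$truth)
  pred <- predict_subclass_from_motifs(occ, prof$diagnostics)
  expect_equal(unname(sim$truth[pred$seq_id]), pred$prediction)
})
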