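hit_row <- function(gene, dom, s, e, ev = 1e-8) {
  data.frame(gene_id = gene, domain_label = dom, ali_start = s, ali_end = e,
             evalue = ev, stringsAsFactors = FALSE)
}

test_that("build_architecture maps, collapses repeats, resolves overlaps", {
  # TIR + NBS + three LRRs collapse to the intact TNL architecture
  h <- rbind(hit_row("g", "TIR", 5, 150), hit_row("g", "NBS", 180, 450),
             hit_row("g", "LRR", 500, 560), hit_row("g", "LRR", 570, 630),
             hit_row("g", "LRR", 640, 700))
  a <- build_architecture(h)
  expect_equal(a$letters, "TNL")
  expect_equal(a$raw_letters, "TNLLL")

  # NBS alone
  expect_equal(build_architecture(hit_row("g", "NBS", 1, 260))$letters, "N")

  # interleaved repeats are preserved
  h <- rbind(hit_row("g", "CC", 1, 60), hit_row("g", "NBS", 80, 330),
             hit_row("g", "LRR", 350, 410), hit_row("g", "CC", 430, 490),
             hit_row("g", "NBS", 510, 760), hit_row("g", "LRR", 780, 840))
  expect_equal(build_architecture(h)$letters, "CNLCNL")

  # >= 50% overlap of the shorter hit: keep the lower E-value
  h <- rbind(hit_row("g", "TIR", 1, 100, 1e-6), hit_row("g", "CC", 40, 100, 1e-3),
             hit_row("g", "NBS", 150, 400))
  expect_equal(build_architecture(h)$letters, "TN")

  # no NBS hit: the gene is rejected with a classed condition
  expect_error(build_architecture(hit_row("g", "TIR", 1, 100)),
               class = "nlrtrace_not_nbs")
})

test_that("collapsing adjacent repeats is idempotent", {
  collapse <- nlrtrace:::collapse_runs
  set.seed(4)
  for (i in 1:200) {
    s <- paste(sample(c("T", "C", "R", "N", "L"), sample(1:12, 1),
                      replace = TRUE), collapse = "")
    once <- collapse(s)
    expect_identical(collapse(once), once)
    expect_false(grepl("(.)\\1", once))
  }
})

test_that("assign_subclass follows N-terminal domain, hints fill truncated genes", {
  arch <- function(letters) structure(
    list(gene_id = "g", raw_letters = letters, letters = letters,
         subclass = NA, category = NA), class = "nlr_architecture")
  a <- assign_subclass(arch("TNL"))
  expect_equal(c(a$subclass, a$category), c("TNL", "intact"))
  a <- assign_subclass(arch("N"), neighbor_hint = "CNL")
  expect_equal(c(a$subclass, a$category), c("CNL", "N"))
  a <- assign_subclass(arch("N"), neighbor_hint = "TNL")
  expect_equal(c(a$subclass, a$category), c("TNL", "N"))
  a <- assign_subclass(arch("NL"))            # no hint: defaults to CNL
  expect_equal(c(a$subclass, a$category), c("CNL", "NL"))
  a <- assign_subclass(arch("CNLCNL"))
  expect_equal(c(a$subclass, a$category), c("CNL", "Other"))
  a <- assign_subclass(arch("RN"))
  expect_equal(c(a$subclass, a$category), c("RNL", "RN"))
  # conflicting TIR+RPW8: category Other, subclass by first N-terminal letter
  expect_warning(a <- assign_subclass(arch("RNTL")), "both TIR and RPW8")
  expect_equal(c(a$subclass, a$category), c("RNL", "Other"))
})

test_that("category partition is exhaustive and mutually exclusive", {
  arch <- function(letters) structure(
    list(gene_id = "g", raw_letters = letters, letters = letters,
         subclass = NA, category = NA), class = "nlr_architecture")
  set.seed(9)
  cats <- c("intact", "TN", "CN", "RN", "NL", "N", "Other")
  for (i in 1:200) {
    s <- nlrtrace:::collapse_runs(paste(
      sample(c("T", "C", "R", "N", "L"), sample(1:8, 1), replace = TRUE),
      collapse = ""))
    if (!grepl("N", s)) next
    a <- suppressWarnings(assign_subclass(arch(s)))
    expect_true(a$category %in% cats)
    x <- substr(a$subclass, 1, 1)
    expected <- if (grepl("T", s) && grepl("R", s)) "Other"
      else if (s == paste0(x, "NL")) "intact"
      else if (s == paste0(x, "N")) paste0(x, "N")
      else if (s %in% c("NL", "N")) s
      else "Other"
    expect_equal(a$category, expected, info = s)
  }
})

test_that("classification recovers simulator truth, with hints for truncated genes", {
  sim <- simulate_architectures(seed = 31)
  cls <- suppressWarnings(classify_genes(sim$hits, sim$hints))
  expect_equal(nrow(cls), nrow(sim$truth))
  m <- merge(cls, sim$truth, by = "gene_id")
  expect_true(all(m$letters.x == m$letters.y))
  expect_true(all(m$subclass.x == m$subclass.y))
  expect_true(all(m$category.x == m$category.y))
  # determinism under a fixed seed
  sim2 <- simulate_architectures(seed = 31)
  expect_identical(sim, sim2)
})

test_that("family summary reproduces printed subclass proportions", {
  cls <- data.frame(
    gene_id = sprintf("g%03d", 1:568),
    subclass = rep(c("CNL", "TNL", "RNL"), c(507, 52, 9)),
    category = "intact", genome_id = "D.longan",
    stringsAsFactors = FALSE)
  s <- summarize_family(cls, total_protein_coding = c(D.longan = 31007))
  expect_equal(s$by_subclass$pct[s$by_subclass$subclass == "CNL"], 89.26)
  expect_equal(s$by_subclass$pct[s$by_subclass$subclass == "TNL"], 9.15)
  expect_equal(s$totals$n_nbs, 568L)
  expect_equal(s$totals$pct_protein_coding, 1.83)
  # category counts sum to subclass counts
  agg <- stats::aggregate(n ~ subclass, s$by_category, sum)
  expect_equal(agg$n[match(s$by_subclass$subclass, agg$subclass)],
               s$by_subclass$n)
})

test_that("family summary handles empty input and mean lengths", {
  s <- summarize_family(data.frame(gene_id = character(0),
                                   subclass = character(0),
                                   category = character(0)))
  expect_equal(nrow(s$totals), 0L)
  cls <- data.frame(gene_id = c("a", "b"), subclass = "CNL",
                    category = "intact", genome_id = "G")
  genes <- data.frame(gene_id = c("a", "b"), genome_id = "G",
                      gene_length = c(6000L, 6163L),
                      cds_length = c(3000L, 3165L))
  s <- summarize_family(cls, genes)
  expect_equal(s$totals$mean_gene_length, 6082)
  expect_equal(s$totals$mean_cds_length, 3083)
})
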