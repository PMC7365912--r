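# Gene-tree / species-tree reconciliation by LCA mapping with
# duplication/loss parsimony, ancestral-lineage enumeration, and copy-number
# ledger propagation.

#' Packaged default species tree
#'
#' The rooted 4-taxon species tree used throughout: Arabidopsis thaliana as
#' outgroup to the three Sapindaceae genomes, with X. sorbifolium diverging
#' before A. yangbiense and D. longan. Unit branch lengths.
#'
#' @return a rooted binary `phylo` with named internal nodes
#'   (`Malvids_MRCA`, `Sapindaceae_MRCA`, `Ay_Dl_MRCA`).
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(A.thaliana:1,(X.sorbifolium:1,(A.yangbiense:1,D.longan:1)",
    "Ay_Dl_MRCA:1)Sapindaceae_MRCA:1)Malvids_MRCA;"))
}

# prepare a species rtree with labels, depths, clade index
species_index <- function(species_tree) {
  st <- as_rtree(species_tree)
  if (!rtree_is_binary(st)) stop("species tree must be binary")
  unnamed <- which(st$label == "")
  if (length(unnamed)) st$label[unnamed] <- paste0("spnode", unnamed)
  if (anyDuplicated(st$label)) stop("species tree node names must be unique")
  st$depth <- rtree_depths(st)
  st
}

#' Reconcile a gene tree with a species tree by LCA mapping
#'
#' Maps every gene-tree node to a species-tree node: leaves map to their
#' species, internal nodes to the species-tree LCA of their children's
#' mappings. A node is a duplication when it maps to the same species node as
#' at least one child, and a speciation otherwise. Per-edge loss counts are
#' filled by [count_losses()], which this function calls.
#'
#' @param gene_tree rooted binary `phylo`; leaf labels either
#'   `"species|gene"` or resolvable through `leaf_map`.
#' @param species_tree rooted binary `phylo` with unique node names (see
#'   [default_species_tree()]).
#' @param leaf_map optional named character vector mapping leaf labels to
#'   species tips (see [read_leaf_map()]).
#' @return an object of class `nlr_reconciliation`: a list with the gene and
#'   species trees (internal form), per-node `mapping` (species node index),
#'   `event` ("leaf"/"speciation"/"duplication"), a per-node `losses` count
#'   for the edge above each node, `loss_branches` (list of species node
#'   labels charged), and a `table` data.frame view.
#' @export
lca_map <- function(gene_tree, species_tree, leaf_map = NULL) {
  gt <- as_rtree(gene_tree)
  if (gt$n_tip == 1L) {
    # single-gene family: collapse the newick artefact root onto the tip
    tip <- rtree_tips(gt)[1]
    gt <- structure(list(n = 1L, n_tip = 1L, parent = 0L,
                         children = list(integer(0)), label = gt$label[tip],
                         root = 1L, postorder = 1L), class = "rtree")
  }
  if (!rtree_is_binary(gt))
    stop("gene tree has polytomies; resolve them (arbitrarily) upstream")
  st <- species_index(species_tree)
  tips <- which(vapply(gt$children, length, 1L) == 0L)
  sp <- leaf_species(gt$label[tips], leaf_map)
  sp_idx <- match(sp, st$label[seq_len(st$n_tip)])
  if (anyNA(sp_idx)) stop("leaf species not in species tree: ",
                          paste(unique(sp[is.na(sp_idx)]), collapse = ", "))
  mapping <- integer(gt$n)
  mapping[tips] <- sp_idx
  event <- character(gt$n)
  event[tips] <- "leaf"
  for (v in gt$postorder) {
    kids <- gt$children[[v]]
    if (length(kids) == 0L) next
    m <- rtree_lca(st, st$depth, mapping[kids[1]], mapping[kids[2]])
    mapping[v] <- m
    event[v] <- if (any(mapping[kids] == m)) "duplication" else "speciation"
  }
  rec <- structure(list(gene_tree = gt, species_tree = st, mapping = mapping,
                        event = event,
                        leaf_species = stats::setNames(sp, gt$label[tips])),
                   class = "nlr_reconciliation")
  rec <- count_losses(rec)
  rec$table <- data.frame(
    node = seq_len(gt$n),
    label = gt$label,
    mapping = st$label[mapping],
    event = event,
    losses_above = rec$losses,
    stringsAsFactors = FALSE)
  rec
}

#' Count losses implied by a reconciliation
#'
#' For the gene-tree edge from parent `p` to child `v`, the mapping path
#' descends from `M(p)` to `M(v)` through `d` species-tree edges; the edge
#' implies `d - 1` losses, plus one more when `p` is a duplication whose
#' mapping differs from `M(v)` (the duplicated copy had to traverse the
#' speciation at `M(p)` too). Each loss is charged to the species-tree branch
#' of the sibling subtree skipped at the corresponding speciation, from the
#' highest skipped branch downward.
#'
#' The gene family is taken to originate at the species root: when the
#' gene-tree root maps below it, one loss is charged to each sibling branch
#' skipped on the way down (disable with `origin = "mapped"` to start the
#' family at the root's own mapping instead).
#'
#' @param rec an `nlr_reconciliation` (mappings computed).
#' @param origin `"root"` (default) charges origination losses from the
#'   species root down to the gene-tree root's mapping; `"mapped"` charges
#'   none.
#' @return `rec` with `losses` (per gene-tree node: losses on the edge above
#'   it; for the root, the origination losses) and `loss_branches` (per
#'   node: character vector of species node labels, one per loss, naming the
#'   branch by its child node).
#' @export
count_losses <- function(rec, origin = c("root", "mapped")) {
  origin <- match.arg(origin)
  gt <- rec$gene_tree; st <- rec$species_tree
  losses <- integer(gt$n)
  loss_branches <- rep(list(character(0)), gt$n)
  for (v in seq_len(gt$n)) {
    p <- gt$parent[v]
    if (p == 0L) {
      if (origin == "mapped") next
      mv <- rec$mapping[v]
      if (mv == st$root) next
      path <- integer(0); s <- mv
      while (s != st$root) { path <- c(path, s); s <- st$parent[s] }
      losses[v] <- length(path)
      loss_branches[[v]] <- st$label[vapply(rev(path), function(x)
        rtree_sibling(st, x), 0L)]
      next
    }
    mp <- rec$mapping[p]; mv <- rec$mapping[v]
    if (mp == mv) next
    # species path mv -> mp (exclusive of mp), bottom-up
    path <- integer(0)
    s <- mv
    while (s != mp) { path <- c(path, s); s <- st$parent[s] }
    d <- length(path)                       # edges on the path
    dup_extra <- rec$event[p] == "duplication"
    losses[v] <- d - 1L + as.integer(dup_extra)
    # charged branches: sibling of each path step entered below a speciation
    # passed through; highest skipped branch first
    steps_down <- rev(path)                 # children of s0, s1, ... in order
    charged <- character(0)
    from <- if (dup_extra) 1L else 2L       # skip the sibling at M(p) unless dup
    if (length(steps_down) >= from) {
      for (i in seq(from, length(steps_down))) {
        sib <- rtree_sibling(st, steps_down[i])
        charged <- c(charged, st$label[sib])
      }
    }
    loss_branches[[v]] <- charged
  }
  rec$losses <- losses
  rec$loss_branches <- loss_branches
  rec
}

#' Total duplication and loss counts of a reconciliation
#'
#' @param rec an `nlr_reconciliation`.
#' @return named numeric vector with `duplications`, `losses`, `total`.
#' @export
event_counts <- function(rec) {
  d <- sum(rec$event == "duplication")
  l <- sum(rec$losses)
  c(duplications = d, losses = l, total = d + l)
}

#' Root a gene tree by duplication/loss minimization
#'
#' Considers every edge of the (un)rooted gene tree as a root position,
#' reconciles each candidate rooting against the species tree, and returns
#' the rooting with the fewest duplications + losses. Ties are broken by
#' fewer duplications, then by the lexicographically smallest sorted leaf set
#' of the smaller root child. Deterministic for fixed input.
#'
#' @param gene_tree a `phylo`, rooted or unrooted; a rooted tree is unrooted
#'   first so all edges compete.
#' @param species_tree rooted binary `phylo`.
#' @param leaf_map optional leaf-to-species map.
#' @return list with `tree` (rooted `phylo`), `events` (named vector from
#'   [event_counts()]) and `reconciliation`.
#' @export
root_by_event_minimization <- function(gene_tree, species_tree,
                                       leaf_map = NULL) {
  if (length(gene_tree$tip.label) < 3L) {
    rec <- lca_map(gene_tree, species_tree, leaf_map)
    return(list(tree = gene_tree, events = event_counts(rec),
                reconciliation = rec))
  }
  und <- tree_adjacency(gene_tree)
  best <- NULL
  for (i in seq_len(nrow(und$edges))) {
    rt <- root_at_edge(und, und$edges[i, 1], und$edges[i, 2])
    phy <- rtree_to_phylo(rt)
    rec <- lca_map(phy, species_tree, leaf_map)
    ev <- event_counts(rec)
    kids <- rt$children[[rt$root]]
    clades <- rtree_clades(rt)
    sides <- lapply(kids, function(k) sort(clades[[k]]))
    smaller <- if (length(sides[[1]]) != length(sides[[2]])) {
      sides[[which.min(lengths(sides))]]
    } else {
      key <- vapply(sides, paste, "", collapse = "\r")
      sides[[which.min(rank(key, ties.method = "first"))]]
    }
    cand <- list(tree = phy, events = ev, reconciliation = rec,
                 key = paste(smaller, collapse = "\r"))
    if (is.null(best) ||
        ev[["total"]] < best$events[["total"]] ||
        (ev[["total"]] == best$events[["total"]] &&
         ev[["duplications"]] < best$events[["duplications"]]) ||
        (ev[["total"]] == best$events[["total"]] &&
         ev[["duplications"]] == best$events[["duplications"]] &&
         cand$key < best$key)) {
      best <- cand
    }
  }
  best[c("tree", "events", "reconciliation")]
}

#' Aggregate events from many reconciliations per species-tree branch
#'
#' Each duplication is binned to the species-tree branch above the node it
#' maps to (duplications mapping to the species root are binned to the root
#' entry); each loss to the branch it was charged to by [count_losses()].
#' With a `subclass` map, events are additionally stratified: an event's
#' subclass is the majority subclass of the gene-tree leaves below it (ties
#' give "mixed").
#'
#' @param recs list of `nlr_reconciliation` objects sharing one species tree.
#' @param species_tree the shared species tree (`phylo`).
#' @param subclass optional named character vector: subclass per gene leaf
#'   label.
#' @return data.frame: `branch` (species node label naming the branch above
#'   it), `duplications`, `losses`, and with `subclass` given also one row
#'   per (branch, subclass).
#' @export
aggregate_events <- function(recs, species_tree, subclass = NULL) {
  st <- species_index(species_tree)
  labs <- st$label
  zero <- function() stats::setNames(numeric(length(labs)), labs)
  if (is.null(subclass)) {
    dups <- zero(); losses <- zero()
    for (rec in recs) {
      is_dup <- rec$event == "duplication"
      for (m in rec$mapping[is_dup]) dups[st$label[m]] <- dups[st$label[m]] + 1
      for (br in unlist(rec$loss_branches)) losses[br] <- losses[br] + 1
    }
    out <- data.frame(branch = labs, duplications = unname(dups),
                      losses = unname(losses), stringsAsFactors = FALSE)
    return(out)
  }
  keys <- character(0); dups <- numeric(0); losses <- numeric(0)
  bump <- function(tab, key) { if (!key %in% names(tab)) tab[key] <- 0
                               tab[key] <- tab[key] + 1; tab }
  dtab <- numeric(0); ltab <- numeric(0)
  for (rec in recs) {
    clades <- rtree_clades(rec$gene_tree)
    node_sub <- vapply(seq_len(rec$gene_tree$n), function(v) {
      s <- subclass[clades[[v]]]
      s <- s[!is.na(s)]
      if (length(s) == 0L) return("mixed")
      tt <- sort(table(s), decreasing = TRUE)
      if (length(tt) > 1L && tt[1] == tt[2]) "mixed" else names(tt)[1]
    }, "")
    for (v in which(rec$event == "duplication")) {
      dtab <- bump(dtab, paste(st$label[rec$mapping[v]], node_sub[v], sep = "\r"))
    }
    for (v in seq_len(rec$gene_tree$n)) {
      for (br in rec$loss_branches[[v]]) {
        ltab <- bump(ltab, paste(br, node_sub[v], sep = "\r"))
      }
    }
  }
  keys <- union(names(dtab), names(ltab))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(branch = vapply(parts, `[`, "", 1),
             subclass = vapply(parts, `[`, "", 2),
             duplications = unname(ifelse(keys %in% names(dtab), dtab[keys], 0)),
             losses = unname(ifelse(keys %in% names(ltab), ltab[keys], 0)),
             stringsAsFactors = FALSE)
}

#' Enumerate ancestral lineages at a reference species node
#'
#' A lineage is the set of extant genes descending from one gene copy present
#' at the reference ancestor. A duplication node mapping exactly to the
#' reference node occurs on the branch leading to it (before the
#' speciation), so each of its children starts a separate lineage; lineage
#' roots are therefore the maximal gene-tree nodes that map to the reference
#' node or below and are not themselves duplications at the reference node,
#' whose parent (if any) either maps to a strict ancestor of the reference
#' node or is such a duplication. Genes mapping outside the reference clade
#' are out of scope.
#'
#' @param rec an `nlr_reconciliation`.
#' @param reference_node label of an internal species-tree node (e.g.
#'   `"Sapindaceae_MRCA"`).
#' @param subclass optional named character vector (subclass per leaf label)
#'   for the majority-subclass lineage label; ties give "mixed".
#' @return data.frame: `lineage_id`, `n_members`, `members` (comma-joined
#'   leaf labels), one logical presence column per genome below the reference
#'   node, and `subclass` when given.
#' @export
extract_lineages <- function(rec, reference_node, subclass = NULL) {
  st <- rec$species_tree; gt <- rec$gene_tree
  ref <- match(reference_node, st$label)
  if (is.na(ref)) stop("unknown species-tree node: ", reference_node)
  if (length(st$children[[ref]]) == 0L)
    stop("reference node must be an internal species-tree node")
  in_clade <- vapply(seq_len(st$n), function(s)
    rtree_is_ancestor(st, st$depth, ref, s), TRUE)
  # a node "qualifies" as part of a lineage when it maps inside the reference
  # clade and is not a stem duplication (a duplication mapping to ref happens
  # on the branch above it, so its children are distinct ancestral copies)
  qualifies <- in_clade[rec$mapping] &
    !(rec$event == "duplication" & rec$mapping == ref)
  roots <- which(vapply(seq_len(gt$n), function(v) {
    if (!qualifies[v]) return(FALSE)
    p <- gt$parent[v]
    p == 0L || !qualifies[p]
  }, TRUE))
  genomes <- st$label[intersect(which(in_clade), seq_len(st$n_tip))]
  clades <- rtree_clades(gt)
  rows <- lapply(seq_along(roots), function(i) {
    members <- clades[[roots[i]]]
    pres <- as.list(genomes %in% rec$leaf_species[members])
    names(pres) <- genomes
    row <- data.frame(lineage_id = sprintf("lineage%03d", i),
                      n_members = length(members),
                      members = paste(members, collapse = ","),
                      stringsAsFactors = FALSE)
    row <- cbind(row, as.data.frame(pres, optional = TRUE))
    if (!is.null(subclass)) {
      s <- subclass[members]; s <- s[!is.na(s)]
      tt <- sort(table(s), decreasing = TRUE)
      row$subclass <- if (length(tt) == 0L) "mixed" else
        if (length(tt) > 1L && tt[1] == tt[2]) "mixed" else names(tt)[1]
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(lineage_id = character(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
    for (g in genomes) out[[g]] <- logical(0)
  }
  out
}

#' Presence-pattern summary of lineages
#'
#' Tabulates lineages by their genome presence pattern (all genomes, each
#' two-genome combination, species-specific).
#'
#' @param lineages data.frame from [extract_lineages()] (one logical column
#'   per genome), or any data.frame of logical presence columns.
#' @param genomes character vector naming the presence columns.
#' @return data.frame with the logical pattern columns and `n` lineages.
#' @export
lineage_presence_summary <- function(lineages, genomes) {
  pres <- lineages[genomes]
  key <- do.call(paste, c(pres, sep = "/"))
  agg <- stats::aggregate(list(n = key), by = lapply(pres, identity), length)
  agg[order(-rowSums(agg[genomes])), , drop = FALSE]
}

#' Per-genome inherited-lineage counts from presence patterns
#'
#' Given presence-pattern counts (one logical column per genome plus `n`),
#' returns how many lineages each genome inherited: the sum of `n` over all
#' patterns in which the genome is present. Exercises the accounting identity
#' that all-present + two-genome + species-specific categories partition the
#' lineages.
#'
#' @param pattern_counts data.frame: logical presence columns and a count
#'   column `n`.
#' @param genomes character vector naming the presence columns (default: all
#'   logical columns).
#' @return named numeric vector of inherited-lineage counts per genome.
#' @export
inherited_lineage_counts <- function(pattern_counts, genomes = NULL) {
  if (is.null(genomes))
    genomes <- names(pattern_counts)[vapply(pattern_counts, is.logical, TRUE)]
  vapply(genomes, function(g) sum(pattern_counts$n[pattern_counts[[g]]]),
         numeric(1))
}

#' Propagate a gene-count ledger along the species tree
#'
#' Starting from an ancestral copy number at `start_node`, applies
#' `count(child) = count(parent) + duplications - losses` along every branch
#' below it, and labels each branch "expansion" (net gain), "contraction"
#' (net loss) or "stable". Each tip gets a pattern string concatenating the
#' branch labels on its root-to-tip path.
#'
#' @param ancestral_count gene count at `start_node` (non-negative).
#' @param events data.frame with columns `branch` (species node label, naming
#'   the branch above that node), `duplications`, `losses`; branches absent
#'   from the table count as (0, 0).
#' @param species_tree rooted binary `phylo`.
#' @param start_node label of the species node holding `ancestral_count`
#'   (default: the species-tree root).
#' @return list with `counts` (named vector: gene count per node at or below
#'   `start_node`), `branches` (data.frame: branch, duplications, losses,
#'   net, label) and `patterns` (named character vector per tip).
#' @export
ledger_propagate <- function(ancestral_count, events, species_tree,
                             start_node = NULL) {
  stopifnot(ancestral_count >= 0,
            all(events$duplications >= 0), all(events$losses >= 0))
  st <- species_index(species_tree)
  start <- if (is.null(start_node)) st$root else match(start_node, st$label)
  if (is.na(start)) stop("unknown start node: ", start_node)
  ev <- function(lbl, what) {
    i <- match(lbl, events$branch)
    if (is.na(i)) 0 else events[[what]][i]
  }
  counts <- rep(NA_real_, st$n)
  counts[start] <- ancestral_count
  order_nodes <- rev(st$postorder)
  branch_rows <- list()
  for (nd in order_nodes) {
    p <- st$parent[nd]
    if (nd == start || p == 0L || is.na(counts[p])) next
    d <- ev(st$label[nd], "duplications"); l <- ev(st$label[nd], "losses")
    counts[nd] <- counts[p] + d - l
    if (counts[nd] < 0)
      stop("inconsistent events: propagated count below zero on branch to '",
           st$label[nd], "'")
    net <- d - l
    branch_rows[[length(branch_rows) + 1L]] <- data.frame(
      branch = st$label[nd], duplications = d, losses = l, net = net,
      label = if (net > 0) "expansion" else if (net < 0) "contraction"
              else "stable",
      stringsAsFactors = FALSE)
  }
  branches <- if (length(branch_rows)) do.call(rbind, branch_rows) else
    data.frame(branch = character(0), duplications = numeric(0),
               losses = numeric(0), net = numeric(0), label = character(0))
  known <- which(!is.na(counts))
  tips <- intersect(known, seq_len(st$n_tip))
  patterns <- vapply(tips, function(tp) {
    path <- character(0)
    nd <- tp
    while (nd != start) {
      path <- c(branches$label[match(st$label[nd], branches$branch)], path)
      nd <- st$parent[nd]
    }
    paste(path, collapse = " -> ")
  }, "")
  names(patterns) <- st$label[tips]
  list(counts = stats::setNames(counts[known], st$label[known]),
       branches = branches, patterns = patterns)
}
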