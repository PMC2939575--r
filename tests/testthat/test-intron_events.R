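# Dollo / Fitch ancestral reconstruction and event inference.

mk_states <- function(tree, ...) {
  rows <- list(...)
  states <- do.call(rbind, rows)
  rownames(states) <- tree$tip.label
  colnames(states) <- paste0("s", seq_len(ncol(states)))
  toy_matrix(states)
}

test_that("an all-present site is present at the root with zero losses", {
  tree <- read_rooted_tree("((a,b),(c,d));")
  m <- toy_matrix(matrix("1", 4, 1, dimnames = list(c("a", "b", "c", "d"), "s1")))
  st <- dollo_reconstruct(m, tree)
  expect_true(all(st$states[, "s1"] == 1L))
  expect_identical(count_loss_edges(st, "s1"), 0L)
  # Fitch agrees on homoplasy-free sites
  sf <- fitch_reconstruct(m, tree)
  expect_identical(sf$states[, "s1"], st$states[, "s1"])
  expect_identical(sf$changes, 0L)
})

test_that("a site in two sister leaves is a single stem gain under Fitch", {
  tree <- read_rooted_tree("((a,b),(c,(d,e)));")
  m <- mk_states(tree, "0", "0", "0", "1", "1")
  sf <- fitch_reconstruct(m, tree)
  expect_identical(sf$changes, 1L)
  ev <- infer_events(sf)
  expect_identical(sum(ev$type == "gain"), 1L)
  expect_identical(sum(ev$type == "loss"), 0L)
  # on an even present/absent split the root tie resolves toward presence
  tree4 <- read_rooted_tree("((a,b),(c,d));")
  m4 <- mk_states(tree4, "1", "1", "0", "0")
  sf4 <- fitch_reconstruct(m4, tree4)
  expect_identical(sf4$changes, 1L)
  expect_identical(unname(sf4$states[intronloss:::root_node(tree4), "s1"]), 1L)
})

test_that("Dollo and Fitch per-site scores match exhaustive minima", {
  set.seed(733)
  n_cases <- 60
  for (i in seq_len(n_cases)) {
    ntips <- sample(3:5, 1)
    tree <- rand_rooted_tree(ntips, prefix = "L",
                             p_polytomy = if (i %% 4 == 0) 0.5 else 0)
    vals <- sample(c("1", "0", "?"), ntips, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
    if (!any(vals == "1")) vals[sample(ntips, 1)] <- "1"
    states <- matrix(vals, ncol = 1,
                     dimnames = list(tree$tip.label, "s1"))
    m <- toy_matrix(states)
    lf <- stats::setNames(vals, tree$tip.label)

    st <- dollo_reconstruct(m, tree)
    expect_identical(count_loss_edges(st, "s1"),
                     as.integer(oracle_dollo_min_losses(tree, lf)),
                     info = sprintf("dollo case %d: %s / %s", i,
                                    ape::write.tree(tree),
                                    paste(vals, collapse = "")))
    # single-gain constraint: present nodes form one connected subtree
    s <- st$states[, "s1"]
    par <- intronloss:::tree_parents(tree)
    pp_edges <- sum(vapply(which(par != 0L),
                           function(v) s[v] == 1L && s[par[v]] == 1L,
                           logical(1)))
    expect_identical(pp_edges, sum(s == 1L) - 1L)

    sf <- fitch_reconstruct(m, tree)
    expect_identical(sf$changes,
                     as.integer(oracle_fitch_min_changes(tree, lf)),
                     info = sprintf("fitch case %d", i))
    # Dollo loss count >= Fitch changes - 1 (the gain accounts for one)
    expect_gte(count_loss_edges(st, "s1"), sf$changes - 1L)
  }
})

test_that("Fitch per-site scores agree with phangorn's parsimony", {
  skip_if_not_installed("phangorn")
  set.seed(911)
  for (i in 1:20) {
    ntips <- sample(4:7, 1)
    tree <- rand_rooted_tree(ntips, prefix = "L")
    vals <- sample(c("1", "0"), ntips, replace = TRUE)
    if (!any(vals == "1")) vals[1] <- "1"
    m <- toy_matrix(matrix(vals, ncol = 1,
                           dimnames = list(tree$tip.label, "s1")))
    sf <- fitch_reconstruct(m, tree)
    dat <- phangorn::phyDat(matrix(vals, ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_identical(as.integer(sf$changes),
                     as.integer(phangorn::parsimony(tree, dat)))
  }
})

test_that("missing states are non-informative and inherit silently", {
  tree <- read_rooted_tree("((a,b),(c,d));")
  # d is missing: no event may be inferred on its terminal branch
  m <- mk_states(tree, "1", "1", "1", "?")
  st <- dollo_reconstruct(m, tree)
  ev <- infer_events(st)
  expect_identical(sum(ev$type == "loss"), 0L)
  expect_identical(unname(st$states[4, "s1"]), 1L)  # tip d inherits presence

  # a missing leaf inside an absent clade adds no second event
  tree5 <- read_rooted_tree("((a,b),(c,(d,e)DE));")
  m2 <- mk_states(tree5, "1", "1", "1", "0", "?")
  st2 <- dollo_reconstruct(m2, tree5)
  losses <- infer_events(st2)
  losses <- losses[losses$type == "loss", ]
  expect_identical(nrow(losses), 1L)
  expect_identical(losses$branch, "DE")
})

test_that("event histories replay exactly to the leaf matrix", {
  set.seed(515)
  for (i in 1:25) {
    tree <- rand_rooted_tree(sample(4:7, 1), prefix = "L")
    ntips <- ape::Ntip(tree)
    states <- matrix(sample(c("1", "0"), ntips * 3, replace = TRUE,
                            prob = c(0.6, 0.4)),
                     nrow = ntips,
                     dimnames = list(tree$tip.label, paste0("s", 1:3)))
    keep <- colSums(states == "1") > 0
    states <- states[, keep, drop = FALSE]
    if (!ncol(states)) next
    m <- toy_matrix(states)
    st <- dollo_reconstruct(m, tree)
    ev <- infer_events(st)
    rp <- replay_events(ev)
    expect_identical(rp[rownames(states), colnames(states), drop = FALSE],
                     states == "1")
    # exactly one gain per site over the whole history
    expect_true(all(table(ev$site_id[ev$type == "gain"]) == 1L))
  }
})

test_that("root anchoring moves the gain to the root and recovers stem losses", {
  tree <- read_rooted_tree("((a,b)AB,(c,d)CD)R;")
  # present only in the (a,b) clade: unanchored Dollo gains at their stem
  m <- mk_states(tree, "1", "1", "0", "0")
  st_free <- dollo_reconstruct(m, tree)
  expect_identical(intronloss:::node_labels(tree)[st_free$gain_node], "AB")
  expect_identical(count_loss_edges(st_free, "s1"), 0L)
  # anchored: ancestral at the root, lost once on the (c,d) stem
  st_anc <- dollo_reconstruct(m, tree, root_state = "s1")
  ev <- infer_events(st_anc)
  losses <- ev[ev$type == "loss", ]
  expect_identical(losses$branch, "CD")
})

test_that("the fixture event history reproduces the published pathway", {
  fx <- build_paper_fixture()
  g2s <- fx$gene_to_species[!fx$gene_to_species$exception, ]
  mat <- build_matrix(fx$structures, fx$alignment,
                      reference_genes = fx$reference_genes)
  rec <- lca_map(fx$gene_tree, fx$species_tree, g2s)
  st <- dollo_reconstruct(
    mat, rec = rec,
    root_state = mat$sites$site_id[!is.na(mat$sites$ancestral_number)])
  ev <- infer_events(st, gene_groups = stats::setNames(g2s$group, g2s$gene_id))

  anc_of <- function(rows) sort(rows$ancestral_number)
  losses <- ev[ev$type == "loss", ]
  # otophysan stem, clade I: ancestral sites 6, 7, 8
  expect_identical(anc_of(losses[losses$branch == "Otophysi" &
                                 losses$lineage == "cladeI", ]), c(6L, 7L, 8L))
  # otocephalan stem, clade I: ancestral site 2
  expect_identical(anc_of(losses[losses$branch == "Otocephala" &
                                 losses$lineage == "cladeI", ]), 2L)
  # salmoniform/esociform clade I: one gain at a non-ancestral (novel) site
  gains <- ev[ev$type == "gain" & ev$branch == "SalmEsoc", ]
  expect_identical(nrow(gains), 1L)
  expect_true(is.na(gains$ancestral_number))
  expect_identical(gains$lineage, "cladeI")

  # summary: six loss-bearing branch x lineage episodes; empty history edge
  s <- summarize_pathway(ev)
  expect_identical(s$n_loss_branches, 6L)
  s0 <- summarize_pathway(infer_events(dollo_reconstruct(
    toy_matrix(matrix("1", 2, 1, dimnames = list(c("a", "b"), "s1"))),
    read_rooted_tree("(a,b);"))))
  expect_identical(s0$n_loss_branches, 0L)  # all-present: no loss branches
})

test_that("duplication inheritance places losses within each gene copy", {
  # without inheritance, strictly minimal Dollo pools the shared loss on
  # the post-duplication stem; with it the loss is replayed per copy
  fx <- build_paper_fixture()
  g2s <- fx$gene_to_species[!fx$gene_to_species$exception, ]
  mat <- build_matrix(fx$structures, fx$alignment,
                      reference_genes = fx$reference_genes)
  rec <- lca_map(fx$gene_tree, fx$species_tree, g2s)
  groups <- stats::setNames(g2s$group, g2s$gene_id)
  site2 <- mat$sites$site_id[which(mat$sites$ancestral_number == 2)]

  ev_min <- infer_events(dollo_reconstruct(mat, rec = rec,
                                           duplication_inherit = FALSE),
                         gene_groups = groups)
  l_min <- ev_min[ev_min$type == "loss" & ev_min$site_id == site2 &
                    ev_min$lineage == "cladeI", ]
  expect_identical(l_min$branch, "Clupeocephala")  # pooled on the stem

  ev_inh <- infer_events(dollo_reconstruct(mat, rec = rec),
                         gene_groups = groups)
  l_inh <- ev_inh[ev_inh$type == "loss" & ev_inh$site_id == site2 &
                    ev_inh$lineage == "cladeI", ]
  expect_setequal(l_inh$branch, c("Otocephala", "Euteleostei"))
  expect_identical(l_inh$lineage, c("cladeI", "cladeI"))
})
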