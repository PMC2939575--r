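# Projection onto the alignment, site clustering, character matrix.

test_that("projection places introns on the correct alignment column", {
  protein <- intronloss:::toy_protein(30)
  gA <- intronloss:::make_toy_gene("gA", "sp1", protein, c(30L, 61L))
  gB <- intronloss:::make_toy_gene("gB", "sp2", protein, c(30L, 61L))

  # identity alignment: identical offsets give identical (column, phase)
  aln <- codon_alignment(c(gA = paste(protein, collapse = ""),
                           gB = paste(protein, collapse = "")))
  pA <- intron_positions(gA); pB <- intron_positions(gB)
  for (i in 1:2) {
    prA <- project_intron(gA, aln, pA[i, ])
    prB <- project_intron(gB, aln, pB[i, ])
    expect_identical(prA[c("column", "phase")], prB[c("column", "phase")])
  }
  # phase carried through unchanged: offsets 30 -> phase 0, 61 -> phase 1
  expect_identical(project_intron(gA, aln, pA[1, ])$phase, 0L)
  expect_identical(project_intron(gA, aln, pA[2, ])$phase, 1L)

  # a 5-residue gap before the intron-bearing residue shifts the column by
  # exactly 5 (brute-force bookkeeping on a 30-residue toy alignment)
  ungapped <- paste(protein, collapse = "")
  gapped <- paste0(substr(ungapped, 1, 5), "-----", substr(ungapped, 6, 30))
  aln2 <- codon_alignment(c(gA = gapped, gB = paste0(ungapped, "-----")))
  prA <- project_intron(gA, aln2, pA[1, ])  # codon_index 10 > gap at res 6
  prB <- project_intron(gB, aln2, pB[1, ])
  expect_identical(prA$column, prB$column + 5L)
  # independent bookkeeping: column = #gaps-before + residue index
  cols <- which(strsplit(gapped, "")[[1]] != "-")
  expect_identical(prA$column, cols[pA$codon_index[1] + 1L])
})

test_that("sites upstream of the aligned region are unprojectable", {
  protein <- intronloss:::toy_protein(30)
  g <- intronloss:::make_toy_gene("g", "sp", protein, c(15L, 60L))
  # alignment covers residues 11..30 only (region_start = 10)
  aln <- codon_alignment(c(g = paste(protein[11:30], collapse = "")),
                         region_start = c(g = 10L))
  pos <- intron_positions(g)
  pr1 <- project_intron(g, aln, pos[1, ])  # codon 5: upstream of region
  pr2 <- project_intron(g, aln, pos[2, ])  # codon 20: inside region
  expect_false(pr1$projectable)
  expect_true(pr2$projectable)
  expect_identical(pr2$column, 20L - 10L + 1L)
})

test_that("clustering keys sites by (column, phase) and numbers ancestral ones", {
  pr <- data.frame(gene_id = c("a", "b", "a", "b"),
                   intron_index = 1:4,
                   column = c(10L, 10L, 10L, 25L),
                   phase = c(0L, 0L, 1L, 2L),
                   projectable = TRUE)
  sites <- cluster_sites(pr, reference_genes = "a")
  # (10,0) shared; (10,1) distinct despite equal column; (25,2) from b only
  expect_identical(nrow(sites), 3L)
  expect_identical(sites$column, c(10L, 10L, 25L))
  expect_identical(sites$phase, c(0L, 1L, 2L))
  expect_identical(sites$ancestral_number, c(1L, 2L, NA_integer_))

  # ancestral numbering is stable under permutation of input order
  sites2 <- cluster_sites(pr[c(4, 2, 3, 1), ], reference_genes = "a")
  expect_identical(sites, sites2)
})

test_that("column-slop merge matches the exhaustive union-find oracle", {
  sites0 <- data.frame(site_id = "c10p0", column = 10L, phase = 0L,
                       ancestral_number = 1L)
  expect_identical(column_slop_merge(sites0, 0L)$column, 10L)

  # same-phase columns 10 and 11 merge at tolerance 1 to the leftmost
  s2 <- data.frame(site_id = c("c10p0", "c11p0"), column = c(10L, 11L),
                   phase = 0L, ancestral_number = c(1L, NA))
  m <- column_slop_merge(s2, 1L)
  expect_identical(nrow(m), 1L)
  expect_identical(m$column, 10L)
  expect_identical(m$ancestral_number, 1L)

  # never merge across phases, whatever the tolerance
  s3 <- data.frame(site_id = c("c10p0", "c10p1"), column = c(10L, 10L),
                   phase = c(0L, 1L), ancestral_number = NA_integer_)
  expect_identical(nrow(column_slop_merge(s3, 100L)), 2L)

  # randomized <=5-site cases against the transitive-closure oracle
  set.seed(404)
  for (i in 1:60) {
    n <- sample(1:5, 1)
    cols <- sort(sample(1:12, n))
    ph <- sample(0:1, n, replace = TRUE)
    tol <- sample(0:3, 1)
    s <- data.frame(site_id = sprintf("c%dp%d_%d", cols, ph, seq_len(n)),
                    column = cols, phase = ph,
                    ancestral_number = NA_integer_)
    m <- column_slop_merge(s, tol)
    groups <- oracle_slop_groups(cols, ph, tol)
    expect_identical(nrow(m), length(unique(groups)))
    # each oracle group's leftmost column appears as a merged site
    for (gid in unique(groups)) {
      expect_true(min(cols[groups == gid]) %in% m$column[m$phase == ph[groups == gid][1]])
    }
    # tolerance 0 is the identity
    m0 <- column_slop_merge(s, 0L)
    expect_identical(sort(m0$column), sort(s$column))
  }
})

test_that("the character matrix has deterministic order and exact row sums", {
  fx <- build_paper_fixture()
  mat <- build_matrix(fx$structures, fx$alignment,
                      reference_genes = fx$reference_genes)
  # fixture: 8 ancestral sites plus the novel salmoniform/esociform site
  expect_identical(sum(!is.na(mat$sites$ancestral_number)), 8L)
  expect_identical(ncol(mat$states), 9L)
  # row sums of "present" equal each gene's coding intron count
  for (g in fx$structures) {
    expect_identical(unname(sum(mat$states[g$gene_id, ] == "1")),
                     nrow(intron_positions(g)))
  }
  # cypriniform clade I rows: exactly 4 present; euteleost clade I: 0
  expect_identical(sum(mat$states["ZHE1", ] == "1"), 4L)
  expect_identical(sum(mat$states["LoHE1", ] == "1"), 4L)
  expect_identical(sum(mat$states["MHCE", ] == "1"), 0L)

  # projection is order-preserving within each gene
  pr <- project_all_introns(fx$structures, fx$alignment)
  for (id in unique(pr$gene_id)) {
    expect_false(is.unsorted(pr$column[pr$gene_id == id]))
  }

  # empty gene list -> empty matrix, no sites
  m0 <- build_matrix(list(), fx$alignment)
  expect_identical(nrow(m0$states), 0L)
  expect_identical(nrow(m0$sites), 0L)

  # gene absent from the alignment is excluded with a warning
  orphan <- intronloss:::make_toy_gene("orphan", "spX",
                                       intronloss:::toy_protein(120), 36L)
  expect_warning(m1 <- build_matrix(c(fx$structures["AwHE"], list(orphan)),
                                    fx$alignment),
                 "orphan")
  expect_identical(unname(rownames(m1$states)), "AwHE")
})

test_that("matrix round-trips exactly on zero-noise simulator output", {
  sim <- simulate_family(simulation_config(seed = 21, loss_prob = 0.15,
                                           gain_prob = 0.05))
  mat <- build_matrix(sim$structures, sim$alignment)
  truth <- sim$ground_truth
  # site identity: offsets -> (column = codon + 1, phase 0)
  sid <- sprintf("c%dp%d", truth$site_offsets %/% 3 + 1, 0)
  names(sid) <- names(truth$site_offsets)
  observed_sites <- names(sid)[sid %in% mat$sites$site_id]
  # every site observed in >= 1 leaf is recovered, none invented
  surviving <- colnames(truth$leaf_states)[colSums(truth$leaf_states) > 0]
  expect_setequal(observed_sites, surviving)
  for (g in rownames(truth$leaf_states)) {
    for (s in surviving) {
      expect_identical(unname(mat$states[g, sid[[s]]] == "1"),
                       unname(truth$leaf_states[g, s]))
    }
  }
})
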