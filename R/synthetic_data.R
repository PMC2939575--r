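# Synthetic data: (a) a fully synthetic reconstruction of the 27-species
# teleost hatching-enzyme study dataset (species tree, gene inventory,
# intron complements, toy sequences) and (b) a gene-family simulator with
# known ground truth for recovery testing.
#
# All sequences are toys: every gene shares one deterministic 120-residue
# protein (so the alignment is the identity), introns are 60 bp with
# canonical GT...AG termini, and species whose identity the study does not
# pin down are labelled with synthetic placeholder names.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

# deterministic toy protein (as a character vector of residues)
#' @keywords internal
toy_protein <- function(len = 120L) {
  i <- seq_len(len) - 1L
  p <- AA20[((i + i %/% 20L) %% 20L) + 1L]
  p[1] <- "M"
  p
}

#' @keywords internal
toy_intron <- function(len = 60L) {
  body <- paste(rep(c("T", "A", "C", "T"), length.out = len - 12L), collapse = "")
  paste0("GTAAGT", body, "TTACAG")
}

# Assemble a gene_structure from a protein and the CDS offsets of its
# introns. The genomic sequence is the spliced CDS (+ stop + short 3'UTR)
# re-interrupted by canonical toy introns.
#' @keywords internal
make_toy_gene <- function(gene_id, species_id, protein, site_offsets,
                          utr3 = "AATAAAGCA", intron_len = 60L) {
  cds <- paste0(paste(CODON_OF[protein], collapse = ""), "TAA")
  tx <- paste0(cds, utr3)
  cds_len <- nchar(cds)
  offs <- sort(as.integer(site_offsets))
  stopifnot(all(offs > 0), all(offs < cds_len))
  bounds <- c(0L, offs, nchar(tx))
  pieces <- vapply(seq_len(length(bounds) - 1L), function(i) {
    substr(tx, bounds[i] + 1L, bounds[i + 1L])
  }, character(1))
  genomic <- paste(pieces, collapse = toy_intron(intron_len))
  starts <- integer(length(pieces)); ends <- integer(length(pieces))
  pos <- 0L
  for (i in seq_along(pieces)) {
    starts[i] <- pos
    ends[i] <- pos + nchar(pieces[i])
    pos <- ends[i] + intron_len
  }
  gene_structure(gene_id = gene_id, species_id = species_id, strand = "+",
                 exons = cbind(starts, ends), cds_start = 0L,
                 cds_end = cds_len, genomic_seq = genomic)
}

# --- the 27-species teleost hatching-enzyme fixture ------------------------

#' @keywords internal
teleost27_newick <- function() {
  oto <- paste0(
    "((Engraulis_japonicus,Sardinops_melanostictus)Clupeiformes,",
    "(Chanos_chanos,((Danio_rerio,Misgurnus_anguillicaudatus)Cypriniformes,",
    "(Paracheirodon_innesi,Electrophorus_electricus,Silurus_asotus)",
    "Characiphysi)Otophysi)Ostariophysi)Otocephala")
  eut <- paste0(
    "(((Oncorhynchus_masou,Oncorhynchus_mykiss)Salmoniformes,",
    "Esox_americanus)SalmEsoc,Oryzias_latipes,Fundulus_heteroclitus,",
    "Gadus_macrocephalus,Paralichthys_olivaceus,Stomias_nebulosus,",
    "Perciformes_sp,Lateolabrax_japonicus,Takifugu_rubripes,",
    "Scorpaeniformes_sp,Mugiliformes_sp)Euteleostei")
  paste0(
    "((Osteoglossum_bicirrhosum,Scleropages_formosus)Osteoglossomorpha,",
    "((Megalops_cyprinoides,Anguilla_japonica,Eurypharynx_pelecanoides,",
    "Aldrovandia_affinis)Elopomorpha,(", oto, ",", eut,
    ")Clupeocephala)Elopocephala)Teleostei;")
}

#' The "teleost27" preset species tree
#'
#' A rooted cladogram of the 27 study species: 2 osteoglossomorphs, 4
#' elopomorphs (one order each), 8 otocephalans in 6 orders and 13
#' euteleosts in 11 orders. Inter-ordinal relationships follow the
#' mitogenomic consensus for teleosts (Otocephala = Clupeiformes +
#' Ostariophysi; Otophysi = Cypriniformes + Characiphysi; Salmoniformes
#' sister to Esociformes within Euteleostei); relationships the study does
#' not constrain are left as polytomies. Two euteleost placeholders carry
#' explicitly synthetic names (`Perciformes_sp`, `Scorpaeniformes_sp`,
#' `Mugiliformes_sp`).
#'
#' @return A rooted `phylo` with labelled internal nodes (Teleostei,
#'   Clupeocephala, Otocephala, Otophysi, Characiphysi, Euteleostei,
#'   SalmEsoc, ...).
#' @export
teleost27_tree <- function() {
  read_rooted_tree(teleost27_newick())
}

# canonical gene inventory: gene, species, clade, ancestral site numbers
#' @keywords internal
fixture_inventory <- function() {
  g <- function(gene_id, species_id, group, sites, copy = NA_character_)
    data.frame(gene_id = gene_id, species_id = species_id, group = group,
               copy = copy, sites = I(list(sites)), stringsAsFactors = FALSE)
  all8 <- 1:8
  inv <- rbind(
    g("AwHE",  "Osteoglossum_bicirrhosum", "basal", all8),
    g("BtHE",  "Scleropages_formosus",     "basal", all8),
    g("McHE",  "Megalops_cyprinoides",     "basal", all8),
    g("EHE4",  "Anguilla_japonica",        "basal", all8),
    g("PeHE2", "Eurypharynx_pelecanoides", "basal", all8),
    g("AaHE",  "Aldrovandia_affinis",      "basal", all8),
    # clade I, otocephalans: 2nd ancestral intron lost
    g("AcHE1", "Engraulis_japonicus",     "cladeI", c(1, 3:8)),
    g("SaHE1", "Sardinops_melanostictus", "cladeI", c(1, 3:8)),
    g("MfHE1", "Chanos_chanos",           "cladeI", c(1, 3:8)),
    g("ZHE1",  "Danio_rerio",             "cladeI", c(1, 3:5)),
    g("LoHE1", "Misgurnus_anguillicaudatus", "cladeI", c(1, 3:5)),
    g("NtHE1", "Paracheirodon_innesi",    "cladeI", 3:5),
    g("EeHE1", "Electrophorus_electricus", "cladeI", 3:5),
    g("CfHE1", "Silurus_asotus",          "cladeI", 3:5),
    # clade I, euteleosts: intron-less (HCE)
    g("MHCE",  "Oryzias_latipes",        "cladeI", integer(0)),
    g("FhHCE", "Fundulus_heteroclitus",  "cladeI", integer(0)),
    g("GmHCE", "Gadus_macrocephalus",    "cladeI", integer(0)),
    g("PoHCE", "Paralichthys_olivaceus", "cladeI", integer(0)),
    g("SnHCE", "Stomias_nebulosus",      "cladeI", integer(0)),
    g("PfHCE", "Perciformes_sp",         "cladeI", integer(0)),
    g("LjHCE", "Lateolabrax_japonicus",  "cladeI", integer(0)),
    g("TrHCE", "Takifugu_rubripes",      "cladeI", integer(0)),
    g("ScHCE", "Scorpaeniformes_sp",     "cladeI", integer(0)),
    g("MgHCE", "Mugiliformes_sp",        "cladeI", integer(0)),
    # clade I, salmoniform/esociform duplicates: copy 1 carries one novel
    # intron at a site matching no other hatching-enzyme gene
    g("MsHCE1", "Oncorhynchus_masou",  "cladeI", "novel", copy = "HCE1"),
    g("RbHCE1", "Oncorhynchus_mykiss", "cladeI", "novel", copy = "HCE1"),
    g("PkHCE1", "Esox_americanus",     "cladeI", "novel", copy = "HCE1"),
    g("MsHCE2", "Oncorhynchus_masou",  "cladeI", integer(0), copy = "HCE2"),
    g("RbHCE2", "Oncorhynchus_mykiss", "cladeI", integer(0), copy = "HCE2"),
    g("PkHCE2", "Esox_americanus",     "cladeI", integer(0), copy = "HCE2"),
    # clade II, otocephalans (clupeiforms + gonorynchiforms only): ancestral
    g("AcHE3", "Engraulis_japonicus",     "cladeII", all8),
    g("SaHE2", "Sardinops_melanostictus", "cladeII", all8),
    g("MfHE3", "Chanos_chanos",           "cladeII", all8),
    # clade II, euteleosts (LCE): 8th ancestral intron lost
    g("MLCE",  "Oryzias_latipes",        "cladeII", 1:7),
    g("FhLCE", "Fundulus_heteroclitus",  "cladeII", 1:7),
    g("GmLCE", "Gadus_macrocephalus",    "cladeII", 1:7),
    g("PoLCE", "Paralichthys_olivaceus", "cladeII", 1:7),
    g("SnLCE", "Stomias_nebulosus",      "cladeII", 1:7),
    g("PfLCE", "Perciformes_sp",         "cladeII", 1:7),
    g("LjLCE", "Lateolabrax_japonicus",  "cladeII", 1:7),
    g("TrLCE", "Takifugu_rubripes",      "cladeII", 1:7),
    g("ScLCE", "Scorpaeniformes_sp",     "cladeII", 1:7),
    g("MgLCE", "Mugiliformes_sp",        "cladeII", 1:7),
    # clade II, salmoniform/esociform: intron-less
    g("MsLCE", "Oncorhynchus_masou",  "cladeII", integer(0)),
    g("RbLCE", "Oncorhynchus_mykiss", "cladeII", integer(0)),
    g("PkLCE", "Esox_americanus",     "cladeII", integer(0)))
  inv
}

# lineage-specific exception genes: flagged, no committed structure
#' @keywords internal
fixture_exceptions <- function() {
  data.frame(
    gene_id = c("EHE7", "PeHE1", "AcHE2", "MfHE2", "AcHE4", "AcHE5"),
    species_id = c("Anguilla_japonica", "Eurypharynx_pelecanoides",
                   "Engraulis_japonicus", "Chanos_chanos",
                   "Engraulis_japonicus", "Engraulis_japonicus"),
    group = c("basal", "basal", "cladeI", "cladeI", "cladeII", "cladeII"),
    stringsAsFactors = FALSE)
}

#' @keywords internal
fixture_gene_newick <- function(inv) {
  ids <- function(group, species) {
    sel <- inv$group == group & inv$species_id %in% species
    inv$gene_id[sel]
  }
  one <- function(group, species) {
    x <- ids(group, species)
    stopifnot(length(x) == 1)
    x
  }
  cI_oto <- sprintf(
    "((%s,%s),(%s,((%s,%s),(%s,%s,%s))))",
    one("cladeI", "Engraulis_japonicus"), one("cladeI", "Sardinops_melanostictus"),
    one("cladeI", "Chanos_chanos"),
    one("cladeI", "Danio_rerio"), one("cladeI", "Misgurnus_anguillicaudatus"),
    one("cladeI", "Paracheirodon_innesi"), one("cladeI", "Electrophorus_electricus"),
    one("cladeI", "Silurus_asotus"))
  se <- function(copy) sprintf("((%s,%s),%s)",
    inv$gene_id[inv$copy %in% copy & inv$species_id == "Oncorhynchus_masou"],
    inv$gene_id[inv$copy %in% copy & inv$species_id == "Oncorhynchus_mykiss"],
    inv$gene_id[inv$copy %in% copy & inv$species_id == "Esox_americanus"])
  eut_sp <- c("Oryzias_latipes", "Fundulus_heteroclitus", "Gadus_macrocephalus",
              "Paralichthys_olivaceus", "Stomias_nebulosus", "Perciformes_sp",
              "Lateolabrax_japonicus", "Takifugu_rubripes",
              "Scorpaeniformes_sp", "Mugiliformes_sp")
  cI_eut <- sprintf("((%s,%s),%s)", se("HCE1"), se("HCE2"),
                    paste(ids("cladeI", eut_sp), collapse = ","))
  cladeI <- sprintf("(%s,%s)", cI_oto, cI_eut)
  cII_oto <- sprintf("((%s,%s),%s)",
    one("cladeII", "Engraulis_japonicus"), one("cladeII", "Sardinops_melanostictus"),
    one("cladeII", "Chanos_chanos"))
  cII_se <- sprintf("((%s,%s),%s)",
    one("cladeII", "Oncorhynchus_masou"), one("cladeII", "Oncorhynchus_mykiss"),
    one("cladeII", "Esox_americanus"))
  cII_eut <- sprintf("(%s,%s)", cII_se,
                     paste(ids("cladeII", eut_sp), collapse = ","))
  cladeII <- sprintf("(%s,%s)", cII_oto, cII_eut)
  sprintf("((AwHE,BtHE),((McHE,EHE4,PeHE2,AaHE),(%s,%s)));", cladeI, cladeII)
}

#' Build the packaged teleost hatching-enzyme fixture
#'
#' Constructs, entirely in code and deterministically, a synthetic dataset
#' encoding the study's 27-species hatching-enzyme gene family:
#' 9-exon-8-intron basal (osteoglossomorph/elopomorph) genes; clade I genes
#' with 7 (clupeiform/gonorynchiform), 4 (cypriniform), 3 (characiphysan)
#' and 0 (euteleostean) introns plus the salmoniform/esociform duplicate
#' pair (one copy with a single novel intron, one intron-less); clade II
#' genes with 8 (otocephalan), 7 (euteleostean, 8th lost) and 0
#' (salmoniform/esociform) introns; clade II absent from otophysans; and
#' the six lineage-specific exception genes flagged without committed
#' structures. Toy sequences share one protein, so the supplied alignment
#' is the identity and every intron is canonical GT...AG.
#'
#' @param protein_len Length of the shared toy protein (default 120
#'   residues; the 8 ancestral sites sit at every 12th codon boundary and
#'   the novel salmoniform/esociform site at codon 50, all phase 0).
#' @return A list with `species_tree`, `gene_tree`, `structures` (named
#'   list of `gene_structure`), `alignment` (`codon_alignment`),
#'   `gene_to_species` (with `group`, `copy`, `exception` columns),
#'   `reference_genes` (basal genes defining the ancestral numbering),
#'   `site_offsets` (CDS offsets of ancestral sites 1..8 and the novel
#'   site) and `expected` (the text-stated event pathway used by the
#'   validation suite).
#' @export
build_paper_fixture <- function(protein_len = 120L) {
  protein <- toy_protein(protein_len)
  anc_offsets <- (1:8) * 36L          # codons 12,24,...,96; phase 0
  novel_offset <- 150L                # codon 50; phase 0
  stopifnot(max(anc_offsets, novel_offset) < 3L * protein_len)

  inv <- fixture_inventory()
  structures <- list()
  aln_rows <- character(0)
  for (i in seq_len(nrow(inv))) {
    sites <- inv$sites[[i]]
    offs <- if (identical(sites, "novel")) novel_offset else anc_offsets[sites]
    structures[[inv$gene_id[i]]] <- make_toy_gene(
      inv$gene_id[i], inv$species_id[i], protein, offs)
    aln_rows[inv$gene_id[i]] <- paste(protein, collapse = "")
  }

  exc <- fixture_exceptions()
  g2s <- rbind(
    data.frame(gene_id = inv$gene_id, species_id = inv$species_id,
               group = inv$group, copy = inv$copy, exception = FALSE,
               stringsAsFactors = FALSE),
    data.frame(gene_id = exc$gene_id, species_id = exc$species_id,
               group = exc$group, copy = NA_character_, exception = TRUE,
               stringsAsFactors = FALSE))

  expected <- list(
    duplication_branches = c("Clupeocephala", "SalmEsoc"),
    gene_loss = data.frame(branch = "Otophysi", lineage = "cladeII",
                           stringsAsFactors = FALSE),
    intron_events = rbind(
      data.frame(lineage = "cladeI", branch = "Otocephala", type = "loss",
                 ancestral_number = 2),
      data.frame(lineage = "cladeI", branch = "Otophysi", type = "loss",
                 ancestral_number = 6:8),
      data.frame(lineage = "cladeI", branch = "Characiphysi", type = "loss",
                 ancestral_number = 1),
      data.frame(lineage = "cladeI", branch = "Euteleostei", type = "loss",
                 ancestral_number = 1:8),
      data.frame(lineage = "cladeII", branch = "Euteleostei", type = "loss",
                 ancestral_number = 8),
      data.frame(lineage = "cladeII", branch = "SalmEsoc", type = "loss",
                 ancestral_number = 1:7),
      data.frame(lineage = "cladeI", branch = "SalmEsoc", type = "gain",
                 ancestral_number = NA)),
    n_loss_branches = 6L,
    max_cladeI_path_losses = 8L,
    root_intron_count = 8L)

  list(species_tree = teleost27_tree(),
       gene_tree = read_rooted_tree(fixture_gene_newick(inv)),
       structures = structures,
       alignment = codon_alignment(aln_rows),
       gene_to_species = g2s,
       reference_genes = inv$gene_id[inv$group == "basal"],
       site_offsets = c(stats::setNames(anc_offsets, paste0("anc", 1:8)),
                        novel = novel_offset),
       expected = expected)
}

#' Write the fixture to standard-format files
#'
#' Emits newick trees, an aligned protein FASTA, a genomic FASTA, the exon
#' table TSV and the gene-to-species TSV into a directory, so the pipeline
#' can be run from files exactly as on user data.
#'
#' @param dir Output directory (created if needed).
#' @param fixture A fixture list from [build_paper_fixture()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(dir, fixture = build_paper_fixture()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(species_tree = file.path(dir, "species_tree.nwk"),
         gene_tree = file.path(dir, "gene_tree.nwk"),
         alignment = file.path(dir, "alignment.faa"),
         genomic = file.path(dir, "genomic.fna"),
         structures = file.path(dir, "structures.tsv"),
         gene_to_species = file.path(dir, "gene_to_species.tsv"))
  ape::write.tree(fixture$species_tree, p["species_tree"])
  ape::write.tree(fixture$gene_tree, p["gene_tree"])
  writeLines(unlist(lapply(names(fixture$alignment$rows), function(id) {
    c(paste0(">", id), fixture$alignment$rows[[id]])
  })), p["alignment"])
  writeLines(unlist(lapply(fixture$structures, function(g) {
    c(paste0(">", g$gene_id), g$genomic_seq)
  })), p["genomic"])
  tab <- do.call(rbind, lapply(fixture$structures, function(g) {
    data.frame(gene_id = g$gene_id, species_id = g$species_id,
               strand = g$strand, exon_start = g$exons[, 1],
               exon_end = g$exons[, 2], cds_start = g$cds_start,
               cds_end = g$cds_end, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, p["structures"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fixture$gene_to_species, p["gene_to_species"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}

# --- simulator -------------------------------------------------------------

#' Simulation configuration
#'
#' @param species_tree `"balanced10"` (default: a 10-leaf rooted tree with
#'   a basal reference lineage), `"teleost27"`, a `phylo`, or a newick
#'   string.
#' @param n_root_sites Number of intron sites present in the root gene
#'   (default 8, the ancestral complement of the study family).
#' @param loss_prob Per-branch, per-site intron loss probability.
#' @param gain_prob Per-branch, per-gene probability of gaining one intron
#'   at a previously unused codon boundary (each novel site arises exactly
#'   once, so simulated histories satisfy the Dollo constraint by
#'   construction).
#' @param duplication_branches Branch labels (child-node addressed) at
#'   which every gene lineage present duplicates.
#' @param gene_loss Optional data.frame `branch`, `lineage`: gene lineages
#'   to delete on given branches.
#' @param subst_prob Per-branch, per-residue substitution probability for
#'   the toy proteins (no indels, so the emitted alignment is positional
#'   identity).
#' @param protein_len Protein length in residues.
#' @param seed Integer seed; the same seed reproduces identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(species_tree = "balanced10",
                              n_root_sites = 8L,
                              loss_prob = 0.1,
                              gain_prob = 0,
                              duplication_branches = character(0),
                              gene_loss = NULL,
                              subst_prob = 0,
                              protein_len = 120L,
                              seed = 1L) {
  for (p in c(loss_prob, gain_prob, subst_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  tree <- if (inherits(species_tree, "phylo")) species_tree
          else if (identical(species_tree, "balanced10")) balanced10_tree()
          else if (identical(species_tree, "teleost27")) teleost27_tree()
          else read_rooted_tree(species_tree)
  assert_rooted(tree)
  structure(list(species_tree = tree, n_root_sites = as.integer(n_root_sites),
                 loss_prob = loss_prob, gain_prob = gain_prob,
                 duplication_branches = duplication_branches,
                 gene_loss = gene_loss, subst_prob = subst_prob,
                 protein_len = as.integer(protein_len),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' The default 10-leaf simulation species tree
#'
#' Rooted, bifurcating, with a basal lineage (`out1`) splitting off first —
#' the usual design of a study clade plus reference outgroup.
#'
#' @return A `phylo` with labelled internal nodes `N1`..`N8`.
#' @export
balanced10_tree <- function() {
  read_rooted_tree(paste0(
    "(out1,(((s1,s2)N3,(s3,s4)N4)N2,((s5,s6)N6,(s7,(s8,s9)N8)N7)N5)N1)root;"))
}

#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a gene family with known intron gain/loss history
#'
#' Evolves gene content and intron complements top-down over the species
#' tree: designated duplications and gene losses, Bernoulli per-site intron
#' losses and per-gene single-origin intron gains on every branch, and
#' optional residue substitutions. Emits leaf gene structures (canonical
#' GT...AG toy introns), the identity protein alignment, the implied gene
#' tree, and the full ground-truth event list.
#'
#' @param cfg A `simulation_config`.
#' @return list with `structures`, `alignment`, `gene_tree`,
#'   `species_tree`, `gene_to_species`, and `ground_truth` (list: `events`
#'   data.frame with `branch`, `lineage`, `type`
#'   (`duplication`/`gene_loss`/`site_loss`/`site_gain`), `site_id`;
#'   `root_sites`; `site_offsets`; `leaf_states` logical matrix).
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    tree <- cfg$species_tree
    lab <- node_labels(tree)
    ch <- tree_children(tree)
    ntip <- ape::Ntip(tree)

    protein <- toy_protein(cfg$protein_len)
    # codon boundaries available as intron positions (offset = 3*codon)
    pool <- setdiff(seq_len(cfg$protein_len - 1L), 0L)
    root_codons <- round(seq(10, cfg$protein_len - 10,
                             length.out = cfg$n_root_sites))
    root_sites <- paste0("anc", seq_len(cfg$n_root_sites))
    site_offsets <- stats::setNames(3L * as.integer(root_codons), root_sites)
    pool <- setdiff(pool, root_codons)
    gain_counter <- 0L

    events <- list()
    note <- function(branch, lineage, type, site_id = NA_character_) {
      events[[length(events) + 1L]] <<- data.frame(
        branch = branch, lineage = lineage, type = type, site_id = site_id,
        stringsAsFactors = FALSE)
    }

    structures <- list()
    aln_rows <- character(0)
    g2s_rows <- list()
    leaf_states <- list()

    # recursive descent; returns, per surviving input gene, a newick
    # fragment for the gene tree
    descend <- function(node, genes) {
      if (node <= ntip) {
        frags <- stats::setNames(vector("list", length(genes)),
                                 vapply(genes, `[[`, character(1), "lineage"))
        for (g in genes) {
          gid <- paste0(lab[node], "|", g$lineage)
          structures[[gid]] <<- make_toy_gene(
            gid, lab[node], g$protein,
            unname(site_offsets[g$sites]))
          aln_rows[gid] <<- paste(g$protein, collapse = "")
          g2s_rows[[length(g2s_rows) + 1L]] <<- data.frame(
            gene_id = gid, species_id = lab[node], lineage = g$lineage,
            stringsAsFactors = FALSE)
          leaf_states[[gid]] <<- g$sites
          frags[[g$lineage]] <- gid
        }
        return(frags)
      }
      out <- stats::setNames(vector("list", length(genes)),
                             vapply(genes, `[[`, character(1), "lineage"))
      per_child <- list()
      for (c_ in ch[[node]]) {
        genes_c <- list()
        for (g in genes) {
          gs <- list(g)
          if (!is.null(cfg$gene_loss)) {
            hit <- cfg$gene_loss$branch == lab[c_] &
                   cfg$gene_loss$lineage == g$lineage
            if (any(hit)) {
              note(lab[c_], g$lineage, "gene_loss")
              next
            }
          }
          if (lab[c_] %in% cfg$duplication_branches) {
            note(lab[c_], g$lineage, "duplication")
            gs <- list(modifyList(g, list(lineage = paste0(g$lineage, "a"),
                                          parent = g$lineage)),
                       modifyList(g, list(lineage = paste0(g$lineage, "b"),
                                          parent = g$lineage)))
          }
          for (gg in gs) {
            # per-site losses
            lost <- gg$sites[stats::runif(length(gg$sites)) < cfg$loss_prob]
            for (s in lost) note(lab[c_], gg$lineage, "site_loss", s)
            gg$sites <- setdiff(gg$sites, lost)
            # single-origin gain
            if (length(pool) && stats::runif(1) < cfg$gain_prob) {
              gain_counter <<- gain_counter + 1L
              codon <- pool[1L]; pool <<- pool[-1L]
              sid <- paste0("novel", gain_counter)
              site_offsets[sid] <<- 3L * codon
              gg$sites <- c(gg$sites, sid)
              note(lab[c_], gg$lineage, "site_gain", sid)
            }
            # substitutions
            if (cfg$subst_prob > 0) {
              mut <- which(stats::runif(length(gg$protein)) < cfg$subst_prob)
              for (i in mut) {
                gg$protein[i] <- sample(setdiff(AA20, gg$protein[i]), 1L)
              }
            }
            genes_c[[length(genes_c) + 1L]] <- gg
          }
        }
        per_child[[length(per_child) + 1L]] <-
          if (length(genes_c)) descend(c_, genes_c) else list()
      }
      for (g in genes) {
        # collect this gene's fragments across children (a duplication on a
        # child branch contributes the pair of its daughter lineages)
        child_frags <- character(0)
        for (fr in per_child) {
          direct <- fr[[g$lineage]]
          if (!is.null(direct)) {
            child_frags <- c(child_frags, direct)
          } else {
            pair <- c(fr[[paste0(g$lineage, "a")]], fr[[paste0(g$lineage, "b")]])
            pair <- pair[!vapply(pair, is.null, logical(1))]
            if (length(pair) >= 2) {
              child_frags <- c(child_frags,
                               paste0("(", paste(unlist(pair), collapse = ","), ")"))
            } else if (length(pair) == 1) {
              child_frags <- c(child_frags, unlist(pair))
            }
          }
        }
        out[[g$lineage]] <-
          if (length(child_frags) >= 2)
            paste0("(", paste(child_frags, collapse = ","), ")")
          else if (length(child_frags) == 1) child_frags
          else NULL
      }
      out
    }

    root_gene <- list(lineage = "g", sites = root_sites, protein = protein)
    frags <- descend(root_node(tree), list(root_gene))
    gt_newick <- frags[["g"]]
    if (is.null(gt_newick)) stop("gene family went extinct in simulation")
    gene_tree <- if (grepl("^\\(", gt_newick))
      read_rooted_tree(paste0(gt_newick, ";")) else NULL  # single survivor

    ev <- if (length(events))
      do.call(rbind, c(events, list(make.row.names = FALSE)))
    else data.frame(branch = character(0), lineage = character(0),
                    type = character(0), site_id = character(0))

    all_sites <- names(site_offsets)
    lstates <- t(vapply(leaf_states,
                        function(s) stats::setNames(all_sites %in% s, all_sites),
                        logical(length(all_sites))))
    list(structures = structures,
         alignment = codon_alignment(aln_rows),
         gene_tree = gene_tree,
         species_tree = tree,
         gene_to_species = do.call(rbind, c(g2s_rows,
                                            list(make.row.names = FALSE))),
         ground_truth = list(events = ev, root_sites = root_sites,
                             site_offsets = site_offsets,
                             leaf_states = lstates))
  })
}
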