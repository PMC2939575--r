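# Gene structures, intron positions/phases, splice sites.

toy_tsv <- function(...) {
  df <- data.frame(...)
  names(df) <- c("gene_id", "species_id", "strand", "exon_start", "exon_end",
                 "cds_start", "cds_end")[seq_along(df)]
  df
}

test_that("parsed structures satisfy the exon/intron/CDS invariants", {
  # single-exon gene: 0 introns
  g1 <- parse_structures(data.frame(
    gene_id = "g1", species_id = "sp", strand = "+",
    exon_start = 0L, exon_end = 903L, cds_start = 0L, cds_end = 903L))[["g1"]]
  expect_s3_class(g1, "gene_structure")
  expect_identical(n_introns(g1), 0L)

  # 9-exon gene: 8 introns, the ancestral hatching-enzyme configuration
  fx <- build_paper_fixture()
  expect_identical(n_introns(fx$structures$AwHE), 8L)
  expect_identical(nrow(fx$structures$AwHE$exons), 9L)

  for (g in fx$structures) {
    expect_gte(sum(g$exons[, 2] - g$exons[, 1]), g$cds_end)
    expect_identical(n_introns(g), nrow(g$exons) - 1L)
    expect_identical((g$cds_end - g$cds_start) %% 3L, 0L)
  }

  # structural errors are caught and name the offender
  expect_error(gene_structure("bad", "sp", "+",
                              cbind(c(0, 50), c(60, 100)), 0, 99),
               "overlap")
  expect_error(gene_structure("bad2", "sp", "+", cbind(0, 100), 0, 100),
               "multiple of 3")
})

test_that("minus-strand records normalize to the plus-strand equivalent", {
  # 60-bp toy gene: 3 exons of 12 bp, 2 introns of 12 bp, CDS = 36 nt
  exons_plus <- cbind(c(0L, 24L, 48L), c(12L, 36L, 60L))
  seq_plus <- paste0("ATGGCTGCTGCT", "GTAAGTTTACAG", "TCTTCTGATGAT",
                     "GTAAGTTTACAG", "CATCATTGGTAA")
  plus <- parse_structures(
    data.frame(gene_id = "p", species_id = "sp", strand = "+",
               exon_start = exons_plus[, 1], exon_end = exons_plus[, 2],
               cds_start = 0L, cds_end = 36L),
    seqs = c(p = seq_plus))[["p"]]

  # same gene annotated on the minus strand of the reverse complement
  seq_minus <- intronloss:::revcomp_chr(seq_plus)
  L <- nchar(seq_minus)
  exons_minus <- cbind(L - exons_plus[, 2], L - exons_plus[, 1])
  minus <- parse_structures(
    data.frame(gene_id = "m", species_id = "sp", strand = "-",
               exon_start = exons_minus[, 1], exon_end = exons_minus[, 2],
               cds_start = 0L, cds_end = 36L),
    seqs = c(m = seq_minus))[["m"]]

  expect_identical(cds_sequence(minus), cds_sequence(plus))
  pp <- intron_positions(plus); pm <- intron_positions(minus)
  expect_identical(pm[c("cds_offset", "codon_index", "phase")],
                   pp[c("cds_offset", "codon_index", "phase")])
  expect_true(all(splice_site_report(minus)$canonical))
})

test_that("intron phases equal cds_offset mod 3, against a brute-force scan", {
  # exon boundary at CDS nt 300 -> phase 0; at 301 -> phase 1
  for (off in c(300L, 301L, 302L)) {
    g <- gene_structure("g", "sp", "+",
                        cbind(c(0L, off + 30L), c(off, off + 30L + (603L - off))),
                        0L, 603L)
    p <- intron_positions(g)
    expect_identical(p$cds_offset, off)
    expect_identical(p$phase, off %% 3L)
    expect_identical(p$codon_index, off %/% 3L)
  }

  # brute force: every nucleotide offset maps to the phase partition
  fx <- build_paper_fixture()
  for (g in fx$structures[c("AwHE", "MfHE1", "ZHE1", "MsHCE1")]) {
    p <- intron_positions(g)
    expect_identical(p$phase, vapply(p$cds_offset, function(o) {
      k <- 0L
      while (o >= 3L) { o <- o - 3L; k <- k + 1L }  # independent mod-3
      o
    }, integer(1L)))
    expect_false(is.unsorted(p$cds_offset, strictly = TRUE))
  }
})

test_that("UTR introns are excluded from coding intron positions", {
  # intron between a 3'UTR-only exon and the rest: boundary at transcript
  # offset 90 with CDS 0..90 -> excluded (insertion at cds_end)
  g <- gene_structure("g", "sp", "+", cbind(c(0L, 120L), c(90L, 150L)),
                      0L, 90L)
  expect_identical(nrow(intron_positions(g)), 0L)
  expect_identical(n_introns(g), 1L)  # still a structural intron
})

test_that("splice-site reports flag canonical GT...AG on the coding strand", {
  mk <- function(intron) {
    seqs <- paste0("ATGGCTGCTGCT", intron, "CATCATTGGTAA")
    gene_structure("g", "sp", "+",
                   cbind(c(0L, 12L + nchar(intron)), c(12L, nchar(seqs))),
                   0L, 24L, genomic_seq = seqs)
  }
  expect_true(splice_site_report(mk("GTAAGTTTTTCAG"))$canonical)
  expect_false(splice_site_report(mk("CTAAGTTTTTCAG"))$canonical)
  expect_false(splice_site_report(mk("GTAAGTTTTTCAA"))$canonical)
  expect_error(splice_site_report(
    gene_structure("g", "sp", "+", cbind(c(0, 20), c(10, 30)), 0, 12)),
    "genomic_seq")

  # simulator-emitted genes are canonical at every junction by construction
  sim <- simulate_family(simulation_config(seed = 11, loss_prob = 0.05))
  for (g in sim$structures) {
    rep_ <- splice_site_report(g)
    expect_true(all(rep_$canonical))
  }
})

test_that("terminal-intron prediction follows the GT donor rule", {
  protein <- intronloss:::toy_protein(40)
  # complete gene (stop codon inside last exon): never predicted
  complete <- intronloss:::make_toy_gene("c", "sp", protein, c(30L, 60L))
  expect_false(predict_terminal_intron(complete))

  # truncated annotation: drop the stop codon from the CDS and append
  # either a GT donor or an AT dinucleotide downstream
  mk_trunc <- function(after) {
    cds <- paste(intronloss:::CODON_OF[protein], collapse = "")
    gene_structure("t", "sp", "+", cbind(0L, nchar(cds)), 0L, nchar(cds),
                   genomic_seq = paste0(cds, after))
  }
  expect_true(predict_terminal_intron(mk_trunc("GTAAGTACGT")))
  expect_true(predict_terminal_intron(mk_trunc("ACGTAAGTAC")))  # GT within window
  expect_false(predict_terminal_intron(mk_trunc("ACAcacacacACAC")))
  expect_false(predict_terminal_intron(mk_trunc(strrep("A", 12))))
  # GT beyond the window is not accepted
  expect_false(predict_terminal_intron(mk_trunc(paste0(strrep("A", 11), "GT")),
                                       window = 10L))
})

test_that("GFF3 input parses to the same structures as the TSV route", {
  skip_if_not_installed("rtracklayer")
  gff <- file.path(tempdir(), "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1\t150\t.\t+\t.\tID=geneA",
    "chr1\ttoy\tmRNA\t1\t150\t.\t+\t.\tID=mA;Parent=geneA;gene_id=gA;species_id=sp1",
    "chr1\ttoy\texon\t1\t60\t.\t+\t.\tParent=mA",
    "chr1\ttoy\texon\t101\t150\t.\t+\t.\tParent=mA",
    "chr1\ttoy\tCDS\t10\t60\t.\t+\t0\tParent=mA",
    "chr1\ttoy\tCDS\t101\t148\t.\t+\t.\tParent=mA"), gff)
  gs <- parse_structures(gff, format = "gff3")
  g <- gs[["gA"]]
  expect_identical(g$species_id, "sp1")
  expect_identical(unname(g$exons[, 1]), c(0L, 100L))
  expect_identical(unname(g$exons[, 2]), c(60L, 150L))
  expect_identical(g$cds_start, 9L)
  expect_identical(g$cds_end, 60L + 48L)
  expect_identical((g$cds_end - g$cds_start) %% 3L, 0L)
  p <- intron_positions(g)
  expect_identical(p$cds_offset, 60L - 9L)
})
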