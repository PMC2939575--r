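# Gene structures, intron positions/phases, and splice-site checks.
#
# Internal coordinate convention: 0-based, half-open intervals on the coding
# strand. Minus-strand input is normalized at the parser boundary (exon order
# and coordinates flipped, sequence reverse-complemented), so every consumer
# below the parser sees plus-strand geometry only.

#' Construct a gene structure
#'
#' A `gene_structure` holds the exon layout of one gene copy together with
#' the CDS extent in transcript coordinates. Exons are genomic intervals
#' (0-based, half-open) in ascending order on the coding strand;
#' `cds_start`/`cds_end` are offsets into the concatenated exons, with
#' `cds_end` one past the stop codon.
#'
#' @param gene_id,species_id Identifiers (single strings).
#' @param strand `"+"` or `"-"`; the original strand of the record. The
#'   stored exon coordinates are always coding-strand.
#' @param exons Two-column matrix or data.frame of `start`, `end`.
#' @param cds_start,cds_end CDS offsets within the concatenated exons.
#' @param genomic_seq Optional nucleotide string covering the gene region
#'   (coding strand), used for splice-site reports.
#' @return An object of class `gene_structure`.
#' @export
gene_structure <- function(gene_id, species_id, strand = "+", exons,
                           cds_start, cds_end, genomic_seq = NULL) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2) stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  g <- structure(
    list(gene_id = as.character(gene_id),
         species_id = as.character(species_id),
         strand = match.arg(strand, c("+", "-")),
         exons = exons,
         cds_start = as.integer(cds_start),
         cds_end = as.integer(cds_end),
         genomic_seq = if (is.null(genomic_seq)) NULL else
           toupper(as.character(genomic_seq))),
    class = "gene_structure")
  validate_gene_structure(g)
}

#' @keywords internal
validate_gene_structure <- function(g) {
  ex <- g$exons
  id <- g$gene_id
  if (nrow(ex) < 1) stop("gene ", id, ": no exons")
  if (any(ex[, 2] <= ex[, 1])) stop("gene ", id, ": empty or inverted exon")
  if (nrow(ex) > 1) {
    if (any(diff(ex[, 1]) <= 0) || any(ex[-1, 1] < ex[-nrow(ex), 2]))
      stop("gene ", id, ": exons overlap or are not ascending")
  }
  tx_len <- sum(ex[, 2] - ex[, 1])
  if (g$cds_start < 0 || g$cds_end > tx_len)
    stop("gene ", id, ": CDS outside concatenated exons")
  cds_len <- g$cds_end - g$cds_start
  if (cds_len <= 0 || cds_len %% 3 != 0)
    stop("gene ", id, ": CDS length ", cds_len, " is not a positive multiple of 3")
  if (!is.null(g$genomic_seq) && max(ex[, 2]) > nchar(g$genomic_seq))
    stop("gene ", id, ": exon coordinates exceed genomic sequence length")
  g
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("<gene_structure %s (%s, %s strand): %d exon(s), %d intron(s), CDS %d..%d>\n",
              x$gene_id, x$species_id, x$strand, nrow(x$exons),
              nrow(x$exons) - 1L, x$cds_start, x$cds_end))
  invisible(x)
}

#' Number of introns of a gene structure
#' @param g A `gene_structure`.
#' @return Integer: exon count minus one.
#' @export
n_introns <- function(g) nrow(g$exons) - 1L

#' @keywords internal
revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           a = "t", c = "g", g = "c", t = "a", n = "n")
  chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  out <- map[chars]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

#' Parse gene structures from a TSV exon table or GFF3 file
#'
#' The TSV format has one row per exon with columns `gene_id`, `species_id`,
#' `strand`, `exon_start`, `exon_end` (0-based, half-open, genomic), and
#' `cds_start`, `cds_end` (transcript offsets, repeated on every row of a
#' gene). GFF3 input (1-based, inclusive; `exon` and `CDS` features grouped
#' by their `Parent` mRNA, one mRNA per gene) is converted to this convention
#' at the boundary. Reading GFF3 requires the rtracklayer package.
#'
#' Minus-strand records are normalized to coding-strand order: coordinates
#' are flipped relative to the record length and the genomic sequence (when
#' given) is reverse-complemented, so that all downstream operations can
#' assume plus-strand geometry.
#'
#' @param records Path to a TSV or GFF3 file, or a data.frame in the TSV
#'   layout.
#' @param seqs Optional genomic sequences: a named character vector, a
#'   `Biostrings::DNAStringSet`, or a FASTA path. Names must match
#'   `gene_id`s; each record holds the genomic region of that gene, to which
#'   the exon coordinates refer.
#' @param format `"auto"` (default), `"tsv"`, or `"gff3"`.
#' @return A named list of `gene_structure` objects, in input order.
#' @export
parse_structures <- function(records, seqs = NULL, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  seqs <- load_seqs(seqs)
  if (is.data.frame(records)) {
    tab <- records
  } else {
    if (format == "auto") {
      format <- if (grepl("\\.gff3?$", records, ignore.case = TRUE)) "gff3" else "tsv"
    }
    tab <- if (format == "gff3") gff3_to_exon_table(records)
           else utils::read.delim(records, stringsAsFactors = FALSE)
  }
  need <- c("gene_id", "species_id", "strand", "exon_start", "exon_end",
            "cds_start", "cds_end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("exon table lacks columns: ", paste(miss, collapse = ", "))

  out <- list()
  for (id in unique(tab$gene_id)) {
    rows <- tab[tab$gene_id == id, , drop = FALSE]
    strand <- rows$strand[1]
    ex <- cbind(start = rows$exon_start, end = rows$exon_end)
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    seq <- if (!is.null(seqs) && id %in% names(seqs)) seqs[[id]] else NULL
    if (strand == "-") {
      # flip onto the coding strand; record length anchors the mirror
      L <- if (!is.null(seq)) nchar(seq) else max(ex[, 2])
      ex <- cbind(start = L - ex[, 2], end = L - ex[, 1])
      ex <- ex[order(ex[, 1]), , drop = FALSE]
      if (!is.null(seq)) seq <- revcomp_chr(seq)
    }
    out[[id]] <- gene_structure(
      gene_id = id, species_id = rows$species_id[1], strand = strand,
      exons = ex, cds_start = rows$cds_start[1], cds_end = rows$cds_end[1],
      genomic_seq = seq)
  }
  out
}

#' @keywords internal
load_seqs <- function(seqs) {
  if (is.null(seqs)) return(NULL)
  if (inherits(seqs, "DNAStringSet")) return(as.list(as.character(seqs)))
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs)) {
    ss <- Biostrings::readDNAStringSet(seqs)
    names(ss) <- sub("\\s.*$", "", names(ss))
    return(as.list(as.character(ss)))
  }
  as.list(seqs)
}

# GFF3 -> internal exon table. CDS features define the CDS extent; exon
# features the transcript. 1-based inclusive converted to 0-based half-open.
#' @keywords internal
gff3_to_exon_table <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 input requires the rtracklayer package")
  gff <- as.data.frame(rtracklayer::readGFF(path))
  mrna <- gff[gff$type == "mRNA", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(mrna))) {
    mid <- mrna$ID[i]
    gene_id <- if (!is.null(mrna$gene_id) && !is.na(mrna$gene_id[i]))
      mrna$gene_id[i] else mid
    species <- if ("species_id" %in% names(mrna) && !is.na(mrna$species_id[i]))
      mrna$species_id[i] else as.character(mrna$seqid[i])
    ex <- exons[vapply(exons$Parent, function(p) mid %in% p, logical(1)), ,
                drop = FALSE]
    cd <- cds[vapply(cds$Parent, function(p) mid %in% p, logical(1)), ,
              drop = FALSE]
    if (!nrow(ex)) stop("mRNA ", mid, " has no exon features")
    if (!nrow(cd)) stop("mRNA ", mid, " has no CDS features")
    strand <- as.character(ex$strand[1])
    ex <- ex[order(ex$start), , drop = FALSE]
    starts0 <- ex$start - 1L
    ends0 <- ex$end
    # CDS extent in transcript coordinates (coding-strand order)
    exlens <- ends0 - starts0
    cum <- c(0L, cumsum(exlens))
    cds_lo_g <- min(cd$start) - 1L
    cds_hi_g <- max(cd$end)
    tx_of <- function(gpos) { # genomic (0-based) -> plus-strand transcript offset
      k <- which(gpos >= starts0 & gpos <= ends0)[1]
      if (is.na(k)) stop("mRNA ", mid, ": CDS boundary outside exons")
      cum[k] + (gpos - starts0[k])
    }
    lo_t <- tx_of(cds_lo_g); hi_t <- tx_of(cds_hi_g - 1L) + 1L
    txlen <- sum(exlens)
    if (strand == "-") { tmp <- lo_t; lo_t <- txlen - hi_t; hi_t <- txlen - tmp }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, species_id = species, strand = strand,
      exon_start = starts0, exon_end = ends0,
      cds_start = lo_t, cds_end = hi_t, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Intron positions of a gene in CDS coordinates
#'
#' Each intron's insertion point is the CDS offset of the first base of the
#' downstream exon; the phase is that offset modulo 3 (0 = between codons,
#' 1/2 = after the first/second base of a codon). Introns falling outside
#' the CDS (UTR introns) are excluded from the result.
#'
#' @param g A `gene_structure`.
#' @return data.frame with columns `gene_id`, `intron_index` (1-based, over
#'   all introns of the gene), `cds_offset`, `codon_index`, `phase`.
#' @export
intron_positions <- function(g) {
  stopifnot(inherits(g, "gene_structure"))
  ex <- g$exons
  k <- nrow(ex) - 1L
  if (k < 1) {
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      cds_offset = integer(0), codon_index = integer(0),
                      phase = integer(0)))
  }
  tx <- cumsum(ex[, 2] - ex[, 1])[seq_len(k)]  # transcript offset of each boundary
  off <- tx - g$cds_start
  keep <- off >= 0L & off < (g$cds_end - g$cds_start)
  data.frame(gene_id = rep(g$gene_id, sum(keep)),
             intron_index = which(keep),
             cds_offset = as.integer(off[keep]),
             codon_index = as.integer(off[keep] %/% 3L),
             phase = as.integer(off[keep] %% 3L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Splice-site dinucleotide report for every intron of a gene
#'
#' Reports the donor (first two) and acceptor (last two) intron bases on the
#' coding strand and flags canonical GT...AG spliceosomal introns.
#'
#' @param g A `gene_structure` with `genomic_seq`.
#' @return data.frame with `gene_id`, `intron_index`, `donor_dinucleotide`,
#'   `acceptor_dinucleotide`, `canonical`.
#' @export
splice_site_report <- function(g) {
  stopifnot(inherits(g, "gene_structure"))
  if (is.null(g$genomic_seq))
    stop("gene ", g$gene_id, ": splice-site report requires genomic_seq")
  ex <- g$exons
  k <- nrow(ex) - 1L
  if (k < 1) {
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      donor_dinucleotide = character(0),
                      acceptor_dinucleotide = character(0),
                      canonical = logical(0)))
  }
  donor <- acceptor <- character(k)
  for (i in seq_len(k)) {
    istart <- ex[i, 2]       # 0-based first intron base
    iend <- ex[i + 1, 1]     # one past last intron base
    donor[i] <- substr(g$genomic_seq, istart + 1, istart + 2)
    acceptor[i] <- substr(g$genomic_seq, iend - 1, iend)
  }
  data.frame(gene_id = g$gene_id, intron_index = seq_len(k),
             donor_dinucleotide = donor, acceptor_dinucleotide = acceptor,
             canonical = donor == "GT" & acceptor == "AG",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict an unconfirmed terminal intron by the GT donor rule
#'
#' When a gene's annotated exons end without reaching a stop codon, a final
#' (unconfirmed) exon may lie further downstream. Presence of the canonical
#' 5'-splice-site donor "GT" shortly after the last confirmed coding
#' position is taken as evidence for a terminal intron and hence for the
#' extra exon. If the annotated CDS already terminates in a stop codon the
#' gene is complete and the prediction is `FALSE` regardless of downstream
#' sequence.
#'
#' @param g A `gene_structure` with `genomic_seq`.
#' @param window Number of genomic positions after the last annotated exon
#'   end at which the candidate donor may start (default 10).
#' @return `TRUE` iff a terminal intron is predicted.
#' @export
predict_terminal_intron <- function(g, window = 10L) {
  stopifnot(inherits(g, "gene_structure"))
  if (is.null(g$genomic_seq))
    stop("gene ", g$gene_id, ": prediction requires genomic_seq")
  cds <- cds_sequence(g)
  last3 <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (last3 %in% c("TAA", "TAG", "TGA")) return(FALSE)
  last_end <- max(g$exons[, 2])  # 0-based, one past last exon base
  for (d in 0:(window - 1L)) {
    di <- substr(g$genomic_seq, last_end + d + 1L, last_end + d + 2L)
    if (identical(di, "GT")) return(TRUE)
  }
  FALSE
}

#' Spliced CDS nucleotide sequence of a gene
#' @param g A `gene_structure` with `genomic_seq`.
#' @return Character string of the CDS (stop codon included).
#' @export
cds_sequence <- function(g) {
  stopifnot(inherits(g, "gene_structure"))
  if (is.null(g$genomic_seq)) stop("gene ", g$gene_id, ": no genomic_seq")
  ex <- g$exons
  tx <- paste(vapply(seq_len(nrow(ex)),
                     function(i) substr(g$genomic_seq, ex[i, 1] + 1, ex[i, 2]),
                     character(1)),
              collapse = "")
  substr(tx, g$cds_start + 1, g$cds_end)
}

#' Write a table of intron positions (with splice-site status) to TSV
#'
#' @param genes List of `gene_structure` objects.
#' @param path Output TSV path, or `NULL` to only return the table.
#' @return (Invisibly) the combined data.frame, one row per coding intron,
#'   with a `canonical` column where sequence is available (NA otherwise).
#' @export
intron_position_table <- function(genes, path = NULL) {
  rows <- lapply(genes, function(g) {
    pos <- intron_positions(g)
    pos$canonical <- rep(NA, nrow(pos))
    if (!is.null(g$genomic_seq) && nrow(pos)) {
      rep_ <- splice_site_report(g)
      pos$canonical <- rep_$canonical[match(pos$intron_index, rep_$intron_index)]
    }
    pos
  })
  tab <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame()
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}
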