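# Projection of intron positions onto a shared protein alignment and
# construction of the homologous intron-site character matrix.
#
# Two introns are treated as the same evolutionary character exactly when
# they project to the same alignment column with the same phase; equal
# columns with different phases are always distinct sites.

#' Construct a codon/protein alignment object
#'
#' Wraps an aligned set of amino-acid sequences (gap character `-`) together
#' with, per gene, the map from ungapped residue index to alignment column
#' and the offset of the aligned region within the full protein.
#'
#' @param rows Named character vector of aligned amino-acid strings (equal
#'   lengths), or a `Biostrings::AAStringSet`.
#' @param region_start Named integer vector: for each gene, the 0-based
#'   residue offset of the first aligned residue within the full protein
#'   (default 0 for all genes, i.e. the alignment covers the protein from
#'   its first residue).
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(rows, region_start = NULL) {
  if (inherits(rows, "AAStringSet")) {
    rows <- stats::setNames(as.character(rows), names(rows))
  }
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by gene_id")
  if (anyDuplicated(names(rows)))
    stop("duplicated gene ids in alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("alignment rows have unequal lengths")
  maps <- lapply(rows, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] != "-")
  })
  rs <- stats::setNames(rep(0L, length(rows)), names(rows))
  if (!is.null(region_start)) {
    rs[names(region_start)] <- as.integer(region_start)
  }
  structure(list(rows = rows, ncol = w, maps = maps, region_start = rs),
            class = "codon_alignment")
}

#' Read a protein alignment from an aligned FASTA file
#' @param path Aligned FASTA (amino acids, `-` gaps).
#' @param region_start See [codon_alignment()].
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, region_start = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  codon_alignment(aa, region_start = region_start)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment: %d sequences x %d columns>\n",
              length(x$rows), x$ncol))
  invisible(x)
}

#' Ungapped sequence of one alignment row
#' @param aln A `codon_alignment`.
#' @param gene_id Row name.
#' @return Character string without gaps.
#' @export
ungapped_row <- function(aln, gene_id) {
  gsub("-", "", aln$rows[[gene_id]], fixed = TRUE)
}

#' Project one intron position onto the alignment
#'
#' The intron is assigned to the alignment column of the residue containing
#' its insertion point (phases 1 and 2) or of the residue immediately
#' following it (phase 0); with `codon_index` counted from the CDS start,
#' both cases reduce to the residue at index `codon_index`. Positions
#' upstream or downstream of the gene's aligned region are unprojectable
#' and later scored "missing".
#'
#' @param g A `gene_structure` (only its `gene_id` is used).
#' @param aln A `codon_alignment` containing a row for the gene.
#' @param p One row of [intron_positions()] (needs `codon_index`, `phase`).
#' @return list with `column` (alignment column or `NA`), `phase`,
#'   `projectable`.
#' @export
project_intron <- function(g, aln, p) {
  id <- if (inherits(g, "gene_structure")) g$gene_id else as.character(g)
  if (!id %in% names(aln$rows)) stop("gene ", id, " absent from alignment")
  res0 <- p$codon_index - aln$region_start[[id]]
  map <- aln$maps[[id]]
  if (res0 < 0 || res0 >= length(map)) {
    return(list(column = NA_integer_, phase = as.integer(p$phase),
                projectable = FALSE))
  }
  list(column = map[[res0 + 1L]], phase = as.integer(p$phase),
       projectable = TRUE)
}

#' Project all coding introns of a set of genes
#'
#' @param genes List of `gene_structure` objects.
#' @param aln A `codon_alignment`. Genes without an alignment row are
#'   skipped with a warning.
#' @return data.frame `gene_id`, `intron_index`, `column`, `phase`,
#'   `projectable`.
#' @export
project_all_introns <- function(genes, aln) {
  out <- list()
  for (g in genes) {
    if (!g$gene_id %in% names(aln$rows)) {
      warning("gene ", g$gene_id, " absent from alignment; excluded")
      next
    }
    pos <- intron_positions(g)
    if (!nrow(pos)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = character(0), intron_index = integer(0),
        column = integer(0), phase = integer(0), projectable = logical(0))
      next
    }
    pr <- lapply(seq_len(nrow(pos)), function(i) project_intron(g, aln, pos[i, ]))
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g$gene_id,
      intron_index = pos$intron_index,
      column = vapply(pr, `[[`, integer(1), "column"),
      phase = vapply(pr, `[[`, integer(1), "phase"),
      projectable = vapply(pr, `[[`, logical(1), "projectable"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      column = integer(0), phase = integer(0),
                      projectable = logical(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cluster projected introns into homologous sites
#'
#' One site per distinct (column, phase) pair, ordered by column then phase.
#' Sites observed in the designated basal reference genes are numbered
#' 1..k left-to-right as `ancestral_number`; all other sites (lineage-
#' specific or novel) get `NA`.
#'
#' @param projections data.frame as from [project_all_introns()]
#'   (unprojectable rows are ignored).
#' @param reference_genes Character vector of gene ids whose sites define
#'   the ancestral numbering; `NULL` leaves all `ancestral_number`s `NA`.
#' @return data.frame `site_id`, `column`, `phase`, `ancestral_number`.
#' @export
cluster_sites <- function(projections, reference_genes = NULL) {
  pr <- projections[projections$projectable, , drop = FALSE]
  key <- paste(pr$column, pr$phase, sep = "/")
  sites <- unique(data.frame(column = pr$column, phase = pr$phase))
  sites <- sites[order(sites$column, sites$phase), , drop = FALSE]
  rownames(sites) <- NULL
  sites$site_id <- sprintf("c%dp%d", sites$column, sites$phase)
  sites$ancestral_number <- rep(NA_integer_, nrow(sites))
  if (!is.null(reference_genes) && nrow(sites)) {
    ref_keys <- unique(key[pr$gene_id %in% reference_genes])
    anc <- paste(sites$column, sites$phase, sep = "/") %in% ref_keys
    sites$ancestral_number[anc] <- seq_len(sum(anc))
  }
  sites[, c("site_id", "column", "phase", "ancestral_number")]
}

#' Merge near-adjacent same-phase sites (alignment jitter tolerance)
#'
#' Sites with equal phase whose columns lie within `tolerance` of each other
#' (chained transitively) are merged to the leftmost column of the group.
#' `tolerance = 0` is the identity. Sites of different phase are never
#' merged, whatever the tolerance.
#'
#' @param sites Site table as from [cluster_sites()].
#' @param tolerance Non-negative integer column distance.
#' @return Site table of the merged sites, with a `merged_from` list column
#'   giving the original site_ids of each group.
#' @export
column_slop_merge <- function(sites, tolerance = 0L) {
  stopifnot(tolerance >= 0)
  out <- list()
  for (ph in sort(unique(sites$phase))) {
    s <- sites[sites$phase == ph, , drop = FALSE]
    s <- s[order(s$column), , drop = FALSE]
    grp <- cumsum(c(1L, diff(s$column) > tolerance))
    for (gidx in unique(grp)) {
      block <- s[grp == gidx, , drop = FALSE]
      anc <- block$ancestral_number[!is.na(block$ancestral_number)]
      out[[length(out) + 1L]] <- data.frame(
        site_id = block$site_id[1],
        column = block$column[1],
        phase = ph,
        ancestral_number = if (length(anc)) min(anc) else NA_integer_,
        merged_from = I(list(block$site_id)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res <- res[order(res$column, res$phase), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the genes x intron-sites presence/absence character matrix
#'
#' States are `"1"` (present), `"0"` (absent) and `"?"` (missing: the site's
#' column lies outside the region of the protein covered by that gene's
#' alignment row). Genes lacking any alignment row are excluded with a
#' warning; row order follows input order and site order is by column then
#' phase, so the matrix is deterministic.
#'
#' @param genes List of `gene_structure` objects.
#' @param aln A `codon_alignment`.
#' @param reference_genes Basal genes defining the ancestral site numbering
#'   (see [cluster_sites()]).
#' @param tolerance Column-jitter tolerance passed to the same-phase merge
#'   step (default 0 = exact column match required).
#' @return An object of class `intron_site_matrix`: list with `states`
#'   (character matrix genes x sites), `sites` (site table), `genes`.
#' @export
build_matrix <- function(genes, aln, reference_genes = NULL, tolerance = 0L) {
  genes <- genes[vapply(genes, function(g) {
    ok <- g$gene_id %in% names(aln$rows)
    if (!ok) warning("gene ", g$gene_id, " absent from alignment; excluded")
    ok
  }, logical(1))]
  pr <- project_all_introns(genes, aln)
  sites <- cluster_sites(pr, reference_genes = reference_genes)
  if (tolerance > 0 && nrow(sites)) {
    merged <- column_slop_merge(sites, tolerance)
    # remap projections onto merged representative columns
    for (i in seq_len(nrow(merged))) {
      from <- merged$merged_from[[i]]
      sel <- sprintf("c%dp%d", pr$column, pr$phase) %in% from
      pr$column[sel] <- merged$column[i]
    }
    sites <- merged[, c("site_id", "column", "phase", "ancestral_number")]
    sites$site_id <- sprintf("c%dp%d", sites$column, sites$phase)
  }
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  states <- matrix("0", nrow = length(genes), ncol = nrow(sites),
                   dimnames = list(gene_ids, sites$site_id))
  prkey <- sprintf("c%dp%d", pr$column, pr$phase)
  for (gi in seq_along(genes)) {
    id <- gene_ids[gi]
    map <- aln$maps[[id]]
    if (length(map)) {
      cov_lo <- min(map); cov_hi <- max(map)
      outside <- sites$column < cov_lo | sites$column > cov_hi
      states[gi, outside] <- "?"
    } else {
      states[gi, ] <- "?"
    }
    mine <- prkey[pr$gene_id == id & pr$projectable]
    states[gi, sites$site_id %in% mine] <- "1"
  }
  structure(list(states = states, sites = sites, genes = gene_ids),
            class = "intron_site_matrix")
}

#' @export
print.intron_site_matrix <- function(x, ...) {
  cat(sprintf("<intron_site_matrix: %d genes x %d sites (%d ancestral)>\n",
              nrow(x$states), ncol(x$states),
              sum(!is.na(x$sites$ancestral_number))))
  invisible(x)
}

#' Write the character matrix and site table to TSV files
#'
#' @param m An `intron_site_matrix`.
#' @param matrix_path,sites_path Output paths (`NULL` to skip either).
#' @return `m`, invisibly.
#' @export
write_matrix_tsv <- function(m, matrix_path = NULL, sites_path = NULL) {
  if (!is.null(matrix_path)) {
    df <- data.frame(gene_id = rownames(m$states), m$states,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(sites_path)) {
    utils::write.table(m$sites, sites_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(m)
}
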