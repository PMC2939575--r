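# End-to-end orchestration: files in, report bundle out.

#' Build / validate a pipeline configuration
#'
#' @param structures Path to the exon-table TSV (or GFF3).
#' @param alignment Path to the aligned protein FASTA.
#' @param gene_tree,species_tree Paths to rooted newick files.
#' @param gene_to_species Path to a TSV with `gene_id`, `species_id` and
#'   optionally `group` (lineage label; genes with group `"basal"` define
#'   the ancestral site numbering), `exception` (logical: lineage-specific
#'   exception genes, excluded unless `include_exceptions`).
#' @param genomic Optional genomic FASTA (enables splice-site reporting).
#' @param out_dir Output directory for the report bundle.
#' @param tolerance Column-jitter tolerance for intron-site clustering.
#' @param method `"dollo"` (default) or `"fitch"` ancestral reconstruction.
#' @param cost_mode `"serial_minimum"` or `"per_intron"` (see [total_cost()]).
#' @param include_exceptions Include flagged exception genes (default FALSE).
#' @param anchor_root Anchor ancestral-numbered sites as present at the
#'   root during Dollo reconstruction (default TRUE; see
#'   [dollo_reconstruct()]).
#' @param duplication_inherit See [dollo_reconstruct()] (default TRUE).
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(structures, alignment, gene_tree, species_tree,
                            gene_to_species, genomic = NULL,
                            out_dir = "intronloss_out", tolerance = 0L,
                            method = c("dollo", "fitch"),
                            cost_mode = c("serial_minimum", "per_intron"),
                            include_exceptions = FALSE, anchor_root = TRUE,
                            duplication_inherit = TRUE, seed = 1L) {
  cfg <- list(structures = structures, alignment = alignment,
              gene_tree = gene_tree, species_tree = species_tree,
              gene_to_species = gene_to_species, genomic = genomic,
              out_dir = out_dir, tolerance = as.integer(tolerance),
              method = match.arg(method), cost_mode = match.arg(cost_mode),
              include_exceptions = isTRUE(include_exceptions),
              anchor_root = isTRUE(anchor_root),
              duplication_inherit = isTRUE(duplication_inherit),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("structures", "alignment", "gene_tree", "species_tree",
              "gene_to_species", "genomic", "out_dir")) {
    if (!is.null(y[[k]]) && !grepl("^/", y[[k]]))
      y[[k]] <- file.path(base, y[[k]])
  }
  do.call(pipeline_config, y)
}

#' @keywords internal
validate_pipeline_config <- function(cfg) {
  req <- c("structures", "alignment", "gene_tree", "species_tree",
           "gene_to_species")
  for (k in req) {
    if (is.null(cfg[[k]])) stop("pipeline config lacks input: ", k)
    if (!file.exists(cfg[[k]]))
      stop("pipeline input does not exist: ", k, " = ", cfg[[k]])
  }
  if (!is.null(cfg$genomic) && !file.exists(cfg$genomic))
    stop("pipeline input does not exist: genomic = ", cfg$genomic)
  if (cfg$tolerance < 0) stop("tolerance must be >= 0")
  cfg
}

#' Run the full intron-evolution pipeline
#'
#' Stages: parse gene structures; derive intron positions (and splice-site
#' status when sequence is available); project onto the alignment and build
#' the intron-site character matrix; reconcile the gene tree with the
#' species tree; reconstruct ancestral intron complements and per-branch
#' events; summarize the pathway; evaluate the expression time-cost model.
#' Each stage's table is written into `out_dir`, together with a JSON
#' manifest recording per-stage record counts, options and the package
#' version. Running twice on identical inputs produces identical bundles.
#' On stage failure a `FAILED` marker naming the stage is left in
#' `out_dir` and the error is re-thrown.
#'
#' @param cfg A `pipeline_config` (or YAML path).
#' @return Invisibly, a list with the in-memory stage results
#'   (`structures`, `matrix`, `reconciliation`, `states`, `events`,
#'   `pathway`, `costs`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    unlink(file.path(cfg$out_dir, "FAILED"))

    stage <- "structures"
    g2s <- utils::read.delim(cfg$gene_to_species, stringsAsFactors = FALSE)
    if (!"group" %in% names(g2s)) g2s$group <- "all"
    if (!"exception" %in% names(g2s)) g2s$exception <- FALSE
    genes <- parse_structures(cfg$structures, seqs = cfg$genomic)
    if (!cfg$include_exceptions) {
      keep <- !(vapply(genes, `[[`, character(1), "gene_id") %in%
                  g2s$gene_id[g2s$exception])
      genes <- genes[keep]
    }
    pos_tab <- intron_position_table(
      genes, file.path(cfg$out_dir, "intron_positions.tsv"))

    stage <- "matrix"
    aln <- read_codon_alignment(cfg$alignment)
    reference <- g2s$gene_id[g2s$group == "basal" & !g2s$exception]
    if (!length(reference)) reference <- NULL
    mat <- build_matrix(genes, aln, reference_genes = reference,
                        tolerance = cfg$tolerance)
    write_matrix_tsv(mat, file.path(cfg$out_dir, "matrix.tsv"),
                     file.path(cfg$out_dir, "sites.tsv"))

    stage <- "reconcile"
    gtree <- read_rooted_tree(cfg$gene_tree)
    stree <- read_rooted_tree(cfg$species_tree)
    rec <- lca_map(gtree, stree, g2s[!g2s$exception | cfg$include_exceptions, ])
    write_reconciliation_json(rec, file.path(cfg$out_dir, "reconciliation.json"))
    loss_tab <- report_gene_losses(rec)
    utils::write.table(loss_tab, file.path(cfg$out_dir, "gene_losses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "events"
    root_state <- if (cfg$anchor_root)
      mat$sites$site_id[!is.na(mat$sites$ancestral_number)] else NULL
    states <- if (cfg$method == "dollo") {
      dollo_reconstruct(mat, rec = rec, root_state = root_state,
                        duplication_inherit = cfg$duplication_inherit)
    } else {
      fitch_reconstruct(mat, rec = rec)
    }
    groups <- stats::setNames(g2s$group, g2s$gene_id)
    ev <- infer_events(states, gene_groups = groups)
    write_events_json(ev, file.path(cfg$out_dir, "events.json"))

    stage <- "pathway"
    path_sum <- summarize_pathway(ev)
    utils::write.table(path_sum$per_lineage,
                       file.path(cfg$out_dir, "pathway_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(path_sum$loss_branches,
                       file.path(cfg$out_dir, "loss_branches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "cost"
    counts <- vapply(genes, function(g) nrow(intron_positions(g)), integer(1))
    names(counts) <- vapply(genes, `[[`, character(1), "gene_id")
    costs <- cost_table(counts, mode = cfg$cost_mode,
                        path = file.path(cfg$out_dir, "costs.tsv"))

    stage <- "manifest"
    manifest <- list(
      package = "intronloss",
      version = as.character(utils::packageVersion("intronloss")),
      seed = cfg$seed,
      options = cfg[c("tolerance", "method", "cost_mode",
                      "include_exceptions", "anchor_root",
                      "duplication_inherit")],
      records = list(genes = length(genes),
                     intron_positions = nrow(pos_tab),
                     sites = nrow(mat$sites),
                     matrix_rows = nrow(mat$states),
                     duplications = sum(rec$events == "duplication"),
                     gene_losses = nrow(rec$losses),
                     events = nrow(ev),
                     loss_branches = path_sum$n_loss_branches,
                     cost_rows = nrow(costs)))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    invisible(list(structures = genes, matrix = mat, reconciliation = rec,
                   states = states, events = ev, pathway = path_sum,
                   costs = costs, manifest = manifest))
  }, error = on_fail)
}

#' Write the packaged fixture and run the pipeline on it
#'
#' Convenience wrapper: materializes the synthetic hatching-enzyme fixture
#' into `fixture_dir`, then runs [run_pipeline()] with default options.
#'
#' @param out_dir Report-bundle directory.
#' @param fixture_dir Where to write the fixture files (default: a
#'   subdirectory `fixture` of `out_dir`).
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_fixture_pipeline <- function(out_dir = "intronloss_out",
                                 fixture_dir = file.path(out_dir, "fixture")) {
  paths <- write_fixture(fixture_dir)
  cfg <- pipeline_config(structures = paths[["structures"]],
                         alignment = paths[["alignment"]],
                         gene_tree = paths[["gene_tree"]],
                         species_tree = paths[["species_tree"]],
                         gene_to_species = paths[["gene_to_species"]],
                         genomic = paths[["genomic"]],
                         out_dir = out_dir)
  run_pipeline(cfg)
}
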