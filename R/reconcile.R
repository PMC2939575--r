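# Gene-tree / species-tree reconciliation by LCA mapping under
# duplication-loss parsimony.
#
# Every gene-tree node is mapped to the last common ancestor (in the species
# tree) of the species of the genes below it. Duplications are called where
# two child lineages of a gene-tree node descend through a common child
# branch of the mapped species node; on binary species trees this is the
# classical "M(v) equals M(child)" criterion, while at species-tree
# polytomies it implements soft-polytomy semantics (unresolved radiations
# never force duplications by themselves). Losses are the minimum implied
# by the mapping and are addressed by the child node of the species-tree
# branch on which the lineage disappeared.

#' Reconcile a rooted gene tree with a rooted species tree
#'
#' @param gtree Rooted gene tree (`phylo`); tips are gene ids.
#' @param stree Rooted species tree (`phylo`); tips are species ids.
#'   Polytomies are allowed and treated as soft.
#' @param gene_to_species data.frame with columns `gene_id`, `species_id`
#'   covering every gene-tree tip.
#' @return An object of class `reconciliation`: list with
#'   \describe{
#'     \item{map}{integer vector, gene-tree node id -> species-tree node id}
#'     \item{events}{character vector per gene-tree node: `"leaf"`,
#'       `"speciation"` or `"duplication"`}
#'     \item{duplications}{data.frame `species_node` (label), `count`}
#'     \item{losses}{data.frame, one row per lost lineage: `gene_node`,
#'       `species_node` (label of the node where the lineage was present),
#'       `branch` (label of the child branch it failed to enter, `NA` when
#'       the species node is a polytomy and the branch is ambiguous)}
#'     \item{gtree, stree, gene_to_species}{the inputs}
#'   }
#' @export
lca_map <- function(gtree, stree, gene_to_species) {
  assert_rooted(gtree); assert_rooted(stree)
  g2s <- stats::setNames(as.character(gene_to_species$species_id),
                         as.character(gene_to_species$gene_id))
  unmapped <- setdiff(gtree$tip.label, names(g2s))
  if (length(unmapped))
    stop("gene leaves missing from gene-to-species table: ",
         paste(unmapped, collapse = ", "))
  bad <- setdiff(unname(g2s[gtree$tip.label]), stree$tip.label)
  if (length(bad))
    stop("species absent from species tree: ", paste(unique(bad), collapse = ", "))

  ntip_g <- ape::Ntip(gtree)
  n_g <- ntip_g + gtree$Nnode
  spar <- tree_parents(stree)
  sdep <- node_depths(stree)
  sch <- tree_children(stree)
  sbelow <- tips_below(stree)
  slab <- node_labels(stree)
  gch <- tree_children(gtree)

  # species tip id for each gene tip
  sp_tip <- match(unname(g2s[gtree$tip.label]), stree$tip.label)

  M <- integer(n_g)
  species_set <- vector("list", n_g)  # species-tree *tip ids* under each gene node
  M[seq_len(ntip_g)] <- sp_tip
  for (t in seq_len(ntip_g)) species_set[[t]] <- sp_tip[t]

  events <- rep("leaf", n_g)
  losses <- list()
  dup_at <- integer(0)

  record_path_losses <- function(gnode, top, bottom, include_top) {
    # lineage ran from species node `top` down to `bottom`; a loss occurs at
    # every traversed node (excluding `bottom`; `top` only when include_top)
    path <- ancestor_path(spar, bottom)           # bottom .. root
    path <- path[seq_len(which(path == top))]      # bottom .. top
    inner <- setdiff(path, c(top, bottom))
    at_nodes <- c(if (include_top && top != bottom) top, inner)
    for (X in at_nodes) {
      # child of X on the path towards `bottom`
      y_idx <- which(path == X) - 1L
      Y <- path[y_idx]
      others <- setdiff(sch[[X]], Y)
      losses[[length(losses) + 1L]] <<- data.frame(
        gene_node = gnode,
        species_node = slab[X],
        branch = if (length(others) == 1) slab[others] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  for (v in node_postorder(gtree)) {
    if (v <= ntip_g) next
    kids <- gch[[v]]
    M[v] <- tree_lca(stree, M[kids], par = spar, dep = sdep)
    species_set[[v]] <- unique(unlist(species_set[kids]))

    # branch sets: children of M(v) through which each gene-child descends
    if (M[v] <= ape::Ntip(stree)) {
      dup <- TRUE  # several gene lineages within a single species
    } else {
      branch_sets <- lapply(kids, function(k) {
        Filter(function(b) any(species_set[[k]] %in% sbelow[[b]]), sch[[M[v]]])
      })
      dup <- FALSE
      for (i in seq_along(kids)) {
        for (j in seq_along(kids)) {
          if (i < j && length(intersect(branch_sets[[i]], branch_sets[[j]]))) {
            dup <- TRUE
          }
        }
      }
    }
    events[v] <- if (dup) "duplication" else "speciation"
    if (dup) dup_at <- c(dup_at, M[v])
  }

  # implied losses per gene-tree edge, given events
  for (v in node_postorder(gtree)) {
    if (v <= ntip_g) next
    for (c_ in gch[[v]]) {
      if (M[c_] == M[v]) next
      record_path_losses(c_, M[v], M[c_],
                         include_top = events[v] == "duplication")
    }
  }

  dups <- if (length(dup_at)) {
    agg <- table(slab[dup_at])
    data.frame(species_node = names(agg), count = as.integer(agg),
               stringsAsFactors = FALSE)
  } else data.frame(species_node = character(0), count = integer(0))
  loss_df <- if (length(losses)) {
    do.call(rbind, c(losses, list(make.row.names = FALSE)))
  } else {
    data.frame(gene_node = integer(0), species_node = character(0),
               branch = character(0))
  }

  structure(list(map = M, events = events, duplications = dups,
                 losses = loss_df, gtree = gtree, stree = stree,
                 gene_to_species = gene_to_species),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation: %d gene leaves, %d duplication(s), %d loss(es)>\n",
              ape::Ntip(x$gtree), sum(x$events == "duplication"),
              nrow(x$losses)))
  invisible(x)
}

#' Total duplication + loss score of a reconciliation
#' @param r A `reconciliation`.
#' @return Integer parsimony score.
#' @export
reconciliation_score <- function(r) {
  sum(r$events == "duplication") + nrow(r$losses)
}

#' Per-branch gene-loss table
#'
#' Aggregates the individual lost lineages of a reconciliation by
#' species-tree branch (child-node addressed). Losses whose branch is
#' ambiguous because the species node is a polytomy are reported under the
#' polytomy node's label with `branch_resolved = FALSE`.
#'
#' @param r A `reconciliation`.
#' @param stree Ignored (kept for call-signature symmetry); the species
#'   tree stored in `r` is used.
#' @return data.frame `branch`, `n_lost`, `branch_resolved`.
#' @export
report_gene_losses <- function(r, stree = NULL) {
  L <- r$losses
  if (!nrow(L)) {
    return(data.frame(branch = character(0), n_lost = integer(0),
                      branch_resolved = logical(0)))
  }
  key <- ifelse(is.na(L$branch), L$species_node, L$branch)
  resolved <- !is.na(L$branch)
  agg <- stats::aggregate(list(n_lost = seq_len(nrow(L))),
                          by = list(branch = key, branch_resolved = resolved),
                          FUN = length)
  agg[order(agg$branch), c("branch", "n_lost", "branch_resolved")]
}

#' Write a reconciliation report to JSON
#'
#' @param r A `reconciliation`.
#' @param path Output JSON path.
#' @return `r`, invisibly.
#' @export
write_reconciliation_json <- function(r, path) {
  glab <- node_labels(r$gtree)
  slab <- node_labels(r$stree)
  rep_ <- list(
    nodes = data.frame(gene_node = glab, maps_to = slab[r$map],
                       event = r$events, stringsAsFactors = FALSE),
    duplications = r$duplications,
    losses = report_gene_losses(r))
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(r)
}
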