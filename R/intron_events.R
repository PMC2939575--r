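# Ancestral intron complements and per-branch gain/loss events.
#
# Dollo parsimony: each intron site is gained exactly once (at the LCA of
# all genes possessing it) and may be lost repeatedly below that gain.
# Reconstruction runs on the gene tree when a reconciliation is supplied,
# so that paralogous copies (e.g. lineage-specific duplicates) keep
# separate histories; events are then mapped onto species-tree branches via
# the reconciliation. Without a reconciliation the supplied tree is used
# directly, with matrix rows attached to its tips.

#' @keywords internal
attach_matrix_tree <- function(m, tree, rec, gene_to_species) {
  if (!is.null(rec)) {
    tree <- rec$gtree
    if (!all(rownames(m$states) %in% tree$tip.label))
      stop("matrix rows missing from the reconciled gene tree: ",
           paste(setdiff(rownames(m$states), tree$tip.label), collapse = ", "))
    row_of_tip <- match(tree$tip.label, rownames(m$states))
  } else {
    assert_rooted(tree)
    if (!is.null(gene_to_species)) {
      g2s <- stats::setNames(as.character(gene_to_species$species_id),
                             as.character(gene_to_species$gene_id))
      tip_gene <- names(g2s)[match(tree$tip.label, unname(g2s))]
      row_of_tip <- match(tip_gene, rownames(m$states))
    } else {
      row_of_tip <- match(tree$tip.label, rownames(m$states))
    }
  }
  list(tree = tree, row_of_tip = row_of_tip)
}

#' Dollo parsimony reconstruction of ancestral intron sites
#'
#' For each site the gain is placed on the node that is the LCA of all
#' genes possessing it; below the gain, the minimal set of losses is
#' implied (each maximal subtree without any possessing gene contributes
#' one loss at its stem). `"?"` (missing) leaves are non-informative: they
#' inherit the state of their parent and never trigger events.
#'
#' @param m An `intron_site_matrix`.
#' @param tree Rooted tree on which to reconstruct (ignored when `rec` is
#'   given). Tips must be matrix rows, or species mapped 1-1 to rows via
#'   `gene_to_species`.
#' @param rec Optional `reconciliation`; reconstruction then runs on its
#'   gene tree and events can be mapped to species-tree branches.
#' @param gene_to_species Optional data.frame `gene_id`, `species_id`.
#' @param root_state Optional character vector of site_ids asserted present
#'   at the root (e.g. the ancestral complement defined by basal reference
#'   genes); the gain of such a site is anchored at the root even when the
#'   genes still possessing it span only part of the tree.
#' @param duplication_inherit When `TRUE` (default) and a reconciliation is
#'   supplied, each daughter lineage of a duplication node inherits the
#'   parent's reconstructed intron complement: a duplication copies the
#'   parent gene, structure included, so losses are placed within the
#'   subsequent independent history of each copy rather than pooled on the
#'   shared post-duplication stem. Set `FALSE` for strictly site-minimal
#'   Dollo.
#' @return Object of class `ancestral_states`: list with `tree`, `states`
#'   (integer matrix, nodes x sites), `gain_node` (node id per site),
#'   `sites` (site table of retained sites), `method = "dollo"`, `rec`.
#' @export
dollo_reconstruct <- function(m, tree = NULL, rec = NULL,
                              gene_to_species = NULL, root_state = NULL,
                              duplication_inherit = TRUE) {
  at <- attach_matrix_tree(m, tree, rec, gene_to_species)
  tree <- at$tree
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  par <- tree_parents(tree)
  below <- tips_below(tree)
  post <- node_postorder(tree)
  pre <- rev(post)
  root <- root_node(tree)
  dup_nodes <- if (!is.null(rec) && duplication_inherit)
    which(rec$events == "duplication") else integer(0)

  keep <- logical(nrow(m$sites))
  states <- matrix(0L, nrow = nn, ncol = nrow(m$sites),
                   dimnames = list(NULL, m$sites$site_id))
  gain <- rep(NA_integer_, nrow(m$sites))

  for (s in seq_len(nrow(m$sites))) {
    leaf <- m$states[at$row_of_tip, s]
    ptips <- which(leaf == "1")
    itips <- which(leaf != "?")
    if (!length(ptips)) {
      warning("site ", m$sites$site_id[s],
              " present in no gene; dropped from reconstruction")
      next
    }
    keep[s] <- TRUE
    g <- if (m$sites$site_id[s] %in% root_state) root
         else tree_lca(tree, ptips)
    gain[s] <- g
    has_p <- vapply(seq_len(nn), function(v) any(below[[v]] %in% ptips),
                    logical(1))
    has_i <- vapply(seq_len(nn), function(v) any(below[[v]] %in% itips),
                    logical(1))
    in_gain <- logical(nn); in_gain[g] <- TRUE
    st <- integer(nn)
    for (v in pre) {
      if (v != g && par[v] != 0L && in_gain[par[v]]) in_gain[v] <- TRUE
      if (!in_gain[v]) { st[v] <- 0L; next }
      st[v] <- if (has_p[v]) 1L
               else if (par[v] %in% dup_nodes && st[par[v]] == 1L) 1L
               else if (!has_i[v]) st[par[v]]   # non-informative: inherit
               else 0L
    }
    states[, s] <- st
  }

  structure(list(tree = tree, states = states[, keep, drop = FALSE],
                 gain_node = gain[keep],
                 sites = m$sites[keep, , drop = FALSE],
                 method = "dollo", rec = rec,
                 changes = NULL),
            class = "ancestral_states")
}

#' Fitch (unordered two-state) parsimony reconstruction
#'
#' Minimum-change reconstruction allowing multiple gains, used as a
#' sensitivity check against the Dollo model. Implemented as unit-cost
#' Sankoff dynamic programming, which stays exact on polytomies; ties at
#' the root are resolved toward "present", and ties below the root toward
#' the parent's state (no spurious events).
#'
#' @inheritParams dollo_reconstruct
#' @return An `ancestral_states` with `method = "fitch"` and a `changes`
#'   vector giving the minimal number of state changes per site.
#' @export
fitch_reconstruct <- function(m, tree = NULL, rec = NULL,
                              gene_to_species = NULL) {
  at <- attach_matrix_tree(m, tree, rec, gene_to_species)
  tree <- at$tree
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- tree_children(tree)
  par <- tree_parents(tree)
  post <- node_postorder(tree)
  pre <- rev(post)

  keep <- logical(nrow(m$sites))
  states <- matrix(0L, nrow = nn, ncol = nrow(m$sites),
                   dimnames = list(NULL, m$sites$site_id))
  changes <- rep(NA_integer_, nrow(m$sites))

  for (s in seq_len(nrow(m$sites))) {
    leaf <- m$states[at$row_of_tip, s]
    if (!any(leaf == "1")) {
      warning("site ", m$sites$site_id[s],
              " present in no gene; dropped from reconstruction")
      next
    }
    keep[s] <- TRUE
    # cost[v, k+1]: min changes in subtree of v given state k at v
    cost <- matrix(0, nrow = nn, ncol = 2)
    for (v in post) {
      if (v <= ntip) {
        obs <- leaf[v]
        cost[v, ] <- c(if (obs == "1") Inf else 0,
                       if (obs == "0") Inf else 0)
      } else {
        for (k in 0:1) {
          cost[v, k + 1] <- sum(vapply(ch[[v]], function(c_) {
            min(cost[c_, k + 1], min(cost[c_, ]) + 1)
          }, numeric(1)))
        }
      }
    }
    root <- root_node(tree)
    changes[s] <- as.integer(min(cost[root, ]))
    st <- integer(nn)
    for (v in pre) {
      if (v == root) {
        st[v] <- if (cost[v, 2] <= cost[v, 1]) 1L else 0L  # tie -> present
      } else {
        k <- st[par[v]]
        same <- cost[v, k + 1]
        other <- cost[v, 2 - k] + 1
        st[v] <- if (same <= other) k else 1L - k           # tie -> parent state
      }
    }
    states[, s] <- st
  }

  structure(list(tree = tree, states = states[, keep, drop = FALSE],
                 gain_node = rep(NA_integer_, sum(keep)),
                 sites = m$sites[keep, , drop = FALSE],
                 method = "fitch", rec = rec,
                 changes = changes[keep]),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("<ancestral_states (%s): %d nodes x %d sites>\n",
              x$method, nrow(x$states), ncol(x$states)))
  invisible(x)
}

# species branch (child-addressed label) for an event on gene edge (v, c):
# the uppermost species-tree edge on the path M(v) -> M(c); when the two
# map to the same species node the event happened within that branch.
#' @keywords internal
species_branch_of_edge <- function(rec, v, c_) {
  slab <- node_labels(rec$stree)
  if (v == 0L) return(slab[rec$map[c_]])      # event at the gene-tree root
  Mv <- rec$map[v]; Mc <- rec$map[c_]
  if (Mv == Mc) return(slab[Mc])
  spar <- tree_parents(rec$stree)
  path <- ancestor_path(spar, Mc)             # Mc .. root
  top_child <- path[which(path == Mv) - 1L]   # node just below Mv on the path
  slab[top_child]
}

#' Infer per-branch intron gain and loss events from ancestral states
#'
#' A loss is recorded on a branch when the site is present at the parent
#' node and absent at the child; gains analogously. Under Dollo the origin
#' of each site is additionally recorded as its single gain event (on the
#' branch above the gain node, or at the root for sites already present
#' there). When the reconstruction carries a reconciliation, events are
#' reported on species-tree branches; otherwise on branches of the
#' reconstruction tree itself.
#'
#' @param states An `ancestral_states`.
#' @param stree Ignored (signature symmetry); the species tree of the
#'   stored reconciliation is used when present.
#' @param gene_groups Optional named character vector gene_id -> lineage
#'   label (e.g. `"cladeI"`); each event is attributed to the lineage of
#'   the genes below its edge (`"shared"` when mixed).
#' @return Object of class `event_history`: data.frame with columns
#'   `type` (`"gain"`/`"loss"`), `site_id`, `ancestral_number`, `branch`
#'   (species or tree branch, child-addressed), `node` (child node id on
#'   the reconstruction tree), `lineage`; plus attributes `tree`, `rec`,
#'   `root_state` (site_ids present at the root).
#' @export
infer_events <- function(states, stree = NULL, gene_groups = NULL) {
  tree <- states$tree
  ntip <- ape::Ntip(tree)
  par <- tree_parents(tree)
  below <- tips_below(tree)
  lab <- node_labels(tree)
  rec <- states$rec

  lineage_of <- function(node) {
    if (is.null(gene_groups)) return("all")
    gs <- unique(gene_groups[tree$tip.label[below[[node]]]])
    gs <- gs[!is.na(gs)]
    if (length(gs) == 1) gs else "shared"
  }
  branch_of <- function(v, c_) {
    if (!is.null(rec)) species_branch_of_edge(rec, v, c_) else lab[c_]
  }

  ev <- list()
  add <- function(type, s, v, c_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      type = type,
      site_id = states$sites$site_id[s],
      ancestral_number = states$sites$ancestral_number[s],
      branch = branch_of(v, c_),
      node = c_,
      lineage = lineage_of(c_),
      stringsAsFactors = FALSE)
  }

  for (s in seq_len(ncol(states$states))) {
    st <- states$states[, s]
    if (states$method == "dollo" && !is.na(states$gain_node[s])) {
      g <- states$gain_node[s]
      add("gain", s, par[g], g)
    }
    for (c_ in seq_along(par)) {
      if (par[c_] == 0L) next
      if (st[par[c_]] == 1L && st[c_] == 0L) add("loss", s, par[c_], c_)
      if (states$method != "dollo" && st[par[c_]] == 0L && st[c_] == 1L)
        add("gain", s, par[c_], c_)
    }
  }
  h <- if (length(ev)) do.call(rbind, c(ev, list(make.row.names = FALSE)))
       else data.frame(type = character(0), site_id = character(0),
                       ancestral_number = integer(0), branch = character(0),
                       node = integer(0), lineage = character(0))
  root <- root_node(tree)
  structure(h, class = c("event_history", "data.frame"),
            tree = tree, rec = rec, gene_groups = gene_groups,
            root_state = states$sites$site_id[states$states[root, ] == 1L])
}

#' Replay an event history from the root and return leaf site states
#'
#' Conservation check: starting from the root intron complement and
#' applying each branch's gains and losses down the tree must reproduce
#' every observed leaf state exactly.
#'
#' @param h An `event_history`.
#' @return Logical matrix, tips x sites, of replayed presence states.
#' @export
replay_events <- function(h) {
  tree <- attr(h, "tree")
  ntip <- ape::Ntip(tree)
  par <- tree_parents(tree)
  pre <- rev(node_postorder(tree))
  sites <- sort(unique(c(h$site_id, attr(h, "root_state"))))
  st <- matrix(FALSE, nrow = length(par), ncol = length(sites),
               dimnames = list(NULL, sites))
  root <- root_node(tree)
  st[root, attr(h, "root_state")] <- TRUE
  for (v in pre) {
    if (v == root) next
    st[v, ] <- st[par[v], ]
    here <- h[h$node == v, , drop = FALSE]
    if (nrow(here)) {
      st[v, here$site_id[here$type == "loss"]] <- FALSE
      st[v, here$site_id[here$type == "gain"]] <- TRUE
    }
  }
  out <- st[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Summarize an event history into a per-lineage pathway table
#'
#' @param h An `event_history`.
#' @return list with
#'   \describe{
#'     \item{per_lineage}{data.frame `lineage`, `n_loss_branches` (branches
#'       carrying at least one loss), `n_losses` (site-level losses),
#'       `n_gains`, `max_path_losses` (maximum cumulative losses along any
#'       root-to-leaf path ending in a gene of that lineage)}
#'     \item{loss_branches}{data.frame `branch`, `lineage`, `n_sites`}
#'     \item{n_loss_branches}{total number of (branch x lineage) pairs with
#'       at least one loss}
#'   }
#' @export
summarize_pathway <- function(h) {
  tree <- attr(h, "tree")
  empty <- data.frame(lineage = character(0), n_loss_branches = integer(0),
                      n_losses = integer(0), n_gains = integer(0),
                      max_path_losses = integer(0))
  if (!nrow(h)) {
    return(list(per_lineage = empty,
                loss_branches = data.frame(branch = character(0),
                                           lineage = character(0),
                                           n_sites = integer(0)),
                n_loss_branches = 0L))
  }
  losses <- h[h$type == "loss", , drop = FALSE]
  lb <- unique(losses[, c("branch", "lineage")])
  lb$n_sites <- vapply(seq_len(nrow(lb)), function(i) {
    sum(losses$branch == lb$branch[i] & losses$lineage == lb$lineage[i])
  }, integer(1))

  # cumulative losses per root-to-leaf path, grouped by the leaf's lineage
  ntip <- ape::Ntip(tree)
  par <- tree_parents(tree)
  loss_per_node <- tabulate(losses$node, nbins = length(par))
  cum <- function(tip) sum(loss_per_node[ancestor_path(par, tip)])

  lineages <- sort(unique(h$lineage))
  per <- lapply(lineages, function(lg) {
    lg_tips <- tips_of_lineage(h, lg)
    data.frame(
      lineage = lg,
      n_loss_branches = sum(lb$lineage == lg),
      n_losses = sum(losses$lineage == lg),
      n_gains = sum(h$type == "gain" & h$lineage == lg),
      max_path_losses = if (length(lg_tips))
        max(vapply(lg_tips, cum, numeric(1))) else 0,
      stringsAsFactors = FALSE)
  })
  list(per_lineage = do.call(rbind, per),
       loss_branches = lb[order(lb$branch, lb$lineage), , drop = FALSE],
       n_loss_branches = nrow(lb))
}

# tips whose gene belongs to the given lineage label, recovered from the
# gene_groups attribution that infer_events stamped on the events: a tip is
# of lineage lg when every event-bearing ancestor attributed to a single
# lineage agrees with lg. Falls back to all tips for the "all" label.
#' @keywords internal
tips_of_lineage <- function(h, lg) {
  tree <- attr(h, "tree")
  groups <- attr(h, "gene_groups")
  ntip <- ape::Ntip(tree)
  if (lg == "all" || is.null(groups)) return(seq_len(ntip))
  which(unname(groups[tree$tip.label]) == lg)
}

#' Write an event history to JSON, keyed by branch
#' @param h An `event_history`.
#' @param path Output JSON path.
#' @return `h`, invisibly.
#' @export
write_events_json <- function(h, path) {
  by_branch <- split(as.data.frame(h)[, c("type", "site_id",
                                          "ancestral_number", "lineage")],
                     h$branch)
  jsonlite::write_json(
    list(root_state = attr(h, "root_state"), branches = by_branch),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(h)
}
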