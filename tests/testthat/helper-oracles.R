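# Independent brute-force oracles and random-case generators.
# These deliberately re-derive every quantity from first principles
# (exhaustive enumeration over mappings / state assignments) and share no
# code with the implementation paths they check.

# random rooted tree by sequential joining of subtree units;
# join_sizes > 2 produce polytomies
rand_rooted_tree <- function(ntips, prefix = "t", p_polytomy = 0) {
  units <- paste0(prefix, seq_len(ntips))
  while (length(units) > 1) {
    # a basal trichotomy reads as unrooted newick, so polytomies are only
    # produced below the root (k = 3 needs > 3 units left)
    k <- if (length(units) > 3 && stats::runif(1) < p_polytomy) 3L else 2L
    pick <- sample(length(units), k)
    joined <- paste0("(", paste(units[pick], collapse = ","), ")")
    units <- c(units[-pick], joined)
  }
  read_rooted_tree(paste0(units, ";"))
}

# --- exhaustive duplication-loss reconciliation ---------------------------

# enumerate every ancestor-consistent mapping of gene-tree internals onto
# the species tree and return the minimal duplication+loss cost
oracle_min_dl <- function(gtree, stree, g2s) {
  spar <- intronloss:::tree_parents(stree)
  sdep <- intronloss:::node_depths(stree)
  sch <- intronloss:::tree_children(stree)
  sbelow <- intronloss:::tips_below(stree)
  ntip_g <- ape::Ntip(gtree)
  gch <- intronloss:::tree_children(gtree)
  post <- intronloss:::node_postorder(gtree)
  internal <- post[post > ntip_g]

  map_tip <- match(g2s$species_id[match(gtree$tip.label, g2s$gene_id)],
                   stree$tip.label)
  # species tip sets under each gene node
  gbelow <- intronloss:::tips_below(gtree)
  spset <- lapply(seq_len(ntip_g + gtree$Nnode),
                  function(v) unique(map_tip[gbelow[[v]]]))

  anc_of <- function(node) intronloss:::ancestor_path(spar, node)

  cost_of <- function(M) {
    dup <- logical(length(M))
    total <- 0L
    for (v in internal) {
      kids <- gch[[v]]
      if (M[v] <= ape::Ntip(stree)) {
        dup[v] <- TRUE
      } else {
        bsets <- lapply(kids, function(k) {
          Filter(function(b) any(spset[[k]] %in% sbelow[[b]]), sch[[M[v]]])
        })
        for (i in seq_along(kids)) for (j in seq_along(kids)) {
          if (i < j && length(intersect(bsets[[i]], bsets[[j]])))
            dup[v] <- TRUE
        }
      }
      total <- total + dup[v]
    }
    for (v in internal) {
      for (c_ in gch[[v]]) {
        d <- sdep[M[c_]] - sdep[M[v]]
        total <- total + if (dup[v]) d else max(d - 1L, 0L)
      }
    }
    total
  }

  best <- Inf
  M <- integer(ntip_g + gtree$Nnode)
  M[seq_len(ntip_g)] <- map_tip
  recurse <- function(i) {
    if (i > length(internal)) {
      best <<- min(best, cost_of(M))
      return(invisible())
    }
    v <- internal[i]
    lca_kids <- intronloss:::tree_lca(stree, M[gch[[v]]], par = spar, dep = sdep)
    for (cand in anc_of(lca_kids)) {
      M[v] <<- cand
      recurse(i + 1L)
    }
    M[v] <<- 0L
  }
  recurse(1L)
  best
}

# --- exhaustive Dollo / Fitch per-site minima -----------------------------

# leaf_states: named character vector over tips, values "1"/"0"/"?"
oracle_dollo_min_losses <- function(tree, leaf_states) {
  par <- intronloss:::tree_parents(tree)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  obs <- leaf_states[tree$tip.label]
  free <- c(which(obs == "?"), (ntip + 1L):nn)
  fixed <- integer(nn)
  fixed[seq_len(ntip)] <- ifelse(obs == "1", 1L, 0L)
  edges <- cbind(par[par != 0L], which(par != 0L))

  connected_present <- function(st) {
    pres <- which(st == 1L)
    if (!length(pres)) return(FALSE)
    # the present set forms one component iff present-present edge count
    # equals |present| - 1 (trees have no cycles)
    e_in <- sum(st[edges[, 1]] == 1L & st[edges[, 2]] == 1L)
    e_in == length(pres) - 1L
  }
  best <- Inf
  for (bits in 0:(2^length(free) - 1L)) {
    st <- fixed
    st[free] <- bitwAnd(bits %/% 2^(seq_along(free) - 1L), 1L)
    if (!connected_present(st)) next
    losses <- sum(st[edges[, 1]] == 1L & st[edges[, 2]] == 0L)
    best <- min(best, losses)
  }
  best
}

oracle_fitch_min_changes <- function(tree, leaf_states) {
  par <- intronloss:::tree_parents(tree)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  obs <- leaf_states[tree$tip.label]
  free <- c(which(obs == "?"), (ntip + 1L):nn)
  fixed <- integer(nn)
  fixed[seq_len(ntip)] <- ifelse(obs == "1", 1L, 0L)
  edges <- cbind(par[par != 0L], which(par != 0L))
  best <- Inf
  for (bits in 0:(2^length(free) - 1L)) {
    st <- fixed
    st[free] <- bitwAnd(bits %/% 2^(seq_along(free) - 1L), 1L)
    best <- min(best, sum(st[edges[, 1]] != st[edges[, 2]]))
  }
  best
}

# exhaustive same-phase transitive-closure merge (union-find over pairs)
oracle_slop_groups <- function(columns, phases, tolerance) {
  n <- length(columns)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && phases[i] == phases[j] &&
        abs(columns[i] - columns[j]) <= tolerance) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# build a bare intron_site_matrix from a character state matrix
toy_matrix <- function(states, phases = NULL) {
  sites <- data.frame(site_id = colnames(states),
                      column = seq_len(ncol(states)),
                      phase = if (is.null(phases)) rep(0L, ncol(states))
                              else phases,
                      ancestral_number = NA_integer_)
  structure(list(states = states, sites = sites, genes = rownames(states)),
            class = "intron_site_matrix")
}

# count loss edges (present parent -> absent child) in an ancestral_states
count_loss_edges <- function(st, site) {
  par <- intronloss:::tree_parents(st$tree)
  s <- st$states[, site]
  sum(vapply(which(par != 0L),
             function(v) s[par[v]] == 1L && s[v] == 0L, logical(1)))
}
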