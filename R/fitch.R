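#' Minimum rearrangement events on a tree by Fitch parsimony
#'
#' Maps an unordered multistate character (the mitochondrial gene-order
#' haplotype of each tip) onto a fixed species tree and returns the
#' minimum number of state changes, one most-parsimonious reconstruction,
#' and the per-node state sets of the bottom-up pass. Branch lengths are
#' ignored; each rearrangement counts as one event.
#'
#' @param tree An [ape::phylo] tree. Unrooted or multifurcating input is
#'   rooted (on `outgroup` when given, else on the first tip) and made
#'   binary with zero-length branches; the minimum change count is
#'   invariant to this choice.
#' @param states Named character vector mapping every tip label to a state.
#' @param outgroup Optional tip label (or vector) to root an unrooted
#'   input on.
#' @return A `fitch_result`: list with `min_changes`, `placements` (data
#'   frame: `parent`, `child`, `from_state`, `to_state`), `node_states`
#'   (the reported reconstruction), `ancestral_sets`, `n_mpr` (number of
#'   most-parsimonious internal assignments), and the rooted `tree`.
#' @export
fitch_min_changes <- function(tree, states, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[[1L]],
                      resolve.root = TRUE)
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(states))
  if (length(missing)) {
    stop("tip(s) missing from the state map: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tips)
  nnode <- tree$Nnode
  edge <- tree$edge
  root <- setdiff(edge[, 1L], edge[, 2L])
  stopifnot(length(root) == 1L)
  children <- split(edge[, 2L], edge[, 1L])
  state_levels <- sort(unique(unname(states[tips])))

  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- states[[tips[[i]]]]
  changes <- 0L
  cladewise <- ape::reorder.phylo(tree, "cladewise")$edge
  depths <- integer(ntip + nnode)
  for (e in seq_len(nrow(cladewise))) {
    depths[cladewise[e, 2L]] <- depths[cladewise[e, 1L]] + 1L
  }
  internal <- (ntip + 1L):(ntip + nnode)
  postorder <- internal[order(depths[internal], decreasing = TRUE)]
  for (v in postorder) {
    kid_sets <- sets[children[[as.character(v)]]]
    inter <- Reduce(intersect, kid_sets)
    if (length(inter)) {
      sets[[v]] <- inter
    } else {
      sets[[v]] <- sort(unique(unlist(kid_sets)))
      changes <- changes + 1L
    }
  }

  # Sankoff unit-cost DP: exact minimum (agrees with the Fitch count on
  # binary trees) and the number of optimal internal assignments
  K <- length(state_levels)
  cost <- matrix(Inf, ntip + nnode, K, dimnames = list(NULL, state_levels))
  count <- matrix(0, ntip + nnode, K, dimnames = list(NULL, state_levels))
  for (i in seq_len(ntip)) {
    cost[i, states[[tips[[i]]]]] <- 0
    count[i, states[[tips[[i]]]]] <- 1
  }
  for (v in postorder) {
    for (s in seq_len(K)) {
      tot <- 0; cnt <- 1
      for (w in children[[as.character(v)]]) {
        opts <- cost[w, ] + (seq_len(K) != s)
        mo <- min(opts)
        tot <- tot + mo
        cnt <- cnt * sum(count[w, abs(opts - mo) < 1e-9])
      }
      cost[v, s] <- tot
      count[v, s] <- cnt
    }
  }
  min_changes <- min(cost[root, ])
  n_mpr <- sum(count[root, abs(cost[root, ] - min_changes) < 1e-9])
  stopifnot(min_changes == changes)

  # top-down pass: prefer the parent's state when it is in the child's
  # first-pass set, otherwise the lexicographically smallest member
  node_states <- character(ntip + nnode)
  node_states[root] <- sort(sets[[root]])[[1L]]
  preorder <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(preorder))) {
    par <- preorder[e, 1L]; child <- preorder[e, 2L]
    node_states[child] <- if (node_states[par] %in% sets[[child]]) {
      node_states[par]
    } else {
      sort(sets[[child]])[[1L]]
    }
  }
  changed <- which(node_states[edge[, 1L]] != node_states[edge[, 2L]])
  label_of <- function(v) {
    ifelse(v <= ntip, tips[v], paste0("node_", v))
  }
  placements <- data.frame(
    parent = label_of(edge[changed, 1L]),
    child = label_of(edge[changed, 2L]),
    from_state = node_states[edge[changed, 1L]],
    to_state = node_states[edge[changed, 2L]],
    stringsAsFactors = FALSE)
  structure(list(min_changes = as.integer(min_changes),
                 placements = placements, node_states = node_states,
                 ancestral_sets = sets, n_mpr = n_mpr, tree = tree),
            class = "fitch_result")
}

#' @export
print.fitch_result <- function(x, ...) {
  cat(sprintf("<fitch_result> %d change(s), %g most-parsimonious reconstruction(s)\n",
              x$min_changes, x$n_mpr))
  if (nrow(x$placements)) {
    for (i in seq_len(nrow(x$placements))) {
      p <- x$placements[i, ]
      cat(sprintf("  %s -> %s : %s => %s\n", p$parent, p$child,
                  p$from_state, p$to_state))
    }
  }
  invisible(x)
}

#' Expand per-individual states into a tip state map
#'
#' Species observed in a single state contribute one tip (named after the
#' species); species whose individuals differ in state (gene-order
#' polymorphism) contribute one tip per individual, so within-species
#' polymorphism is representable on the tree.
#'
#' @param states_by_individual Named character vector: individual -> state.
#' @param species_map Named character vector: individual -> species.
#' @return Named character vector usable as a tip state map.
#' @export
polymorphic_species_expand <- function(states_by_individual, species_map) {
  inds <- names(states_by_individual)
  no_species <- setdiff(inds, names(species_map))
  if (length(no_species)) {
    stop("individual(s) with no species assignment: ",
         paste(no_species, collapse = ", "))
  }
  out <- character(); nm <- character()
  for (sp in unique(unname(species_map[inds]))) {
    members <- inds[species_map[inds] == sp]
    sts <- unique(unname(states_by_individual[members]))
    if (length(sts) == 1L) {
      out <- c(out, sts); nm <- c(nm, sp)
    } else {
      out <- c(out, unname(states_by_individual[members]))
      nm <- c(nm, members)
    }
  }
  setNames(out, nm)
}

#' Replace a species tip by a clade of its individuals
#'
#' Helper for representing within-species gene-order polymorphism on a
#' species tree: the named tip is replaced by a zero-branch-length clade
#' containing one tip per individual.
#'
#' @param tree An [ape::phylo] tree.
#' @param tip Tip label to expand.
#' @param individuals Character vector of individual labels.
#' @return The expanded tree.
#' @export
expand_tip <- function(tree, tip, individuals) {
  stopifnot(tip %in% tree$tip.label, length(individuals) >= 1L)
  if (length(individuals) == 1L) {
    tree$tip.label[tree$tip.label == tip] <- individuals
    return(tree)
  }
  sub <- ape::read.tree(text = paste0(
    "(", paste(individuals, collapse = ","), ");"))
  sub <- ape::multi2di(sub)
  sub$edge.length <- rep(0, nrow(sub$edge))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  ape::bind.tree(tree, sub, where = which(tree$tip.label == tip))
}
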