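#' Detect duplication nodes by the species-overlap criterion
#'
#' An internal node of a rooted gene tree is a duplication if the species
#' sets of (any) two of its child subtrees intersect: at least one species
#' kept both copies, so the node cannot be a speciation.  Events are returned
#' in preorder (root first).
#'
#' @param tree a rooted `phylo`; leaf labels encode species in their first
#'   `|`-separated field (see [parse_seq_ids()]), or supply `species_map`.
#' @param ref optional `species_ref` used to validate species tokens.
#' @param species_map optional named character vector mapping leaf label to
#'   species token, overriding header parsing.
#' @return data frame with one row per duplication node: `node` (node number
#'   in `tree`), `support` (numeric, `NA` when absent), and list columns
#'   `left_species`, `right_species` (species sets of the two children; for
#'   multifurcations the first overlapping pair of children).
#' @examples
#' tr <- ape::read.tree(text = "((Hsap|a|1,Mmus|a|-),(Hsap|b|2,Mmus|b|-));")
#' detect_duplications(tr)$node  # the root
#' @export
detect_duplications <- function(tree, ref = NULL, species_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species-overlap detection needs a rooted tree")
  species <- leaf_species(tree, ref, species_map)
  ntip <- ape::Ntip(tree)
  tu <- tips_under_nodes(tree)
  sp_under <- lapply(tu, function(tips) unique(species[tips]))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  nodes <- integer(0); left <- list(); right <- list(); support <- numeric(0)
  for (nd in preorder_nodes(tree)) {
    kids <- children[[as.character(nd)]]
    if (is.null(kids) || length(kids) < 2) next
    hit <- NULL
    for (i in seq_len(length(kids) - 1L)) {
      for (j in (i + 1L):length(kids)) {
        if (length(intersect(sp_under[[kids[i]]], sp_under[[kids[j]]]))) {
          hit <- c(i, j); break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) next
    nodes <- c(nodes, nd)
    left <- c(left, list(sort(sp_under[[kids[hit[1]]]])))
    right <- c(right, list(sort(sp_under[[kids[hit[2]]]])))
    support <- c(support, node_support(tree, nd))
  }
  out <- data.frame(node = nodes, support = support)
  out$left_species <- if (length(left)) left else list()
  out$right_species <- if (length(right)) right else list()
  out
}

leaf_species <- function(tree, ref = NULL, species_map = NULL) {
  if (!is.null(species_map)) {
    sp <- unname(species_map[tree$tip.label])
    if (anyNA(sp)) stop("species_map does not cover all leaves")
  } else {
    sp <- parse_seq_ids(tree$tip.label)$species
  }
  if (!is.null(ref)) {
    bad <- setdiff(sp, ref$tree$tip.label)
    if (length(bad))
      stop("leaf species absent from reference tree: ",
           paste(bad, collapse = ", "))
  }
  sp
}

preorder_nodes <- function(tree) {
  ntip <- ape::Ntip(tree)
  ord <- ape::reorder.phylo(tree, "cladewise")
  unique(c(ntip + 1L, ord$edge[ord$edge[, 2] > ntip, 2]))
}

node_support <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  lab <- tree$node.label
  if (is.null(lab)) return(NA_real_)
  v <- suppressWarnings(as.numeric(lab[node - ntip]))
  v
}

#' Date duplication events into speciation-bounded epochs
#'
#' Each duplication is placed on the reference species tree: the younger
#' bound is the speciation at the MRCA of the species found in the two child
#' subtrees (the duplication must predate it), and the older bound is the
#' speciation at the MRCA of those species together with the species of the
#' gene tree's sister lineage above the node (the duplication must postdate
#' it; unbounded at the gene-tree root).  The epoch bin (`B1`-`B4`, see
#' [epoch_bin()]) is assigned from the younger bound; when the two bounds
#' fall in different bins the event is additionally flagged `ambiguous`,
#' matching the "at least prior to" reading of such intervals.
#'
#' @param events the data frame from [detect_duplications()].
#' @param tree the rooted gene tree the events came from.
#' @param ref a `species_ref`.
#' @param family optional family name carried into the output.
#' @inheritParams detect_duplications
#' @return `events` with added columns `family`, `bin`, `refined_split`,
#'   `younger_bound`, `older_bound` and `ambiguous`.
#' @export
date_duplications <- function(events, tree, ref, family = NA_character_,
                              species_map = NULL) {
  stopifnot(inherits(ref, "species_ref"))
  species <- leaf_species(tree, ref, species_map)
  ntip <- ape::Ntip(tree)
  tu <- tips_under_nodes(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  n <- nrow(events)
  bin <- character(n); refined <- character(n); ambiguous <- logical(n)
  younger <- character(n); older <- character(n)
  for (i in seq_len(n)) {
    nd <- events$node[i]
    sp <- unique(species[tu[[nd]]])
    L <- lca_node(ref, sp)
    eb <- epoch_bin(ref, L)
    bin[i] <- eb$bin
    refined[i] <- eb$refined
    younger[i] <- bound_label(ref, L)
    root <- ntip + 1L
    if (nd == root || parent[nd] == 0L) {
      older[i] <- NA_character_
      ambiguous[i] <- FALSE
    } else {
      par <- parent[nd]
      sib_sp <- unique(species[tu[[par]]])
      A <- lca_node(ref, union(sp, sib_sp))
      older[i] <- bound_label(ref, A)
      ambiguous[i] <- A != L && epoch_bin(ref, A)$bin != eb$bin
    }
  }
  events$family <- rep(family, n)
  events$bin <- bin
  events$refined_split <- refined
  events$younger_bound <- younger
  events$older_bound <- older
  events$ambiguous <- ambiguous
  events
}

bound_label <- function(ref, node) {
  nm <- split_name(ref, node)
  if (!is.na(nm)) return(nm)
  if (node <= ape::Ntip(ref$tree)) return(ref$tree$tip.label[node])
  paste0("node", node)
}

#' Filter duplication events by bootstrap support
#'
#' Keeps events whose support strictly exceeds `min_support`.  Events with no
#' support value (the gene-tree root, or trees built without bootstrap) are
#' retained and flagged in the `support_flag` column.
#'
#' @param events a dated or undated event data frame with a `support`
#'   column.
#' @param min_support support threshold in percent (default 50).
#' @return the filtered events, with a `support_flag` column
#'   (`"unsupported"` for retained events lacking a support value, otherwise
#'   `""`).
#' @export
filter_by_support <- function(events, min_support = 50) {
  keep <- is.na(events$support) | events$support > min_support
  out <- events[keep, , drop = FALSE]
  out$support_flag <- ifelse(is.na(out$support), "unsupported", "")
  if (nrow(out) == 0)
    warning("no duplication events exceed the support threshold")
  out
}

#' Histogram of duplication events over epoch bins
#'
#' @param events dated events (rows from [date_duplications()], possibly
#'   several families bound together).  All events must carry a `bin`.
#' @return matrix of counts with one row per family (alphabetical) plus a
#'   `total` row, and one column per bin (`B1`, `B2`, `B3`, `B4`, `other`).
#' @export
epoch_histogram <- function(events) {
  bins <- c("B1", "B2", "B3", "B4", "other")
  if (nrow(events) > 0 && (is.null(events$bin) || anyNA(events$bin)))
    stop("undated events present; run date_duplications() first")
  fams <- sort(unique(as.character(events$family)))
  counts <- matrix(0L, nrow = length(fams) + 1L, ncol = length(bins),
                   dimnames = list(c(fams, "total"), bins))
  for (f in fams) {
    tab <- table(factor(events$bin[events$family == f], levels = bins))
    counts[f, ] <- as.integer(tab)
  }
  counts["total", ] <- colSums(counts[seq_along(fams), , drop = FALSE])
  counts
}
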