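aln_int_matrix <- function(a) {
  m <- unclass(a)
  im <- matrix(match(m, c(AA20, "-", "X", ".", "*", LETTERS)),
               nrow = nrow(m))
  storage.mode(im) <- "integer"
  im
}

#' Uncorrected p-distance matrix of an alignment
#'
#' Pairwise proportion of differing amino-acid sites.  Intended for trimmed
#' (gap-free) alignments; any residual characters are compared literally.
#'
#' @param a an `aa_alignment` with at least one column.
#' @return symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   identifiers, entries in `[0, 1]`.
#' @examples
#' a <- read_alignment(text = ">s1\nACDE\n>s2\nACDF\n")
#' p_distance_matrix(a)["s1", "s2"]  # 0.25
#' @export
p_distance_matrix <- function(a) {
  stopifnot(inherits(a, "aa_alignment"))
  if (ncol(a) < 1L) stop("zero-length alignment")
  d <- .pdist_cpp(aln_int_matrix(a))
  dimnames(d) <- list(rownames(a), rownames(a))
  d
}

#' Poisson-corrected distance matrix
#'
#' The multiple-hit correction `d = -ln(1 - p)` applied to the p-distance,
#' the model-corrected companion to [p_distance_matrix()].  Saturated pairs
#' (`p = 1`) have no finite corrected distance and raise an error naming the
#' pair.
#'
#' @inheritParams p_distance_matrix
#' @return symmetric numeric matrix of corrected distances.
#' @export
poisson_distance_matrix <- function(a) {
  p <- p_distance_matrix(a)
  if (any(p >= 1)) {
    ij <- which(p >= 1, arr.ind = TRUE)[1, ]
    stop("saturated pair (p = 1): ", rownames(p)[ij[1]], " vs ",
         colnames(p)[ij[2]])
  }
  -log(1 - p)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: the pair minimising
#' `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined at each
#' step, with branch lengths from the usual closed forms.  Ties in `Q` are
#' broken by the lexicographically smallest active pair index, so the result
#' is deterministic.  Negative branch lengths are clamped to zero and the
#' deficit transferred to the sibling branch.
#'
#' @param dm symmetric distance matrix with taxon dimnames (at least 3 taxa).
#' @return an unrooted `phylo` tree (trifurcating root node).
#' @examples
#' d <- matrix(c(0, 2, 4, 4,  2, 0, 4, 4,  4, 4, 0, 2,  4, 4, 2, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d)
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  labs <- rownames(dm)
  safe <- paste0("x", seq_len(n))  # shield labels from newick metacharacters
  nwk <- .nj_cpp(dm, safe)
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- labs[match(tr$tip.label, safe)]
  tr
}

# canonical key of the bipartition induced by the tip set `tips` (labels)
split_key <- function(tips, all_tips) {
  side <- sort(tips)
  other <- sort(setdiff(all_tips, tips))
  if (length(other) == 0) return(NA_character_)
  anchor <- sort(all_tips)[1]
  if (!anchor %in% side) side <- other
  paste(side, collapse = "\r")
}

# all non-trivial bipartition keys of a tree (as an unrooted topology)
tree_split_keys <- function(tree) {
  all_tips <- tree$tip.label
  tu <- tips_under_nodes(tree)
  ntip <- ape::Ntip(tree)
  keys <- character(0)
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[tu[[nd]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    keys <- c(keys, split_key(tips, all_tips))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree for each pseudo-replicate, and annotates every internal branch of the
#' point-estimate tree with the percentage of replicates containing the same
#' bipartition.  Supports are keyed to unrooted bipartitions and stored both
#' as node labels and in the `"splits"` attribute, which [root_tree()] uses
#' to re-annotate after rooting.
#'
#' @param a a trimmed `aa_alignment`.
#' @param B number of pseudo-replicates (default 1000).
#' @param seed integer seed; mandatory for reproducibility.
#' @param dist `"p"` for the uncorrected p-distance or `"poisson"` for the
#'   corrected distance.
#' @return an unrooted `phylo` with `node.label` giving percent support and
#'   attribute `"splits"` (named numeric vector keyed by bipartition).
#' @export
bootstrap_support <- function(a, B = 1000, seed, dist = c("p", "poisson")) {
  stopifnot(inherits(a, "aa_alignment"), B >= 1)
  if (missing(seed)) stop("a bootstrap seed is required")
  dist <- match.arg(dist)
  dfun <- if (dist == "p") p_distance_matrix else poisson_distance_matrix
  point <- nj_tree(dfun(a))
  L <- ncol(a)
  im <- aln_int_matrix(a)
  labs <- rownames(a)
  safe <- paste0("x", seq_along(labs))
  counts <- new.env(parent = emptyenv())
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    d <- .pdist_cpp(im[, cols, drop = FALSE])
    if (dist == "poisson") {
      if (any(d >= 1)) next  # saturated replicate carries no signal
      d <- -log(1 - d)
    }
    tr <- ape::read.tree(text = .nj_cpp(d, safe))
    tr$tip.label <- labs[match(tr$tip.label, safe)]
    for (key in tree_split_keys(tr)) {
      prev <- counts[[key]]
      counts[[key]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }
  tu <- tips_under_nodes(point)
  ntip <- ape::Ntip(point)
  supports <- numeric(0)
  node_lab <- character(point$Nnode)
  for (nd in (ntip + 1L):(ntip + point$Nnode)) {
    tips <- point$tip.label[tu[[nd]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    key <- split_key(tips, point$tip.label)
    hits <- counts[[key]]
    pct <- round(100 * (if (is.null(hits)) 0 else hits) / B, 1)
    supports[key] <- pct
    node_lab[nd - ntip] <- format(pct)
  }
  point$node.label <- node_lab
  attr(point, "splits") <- supports
  attr(point, "boot") <- B
  point
}

#' Root a gene tree with an outgroup
#'
#' Places the root on the branch separating the outgroup's most recent common
#' ancestor from the remaining leaves.  If the outgroup is not monophyletic
#' in the unrooted tree, the root is placed on the edge that best separates
#' outgroup from ingroup (maximal fraction of correctly assigned leaves) and
#' a warning is emitted.  Bootstrap annotations made by
#' [bootstrap_support()] are re-attached to the rooted tree by bipartition,
#' so supports stay with the clades they measure.
#'
#' @param tree a `phylo` (typically from [nj_tree()] or
#'   [bootstrap_support()]).
#' @param outgroup character vector of leaf labels; a nonempty proper subset
#'   of the leaves.
#' @return a rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  outgroup <- unique(as.character(outgroup))
  if (length(outgroup) == 0) stop("outgroup must be nonempty")
  bad <- setdiff(outgroup, tree$tip.label)
  if (length(bad)) stop("outgroup leaves not in tree: ",
                        paste(bad, collapse = ", "))
  if (setequal(outgroup, tree$tip.label))
    stop("outgroup cannot contain every leaf")
  ut <- ape::unroot(tree)
  side <- best_outgroup_side(ut, outgroup)
  if (!setequal(side, outgroup))
    warning("outgroup is not monophyletic; rooting on the edge with ",
            "maximal outgroup-side purity")
  # rooting on an edge gives the same rooted topology from either side;
  # ape accepts the orientation that forms a clade in its representation
  rt <- tryCatch(ape::root(ut, outgroup = side, resolve.root = TRUE),
                 error = function(e)
                   ape::root(ut, outgroup = setdiff(ut$tip.label, side),
                             resolve.root = TRUE))
  splits <- attr(tree, "splits")
  if (!is.null(splits)) {
    tu <- tips_under_nodes(rt)
    ntip <- ape::Ntip(rt)
    lab <- character(rt$Nnode)
    for (nd in (ntip + 1L):(ntip + rt$Nnode)) {
      tips <- rt$tip.label[tu[[nd]]]
      if (length(tips) <= 1L || length(tips) >= ntip) next
      key <- split_key(tips, rt$tip.label)
      if (!is.na(key) && key %in% names(splits))
        lab[nd - ntip] <- format(splits[[key]])
    }
    rt$node.label <- lab
    attr(rt, "splits") <- splits
  }
  rt
}

# the edge side (tip set) best matching the outgroup in an unrooted tree;
# returns the outgroup itself when it is monophyletic
best_outgroup_side <- function(ut, outgroup) {
  tips <- ut$tip.label
  n <- length(tips)
  tu <- tips_under_nodes(ut)
  ntip <- ape::Ntip(ut)
  inner <- if (ut$Nnode >= 2L) (ntip + 2L):(ntip + ut$Nnode) else integer(0)
  cand <- c(lapply(seq_len(ntip), function(i) tips[i]),
            lapply(inner, function(nd) tips[tu[[nd]]]))
  best <- NULL; best_score <- c(-1, -1)
  for (half in cand) {
    if (length(half) == 0 || length(half) == n) next
    for (side in list(half, setdiff(tips, half))) {
      inb <- sum(side %in% outgroup)
      outb <- length(outgroup) - inb
      correct <- inb + ((n - length(side)) - outb)
      purity <- inb / length(side)     # tie-break: purest outgroup side
      if (correct > best_score[1] ||
          (correct == best_score[1] && purity > best_score[2])) {
        best_score <- c(correct, purity)
        best <- side
      }
    }
  }
  if (setequal(best, outgroup)) outgroup else best
}

#' Flag leaves whose placement contradicts the species history
#'
#' A sequence placed far from its true orthologs (for example an invertebrate
#' sequence nested inside a mammalian clade) inflates the species overlap of
#' ancestral nodes and fabricates ancient duplications.  This screen counts
#' duplication nodes whose species overlap maps at or above the
#' invertebrate-vertebrate split (epoch `B1`) and greedily flags the leaf
#' whose removal reduces that count the most (alphabetical tie-break),
#' repeating until no single removal helps.  Genuine ancient duplications
#' supported by whole clades survive the screen: no single leaf removal
#' dissolves them.  The caller decides whether to drop the flagged leaves.
#'
#' @param tree a rooted `phylo` whose leaf labels encode species (see
#'   [parse_seq_ids()]).
#' @param ref a `species_ref`.
#' @return character vector of flagged leaf labels (possibly empty).
#' @export
flag_discordant_leaves <- function(tree, ref) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  badness <- function(tr) {
    if (ape::Ntip(tr) < 3) return(0L)
    ev <- detect_duplications(tr, ref)
    if (nrow(ev) == 0) return(0L)
    bins <- vapply(seq_len(nrow(ev)), function(i) {
      sp <- union(ev$left_species[[i]], ev$right_species[[i]])
      epoch_bin(ref, lca_node(ref, sp))$bin
    }, character(1))
    sum(bins == "B1")
  }
  flagged <- character(0)
  cur <- tree
  score <- badness(cur)
  while (score > 0L && ape::Ntip(cur) > 3) {
    leaves <- sort(cur$tip.label)
    scores <- vapply(leaves, function(leaf)
      badness(ape::drop.tip(cur, leaf)), integer(1))
    red <- score - scores
    if (max(red) <= 0L) break
    pick <- leaves[which.max(red)]   # largest reduction, alphabetical ties
    flagged <- c(flagged, pick)
    cur <- ape::drop.tip(cur, pick)
    score <- badness(cur)
  }
  flagged
}
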