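#' Load the reference metazoan taxonomy and species tree
#'
#' Builds the reference framework used for relative (ordinal) dating of gene
#' duplications: a rooted species tree, clade membership for every taxon, and
#' the named speciation splits on the human root path that delimit the epoch
#' scale.  The packaged fixture covers the 46 metazoan species sampled in the
#' underlying survey (25 tetrapods, 5 teleost fish and 16 invertebrates).
#'
#' The taxonomy table must have columns `species_id`, `binomial`,
#' `common_name` and `clade_tags` (semicolon-separated tags from
#' `tetrapod`, `teleost`, `vertebrate`, `invertebrate`,
#' `chordate-invertebrate`, `protostome`, `non-bilaterian`).  Exactly one of
#' `tetrapod`/`teleost`/`invertebrate` is required per taxon, and every
#' tetrapod or teleost must also carry `vertebrate`.  The newick tree must be
#' rooted, its tips must match the taxonomy, and the major clades implied by
#' the tags must be monophyletic.
#'
#' Named splits are taken from internal node labels of the newick.  Two
#' aliases are added for nodes that carry a different primary label:
#' `invertebrate_vertebrate_split` (the split of vertebrates from their
#' closest sampled invertebrate relatives, here the tunicate split) and
#' `bilaterian_nonbilaterian_split` (the cnidarian split).
#'
#' @param taxonomy path to the taxonomy TSV (default: packaged fixture).
#' @param newick path to the rooted reference newick (default: packaged
#'   fixture).
#' @param human `species_id` of the focal species whose root path carries the
#'   epoch scale.
#' @return an object of class `species_ref`: a list with elements `tree`
#'   (an [ape::read.tree()] phylo), `taxa` (data frame), `splits` (named
#'   integer vector of node numbers), `human_path` (node numbers on the path
#'   root to human), `clades` (list of tip label vectors) and `human`.
#' @examples
#' ref <- load_reference_taxonomy()
#' length(ref$clades$tetrapod)
#' @export
load_reference_taxonomy <- function(taxonomy = pkg_extdata("taxonomy.tsv"),
                                    newick = pkg_extdata("species_tree.nwk"),
                                    human = "Hsap") {
  tax <- utils::read.delim(taxonomy, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("species_id", "binomial", "common_name", "clade_tags")
  if (!all(need %in% names(tax)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tax$species_id))
    stop("duplicated species_id in taxonomy table")
  tags <- strsplit(tax$clade_tags, ";", fixed = TRUE)
  names(tags) <- tax$species_id
  primary <- c("tetrapod", "teleost", "invertebrate")
  for (sp in tax$species_id) {
    hit <- intersect(tags[[sp]], primary)
    if (length(hit) != 1L)
      stop("taxon ", sp, " must carry exactly one of ",
           paste(primary, collapse = "/"))
    if (hit %in% c("tetrapod", "teleost") && !"vertebrate" %in% tags[[sp]])
      stop("taxon ", sp, " is ", hit, " but lacks the vertebrate tag")
    if (hit == "invertebrate" && "vertebrate" %in% tags[[sp]])
      stop("taxon ", sp, " is tagged both invertebrate and vertebrate")
  }

  tree <- ape::read.tree(newick)
  if (is.null(tree)) stop("could not parse reference newick")
  if (!ape::is.rooted(tree)) stop("reference species tree must be rooted")
  unknown <- setdiff(tree$tip.label, tax$species_id)
  if (length(unknown))
    stop("tree leaves missing from taxonomy table: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(tax$species_id, tree$tip.label)
  if (length(absent))
    stop("taxonomy species missing from tree: ", paste(absent, collapse = ", "))
  if (!human %in% tree$tip.label) stop("focal species not in tree: ", human)

  clades <- lapply(c(tetrapod = "tetrapod", teleost = "teleost",
                     invertebrate = "invertebrate", vertebrate = "vertebrate"),
                   function(tag) tax$species_id[vapply(tags, function(x)
                     tag %in% x, logical(1))[tax$species_id]])

  tips_under <- tips_under_nodes(tree)
  # monophyly of tagged clades (invertebrates are the complement of the
  # vertebrate clade and need not be monophyletic themselves)
  for (cl in c("tetrapod", "teleost", "vertebrate")) {
    members <- clades[[cl]]
    if (length(members) < 2) next
    mrca <- ape::getMRCA(tree, members)
    if (!setequal(tree$tip.label[tips_under[[mrca]]], members))
      stop("clade tag '", cl, "' contradicts the tree topology")
  }

  nlab <- tree$node.label
  ntip <- ape::Ntip(tree)
  splits <- integer(0)
  if (!is.null(nlab)) {
    named <- which(!is.na(nlab) & nzchar(nlab))
    splits <- stats::setNames(ntip + named, nlab[named])
    if (anyDuplicated(names(splits)))
      stop("duplicated split names in reference tree")
  }
  if ("tunicate_split" %in% names(splits) &&
      !"invertebrate_vertebrate_split" %in% names(splits))
    splits["invertebrate_vertebrate_split"] <- splits[["tunicate_split"]]
  if ("cnidarian_split" %in% names(splits) &&
      !"bilaterian_nonbilaterian_split" %in% names(splits))
    splits["bilaterian_nonbilaterian_split"] <- splits[["cnidarian_split"]]

  human_tip <- match(human, tree$tip.label)
  human_path <- c(rev(ancestor_chain(tree, human_tip)), human_tip)

  ref <- list(tree = tree, taxa = tax, tags = tags, splits = splits,
              clades = clades, human = human, human_path = human_path,
              tips_under = tips_under)
  class(ref) <- "species_ref"
  validate_epoch_scale(ref)
  ref
}

# tip index sets under every node (tips map to themselves)
tips_under_nodes <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  out <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chl <- po$edge[e, 2]
    out[[par]] <- c(out[[par]], out[[chl]])
  }
  lapply(out, sort)
}

# node numbers from a node up to (and including) the root
ancestor_chain <- function(tree, node) {
  root <- ape::Ntip(tree) + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  chain <- integer(0)
  while (node != root) {
    node <- parent[node]
    chain <- c(chain, node)
  }
  chain
}

validate_epoch_scale <- function(ref) {
  need <- c("invertebrate_vertebrate_split", "teleost_tetrapod_split")
  miss <- setdiff(need, names(ref$splits))
  if (length(miss))
    stop("reference tree lacks required named splits: ",
         paste(miss, collapse = ", "))
  for (nm in names(ref$splits))
    if (!ref$splits[[nm]] %in% ref$human_path &&
        !nm %in% c("teleost_crown"))
      stop("named split '", nm, "' is not on the human root path")
  ord <- match(ref$splits[setdiff(names(ref$splits), "teleost_crown")],
               ref$human_path)
  if (anyNA(ord)) stop("split ordering could not be established")
  invisible(ref)
}

#' @export
print.species_ref <- function(x, ...) {
  cat("Reference species framework\n")
  cat("  taxa:", nrow(x$taxa),
      sprintf("(%d tetrapods, %d teleosts, %d invertebrates)\n",
              length(x$clades$tetrapod), length(x$clades$teleost),
              length(x$clades$invertebrate)))
  cat("  named splits:", paste(names(x$splits), collapse = ", "), "\n")
  invisible(x)
}

#' Most recent common ancestor of a species set
#'
#' @param ref a `species_ref` from [load_reference_taxonomy()].
#' @param species character vector of `species_id` tokens.
#' @return the node number of the MRCA in `ref$tree` (a tip number when
#'   `species` is a single species).  The name of the corresponding split, if
#'   the node is named, is attached as the names attribute.
#' @examples
#' ref <- load_reference_taxonomy()
#' lca_node(ref, c("Hsap", "Dmel"))
#' @export
lca_node <- function(ref, species) {
  stopifnot(inherits(ref, "species_ref"))
  species <- unique(as.character(species))
  if (length(species) == 0) stop("empty species set")
  bad <- setdiff(species, ref$tree$tip.label)
  if (length(bad))
    stop("species not in reference tree: ", paste(bad, collapse = ", "))
  node <- if (length(species) == 1L) {
    match(species, ref$tree$tip.label)
  } else {
    ape::getMRCA(ref$tree, species)
  }
  nm <- names(ref$splits)[match(node, ref$splits)]
  stats::setNames(node, if (is.na(nm)) "" else nm)
}

#' Name of the split at a species-tree node, if any
#' @keywords internal
split_name <- function(ref, node) {
  hits <- names(ref$splits)[ref$splits == node]
  if (length(hits) == 0) return(NA_character_)
  # prefer the epoch-scale alias where present
  pref <- intersect(c("invertebrate_vertebrate_split",
                      "bilaterian_nonbilaterian_split"), hits)
  if (length(pref)) pref[1] else hits[1]
}

#' Epoch bin of a duplication mapped to a species-tree node
#'
#' The ordinal epoch scale has four reporting bins: `B1` before the
#' invertebrate-vertebrate split, `B2` after it and before the
#' teleost-tetrapod split, `B3` teleost-lineage specific, `B4`
#' tetrapod-lineage specific.  A duplication whose species overlap maps to a
#' node confined to an invertebrate subclade is outside the scale and
#' reported as `other`.  For `B1` the refining named split (the speciation
#' the duplication predates) is returned as well.
#'
#' @param ref a `species_ref`.
#' @param node species-tree node number (typically from [lca_node()]).
#' @return list with elements `bin` and `refined` (named split for `B1`,
#'   otherwise `NA`).
#' @export
epoch_bin <- function(ref, node) {
  node <- as.integer(node)
  tips <- ref$tree$tip.label[ref$tips_under[[node]]]
  if (all(tips %in% ref$clades$teleost))
    return(list(bin = "B3", refined = NA_character_))
  if (all(tips %in% ref$clades$tetrapod))
    return(list(bin = "B4", refined = NA_character_))
  idx <- match(node, ref$human_path)
  if (!is.na(idx)) {
    iv <- match(ref$splits[["invertebrate_vertebrate_split"]], ref$human_path)
    tt <- match(ref$splits[["teleost_tetrapod_split"]], ref$human_path)
    if (idx <= iv)
      return(list(bin = "B1", refined = split_name(ref, node)))
    if (idx <= tt)
      return(list(bin = "B2", refined = NA_character_))
  }
  list(bin = "other", refined = NA_character_)
}
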