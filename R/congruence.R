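# Schematic topologies are stored as nested lists:
#   leaf:     list(chrs = character vector of chromosome tokens)
#   internal: list(children = list of nodes)
# A leaf's `chrs` set holds every chromosome represented at that slot (the
# figure-style compound labels such as "8/6"); two leaves match if their sets
# intersect.

new_schematic <- function(root, family = NA_character_,
                          window = NA_character_) {
  structure(list(root = root, family = family, window = window),
            class = "schematic")
}

schem_leaf <- function(chrs) list(chrs = sort(unique(as.character(chrs))))
is_schem_leaf <- function(node) !is.null(node$chrs)

#' Parse a schematic topology from a mini-newick string
#'
#' Leaves are chromosome tokens, with `/` separating the members of a
#' compound slot (e.g. `"((20,1),8);"` or `"((1/6,8),20);"`).  `*` is a
#' wildcard leaf matching any chromosome.
#'
#' @param newick a rooted newick string with chromosome-token leaves.
#' @param family optional family name.
#' @return a `schematic` object.
#' @examples
#' as_schematic("((20,1),8);", family = "MROH")
#' @export
as_schematic <- function(newick, family = NA_character_) {
  if (inherits(newick, "schematic")) return(newick)
  tr <- ape::read.tree(text = gsub("\\s", "", newick))
  if (is.null(tr)) stop("could not parse schematic newick")
  build <- function(nd, tu, children) {
    kids <- children[[as.character(nd)]]
    if (is.null(kids)) {
      return(schem_leaf(strsplit(tr$tip.label[nd], "/", fixed = TRUE)[[1]]))
    }
    list(children = lapply(kids, build, tu = tu, children = children))
  }
  children <- split(tr$edge[, 2], tr$edge[, 1])
  root <- ape::Ntip(tr) + 1L
  node <- if (ape::Ntip(tr) == 1L) schem_leaf(tr$tip.label) else
    build(root, NULL, children)
  new_schematic(node, family = family)
}

#' @export
format.schematic <- function(x, ...) schem_newick(x$root)

#' @export
print.schematic <- function(x, ...) {
  cat("Schematic topology",
      if (!is.na(x$family)) paste0("[", x$family, "]"), format(x),
      paste0("(", schematic_symmetry(x), ")"), "\n")
  invisible(x)
}

schem_newick <- function(node) {
  if (is_schem_leaf(node)) return(paste(node$chrs, collapse = "/"))
  paste0("(", paste(vapply(node$children, schem_newick, ""),
                    collapse = ","), ")")
}

# order-invariant canonical form (children sorted by their canonical string)
schem_canonical <- function(node) {
  if (is_schem_leaf(node)) return(paste(node$chrs, collapse = "/"))
  kids <- sort(vapply(node$children, schem_canonical, ""))
  paste0("(", paste(kids, collapse = ","), ")")
}

#' Canonical form of a schematic topology
#'
#' A string representation invariant to child order, used for consensus
#' calling within co-duplicated groups.
#'
#' @param x a `schematic`.
#' @return character scalar.
#' @export
canonical_form <- function(x) schem_canonical(as_schematic(x)$root)

schem_n_leaves <- function(node) {
  if (is_schem_leaf(node)) return(1L)
  sum(vapply(node$children, schem_n_leaves, integer(1)))
}

schem_all_chrs <- function(node) {
  if (is_schem_leaf(node)) return(node$chrs)
  unique(unlist(lapply(node$children, schem_all_chrs)))
}

#' Symmetry class of a schematic topology
#'
#' `symmetric` for the two-by-two shape `((A,B),(C,D))`; every other shape
#' (in particular the three-leaf caterpillars) is `asymmetric`.
#'
#' @param x a `schematic`.
#' @return `"symmetric"` or `"asymmetric"`.
#' @export
schematic_symmetry <- function(x) {
  root <- as_schematic(x)$root
  if (is_schem_leaf(root)) return("asymmetric")
  kids <- root$children
  ok <- length(kids) == 2 && all(vapply(kids, function(k)
    !is_schem_leaf(k) && length(k$children) == 2 &&
      all(vapply(k$children, is_schem_leaf, logical(1))), logical(1)))
  if (ok) "symmetric" else "asymmetric"
}

#' Collapse a gene tree to its schematic topology for an epoch window
#'
#' Restricts a rooted, dated gene tree to the focal species' paralogs and
#' keeps only the branching structure created by duplications dated to the
#' focal epoch window (default `B2`, the vertebrate-stem window between the
#' invertebrate-vertebrate and teleost-tetrapod splits).  All other
#' structure is absorbed: duplications younger than the window merge their
#' paralogs into a single compound slot (the figure-style `8/6` labels), and
#' for duplications older than the window only the subtree carrying the most
#' window duplications (the family's analysed section) is retained.
#' Same-chromosome paralogs under one node collapse to one leaf.
#'
#' Families with fewer than two window duplications carry no usable
#' congruence signal and raise an error of class `paralogon_exclusion`.
#'
#' @param tree rooted gene tree (`phylo`).
#' @param events dated events from [date_duplications()] (filter by support
#'   first if desired).
#' @param ref a `species_ref`.
#' @param window focal epoch bin (default `"B2"`).
#' @param chrom_map optional named chromosome vector keyed by leaf label;
#'   defaults to the third `|`-field of the leaf names.
#' @param family family name attached to the schematic.
#' @return a `schematic`.
#' @export
schematic_topology <- function(tree, events, ref, window = "B2",
                               chrom_map = NULL, family = NA_character_) {
  stopifnot(inherits(tree, "phylo"))
  meta <- parse_seq_ids(tree$tip.label)
  species <- meta$species
  chrom <- if (is.null(chrom_map)) meta$chromosome else
    unname(chrom_map[tree$tip.label])
  win_nodes <- events$node[!is.na(events$bin) & events$bin == window]
  if (length(win_nodes) < 2)
    stop(structure(class = c("paralogon_exclusion", "error", "condition"),
                   list(message = paste0(
                     "family ", family, " has ", length(win_nodes),
                     " duplication(s) in window ", window,
                     "; at least 2 are required for congruence analysis"),
                     call = sys.call())))
  bin_rank <- c(B1 = 1, B2 = 2, B3 = 3, B4 = 3, other = 3)
  node_bin <- stats::setNames(events$bin, events$node)
  ntip <- ape::Ntip(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  human <- ref$human

  count_win <- function(nd) {
    kids <- children[[as.character(nd)]]
    if (is.null(kids)) return(0L)
    sum(nd %in% win_nodes) + sum(vapply(kids, count_win, integer(1)))
  }
  build <- function(nd) {
    kids <- children[[as.character(nd)]]
    if (is.null(kids)) {
      if (identical(species[nd], human)) {
        ch <- chrom[nd]
        if (is.na(ch)) stop("human paralog without chromosome label: ",
                            tree$tip.label[nd])
        return(schem_leaf(ch))
      }
      return(NULL)
    }
    bin <- if (as.character(nd) %in% names(node_bin))
      node_bin[[as.character(nd)]] else NA_character_
    if (!is.na(bin) && bin_rank[[bin]] == 1 && !(nd %in% win_nodes)) {
      # pre-window duplication: keep the section with most window events
      scores <- vapply(kids, count_win, integer(1))
      return(build(kids[[which.max(scores)]]))
    }
    sub <- Filter(Negate(is.null), lapply(kids, build))
    if (length(sub) == 0) return(NULL)
    if (length(sub) == 1) return(sub[[1]])
    if (nd %in% win_nodes) {
      return(list(children = sub))
    }
    # younger-than-window duplication (or undatable overlap): one slot
    schem_leaf(unlist(lapply(sub, schem_all_chrs)))
  }
  root <- build(ntip + 1L)
  if (is.null(root) || is_schem_leaf(root))
    stop(structure(class = c("paralogon_exclusion", "error", "condition"),
                   list(message = paste0("family ", family,
                     " retains no window duplication structure for ",
                     human), call = sys.call())))
  root <- merge_equal_leaves(root)
  s <- new_schematic(root, family = family, window = window)
  s
}

# siblings that are leaves with identical chromosome sets collapse to one
merge_equal_leaves <- function(node) {
  if (is_schem_leaf(node)) return(node)
  kids <- lapply(node$children, merge_equal_leaves)
  isl <- vapply(kids, is_schem_leaf, logical(1))
  if (any(isl)) {
    keys <- vapply(kids[isl], function(k) paste(k$chrs, collapse = "/"), "")
    kids <- c(kids[!isl], kids[isl][!duplicated(keys)])
  }
  if (length(kids) == 1) return(kids[[1]])
  list(children = kids)
}

#' Minimum translocations separating two schematic topologies
#'
#' The minimum number of leaf-label substitutions turning one labelling into
#' the other under the best rooted-tree isomorphism, computed exactly by
#' exhaustive matching (schematics are tiny).  Compound slots (`8/6`) match
#' at zero cost whenever the chromosome sets intersect; `*` is a wildcard.
#' Shapes that are not isomorphic are incongruent at any allowance and give
#' `Inf`.  With `pad = TRUE` size mismatches are tolerated instead: surplus
#' subtrees are matched against wildcard padding at a cost of one per leaf.
#'
#' @param a,b `schematic` objects (or newick strings).
#' @param pad logical; pad size mismatches with wildcard leaves instead of
#'   returning `Inf`.
#' @return non-negative integer, or `Inf` for incongruent shapes.
#' @examples
#' translocation_distance("((20,1),8);", "((2,13),X);")  # 3
#' translocation_distance("((1,2),3);", "((1,2),(3,4));")  # Inf
#' @export
translocation_distance <- function(a, b, pad = FALSE) {
  a <- as_schematic(a); b <- as_schematic(b)
  d <- schem_dist(a$root, b$root, pad = pad)
  if (is.finite(d)) as.integer(d) else d
}

leaf_cost <- function(u, v) {
  if ("*" %in% u$chrs || "*" %in% v$chrs) return(0)
  if (length(intersect(u$chrs, v$chrs))) 0 else 1
}

schem_dist <- function(u, v, pad = FALSE) {
  ul <- is_schem_leaf(u); vl <- is_schem_leaf(v)
  if (ul && vl) return(leaf_cost(u, v))
  if (ul || vl) {
    if (!pad) return(Inf)
    leaf <- if (ul) u else v
    node <- if (ul) v else u
    # the lone leaf matches its best counterpart; remaining leaves are
    # surplus matched to wildcard padding at cost 1 each
    sub <- schem_leaves(node)
    best <- min(vapply(sub, leaf_cost, numeric(1), v = leaf))
    return(best + (length(sub) - 1L))
  }
  ku <- u$children; kv <- v$children
  if (length(ku) != length(kv)) {
    if (!pad) return(Inf)
    if (length(ku) > length(kv)) { tmp <- ku; ku <- kv; kv <- tmp }
    # match the smaller child list into the larger; surplus subtrees cost
    # one per leaf (wildcard padding)
    return(min_assign(ku, kv, pad = TRUE, surplus = TRUE))
  }
  min_assign(ku, kv, pad = pad, surplus = FALSE)
}

schem_leaves <- function(node) {
  if (is_schem_leaf(node)) return(list(node))
  do.call(c, lapply(node$children, schem_leaves))
}

# minimum-cost assignment of child list `ku` onto distinct members of `kv`
# (|ku| <= |kv|), by exhaustive permutation; unmatched kv subtrees cost their
# leaf count when `surplus` is TRUE
min_assign <- function(ku, kv, pad, surplus) {
  m <- length(ku); n <- length(kv)
  cost <- matrix(0, m, n)
  for (i in seq_len(m))
    for (j in seq_len(n))
      cost[i, j] <- schem_dist(ku[[i]], kv[[j]], pad = pad)
  sizes <- vapply(kv, schem_n_leaves, integer(1))
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > m) {
      tot <- acc + if (surplus) sum(sizes[!used]) else 0
      if (tot < best) best <<- tot
      return()
    }
    for (j in seq_len(n)) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1L, used, acc + cost[i, j])
      used[j] <- FALSE
    }
  }
  rec(1L, logical(n), 0)
  best
}

#' Are two schematic topologies congruent at a translocation allowance?
#'
#' @inheritParams translocation_distance
#' @param k allowed number of translocations.
#' @return logical.
#' @export
congruent <- function(a, b, k, pad = FALSE) {
  translocation_distance(a, b, pad = pad) <= k
}

#' Cluster families into co-duplicated groups
#'
#' Builds the congruence graph (edges between schematic pairs whose
#' translocation distance is within the allowance) and returns its connected
#' components as co-duplicated groups.  The pairwise congruence predicate is
#' not transitive, so intra-group pairs exceeding their allowance can occur
#' inside a component; they are reported in `flagged_pairs`.
#'
#' @param schematics list of `schematic` objects (each with a `family`).
#' @param k translocation allowance: a single number, or a data frame with
#'   columns `family_a`, `family_b`, `k` giving per-pair allowances (pairs
#'   not listed fall back to `default_k`).
#' @param default_k fallback allowance for pairs absent from a per-pair
#'   table.
#' @param pad passed to [translocation_distance()].
#' @return object of class `coduplication_groups`: list with `groups` (list
#'   of family-name vectors, ordered by smallest member), `consensus`
#'   (modal canonical topology per group), `symmetry`, `distances` (matrix),
#'   `membership` (named integer vector) and `flagged_pairs`.
#' @examples
#' s <- lapply(c(A = "((1,2),3);", B = "((1,2),3);", C = "((1,2),(3,4));"),
#'             as_schematic)
#' for (f in names(s)) s[[f]]$family <- f
#' co_duplication_groups(s, k = 0)$groups
#' @export
co_duplication_groups <- function(schematics, k = 3, default_k = 0,
                                  pad = FALSE) {
  if (length(schematics) == 0) stop("at least one schematic is required")
  schematics <- lapply(schematics, as_schematic)
  fams <- unname(vapply(schematics, function(s) s$family, ""))
  if (anyNA(fams) || anyDuplicated(fams))
    stop("every schematic needs a unique family name")
  n <- length(schematics)
  D <- matrix(Inf, n, n, dimnames = list(fams, fams))
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    D[i, j] <- D[j, i] <-
      translocation_distance(schematics[[i]], schematics[[j]], pad = pad)
  K <- allowance_matrix(fams, k, default_k)
  adj <- is.finite(D) & D <= K
  comp <- connected_components(adj)
  ord <- order(vapply(comp, function(g) min(fams[g]), ""))
  comp <- comp[ord]
  groups <- lapply(comp, function(g) sort(fams[g]))
  consensus <- vapply(comp, function(g) {
    forms <- vapply(schematics[g], canonical_form, "")
    tab <- sort(table(forms), decreasing = TRUE)
    nm <- names(tab)[tab == max(tab)]
    sort(nm)[1]
  }, "")
  symmetry <- vapply(consensus, function(f)
    schematic_symmetry(as_schematic(paste0(f, ";"))), "")
  membership <- stats::setNames(integer(length(fams)), fams)
  for (gi in seq_along(comp)) membership[fams[comp[[gi]]]] <- gi
  flagged <- data.frame(family_a = character(0), family_b = character(0),
                        distance = numeric(0))
  for (gi in seq_along(comp)) {
    g <- comp[[gi]]
    if (length(g) < 2) next
    for (ii in seq_len(length(g) - 1)) for (jj in (ii + 1):length(g)) {
      i <- g[ii]; j <- g[jj]
      if (!adj[i, j])
        flagged <- rbind(flagged, data.frame(
          family_a = fams[i], family_b = fams[j], distance = D[i, j]))
    }
  }
  structure(list(groups = groups, consensus = unname(consensus),
                 symmetry = unname(symmetry), distances = D,
                 membership = membership, flagged_pairs = flagged),
            class = "coduplication_groups")
}

allowance_matrix <- function(fams, k, default_k) {
  n <- length(fams)
  if (is.numeric(k) && length(k) == 1) {
    return(matrix(k, n, n, dimnames = list(fams, fams)))
  }
  if (is.data.frame(k)) {
    need <- c("family_a", "family_b", "k")
    if (!all(need %in% names(k)))
      stop("per-pair allowance table needs columns ",
           paste(need, collapse = ", "))
    K <- matrix(default_k, n, n, dimnames = list(fams, fams))
    for (r in seq_len(nrow(k))) {
      a <- as.character(k$family_a[r]); b <- as.character(k$family_b[r])
      if (a %in% fams && b %in% fams) K[a, b] <- K[b, a] <- k$k[r]
    }
    return(K)
  }
  if (is.matrix(k)) return(k[fams, fams])
  stop("k must be a scalar, a matrix or a per-pair data frame")
}

connected_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps <- c(comps, list(sort(members)))
  }
  comps
}

#' @export
print.coduplication_groups <- function(x, ...) {
  cat("Co-duplicated groups:", length(x$groups), "\n")
  for (i in seq_along(x$groups))
    cat(sprintf("  %d. {%s}  consensus %s (%s)\n", i,
                paste(x$groups[[i]], collapse = ", "),
                x$consensus[i], x$symmetry[i]))
  if (nrow(x$flagged_pairs))
    cat("  flagged intra-group pairs exceeding allowance:",
        nrow(x$flagged_pairs), "\n")
  invisible(x)
}

#' The packaged schematic-topology fixture for the congruence analysis
#'
#' Loads the 16 family schematics entering the co-duplication comparison
#' together with the published per-panel translocation allowances, and the
#' derived per-pair allowance table (pairs for which no translocation events
#' were posited get allowance 0, i.e. strict congruence).
#'
#' @return list with `schematics` (named list of `schematic`), `table` (the
#'   raw fixture data frame) and `allowances` (per-pair data frame usable as
#'   `k` in [co_duplication_groups()]).
#' @export
coduplication_fixture <- function() {
  tab <- utils::read.delim(pkg_extdata("coduplication_schematics.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  schematics <- lapply(seq_len(nrow(tab)), function(i)
    as_schematic(tab$schematic[i], family = tab$family[i]))
  names(schematics) <- tab$family
  pairs <- list()
  for (p in unique(tab$panel)) {
    fams <- tab$family[tab$panel == p]
    kk <- tab$allowance[tab$panel == p][1]
    if (length(fams) < 2) next
    cmb <- utils::combn(fams, 2)
    pairs[[p]] <- data.frame(family_a = cmb[1, ], family_b = cmb[2, ],
                             k = kk, stringsAsFactors = FALSE)
  }
  list(schematics = schematics, table = tab,
       allowances = do.call(rbind, pairs))
}
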