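#' Specify a duplication-history simulation scenario
#'
#' A scenario fixes everything the simulator needs to generate gene families
#' with known duplication histories: the mode contrasting the two competing
#' hypotheses (`two_round_WGD` — every family duplicates twice at the same
#' two points on the vertebrate stem, 1 to 2 to 4 copies; `independent_SD`
#' — each family draws its own duplication placements; `mixed` — half and
#' half), the species sample, loss and translocation probabilities, and the
#' sequence model.
#'
#' Defaults emulate the study conditions of a paralogon survey: families
#' ascertained for retained paralogs on the target chromosomes (no loss on
#' the focal human lineage), occasional missing orthologs elsewhere, rare
#' translocations, alignments of 1000 gap-free amino-acid columns at a
#' moderate substitution rate.  The default species sample is a 12-taxon
#' subsample of the reference tree spanning all named splits used in dating.
#'
#' @param mode one of `"two_round_WGD"`, `"independent_SD"`, `"mixed"`.
#' @param n_families number of families to simulate.
#' @param species species sample (tokens from the reference taxonomy).
#' @param placements for `independent_SD`: candidate placement edges, each a
#'   `c(top, bottom)` pair of named splits on the human root path (see
#'   [simulation_placements()]).
#' @param n_events duplications per family in `independent_SD` mode.
#' @param loss_prob probability that a non-focal species loses a given copy.
#' @param human_loss_prob loss probability on the focal (human) lineage;
#'   kept at 0 by default because surveyed families are ascertained for
#'   retention.
#' @param transloc_prob probability that an extant human copy is relabelled
#'   to a random other chromosome.
#' @param seq_length alignment columns to simulate.
#' @param rate amino-acid substitutions per site per unit branch length.
#' @param target_chroms chromosome labels assigned to copies at birth.
#' @param seed integer seed (mandatory).
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(mode = c("two_round_WGD", "independent_SD", "mixed"),
                          n_families = 10,
                          species = c("Hsap", "Mmus", "Mdom", "Ggal", "Xtro",
                                      "Drer", "Olat", "Gacu", "Bflo", "Cint",
                                      "Dmel", "Nvec"),
                          placements = simulation_placements(),
                          n_events = 2,
                          loss_prob = 0.1,
                          human_loss_prob = 0,
                          transloc_prob = 0.05,
                          seq_length = 1000,
                          rate = 1,
                          target_chroms = c("1", "2", "8", "20"),
                          seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a simulation seed is mandatory")
  stopifnot(n_families >= 1, seq_length >= 1,
            loss_prob >= 0, loss_prob <= 1,
            human_loss_prob >= 0, human_loss_prob <= 1,
            transloc_prob >= 0, transloc_prob <= 1)
  structure(list(mode = mode, n_families = n_families, species = species,
                 placements = placements, n_events = n_events,
                 loss_prob = loss_prob, human_loss_prob = human_loss_prob,
                 transloc_prob = transloc_prob, seq_length = seq_length,
                 rate = rate, target_chroms = target_chroms,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Candidate duplication placements for independent-duplication scenarios
#'
#' Each placement is an edge of the reference species tree given by the
#' named splits above and below it; a duplication on that edge is expected
#' to date to the corresponding epoch bin.  The default set spans the four
#' reporting bins: a pre-bilaterian placement (`B1`), the
#' tunicate-to-vertebrate stem (`B2`), the teleost stem (`B3`) and the
#' tetrapod stem (`B4`).
#'
#' @return list of `c(top, bottom)` character pairs with a `bin` attribute.
#' @export
simulation_placements <- function() {
  list(pre_bilaterian = c("placozoan_split", "cnidarian_split"),
       vertebrate_stem = c("invertebrate_vertebrate_split",
                           "teleost_tetrapod_split"),
       teleost_stem = c("teleost_tetrapod_split", "teleost_crown"),
       tetrapod_stem = c("teleost_tetrapod_split", "amphibian_split"))
}

node_depths <- function(tree) {
  # height above the leaves, assuming an ultrametric tree
  ed <- ape::node.depth.edgelength(tree)
  max(ed) - ed
}

#' Simulate gene-family trees with known duplication histories
#'
#' Generates, for every family, a gene tree grown along the reference
#' species tree with duplication events at the scenario's placements, loss
#' applied per copy and species, and chromosome labels assigned at birth and
#' perturbed by translocation.  In `two_round_WGD` mode all families share
#' the same two nested events on the vertebrate stem; in `independent_SD`
#' mode every family draws its own placements (with replacement) from
#' `spec$placements`.
#'
#' @param spec a [scenario_spec()].
#' @param ref a `species_ref`.
#' @return a `ground_truth` list: per family `tree` (phylo with branch
#'   lengths, leaf labels `species|gene|chromosome`), `events` (data frame
#'   with the true placement and epoch bin of every duplication),
#'   `human_chroms`; plus the overall `partition` (true co-duplication
#'   grouping of families) and the echoed `spec`.
#' @export
simulate_family_trees <- function(spec, ref) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(ref, "species_ref"))
  set.seed(spec$seed)
  tr <- ref$tree
  depths <- node_depths(tr)
  for (pl in spec$placements) {
    if (!all(pl %in% names(ref$splits)))
      stop("invalid placement interval: ", paste(pl, collapse = " -> "))
  }
  modes <- if (spec$mode == "mixed") {
    rep(c("two_round_WGD", "independent_SD"), length.out = spec$n_families)
  } else rep(spec$mode, spec$n_families)

  # shared 2R events: two nested duplications on the vertebrate stem
  stem <- c("invertebrate_vertebrate_split", "teleost_tetrapod_split")
  stem_depths <- depths[ref$splits[stem]]
  wgd_times <- stem_depths[1] - diff(range(stem_depths)) * c(1, 2) / 3

  fams <- vector("list", spec$n_families)
  names(fams) <- sprintf("F%02d", seq_len(spec$n_families))
  partition <- integer(spec$n_families)
  names(partition) <- names(fams)
  next_group <- 1L
  wgd_group <- NA_integer_
  for (fi in seq_len(spec$n_families)) {
    fam <- names(fams)[fi]
    if (modes[fi] == "two_round_WGD") {
      # genome-wide events: every copy crossing the stem duplicates
      ev <- data.frame(
        top = stem[1], bottom = stem[2], time = wgd_times,
        scope = "genome", stringsAsFactors = FALSE)
      if (is.na(wgd_group)) { wgd_group <- next_group; next_group <- next_group + 1L }
      partition[fi] <- wgd_group
    } else {
      # single-locus events: only the founder copy lineage duplicates
      idx <- sample.int(length(spec$placements), spec$n_events,
                        replace = TRUE)
      ev <- do.call(rbind, lapply(idx, function(i) {
        pl <- spec$placements[[i]]
        dtop <- depths[ref$splits[[pl[1]]]]
        dbot <- depths[ref$splits[[pl[2]]]]
        data.frame(top = pl[1], bottom = pl[2],
                   time = stats::runif(1, dbot, dtop),
                   scope = "single", stringsAsFactors = FALSE)
      }))
      partition[fi] <- next_group
      next_group <- next_group + 1L
    }
    ev <- ev[order(-ev$time), , drop = FALSE]
    ev$event_id <- paste0("e", seq_len(nrow(ev)))
    ev$bin <- vapply(ev$bottom, function(b)
      epoch_bin(ref, ref$splits[[b]])$bin, character(1))
    fams[[fi]] <- grow_family(fam, ev, spec, ref, depths)
    fams[[fi]]$events <- cbind(family = fam, ev)
  }
  structure(list(families = fams, partition = partition, spec = spec),
            class = "ground_truth")
}

# grow one family's gene tree: copies traverse the species tree, duplicating
# on their event edges and dropping leaves by the loss model
grow_family <- function(fam, events, spec, ref, depths) {
  tr <- ref$tree
  ntip <- ape::Ntip(tr)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  copy_counter <- 0L
  used_chroms <- character(0)
  founder <- spec$target_chroms[1]

  # genome-wide (block) duplications fill the target chromosomes in order,
  # emulating linked copies on shared paralogon blocks; independent
  # single-locus duplications land on a random free chromosome
  new_chrom <- function(scope = "genome") {
    free <- setdiff(spec$target_chroms, used_chroms)
    pool <- if (length(free)) free else
      setdiff(c(as.character(1:22), "X"), used_chroms)
    ch <- if (scope == "genome") pool[1] else sample(pool, 1)
    used_chroms <<- c(used_chroms, ch)
    ch
  }

  # descend(node, entry_depth, chrom, pending events sorted old->young):
  # returns nested list tree or NULL when the whole copy subtree is lost
  descend <- function(node, entry_depth, chrom, pending) {
    exit_depth <- depths[node]
    on_edge <- which(pending$apply_node == node &
                     pending$time < entry_depth & pending$time >= exit_depth &
                     (pending$scope == "genome" | chrom == founder))
    if (length(on_edge)) {
      i <- on_edge[1]
      ev_time <- pending$time[i]
      ch2 <- new_chrom(pending$scope[i])
      rest <- pending[-i, , drop = FALSE]
      left <- descend(node, ev_time, chrom, rest)
      right <- descend(node, ev_time, ch2, rest)
      kids <- Filter(Negate(is.null), list(left, right))
      if (length(kids) == 0) return(NULL)
      if (length(kids) == 1) return(kids[[1]])
      return(list(depth = ev_time, children = kids, event = pending$event_id[i]))
    }
    kids_nodes <- children[[as.character(node)]]
    if (is.null(kids_nodes)) {                       # species leaf
      sp <- tr$tip.label[node]
      if (!sp %in% spec$species) return(NULL)
      p_loss <- if (sp == ref$human) spec$human_loss_prob else spec$loss_prob
      if (stats::runif(1) < p_loss) return(NULL)
      copy_counter <<- copy_counter + 1L
      return(list(depth = 0, species = sp, chrom = chrom,
                  copy = copy_counter))
    }
    sub <- lapply(kids_nodes, descend, entry_depth = exit_depth,
                  chrom = chrom, pending = pending)
    sub <- Filter(Negate(is.null), sub)
    if (length(sub) == 0) return(NULL)
    if (length(sub) == 1) return(sub[[1]])
    list(depth = exit_depth, children = sub, event = NA_character_)
  }

  pending <- events
  # the event edge is the species-tree edge whose bottom node is the named
  # split below the placement
  pending$apply_node <- vapply(events$bottom, function(b)
    ref$splits[[b]], integer(1))
  root_node <- ntip + 1L
  gt <- descend(root_node, depths[root_node] + 1e-9, new_chrom(), pending)
  if (is.null(gt)) stop("family ", fam, " lost every copy; lower loss_prob")

  # translocation: extant human copies may move to a random other chromosome
  relabel <- function(node) {
    if (!is.null(node$species)) {
      if (node$species == ref$human &&
          stats::runif(1) < spec$transloc_prob) {
        node$chrom <- sample(setdiff(c(as.character(1:22), "X"),
                                     node$chrom), 1)
        node$translocated <- TRUE
      }
      return(node)
    }
    node$children <- lapply(node$children, relabel)
    node
  }
  gt <- relabel(gt)

  phy <- gene_tree_phylo(gt, fam)
  human_leaves <- grepl(paste0("^", ref$human, "\\|"), phy$tip.label)
  meta <- parse_seq_ids(phy$tip.label[human_leaves])

  # one duplication NODE per surviving application of an event (a
  # genome-wide event crossing k copies leaves up to k nodes)
  collect_nodes <- function(node) {
    if (!is.null(node$species)) return(character(0))
    c(if (!is.na(node$event)) node$event else character(0),
      unlist(lapply(node$children, collect_nodes)))
  }
  node_ev <- collect_nodes(gt)
  list(tree = phy,
       human_chroms = stats::setNames(meta$chromosome, meta$gene),
       true_bins = events$bin[match(node_ev, events$event_id)])
}

# nested-list gene tree -> phylo with branch lengths (depth differences)
gene_tree_phylo <- function(gt, fam) {
  nwk <- function(node, parent_depth) {
    bl <- parent_depth - node$depth
    if (!is.null(node$species)) {
      lab <- sprintf("%s|%s_c%d|%s", node$species, fam, node$copy,
                     node$chrom)
      return(sprintf("%s:%.8f", lab, bl))
    }
    inner <- paste(vapply(node$children, nwk, "",
                          parent_depth = node$depth), collapse = ",")
    sprintf("(%s):%.8f", inner, bl)
  }
  txt <- paste0(sub(":[0-9.]+$", "", nwk(gt, gt$depth)), ";")
  ape::read.tree(text = txt)
}

#' Evolve amino-acid sequences along simulated gene trees
#'
#' Simple i.i.d.-site exchangeable substitution model: along a branch of
#' length `b` each site substitutes with probability `1 - exp(-rate * b)`,
#' drawing uniformly among the other 19 amino acids.  No indels are
#' simulated, so the emitted alignments are exact and the trimming stage is
#' a no-op on them.
#'
#' @param truth a `ground_truth` from [simulate_family_trees()].
#' @param spec the same [scenario_spec()] (supplies length, rate, seed).
#' @return named list of `aa_alignment` objects, one per family.
#' @export
evolve_sequences <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(spec$seed + 1L)
  lapply(truth$families, function(fm) {
    phy <- fm$tree
    L <- spec$seq_length
    ntip <- ape::Ntip(phy)
    root <- ntip + 1L
    nnode <- ntip + phy$Nnode
    seqs <- vector("list", nnode)
    seqs[[root]] <- sample(AA20, L, replace = TRUE)
    ord <- ape::reorder.phylo(phy, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; chl <- ord$edge[e, 2]
      bl <- ord$edge.length[e]
      s <- seqs[[par]]
      hit <- which(stats::runif(L) < 1 - exp(-spec$rate * bl))
      if (length(hit)) {
        shift <- sample.int(19L, length(hit), replace = TRUE)
        cur <- match(s[hit], AA20)
        s[hit] <- AA20[((cur - 1L + shift) %% 20L) + 1L]
      }
      seqs[[chl]] <- s
    }
    aa_alignment(vapply(seq_len(ntip), function(i)
      paste(seqs[[i]], collapse = ""), ""), ids = phy$tip.label)
  })
}
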