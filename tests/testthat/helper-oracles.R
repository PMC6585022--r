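# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: tree fitting goes through phangorn, schematic
# comparison through plain nested lists and exhaustive enumeration.

ref_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_reference_taxonomy()
    cache
  }
})

# random unrooted tree with positive branch lengths and its additive matrix
random_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# exhaustive least-squares topology search: fit every unrooted topology by
# non-negative least squares and return the one with minimal residual
ls_best_topology <- function(dm) {
  labs <- rownames(dm)
  cands <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  rss <- vapply(cands, function(tr) {
    fit <- phangorn::nnls.tree(stats::as.dist(dm), tr,
                               method = "unrooted")
    sum((ape::cophenetic.phylo(fit)[labs, labs] - dm)^2)
  }, numeric(1))
  cands[[which.min(rss)]]
}

same_topology <- function(a, b) {
  phangorn::RF.dist(ape::unroot(a), ape::unroot(b)) == 0
}

# -- schematic oracle ---------------------------------------------------

# parse a schematic newick into a plain nested list (independent of the
# package's parser): leaf = character vector of chromosome tokens
oracle_parse <- function(newick) {
  tr <- ape::read.tree(text = newick)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  rec <- function(nd) {
    k <- kids[[as.character(nd)]]
    if (is.null(k)) return(strsplit(tr$tip.label[nd], "/", fixed = TRUE)[[1]])
    lapply(k, rec)
  }
  rec(ape::Ntip(tr) + 1L)
}

# every child-ordering of the tree, as (shape string, list of leaf labels)
oracle_orderings <- function(node) {
  if (!is.list(node)) {
    return(list(list(shape = "L", leaves = list(node))))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  out <- list()
  for (ord in perms(seq_along(node))) {
    kid_sets <- lapply(node[ord], oracle_orderings)
    combos <- list(list(shape = "", leaves = list()))
    for (ks in kid_sets) {
      combos <- do.call(c, lapply(combos, function(cm)
        lapply(ks, function(k)
          list(shape = paste0(cm$shape, k$shape),
               leaves = c(cm$leaves, k$leaves)))))
    }
    out <- c(out, lapply(combos, function(cm)
      list(shape = paste0("(", cm$shape, ")"), leaves = cm$leaves)))
  }
  out
}

# brute-force translocation distance: minimum leaf mismatches over all
# orderings of `a` whose shape matches a fixed ordering of `b`
oracle_translocation <- function(na, nb) {
  a <- oracle_parse(na); b <- oracle_parse(nb)
  b0 <- oracle_orderings(b)[[1]]
  best <- Inf
  for (cand in oracle_orderings(a)) {
    if (cand$shape != b0$shape) next
    mism <- sum(!mapply(function(x, y)
      "*" %in% x || "*" %in% y || length(intersect(x, y)) > 0,
      cand$leaves, b0$leaves))
    best <- min(best, mism)
  }
  best
}

# random schematic newick over a fixed shape with labels drawn from a pool
random_schematic_newick <- function(shape_id, pool = c(as.character(1:9), "X")) {
  shapes <- c("((%s,%s),%s);", "((%s,%s),(%s,%s));", "(((%s,%s),%s),%s);",
              "((((%s,%s),%s),%s),%s);", "((%s,%s,%s),%s);")
  sh <- shapes[[shape_id]]
  nlv <- lengths(regmatches(sh, gregexpr("%s", sh)))
  do.call(sprintf, c(list(sh), as.list(sample(pool, nlv, replace = TRUE))))
}
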