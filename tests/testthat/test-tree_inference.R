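test_that("p-distance and Poisson correction follow their closed forms", {
  a <- read_alignment(text = ">s1\nACDE\n>s2\nACDE\n>s3\nACDF\n")
  d <- p_distance_matrix(a)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 0.25)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  pd <- poisson_distance_matrix(a)
  expect_equal(pd["s1", "s2"], 0)
  expect_equal(pd["s1", "s3"], -log(0.75))

  sat <- aa_alignment(c(u = "AAAA", v = "CCCC"))
  expect_error(poisson_distance_matrix(sat), "saturated pair.*[uv] vs [uv]")
})

test_that("NJ recovers the quartet and the three-taxon closed form", {
  d <- matrix(c(0, 2, 4, 4,  2, 0, 4, 4,  4, 4, 0, 2,  4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1));")
  expect_true(same_topology(tr, truth))
  # the AB|CD internal edge has length 2
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_equal(internal, 2)

  d3 <- matrix(c(0, 5, 10,  5, 0, 9,  10, 9, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 3, b = 2, c = 7))

  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("tied Q values resolve deterministically", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- ape::write.tree(nj_tree(d))
  t2 <- ape::write.tree(nj_tree(d))
  expect_identical(t1, t2)
  # the lexicographically smallest pair (rows 1,2) is joined first
  expect_match(t1, "\\(a:[0-9.]+,b:[0-9.]+\\)")
})

test_that("NJ recovers the generating topology of additive matrices", {
  set.seed(401)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    ra <- random_additive(n)
    inferred <- nj_tree(ra$dm)
    expect_true(same_topology(inferred, ra$tree))
  }
})

test_that("NJ agrees with exhaustive least-squares search on small matrices", {
  set.seed(402)
  for (i in 1:10) {
    n <- sample(4:5, 1)
    ra <- random_additive(n)
    expect_true(same_topology(nj_tree(ra$dm), ls_best_topology(ra$dm)))
  }
})

test_that("bootstrap gives full support to clean splits, deterministically", {
  set.seed(7)
  h1 <- paste(sample(c("A", "C"), 100, TRUE), collapse = "")
  h2 <- chartr("AC", "DE", h1)
  a <- aa_alignment(c(s1 = h1, s2 = h1, s3 = h2, s4 = h2))
  bt <- bootstrap_support(a, B = 200, seed = 99)
  sp <- attr(bt, "splits")
  expect_equal(unname(sp), 100)  # the single informative bipartition
  bt2 <- bootstrap_support(a, B = 200, seed = 99)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))
  expect_error(bootstrap_support(a, B = 10), "seed")

  # supports are invariant to leaf order
  perm <- c(3, 1, 4, 2)
  ap <- aa_alignment(setNames(c(h2, h1, h2, h1),
                              c("s3", "s1", "s4", "s2")))
  btp <- bootstrap_support(ap, B = 200, seed = 99)
  expect_equal(attr(btp, "splits"), sp)
})

test_that("bootstrap supports stay in range on noisy simulated data", {
  ref <- ref_fixture()
  spec <- scenario_spec("independent_SD", n_families = 1, seq_length = 200,
                        rate = 2, seed = 31)
  aln <- evolve_sequences(simulate_family_trees(spec, ref))[[1]]
  bt <- bootstrap_support(aln, B = 50, seed = 5)
  sp <- attr(bt, "splits")
  expect_true(all(sp >= 0 & sp <= 100))
  bt2 <- bootstrap_support(aln, B = 50, seed = 5)
  expect_equal(attr(bt2, "splits"), sp)
})

test_that("outgroup rooting places and annotates the root correctly", {
  tr <- ape::read.tree(text = "(h1:1,h2:1,fly:4);")
  rt <- root_tree(tr, "fly")
  expect_true(ape::is.rooted(rt))
  kids <- rt$edge[rt$edge[, 1] == ape::Ntip(rt) + 1L, 2]
  expect_true(match("fly", rt$tip.label) %in% kids)

  # subfamily rooting: one subfamily roots the other
  tr2 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  rt2 <- root_tree(ape::unroot(tr2), c("b1", "b2"))
  expect_true(ape::is.monophyletic(rt2, c("a1", "a2")))
  expect_error(root_tree(tr, c("h1", "h2", "fly")), "every leaf")

  # rooting then unrooting returns the original unrooted topology
  set.seed(11)
  tru <- ape::rtree(8, rooted = FALSE)
  rt3 <- root_tree(tru, sample(tru$tip.label, 3))
  expect_equal(phangorn::RF.dist(ape::unroot(rt3), tru), 0)
})

test_that("non-monophyletic outgroups root by purity with a warning", {
  tr <- ape::read.tree(text = "(((o1:1,i1:1):1,i2:1):1,(o2:1,o3:1):1);")
  expect_warning(rt <- root_tree(ape::unroot(tr), c("o1", "o2", "o3")),
                 "not monophyletic")
  expect_true(ape::is.rooted(rt))
})

test_that("discordant leaves are flagged, concordant trees are clean", {
  ref <- ref_fixture()
  # one fly sequence nested inside the mammal clade fabricates an ancient
  # duplication at the root
  bad <- ape::read.tree(text = paste0(
    "(((Hsap|a|1,(Dmel|x|-,Mmus|a|-)),(Hsap|b|2,Mmus|b|-)),Dmel|o|-);"))
  expect_equal(flag_discordant_leaves(bad, ref), "Dmel|x|-")

  good <- ape::read.tree(text =
    "(((Hsap|a|1,Mmus|a|-),Drer|a|-),Dmel|a|-);")
  expect_length(flag_discordant_leaves(good, ref), 0)

  solo <- ape::read.tree(text = "((Hsap|a|1,Hsap|b|2),Hsap|c|8);")
  expect_length(flag_discordant_leaves(solo, ref), 0)
})
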