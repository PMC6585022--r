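test_that("schematics collapse gene trees to window duplication structure", {
  ref <- ref_fixture()
  # three human paralogs separated by two stem duplications, with zebrafish
  # orthologs interleaved so the overlaps span the vertebrate crown
  tr <- ape::read.tree(text = paste0(
    "((((Hsap|g1|1,Drer|g1|-),(Hsap|g2|8,Drer|g2|-)),",
    "(Hsap|g3|20,Drer|g3|-)),Bflo|o|-);"))
  ev <- date_duplications(detect_duplications(tr, ref), tr, ref, "toy")
  expect_equal(ev$bin, c("B2", "B2"))
  s <- schematic_topology(tr, ev, ref, family = "toy")
  expect_equal(canonical_form(s), "((1,8),20)")
  expect_equal(schematic_symmetry(s), "asymmetric")

  # a single window duplication is excluded from the congruence analysis
  tr1 <- ape::read.tree(text =
    "(((Hsap|g1|1,Drer|g1|-),(Hsap|g2|8,Drer|g2|-)),Bflo|o|-);")
  ev1 <- date_duplications(detect_duplications(tr1, ref), tr1, ref, "toy1")
  expect_error(schematic_topology(tr1, ev1, ref, family = "toy1"),
               class = "paralogon_exclusion")

  # same-chromosome paralogs under one node merge to a single leaf, and a
  # younger (human-lineage) duplication folds into a compound slot
  tr2 <- ape::read.tree(text = paste0(
    "(((((Hsap|g1|1,Hsap|g1b|6),Drer|g1|-),((Hsap|g2|8,Hsap|g2b|8),",
    "Drer|g2|-)),(Hsap|g3|20,Drer|g3|-)),Bflo|o|-);"))
  ev2 <- date_duplications(detect_duplications(tr2, ref), tr2, ref, "toy2")
  s2 <- schematic_topology(tr2, ev2, ref, family = "toy2")
  expect_equal(canonical_form(s2), "((1/6,8),20)")
})

test_that("a clean 2R simulation gives the symmetric four-slot schematic", {
  ref <- ref_fixture()
  spec <- scenario_spec("two_round_WGD", n_families = 2, loss_prob = 0,
                        transloc_prob = 0, seed = 9)
  truth <- simulate_family_trees(spec, ref)
  for (fam in names(truth$families)) {
    fm <- truth$families[[fam]]
    ev <- date_duplications(detect_duplications(fm$tree, ref), fm$tree,
                            ref, family = fam)
    s <- schematic_topology(fm$tree, ev, ref, family = fam)
    expect_equal(schematic_symmetry(s), "symmetric")
    expect_equal(canonical_form(s), "((1,8),(2,20))")
  }
})

test_that("translocation distance counts relabelled leaves exactly", {
  expect_equal(translocation_distance("((20,1),8);", "((20,1),8);"), 0L)
  expect_equal(translocation_distance("((20,1),8);", "((2,13),X);"), 3L)
  expect_identical(translocation_distance("((1,2),3);", "((1,2),(3,4));"),
                   Inf)
  # compound slots match on intersection; wildcards match anything
  expect_equal(translocation_distance("((1/6,8),20);", "((6,8),20);"), 0L)
  expect_equal(translocation_distance("((*,8),20);", "((13,8),20);"), 0L)
  # padding mode tolerates the size mismatch at one per surplus leaf
  expect_equal(translocation_distance("((1,2),3);", "((1,2),(3,4));",
                                      pad = TRUE), 1L)
})

test_that("distance is a reflexive, symmetric match for the brute force", {
  set.seed(77)
  for (i in 1:60) {
    sid <- sample(1:5, 1)
    na <- random_schematic_newick(sid)
    nb <- random_schematic_newick(sid)
    a <- as_schematic(na); b <- as_schematic(nb)
    expect_equal(translocation_distance(a, a), 0L)
    d1 <- translocation_distance(a, b)
    expect_equal(d1, translocation_distance(b, a))
    expect_equal(as.numeric(d1), oracle_translocation(na, nb))
  }
  # different shapes disagree at any labelling
  expect_identical(
    translocation_distance("(((1,2),3),4);", "((1,2),(3,4));"), Inf)
})

test_that("congruence respects the allowance", {
  a <- "((20,1),8);"; b <- "((2,13),X);"
  expect_true(congruent(a, b, k = 3))
  expect_false(congruent(a, b, k = 2))
  expect_true(congruent(a, a, k = 0))
})

test_that("grouping forms connected components, invariant to input order", {
  mk <- function(nwk, fam) as_schematic(nwk, family = fam)
  same <- lapply(1:4, function(i) mk("((1,2),3);", paste0("f", i)))
  g1 <- co_duplication_groups(same, k = 0)
  expect_length(g1$groups, 1)

  distinct <- list(mk("((1,2),3);", "a"), mk("((4,5),6);", "b"),
                   mk("((7,8),9);", "c"))
  g0 <- co_duplication_groups(distinct, k = 0)
  expect_length(g0$groups, 3)

  mixed <- list(mk("((1,2),3);", "a"), mk("((1,2),4);", "b"),
                mk("((1,2),(3,4));", "c"))
  gm <- co_duplication_groups(mixed, k = 1)
  expect_equal(gm$groups, list(c("a", "b"), "c"))
  gm2 <- co_duplication_groups(rev(mixed), k = 1)
  expect_equal(gm2$groups, gm$groups)
  expect_equal(gm$symmetry, c("asymmetric", "symmetric"))
})

test_that("2R versus independent simulations separate in group structure", {
  ref <- ref_fixture()
  # all families duplicated twice simultaneously -> one co-duplicated group
  spec <- scenario_spec("two_round_WGD", n_families = 5, loss_prob = 0,
                        transloc_prob = 0.05, seed = 21)
  truth <- simulate_family_trees(spec, ref)
  schems <- lapply(names(truth$families), function(fam) {
    fm <- truth$families[[fam]]
    ev <- date_duplications(detect_duplications(fm$tree, ref), fm$tree,
                            ref, family = fam)
    schematic_topology(fm$tree, ev, ref, family = fam)
  })
  expect_length(co_duplication_groups(schems, k = 3)$groups, 1)
})
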