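test_that("species overlap separates duplications from speciations", {
  ref <- ref_fixture()
  dup <- ape::read.tree(text = "((Hsap|a|1,Mmus|a|-),(Hsap|b|2,Mmus|b|-));")
  ev <- detect_duplications(dup, ref)
  expect_equal(ev$node, ape::Ntip(dup) + 1L)
  expect_equal(ev$left_species[[1]], c("Hsap", "Mmus"))

  spec_only <- ape::read.tree(text = "((Hsap|a|1,Mmus|a|-),Ggal|a|-);")
  expect_equal(nrow(detect_duplications(spec_only, ref)), 0)

  partial <- ape::read.tree(text = "((Hsap|a|1,Dmel|a|-),(Hsap|b|2,Mmus|b|-));")
  ev3 <- detect_duplications(partial, ref)
  expect_equal(ev3$node, ape::Ntip(partial) + 1L)
  expect_equal(intersect(ev3$left_species[[1]], ev3$right_species[[1]]),
               "Hsap")

  expect_error(detect_duplications(ape::unroot(
    ape::read.tree(text = "((a|x|-,b|x|-),(c|x|-,d|x|-),e|x|-);")), ref),
    "rooted")
})

test_that("events date to the bins their species spans dictate", {
  ref <- ref_fixture()
  # vertebrate-stem duplication, amphioxus sister above: B2, interval
  # straddles the invertebrate-vertebrate boundary so it is ambiguous
  tr <- ape::read.tree(text = paste0(
    "(((Hsap|a|1,(Ggal|a|-,Drer|a|-)),(Hsap|b|2,Drer|b|-)),Bflo|o|-);"))
  ev <- date_duplications(detect_duplications(tr, ref), tr, ref, "fam")
  expect_equal(ev$bin, "B2")
  expect_equal(ev$younger_bound, "teleost_tetrapod_split")
  expect_equal(ev$older_bound, "cephalochordate_split")
  expect_true(ev$ambiguous)

  # teleost-lineage duplication
  tr2 <- ape::read.tree(text =
    "((Drer|a|-,(Trub|b|-,Tnig|b|-,Drer|b|-)),Hsap|o|1);")
  ev2 <- date_duplications(detect_duplications(tr2, ref), tr2, ref)
  expect_equal(ev2$bin, "B3")

  # pre-bilaterian duplication, refined by the split it predates
  tr3 <- ape::read.tree(text =
    "((Hsap|a|1,Dmel|a|-),(Hsap|b|2,Nvec|b|-));")
  ev3 <- date_duplications(detect_duplications(tr3, ref), tr3, ref)
  expect_equal(ev3$bin, "B1")
  expect_equal(ev3$refined_split, "bilaterian_nonbilaterian_split")
  expect_true(is.na(ev3$older_bound))  # root event: unbounded above
})

test_that("a tree with every species once yields zero duplications", {
  ref <- ref_fixture()
  set.seed(12)
  for (i in 1:10) {
    sp <- sample(ref$tree$tip.label, 6)
    tr <- ape::rtree(6, rooted = TRUE,
                     tip.label = paste0(sp, "|g|-"))
    expect_equal(nrow(detect_duplications(tr, ref)), 0)
  }
})

test_that("support filtering keeps strong events and flags unsupported ones", {
  ev <- data.frame(node = 1:3, support = c(95, 40, NA), family = "f",
                   bin = "B2")
  kept <- filter_by_support(ev, 50)
  expect_equal(kept$node, c(1L, 3L))
  expect_equal(kept$support_flag, c("", "unsupported"))
  expect_equal(nrow(filter_by_support(ev, 0)), 3)
  expect_warning(filter_by_support(ev[1:2, ], 99), "no duplication events")
})

test_that("epoch histograms tally events and conserve totals", {
  ev <- data.frame(family = c("a", "a", "a", "b"),
                   bin = c("B1", "B2", "B2", "B3"), support = NA)
  h <- epoch_histogram(ev)
  expect_equal(unname(h["a", c("B1", "B2")]), c(1L, 2L))
  expect_equal(unname(h["total", ]), c(1L, 2L, 1L, 0L, 0L))
  expect_equal(sum(h["total", ]), nrow(ev))
  expect_equal(rownames(h), c("a", "b", "total"))

  empty <- epoch_histogram(data.frame(family = character(0),
                                      bin = character(0)))
  expect_equal(sum(empty), 0)
  expect_error(epoch_histogram(data.frame(family = "a", bin = NA)),
               "undated")
})

test_that("dating the simulator's true trees reproduces its ground truth", {
  ref <- ref_fixture()
  # loss-free scenario: every event node survives, so species overlap on the
  # true tree must recover counts and bins exactly
  spec <- scenario_spec("mixed", n_families = 10, loss_prob = 0, seed = 55)
  truth <- simulate_family_trees(spec, ref)
  for (fam in names(truth$families)) {
    fm <- truth$families[[fam]]
    ev <- date_duplications(detect_duplications(fm$tree, ref), fm$tree,
                            ref, family = fam)
    expect_equal(sort(ev$bin), sort(fm$true_bins), label = fam)
  }
})
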