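test_that("scenario specs validate their parameters", {
  expect_error(scenario_spec("two_round_WGD", n_families = 2), "seed")
  expect_error(scenario_spec("two_round_WGD", n_families = 2,
                             loss_prob = 1.5, seed = 1))
  bad <- scenario_spec("independent_SD", n_families = 1, seed = 1,
                       placements = list(c("no_such_split", "also_bad")))
  expect_error(simulate_family_trees(bad, ref_fixture()),
               "invalid placement")
})

test_that("simulation is reproducible from the seed alone", {
  ref <- ref_fixture()
  spec <- scenario_spec("mixed", n_families = 4, seq_length = 50, seed = 3)
  t1 <- simulate_family_trees(spec, ref)
  t2 <- simulate_family_trees(spec, ref)
  expect_identical(lapply(t1$families, function(f) ape::write.tree(f$tree)),
                   lapply(t2$families, function(f) ape::write.tree(f$tree)))
  a1 <- evolve_sequences(t1)
  a2 <- evolve_sequences(t2)
  expect_identical(lapply(a1, unclass), lapply(a2, unclass))
})

test_that("two-round histories are nested on the stem; independent draws vary", {
  ref <- ref_fixture()
  spec <- scenario_spec("two_round_WGD", n_families = 3, loss_prob = 0,
                        transloc_prob = 0, seed = 5)
  truth <- simulate_family_trees(spec, ref)
  expect_equal(unname(truth$partition), rep(1L, 3))
  for (fm in truth$families) {
    expect_equal(sort(fm$true_bins), c("B2", "B2", "B2"))
    expect_setequal(unname(fm$human_chroms), c("1", "2", "8", "20"))
  }

  # placements pin the true bins by construction
  spec2 <- scenario_spec("independent_SD", n_families = 2, n_events = 1,
                         loss_prob = 0, seed = 8,
    placements = simulation_placements()[c("pre_bilaterian",
                                           "teleost_stem")])
  truth2 <- simulate_family_trees(spec2, ref)
  expect_equal(length(unique(truth2$partition)), 2)
  for (fm in truth2$families)
    expect_true(all(fm$true_bins %in% c("B1", "B3")))
})

test_that("sequence evolution respects rate zero and emits valid alignments", {
  ref <- ref_fixture()
  spec <- scenario_spec("two_round_WGD", n_families = 1, seq_length = 40,
                        rate = 0, seed = 13)
  truth <- simulate_family_trees(spec, ref)
  alns <- evolve_sequences(truth)
  m <- unclass(alns[[1]])
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1)))
  expect_equal(ncol(m), 40)
  # gap-free by construction: trimming is a no-op
  expect_identical(unclass(trim_complete_deletion(alns[[1]])), m)
})
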