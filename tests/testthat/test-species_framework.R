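test_that("packaged reference holds 46 taxa in the published clade counts", {
  ref <- ref_fixture()
  expect_equal(nrow(ref$taxa), 46)
  expect_length(ref$clades$tetrapod, 25)
  expect_length(ref$clades$teleost, 5)
  expect_length(ref$clades$invertebrate, 16)
  expect_setequal(ref$clades$vertebrate,
                  c(ref$clades$tetrapod, ref$clades$teleost))
})

test_that("toy taxonomies load, and tag/topology contradictions are caught", {
  tf_tax <- withr::local_tempfile(fileext = ".tsv")
  tf_nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("species_id\tbinomial\tcommon_name\tclade_tags",
               "Hsap\tHomo sapiens\tHuman\ttetrapod;vertebrate",
               "Drer\tDanio rerio\tZebrafish\tteleost;vertebrate",
               "Dmel\tDrosophila melanogaster\tFly\tinvertebrate"), tf_tax)
  writeLines(paste0("(Dmel:3,(Drer:2,Hsap:2)teleost_tetrapod_split:1)",
                    "invertebrate_vertebrate_split;"), tf_nwk)
  ref <- load_reference_taxonomy(tf_tax, tf_nwk)
  expect_equal(unname(lca_node(ref, c("Hsap", "Dmel"))),
               unname(ref$splits[["invertebrate_vertebrate_split"]]))

  # human mis-tagged as teleost: the teleost clade is no longer monophyletic
  writeLines(c("species_id\tbinomial\tcommon_name\tclade_tags",
               "Hsap\tHomo sapiens\tHuman\tteleost;vertebrate",
               "Drer\tDanio rerio\tZebrafish\tteleost;vertebrate",
               "Ggal\tGallus gallus\tChicken\ttetrapod;vertebrate",
               "Dmel\tDrosophila melanogaster\tFly\tinvertebrate"), tf_tax)
  writeLines(paste0("(Dmel:3,(Drer:2,(Ggal:1,Hsap:1):1)",
                    "teleost_tetrapod_split:1)invertebrate_vertebrate_split;"),
             tf_nwk)
  expect_error(load_reference_taxonomy(tf_tax, tf_nwk), "monophyletic|contradicts")

  # a leaf absent from the taxonomy
  writeLines(c("species_id\tbinomial\tcommon_name\tclade_tags",
               "Hsap\tHomo sapiens\tHuman\ttetrapod;vertebrate"), tf_tax)
  expect_error(load_reference_taxonomy(tf_tax, tf_nwk), "missing")
})

test_that("lca_node resolves known ancestors and rejects bad input", {
  ref <- ref_fixture()
  expect_equal(unname(lca_node(ref, "Hsap")),
               match("Hsap", ref$tree$tip.label))
  expect_equal(names(lca_node(ref, c("Hsap", "Mmus", "Drer"))),
               "teleost_tetrapod_split")
  expect_equal(names(lca_node(ref, c("Hsap", "Dmel"))),
               "protostome_deuterostome_split")
  expect_error(lca_node(ref, character(0)), "empty")
  expect_error(lca_node(ref, "Xxxx"), "not in reference")

  # idempotent under adding descendants of the current LCA
  base <- lca_node(ref, c("Hsap", "Drer"))
  expect_equal(unname(lca_node(ref, c("Hsap", "Drer", "Mmus", "Olat"))),
               unname(base))
})

test_that("every species-tree node falls in exactly one epoch bin", {
  ref <- ref_fixture()
  nn <- ape::Ntip(ref$tree) + ref$tree$Nnode
  bins <- vapply(seq_len(nn), function(nd) epoch_bin(ref, nd)$bin,
                 character(1))
  expect_true(all(bins %in% c("B1", "B2", "B3", "B4", "other")))
  # anchor the scale
  expect_equal(epoch_bin(ref, ref$splits[["teleost_tetrapod_split"]])$bin, "B2")
  expect_equal(epoch_bin(ref, ref$splits[["invertebrate_vertebrate_split"]])$bin,
               "B1")
  expect_equal(epoch_bin(ref, ref$splits[["teleost_crown"]])$bin, "B3")
  expect_equal(epoch_bin(ref, ref$splits[["amphibian_split"]])$bin, "B4")
  expect_equal(epoch_bin(ref, unname(lca_node(ref, c("Dmel", "Amel"))))$bin,
               "other")
  # B1 refinement names the split the duplication predates
  eb <- epoch_bin(ref, unname(lca_node(ref, c("Hsap", "Nvec"))))
  expect_equal(eb$bin, "B1")
  expect_equal(eb$refined, "bilaterian_nonbilaterian_split")
})
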