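test_that("the canonical network loads with the expected structure", {
  net <- fx_net()
  expect_s3_class(net, "metabolic_network")
  expect_identical(nrow(net$species), 98L)
  expect_identical(length(net$reactions), 87L)
  expect_identical(dim(net$S), c(98L, 87L))
  # compartments and partition coefficients
  expect_setequal(net$compartments$id,
                  c("extracellular", "cytosol", "mitochondrion"))
  expect_equal(sort(net$compartments$volume_fraction), c(0.05, 0.20, 0.75))
  expect_equal(sum(net$compartments$volume_fraction), 1.0)
  # no orphan species
  expect_true(all(rowSums(net$S != 0) >= 1))
})

test_that("carbon is conserved by every non-boundary reaction", {
  net <- fx_net()
  carbon <- setNames(net$species$carbon, net$species$id)
  boundary <- vapply(net$reactions, `[[`, TRUE, "boundary")
  bal <- drop(crossprod(net$S, carbon))
  expect_true(all(abs(bal[!boundary]) < 1e-9))
  # the CO2 exchange removes carbon, so boundary columns are exempt
  expect_lt(bal[match("EX_CO2", net$reaction_ids)], 0)
})

test_that("pathway membership matches the canonical composition", {
  net <- fx_net()
  expect_setequal(pathway_members(net, "tca"),
                  c("CS", "ACO", "IDH", "AKGDH", "SCS", "SDH", "FUM", "MDH"))
  expect_length(pathway_members(net, "exchange"), 6L)
  expect_setequal(pathway_members(net, "exchange"), exchange_reactions(net))
  all_tagged <- unlist(lapply(pathway_tags(), pathway_members, net = net))
  expect_setequal(all_tagged, net$reaction_ids)
  expect_identical(anyDuplicated(all_tagged), 0L)
  expect_error(pathway_members(net, "nonsense"), "unknown pathway tag")
  # beta-oxidation spiral: 7 rounds x 4 enzymatic steps
  bo <- pathway_members(net, "beta_oxidation")
  expect_length(bo, 28L)
  expect_setequal(bo, c(sprintf("ACAD%d", 1:7), sprintf("ECH%d", 1:7),
                        sprintf("HACD%d", 1:7), sprintf("KAT%d", 1:7)))
})

test_that("a toy two-species file gives the identity stoichiometric matrix", {
  net <- toy_ab()
  expect_identical(unname(stoichiometric_matrix(net)),
                   matrix(c(-1, 1), 2, 1))
})

test_that("schema violations are rejected with informative errors", {
  # missing species reference
  path <- toy_network_file(
    list(toy_sp("a")),
    list(toy_rx("AX", list(a = -1, xyz_m = 1))))
  expect_error(load_network(path), "undeclared species")
  # carbon imbalance in a non-boundary reaction
  path2 <- toy_network_file(
    list(toy_sp("a", carbon = 2), toy_sp("b", carbon = 1)),
    list(toy_rx("AB", list(a = -1, b = 1))))
  expect_error(load_network(path2), "carbon imbalance.*AB")
  # suffix inconsistent with compartment
  path3 <- toy_network_file(
    list(toy_sp("a_m", comp = "cytosol"), toy_sp("b")),
    list(toy_rx("AB", list(a_m = -1, b = 1))))
  expect_error(load_network(path3), "suffix")
})

test_that("serialization round-trips the canonical network exactly", {
  net <- fx_net()
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  net2 <- load_network(path)
  expect_identical(net2$species$id, net$species$id)
  expect_identical(net2$reaction_ids, net$reaction_ids)
  expect_equal(net2$S, net$S)
  expect_equal(net2$species$conc, net$species$conc)
  expect_equal(vapply(net2$reactions, `[[`, 0, "dg0"),
               vapply(net$reactions, `[[`, 0, "dg0"))
})

test_that("genotype reaction sets partition sensibly", {
  net <- fx_net()
  m <- mito_reactions(net)
  expect_true(all(c("CS", "C1", "ATPS", "ACAD1", "CPT1", "PDH") %in% m))
  expect_false(any(c("HK", "PK", "LDH", "CK") %in% m))
  expect_setequal(fa_transport_reactions(net),
                  c("FAT", "FACS", "CPT1", "PCT", "CPT2"))
  expect_length(fao_reactions(net), 33L)  # 5 transport + 28 spiral
})
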