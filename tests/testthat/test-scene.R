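test_that("density classes follow the low/high molecule-density regimes", {
  expect_equal(molecule_density(5, 1)$class, "low")
  expect_equal(molecule_density(12, 1)$class, "high")
  expect_equal(molecule_density(2, 1)$class, "out_of_range")
  expect_equal(molecule_density(10, 1)$density_um2, 10)
  sc <- place_molecules(10, 1000, seed = 1)
  expect_equal(sc$density_um2, 10)
  expect_equal(sc$density_class, "high")
  expect_error(place_molecules(5, 1000, density_class = "high", seed = 1),
               "outside")
  expect_error(place_molecules(12, 1000, density_class = "low", seed = 1),
               "outside")
})

test_that("bridging probabilities are validated", {
  expect_error(bridging_config(p_intra = -0.1))
  expect_error(bridging_config(p_inter = 1.5))
})

test_that("a no-bridging scene with a quiet seed has zero junctions", {
  sc <- place_molecules(4, 1000, seed = 2,
                        bridging = bridging_config(0, 0, 0))
  expect_equal(nrow(sc$junctions), 0)
})

test_that("forced bridging of two chains yields one inter junction", {
  sc <- place_molecules(2, 1000, seed = 4,
                        bridging = bridging_config(0, 1, 1))
  inter <- sc$junctions[sc$junctions$type == "inter", ]
  expect_equal(nrow(inter), 1)
  expect_setequal(c(inter$mol1, inter$mol2), c(1, 2))
  expect_true(all(inter$protein_bound))
})

test_that("ground-truth junctions satisfy their structural invariants", {
  for (seed in 1:4) {
    sc <- place_molecules(10, 1000, seed = seed)
    j <- sc$junctions
    if (nrow(j) == 0) next
    expect_true(all(j$x >= 0 & j$x <= 1000 & j$y >= 0 & j$y <= 1000))
    expect_true(all(j$mol1[j$type == "intra"] == j$mol2[j$type == "intra"]))
    expect_true(all(j$mol1[j$type == "inter"] != j$mol2[j$type == "inter"]))
  }
})

test_that("truth junction counts match an independent brute-force oracle", {
  for (seed in c(1, 3, 5)) {
    sc <- place_molecules(6, 800, seed = seed,
                          bridging = bridging_config(0.3, 0.2, 0.5))
    expect_equal(nrow(sc$junctions),
                 oracle_crossings(sc$chains, 800, sc$capture_radius))
  }
})

test_that("scene assembly is deterministic under a seed", {
  a <- place_molecules(8, 1000, seed = 9)
  b <- place_molecules(8, 1000, seed = 9)
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$chains[[5]]$vertices, b$chains[[5]]$vertices)
})
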