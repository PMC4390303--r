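test_that("bundled photon lines carry the expected energies and yields", {
  iodine <- load_nuclide("I-131")
  main <- iodine$photons[abs(iodine$photons$energy - 364.5) < 0.5, ]
  expect_equal(nrow(main), 1)
  expect_equal(main$yield, 0.812, tolerance = 1e-6)

  lutetium <- load_nuclide("Lu-177")
  l1 <- lutetium$photons[abs(lutetium$photons$energy - 112.9) < 0.5, ]
  l2 <- lutetium$photons[abs(lutetium$photons$energy - 208.4) < 0.5, ]
  expect_equal(l1$yield, 0.062, tolerance = 1e-6)
  expect_equal(l2$yield, 0.104, tolerance = 1e-6)
})

test_that("beta spectra reproduce the nominal mean and maximum energies", {
  cases <- list(list("I-131", 181.4, 606.3), list("Lu-177", 134.2, 498))
  for (cs in cases) {
    nuc <- load_nuclide(cs[[1]])
    expect_lt(abs(mean_beta_energy(nuc) / cs[[2]] - 1), 0.02)
    expect_lt(abs(max_beta_energy(nuc) / cs[[3]] - 1), 0.01)
  }
})

test_that("beta bin yields are non-negative and sum to at most one branch", {
  for (nm in c("I-131", "Lu-177")) {
    nuc <- load_nuclide(nm)
    b <- nuc$electrons[nuc$electrons$kind == "beta_spectrum_bin", ]
    expect_true(all(b$yield >= 0))
    expect_lte(sum(b$yield), 1 + 0.01)
    expect_gt(sum(b$yield), 0.95)
  }
})

test_that("electron inventories exceed the beta-only mean by the CE/Auger share", {
  # conversion and Auger electrons are part of the channel, so the
  # per-decay electron energy must sit strictly above the beta mean
  iodine <- load_nuclide("I-131")
  lutetium <- load_nuclide("Lu-177")
  e_i <- emitted_energy_per_decay(iodine, "electrons")
  e_lu <- emitted_energy_per_decay(lutetium, "electrons")
  expect_gt(e_i, 181.4); expect_lt(e_i, 210)
  expect_gt(e_lu, 134.2); expect_lt(e_lu, 160)
})

test_that("decay constants follow ln(2)/half-life", {
  expect_equal(decay_constant(load_nuclide("I-131")),
               log(2) / (8.023 * 86400), tolerance = 1e-12)
  expect_equal(decay_constant(load_nuclide("I-131")), 9.999e-7,
               tolerance = 1e-4)
  expect_equal(decay_constant(load_nuclide("Lu-177")), 1.207e-6,
               tolerance = 1e-4)
  expect_equal(decay_constant(make_nuclide(half_life_s = log(2))), 1)
})

test_that("emitted energy per decay is the yield-weighted sum", {
  iodine <- load_nuclide("I-131")
  expect_gte(emitted_energy_per_decay(iodine, "photons"), 364.5 * 0.812)
  lutetium <- load_nuclide("Lu-177")
  b <- lutetium$electrons[lutetium$electrons$kind == "beta_spectrum_bin", ]
  expect_equal(sum(b$energy * b$yield), 134.2, tolerance = 0.02 * 134.2)
  expect_identical(emitted_energy_per_decay(make_nuclide(), "photons"), 0)
})

test_that("loading errors are explicit", {
  expect_error(load_nuclide("Tc-99m"), "available.*I-131")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("# half_life_days: 1.0",
               "kind\tenergy_keV\tyield_per_decay",
               "photon\toops\t0.5"), bad)
  expect_error(load_nuclide("x", path = bad), "malformed")
  nohl <- tempfile(fileext = ".tsv")
  writeLines(c("kind\tenergy_keV\tyield_per_decay", "photon\t100\t0.5"), nohl)
  expect_error(load_nuclide("x", path = nohl), "half_life")
})
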