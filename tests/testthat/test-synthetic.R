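test_that("backbone templates span coiled to extended and honour targets", {
  ext <- make_backbone(20, "extended", target_end_to_end = 26)
  expect_equal(end_to_end(ext), 26, tolerance = 1e-9)
  expect_lt(end_to_end(make_backbone(20, "coiled_C")),
            end_to_end(make_backbone(20, "semi_open")))
  expect_lt(end_to_end(make_backbone(20, "semi_open")),
            end_to_end(make_backbone(20, "extended")))
  expect_error(make_backbone(10, "extended", target_end_to_end = 26),
               "unreachable")
  # determinism: same seed, same noise
  a <- make_backbone(20, "coiled_C", noise_sigma = 0.4, seed = 99)
  b <- make_backbone(20, "coiled_C", noise_sigma = 0.4, seed = 99)
  expect_identical(as.matrix(a), as.matrix(b))
  expect_false(identical(
    as.matrix(make_backbone(20, "coiled_C", noise_sigma = 0.4, seed = 1)),
    as.matrix(a)
  ))
})

test_that("conformation sets carry planted family labels", {
  cs <- make_conformation_set(
    tibble::tibble(shape = c("coiled_C", "extended"), count = c(100, 100),
                   noise_sigma = 0.3),
    seed = 1
  )
  expect_equal(nrow(cs), 200)
  expect_equal(unname(table(cs$family))[order(unique(cs$family))],
               c(100, 100), ignore_attr = TRUE)
  cs2 <- make_conformation_set(
    tibble::tibble(shape = c("coiled_C", "extended"), count = c(100, 100),
                   noise_sigma = 0.3),
    seed = 1
  )
  expect_identical(cs$coords, cs2$coords)
})

test_that("solvated-frame generator respects counts, box and density limits", {
  solute <- make_backbone(10, "extended")
  fr <- make_solvated_frame(solute, 20, 300, box = c(40, 40, 40), seed = 5)
  expect_equal(sum(fr$solvent$species == "THF"), 20)
  expect_equal(sum(fr$solvent$species == "water"), 300)
  expect_true(all(fr$solvent$x >= 0 & fr$solvent$x <= 40))
  all_w <- make_solvated_frame(solute, 0, 50, box = c(40, 40, 40), seed = 5)
  expect_true(all(all_w$solvent$species == "water"))
  expect_error(
    make_solvated_frame(solute, 1e5, 1e6, box = c(30, 30, 30)),
    "overfilled"
  )
  fr2 <- make_solvated_frame(solute, 20, 300, box = c(40, 40, 40), seed = 5)
  expect_identical(fr$solvent, fr2$solvent)
})

test_that("metropolis windows match the harmonic-oracle width", {
  kt <- 0.0083144621 * 300
  s <- sample_umbrella("flat", 0.5, force_constant = 1e6,
                       n_per_window = 4000, seed = 8)
  expect_equal(sd(s$cv), sqrt(kt / 1e6), tolerance = 0.1)
  acc <- attr(s, "acceptance")$acceptance
  expect_true(all(acc > 0.15 & acc < 0.7))
  # symmetric double well: the window at the barrier top stays centred there
  s2 <- sample_umbrella("doublewell", 0.5, force_constant = 200,
                        n_per_window = 5000, seed = 9, dg = 5)
  expect_equal(mean(s2$cv), 0.5, tolerance = 0.03)
  s3 <- sample_umbrella("doublewell", 0.5, force_constant = 200,
                        n_per_window = 5000, seed = 9, dg = 5)
  expect_identical(s2$cv, s3$cv)
})

test_that("the double-well potential plants its barrier exactly", {
  expect_equal(doublewell_potential(0), 0)
  expect_equal(doublewell_potential(1), 0)
  expect_equal(doublewell_potential(0.5, dg = 5), 5)
  expect_equal(doublewell_potential(1.5, dg = 5, a = 1, L = 1), 5)
})

test_that("energy tables plant exact totals", {
  tab <- make_energy_table(-5, -12, tibble::tibble(n_peptoid = 3, m_units = 7))
  expect_equal(tab$records$e_total, 3 * -5 + 7 * -12)
  expect_equal(tab$reference$e_per_unit, -12)
})

test_that("agglomerates scale their compactness with the spacing factor", {
  tight <- make_agglomerate(6, 12, "stack", scale = 0.7)
  loose <- make_agglomerate(6, 12, "stack", scale = 1.3)
  expect_lt(radius_of_gyration(tight), radius_of_gyration(loose))
  sheet <- make_agglomerate(4, 12, "sheet")
  expect_equal(nrow(sheet), 48)
  expect_equal(attr(sheet, "n_chains"), 4)
})
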