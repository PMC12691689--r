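test_that("donor saturation follows the ATP Michaelis factor", {
  expect_equal(donor_saturation(82, 82), 0.5)
  expect_equal(donor_saturation(0, 82), 0)
  expect_equal(donor_saturation(5000, 82), 5000 / 5082, tolerance = 1e-12)
  # strictly increasing and bounded in [0, 1)
  s <- donor_saturation(c(0, 1, 10, 100, 1e4, 1e6), 82)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s < 1))
  expect_error(donor_saturation(100, 0), class = "alarmkin_invalid_parameter")
  expect_error(donor_saturation(-1, 82), class = "alarmkin_invalid_parameter")
})

test_that("competition denominator sums relative occupancies over acceptors present", {
  p <- fixture_params()
  expect_equal(competition_denominator(c(ATP = 0), p), 1)
  expect_equal(competition_denominator(c(ATP = 5000), p), 4.571429,
               tolerance = 1e-6)
  expect_equal(
    competition_denominator(c(ATP = 5000, GMP = 500), two_acceptor_params()),
    14.571429, tolerance = 1e-6
  )
  err <- expect_error(competition_denominator(c(ATP = 5000, GMP = 500), p),
                      class = "alarmkin_missing_parameter")
  expect_match(conditionMessage(err), "GMP")
})

test_that("competitive velocity matches hand arithmetic and its limits", {
  p <- fixture_params()
  expect_equal(competition_velocity("ATP", c(ATP = 5000), p), 87.625443,
               tolerance = 1e-6)
  expect_equal(competition_velocity("GMP", c(ATP = 5000, GMP = 0),
                                    two_acceptor_params()), 0)
  # a competitor at overwhelming concentration abolishes the velocity
  v_alone <- competition_velocity("ATP", c(ATP = 5000), two_acceptor_params())
  v_swamped <- competition_velocity(
    "ATP", c(ATP = 5000, GMP = 1e12), two_acceptor_params()
  )
  expect_lt(v_swamped, 1e-6 * v_alone)
})

test_that("with a single acceptor the model reduces to the double Michaelis product", {
  withr::with_seed(11, {
    for (i in 1:50) {
      km_d <- 10^runif(1, 0, 3)
      km_a <- 10^runif(1, 1, 4)
      vmax <- runif(1, 1, 200)
      s <- 10^runif(1, 0, 4)
      p <- kinetic_params(km_d, tibble::tibble(
        species = "ATP", km_uM = km_a, vmax_uM_min = vmax
      ))
      # ATP alone occupies both sites: v = Vmax * MM(acceptor) * MM(donor)
      v <- competition_velocity("ATP", c(ATP = s), p)
      expected <- vmax * s / (km_a + s) * s / (km_d + s)
      expect_equal(v, expected, tolerance = 1e-9)
    }
  })
})

test_that("velocity is monotone in own, donor, and competitor concentrations", {
  p <- two_acceptor_params()
  own <- sapply(c(10, 100, 1000, 5000), function(s)
    competition_velocity("GMP", c(ATP = 1000, GMP = s), p))
  expect_true(all(diff(own) > 0))
  donor <- sapply(c(10, 100, 1000, 5000), function(a)
    competition_velocity("GMP", c(ATP = a, GMP = 100), p))
  # raising ATP raises donor saturation but also competes at the acceptor
  # site; the model only guarantees monotone decrease in a non-ATP competitor
  comp <- sapply(c(0, 100, 1000, 10000), function(g)
    competition_velocity("ATP", c(ATP = 5000, GMP = g), p))
  expect_true(all(diff(comp) < 0))
})

test_that("forward occupancies match their closed forms and sum to one", {
  p2 <- two_acceptor_params()
  occ <- occupancy_forward(c(ATP = 5000), fixture_params())
  expect_equal(occ$theta[occ$species == "ATP"], 0.78125, tolerance = 1e-9)
  expect_equal(occ$theta[occ$species == "apo"], 0.21875, tolerance = 1e-9)

  occ2 <- occupancy_forward(c(ATP = 5000, GMP = 500), p2)
  expect_equal(occ2$theta[occ2$species == "apo"], 0.0686275, tolerance = 1e-5)
  expect_equal(occ2$theta[occ2$species == "ATP"], 0.2450980, tolerance = 1e-5)
  expect_equal(occ2$theta[occ2$species == "GMP"], 0.6862745, tolerance = 1e-5)

  empty <- occupancy_forward(c(ATP = 0), fixture_params())
  expect_equal(empty$theta[empty$species == "apo"], 1)

  withr::with_seed(7, {
    for (i in 1:100) {
      case <- random_two_acceptor_case()
      occ <- occupancy_forward(case$condition, case$params)
      expect_equal(sum(occ$theta), 1, tolerance = 1e-12)
      expect_true(all(occ$theta >= 0 & occ$theta <= 1))
    }
  })
})

test_that("the species vocabulary is closed and maps acceptors to products", {
  tab <- nucleotide_species()
  expect_equal(sum(tab$can_donate), 1L)
  expect_equal(tab$species[tab$can_donate], "ATP")
  expect_equal(product_of(c("ATP", "GMP")), c("pppApp", "pGpp"))
  expect_equal(species_of_product("ppGpp"), "GDP")
  expect_error(product_of("CTP"), class = "alarmkin_invalid_parameter")
  expect_error(as_concentrations(c(XTP = 5)), class = "alarmkin_invalid_parameter")
  expect_error(as_concentrations(c(ATP = -1)), class = "alarmkin_invalid_parameter")
})

test_that("kinetic parameter sets are validated on construction", {
  expect_error(kinetic_params(0, tibble::tibble(
    species = "ATP", km_uM = 1400, vmax_uM_min = 114
  )), class = "alarmkin_invalid_parameter")
  expect_error(kinetic_params(82, tibble::tibble(
    species = "ATP", km_uM = -1, vmax_uM_min = 114
  )), class = "alarmkin_invalid_parameter")
  expect_error(kinetic_params(82, tibble::tibble(
    species = c("ATP", "ATP"), km_uM = c(1, 2), vmax_uM_min = c(1, 2)
  )), class = "alarmkin_invalid_parameter")
  p <- paper_params()
  expect_s3_class(p, "kinetic_params")
  expect_equal(p$km_donor_uM, 82)
  expect_equal(p$acceptors$km_uM[p$acceptors$species == "ATP"], 1400)
  expect_equal(p$vmax_pppGpp_uM_min, 110)
  expect_equal(p$enzyme_nM, 0.30)
  expect_true(all(c("ADP", "AMP", "GMP") %in% demo_truth()$acceptors$species))
})
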