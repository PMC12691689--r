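test_that("product-ratio specificity constants follow the cancellation identity", {
  expect_equal(specificity_from_ratio(2, 1, 500, 5000, 114, 1400),
               1.628571, tolerance = 1e-6)
  expect_equal(specificity_from_ratio(0, 1, 500, 5000, 114, 1400), 0)
  # self-ratio returns the ATP specificity constant itself
  expect_equal(specificity_from_ratio(5, 5, 5000, 5000, 114, 1400),
               114 / 1400)
  expect_error(specificity_from_ratio(1, 0, 500, 5000, 114, 1400),
               class = "alarmkin_undefined_ratio")
})

test_that("occupancy deconvolution inverts the forward model exactly", {
  # ATP-only condition: occupancies close at theta_x = 0
  dec <- deconvolve_km(87.625443, c(ATP = 5000), 114, 82, 1400)
  expect_equal(dec$theta_atp, 0.78125, tolerance = 1e-6)
  expect_equal(dec$theta_apo, 0.21875, tolerance = 1e-6)
  expect_equal(dec$theta_x, 0, tolerance = 1e-6)
  expect_true(is.na(dec$km_x_uM))

  # two-acceptor condition generated with known competitor Km
  p <- two_acceptor_params(km_gmp = 50)
  cond <- c(ATP = 5000, GMP = 500)
  v_p <- competition_velocity("ATP", cond, p)
  dec2 <- deconvolve_km(v_p, cond, 114, 82, 1400)
  expect_equal(dec2$theta_apo, 0.0686275, tolerance = 1e-5)
  expect_equal(dec2$theta_atp, 0.2450980, tolerance = 1e-5)
  expect_equal(dec2$theta_x, 0.6862745, tolerance = 1e-5)
  expect_equal(dec2$km_x_uM, 50, tolerance = 1e-9)

  # occupancies agree with the forward profile
  occ <- occupancy_forward(cond, p)
  expect_equal(dec2$theta_atp, occ$theta[occ$species == "ATP"],
               tolerance = 1e-12)
  expect_equal(dec2$theta_x, occ$theta[occ$species == "GMP"],
               tolerance = 1e-12)
})

test_that("deconvolution refuses impossible or inconsistent velocities", {
  # faster than full saturation allows
  expect_error(
    deconvolve_km(114 * donor_saturation(5000, 82) * 1.01,
                  c(ATP = 5000, GMP = 500), 114, 82, 1400),
    class = "alarmkin_deconvolution_error"
  )
  # velocity too high for the competitor load: theta_x <= 0, never clamped
  p <- two_acceptor_params(km_gmp = 50)
  cond <- c(ATP = 5000, GMP = 500)
  v_p <- competition_velocity("ATP", cond, p)
  err <- expect_error(deconvolve_km(v_p * 3.5, cond, 114, 82, 1400),
                      class = "alarmkin_deconvolution_error")
  expect_false(is.null(err$thetas))
  expect_error(deconvolve_km(10, c(ATP = 5000, GMP = 5, ADP = 5),
                             114, 82, 1400),
               class = "alarmkin_design_error")
})

test_that("deconvolution is algebraically exact over random kinetic regimes", {
  withr::with_seed(23, {
    for (i in 1:200) {
      case <- random_two_acceptor_case()
      p <- case$params
      atp_row <- p$acceptors[p$acceptors$species == "ATP", ]
      v_p <- competition_velocity("ATP", case$condition, p)
      dec <- deconvolve_km(v_p, case$condition,
                           atp_row$vmax_uM_min, p$km_donor_uM, atp_row$km_uM)
      expect_equal(dec$km_x_uM, case$km_x, tolerance = 1e-9)
      expect_equal(dec$theta_apo + dec$theta_atp + dec$theta_x, 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("turnover correction rescales sub-saturating rates", {
  kcat <- kcat_from_rate(23, 0.30, 5000, 82, 1400)
  expect_equal(kcat, 99742.7, tolerance = 1e-5)
  expect_equal(kcat_from_rate(0, 0.30, 5000, 82, 1400), 0)
  # at saturating ATP the correction disappears
  expect_equal(kcat_from_rate(30, 1, 1e12, 82, 1400), 30 / (1 / 1000),
               tolerance = 1e-6)
  expect_error(kcat_from_rate(23, 0, 5000, 82, 1400),
               class = "alarmkin_invalid_parameter")
})

test_that("kcat scaling is commensurate with Vmax and monotone", {
  tab <- tibble::tibble(species = c("ATP", "GTP", "GMP"),
                        vmax_uM_min = c(114, 110, 0))
  out <- scale_kcats(1e5, tab)
  expect_equal(out$kcat_min[out$species == "GTP"], 1e5 * 110 / 114)
  expect_equal(out$kcat_min[out$species == "ATP"], 1e5)
  expect_equal(out$kcat_min[out$species == "GMP"], 0)
  expect_equal(order(out$kcat_min), order(tab$vmax_uM_min))
  expect_error(scale_kcats(1e5, tibble::tibble(species = "GTP",
                                               vmax_uM_min = 110)),
               class = "alarmkin_invalid_parameter")
})

test_that("initial velocity from stop-time aliquots stays in the linear regime", {
  # 12 uM/min true rate, 1 mM limiting substrate; the 30 s point qualifies
  expect_equal(velocity_from_progress(c(6, 24, 150), c(0.5, 2, 5), 1000), 12)
  # all aliquots past 10% consumption
  expect_error(velocity_from_progress(c(200, 400), c(2, 5), 1000),
               class = "alarmkin_insufficient_data")
})

test_that("the full stepwise inference recovers a noise-free truth table", {
  truth <- demo_truth()
  v <- simulate_velocities(truth, paper_design(), cv = 0)
  tab <- run_full_inference(v, enzyme_nM = 0.30)

  expect_equal(attr(tab, "km_donor_uM"), 82, tolerance = 1e-6)
  atp <- tab[tab$acceptor == "ATP", ]
  expect_equal(atp$km_uM, 1400, tolerance = 1e-6)
  expect_equal(atp$vmax_uM_min, 114, tolerance = 1e-6)
  expect_equal(tab$vmax_uM_min[tab$acceptor == "GTP"], 110, tolerance = 1e-6)

  for (x in c("ADP", "AMP", "GMP")) {
    truth_row <- truth$acceptors[truth$acceptors$species == x, ]
    row <- tab[tab$acceptor == x, ]
    expect_equal(row$km_uM, truth_row$km_uM, tolerance = 1e-6)
    expect_equal(row$vmax_uM_min, truth_row$vmax_uM_min, tolerance = 1e-6)
    expect_equal(row$vmax_over_km_min, truth_row$vmax_uM_min / truth_row$km_uM,
                 tolerance = 1e-6)
  }
  # kcat columns: kcat/Km == kcat / Km row-wise; scaling follows Vmax
  ok <- !is.na(tab$km_uM)
  expect_equal(tab$kcat_over_km_min_uM[ok], tab$kcat_min[ok] / tab$km_uM[ok])
  expect_equal(tab$kcat_min[tab$acceptor == "ATP"], 114 / (0.30 / 1000))
})

test_that("the pipeline validates its design blocks and isolates failures", {
  truth <- demo_truth()
  v <- simulate_velocities(truth, paper_design(), cv = 0)
  expect_error(run_full_inference(v[v$block != "acceptor", ]),
               class = "alarmkin_design_error")
  expect_error(run_full_inference(v[v$block != "donor", ]),
               class = "alarmkin_design_error")

  # mixing enzyme batches is refused
  vb <- v
  vb$batch <- rep(c("b1", "b2"), length.out = nrow(vb))
  expect_error(run_full_inference(vb), class = "alarmkin_design_error")

  # a corrupted competition is flagged without aborting the others
  vc <- v
  bad <- vc$condition_id == "comp_GMP" & vc$product == "pppApp"
  vc$velocity_uM_min[bad] <- vc$velocity_uM_min[bad] * 5
  tab <- run_full_inference(vc)
  expect_true(!is.na(tab$flag[tab$acceptor == "GMP"]))
  expect_equal(tab$km_uM[tab$acceptor == "ADP"], 250, tolerance = 1e-6)

  # GDP competitions are reported only as a co-elution flag
  vg <- dplyr::bind_rows(v, tibble::tibble(
    block = "competition", condition_id = "comp_GDP",
    conc_ATP_uM = 5000, conc_ADP_uM = 0, conc_AMP_uM = 0, conc_GTP_uM = 0,
    conc_GDP_uM = 5000, conc_GMP_uM = 0,
    product = c("pppApp", "ppGpp"), velocity_uM_min = c(50, 20),
    replicate_id = 1L
  ))
  tabg <- run_full_inference(vg)
  gdp <- tabg[tabg$acceptor == "GDP", ]
  expect_match(gdp$flag, "co-elution")
  expect_true(is.na(gdp$km_uM))
})

test_that("bootstrap resampling yields finite empirical errors", {
  truth <- demo_truth()
  v <- simulate_velocities(truth, paper_design(), cv = 0.05, replicates = 4,
                           seed = 9)
  tab <- run_full_inference(v, n_boot = 20, seed = 10)
  comp <- tab[tab$acceptor %in% c("ADP", "AMP", "GMP"), ]
  expect_true(all(is.finite(comp$km_se_uM)))
  expect_true(all(comp$km_se_uM > 0))
})

test_that("kinetic tables carry tidy, glance and plotting methods", {
  v <- simulate_velocities(demo_truth(), paper_design(), cv = 0)
  tab <- run_full_inference(v, enzyme_nM = 0.30)
  td <- tidy(tab)
  expect_false(inherits(td, "kinetic_table"))
  g <- glance(tab)
  expect_equal(g$km_donor_uM, 82, tolerance = 1e-6)
  expect_s3_class(autoplot(tab), "ggplot")
  expect_output(print(tab), "donor-site Km")
})
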