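#' Specificity constant of a competitor from a product ratio
#'
#' In one reaction where acceptor `x` competes with ATP, the ratio of the two
#' product velocities cancels both the shared acceptor-site denominator and
#' the donor factor, leaving
#' \deqn{\frac{V_{max}(x)}{K_m(x)} = \frac{v_x}{v_{pppApp}} \cdot
#'       \frac{V_{max}(pppApp)}{K_m(ATP)} \cdot \frac{[ATP]}{[x]}}
#' so the per-batch specificity constant (1/min) of `x` follows from the
#' product ratio without knowing Km and Vmax separately.
#'
#' @param v_x Velocity of the competitor's product, uM/min.
#' @param v_pppApp Velocity of pppApp synthesis in the same reaction,
#'   uM/min, > 0.
#' @param conc_x_uM,conc_atp_uM Concentrations of `x` and ATP, uM.
#' @param vmax_pppApp_uM_min,km_acceptor_atp_uM ATP-acceptor constants from
#'   [fit_acceptor_atp()].
#' @return Vmax/Km for `x` in 1/min.
#' @examples
#' specificity_from_ratio(2, 1, 500, 5000, 114, 1400)
#' @export
specificity_from_ratio <- function(v_x, v_pppApp, conc_x_uM, conc_atp_uM,
                                   vmax_pppApp_uM_min, km_acceptor_atp_uM) {
  if (any(v_pppApp <= 0)) {
    abort_undefined_ratio("v_pppApp must be positive: the product ratio is undefined.")
  }
  if (any(conc_x_uM <= 0) || any(conc_atp_uM <= 0)) {
    abort_invalid("Both competitor and ATP concentrations must be positive.")
  }
  (v_x / v_pppApp) * (vmax_pppApp_uM_min / km_acceptor_atp_uM) *
    (conc_atp_uM / conc_x_uM)
}

#' Deconvolve a competitor's Km from acceptor-site occupancies
#'
#' Inverts a measured pppApp velocity into fractional saturations of the
#' acceptor site and from those the competitor's Michaelis constant:
#' \deqn{\theta_{ATP} = \frac{v_{pppApp}}{V_{max}(pppApp)} \cdot
#'       \frac{1 + [ATP]/K_d}{[ATP]/K_d}} (occupancy by ATP),
#' \deqn{\theta_{apo} = \theta_{ATP} K_m(ATP) / [ATP]} (empty site),
#' \deqn{\theta_x = 1 - \theta_{apo} - \theta_{ATP}} (occupancy by `x`), and
#' \deqn{K_m(x) = \frac{\theta_{apo}}{\theta_x}[x].}
#' The inversion is algebraically exact for velocities generated by the
#' competitive model. Occupancies pushed inconsistent by noise
#' (\eqn{\theta_x \le 0} or \eqn{\theta_{apo} + \theta_{ATP} > 1}) raise a
#' deconvolution error carrying the three occupancies; they are never
#' clamped, since clamping would fabricate a Km.
#'
#' @param v_pppApp Measured pppApp velocity, uM/min.
#' @param condition Condition containing ATP plus at most one other acceptor;
#'   see [as_concentrations()].
#' @param vmax_pppApp_uM_min,km_donor_uM,km_acceptor_atp_uM Constants from
#'   the titration fits.
#' @return One-row tibble: `species_x`, `theta_apo`, `theta_atp`, `theta_x`,
#'   `km_x_uM` (NA when no competitor is present).
#' @examples
#' p <- demo_truth()
#' cond <- c(ATP = 5000, GMP = 500)
#' v <- competition_velocity("ATP", cond, p)
#' deconvolve_km(v, cond, 114, 82, 1400)
#' @export
deconvolve_km <- function(v_pppApp, condition, vmax_pppApp_uM_min,
                          km_donor_uM, km_acceptor_atp_uM) {
  conc <- as_concentrations(condition)
  atp <- conc[["ATP"]]
  if (atp <= 0) abort_invalid("The condition must contain ATP.")
  others <- setdiff(names(conc)[conc > 0], "ATP")
  if (length(others) > 1L) {
    abort_design(paste0(
      "Occupancy deconvolution needs ATP plus at most one competitor; found: ",
      paste(others, collapse = ", "), "."
    ))
  }
  r <- atp / km_donor_uM
  theta_atp <- (v_pppApp / vmax_pppApp_uM_min) * (1 + r) / r
  if (theta_atp >= 1) {
    abort_deconvolution(
      "Implied ATP occupancy >= 1: the measured velocity exceeds what full acceptor-site saturation allows.",
      thetas = c(theta_atp = theta_atp)
    )
  }
  theta_apo <- theta_atp * km_acceptor_atp_uM / atp
  theta_x <- 1 - theta_apo - theta_atp
  th <- c(theta_apo = theta_apo, theta_atp = theta_atp, theta_x = theta_x)
  if (length(others) == 1L) {
    if (theta_apo + theta_atp > 1 || theta_x <= 0) {
      abort_deconvolution(
        "Inconsistent occupancies (theta_x <= 0): measurement noise pushed the deconvolution outside the model.",
        thetas = th
      )
    }
    km_x <- (theta_apo / theta_x) * conc[[others]]
    species_x <- others
  } else {
    km_x <- NA_real_
    species_x <- NA_character_
  }
  tibble(
    species_x = species_x,
    theta_apo = theta_apo,
    theta_atp = theta_atp,
    theta_x = theta_x,
    km_x_uM = km_x
  )
}

#' Turnover number from an observed sub-saturating rate
#'
#' Divides an observed synthesis velocity by the enzyme concentration and
#' corrects for incomplete saturation of both sites at the working ATP
#' concentration:
#' \deqn{k_{cat} = \frac{v/[E]}{\frac{[ATP]}{K_d + [ATP]} \cdot
#'       \frac{[ATP]}{K_a + [ATP]}}}
#' At saturating ATP the correction factor tends to 1 and kcat is simply
#' v/[E].
#'
#' @param velocity_uM_min Observed pppApp velocity in an ATP-only reaction.
#' @param enzyme_nM Enzyme concentration, nM, > 0.
#' @param atp_uM Working ATP concentration, uM.
#' @param km_donor_uM,km_acceptor_atp_uM Michaelis constants of the two sites.
#' @return kcat in 1/min.
#' @examples
#' kcat_from_rate(23, 0.30, 5000, 82, 1400)  # ~1.0e5 per min
#' @export
kcat_from_rate <- function(velocity_uM_min, enzyme_nM, atp_uM,
                           km_donor_uM, km_acceptor_atp_uM) {
  if (!is.numeric(enzyme_nM) || any(enzyme_nM <= 0)) {
    abort_invalid("enzyme_nM must be positive.")
  }
  sat <- donor_saturation(atp_uM, km_donor_uM) *
    atp_uM / (km_acceptor_atp_uM + atp_uM)
  (velocity_uM_min / (enzyme_nM / 1000)) / sat
}

#' Scale per-acceptor kcat values from a reference turnover number
#'
#' Turnover numbers for the other alarmones are set commensurate with their
#' maximal velocities: \eqn{k_{cat}(x) = k_{cat,ref} V_{max}(x) /
#' V_{max}(pppApp)}, where the reference is the pppApp turnover number.
#'
#' @param kcat_reference Reference kcat (1/min) for pppApp synthesis.
#' @param vmax_table Data frame with columns `species` and `vmax_uM_min`,
#'   containing an ATP row (the pppApp reference).
#' @return A tibble with columns `species` and `kcat_min`.
#' @examples
#' scale_kcats(1e5, tibble::tibble(species = c("ATP", "GTP"),
#'                                 vmax_uM_min = c(114, 110)))
#' @export
scale_kcats <- function(kcat_reference, vmax_table) {
  if (!all(c("species", "vmax_uM_min") %in% names(vmax_table))) {
    abort_invalid("vmax_table must have columns species and vmax_uM_min.")
  }
  ref <- vmax_table$vmax_uM_min[vmax_table$species == "ATP"]
  if (length(ref) != 1L || is.na(ref) || ref <= 0) {
    abort_invalid("vmax_table must contain an ATP row with positive Vmax (the pppApp reference).")
  }
  tibble(
    species = vmax_table$species,
    kcat_min = kcat_reference * vmax_table$vmax_uM_min / ref
  )
}

#' Initial velocity from stop-time product measurements
#'
#' When product-vs-time aliquots are supplied instead of velocities, the
#' initial velocity is taken as product over time through the origin at the
#' earliest stop time at which less than 10% of the limiting substrate has
#' been consumed, keeping the estimate inside the initial-rate regime.
#'
#' @param product_uM Product amounts at each stop time, uM.
#' @param time_min Stop times, min, > 0.
#' @param limiting_uM Concentration of the limiting substrate, uM.
#' @param max_fraction Consumption threshold (default 0.1).
#' @return Velocity in uM/min.
#' @export
velocity_from_progress <- function(product_uM, time_min, limiting_uM,
                                   max_fraction = 0.1) {
  if (length(product_uM) != length(time_min) || any(time_min <= 0)) {
    abort_invalid("product_uM and time_min must match, with positive times.")
  }
  ord <- order(time_min)
  ok <- product_uM[ord] < max_fraction * limiting_uM
  if (!any(ok)) {
    abort_insufficient(
      "No stop time lies inside the initial-rate regime (< 10% substrate consumption)."
    )
  }
  i <- ord[which(ok)[1]]
  product_uM[i] / time_min[i]
}
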