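#' Fractional saturation of the PPi-donor site
#'
#' The donor site binds ATP only; its fractional saturation is the
#' Michaelis factor \eqn{[ATP] / (K_{m,donor} + [ATP])}, the right-hand
#' factor of the competitive velocity model. Vectorised over `atp_uM`.
#'
#' @param atp_uM ATP concentration(s), uM, >= 0.
#' @param km_donor_uM Donor-site Km, uM, > 0.
#' @return Fraction(s) in \[0, 1).
#' @examples
#' donor_saturation(82, 82)    # 0.5 at Km
#' donor_saturation(5000, 82)  # near saturation
#' @export
donor_saturation <- function(atp_uM, km_donor_uM) {
  if (!is.numeric(km_donor_uM) || any(is.na(km_donor_uM)) || any(km_donor_uM <= 0)) {
    abort_invalid("km_donor_uM must be positive.")
  }
  if (!is.numeric(atp_uM) || any(is.na(atp_uM)) || any(atp_uM < 0)) {
    abort_invalid("atp_uM must be non-negative.")
  }
  atp_uM / (km_donor_uM + atp_uM)
}

#' Acceptor-site competition denominator
#'
#' The shared acceptor site sees every nucleotide present; the binding
#' polynomial \eqn{D = 1 + \sum_i [i]/K_{m,acceptor}(i)} over all acceptors in
#' the condition normalises each substrate's occupancy.
#'
#' @param condition Named concentration vector (uM) or one-row data frame;
#'   see [as_concentrations()].
#' @param params A [kinetic_params()] object supplying acceptor Km values for
#'   every species present at nonzero concentration.
#' @return The dimensionless denominator D >= 1.
#' @examples
#' p <- paper_params()
#' competition_denominator(c(ATP = 5000), p)
#' @export
competition_denominator <- function(condition, params) {
  conc <- as_concentrations(condition)
  stopifnot(inherits(params, "kinetic_params"))
  present <- names(conc)[conc > 0]
  missing <- setdiff(present, params$acceptors$species)
  if (length(missing)) {
    abort_missing_param(paste0(
      "No acceptor-site Km in the parameter set for species present in the ",
      "condition: ", paste(missing, collapse = ", "), "."
    ))
  }
  km <- setNames(params$acceptors$km_uM, params$acceptors$species)
  1 + sum(conc[present] / km[present])
}

#' Competitive phosphorylation velocity of one acceptor
#'
#' Velocity of pyrophosphoryl transfer onto acceptor `x` when all nucleotides
#' in the condition compete for the single acceptor site while ATP saturates
#' the donor site according to its own Michaelis factor:
#' \deqn{v_x = V_{max}(x) \frac{[x]/K_{m,x}}{1 + \sum_i [i]/K_{m,i}} \cdot
#'       \frac{[ATP]}{K_{m,donor} + [ATP]}}
#' With a single acceptor this reduces to the product of two Michaelis
#' factors; any competitor strictly lowers it.
#'
#' @param x Acceptor species name.
#' @inheritParams competition_denominator
#' @return Velocity in uM/min.
#' @examples
#' competition_velocity("ATP", c(ATP = 5000), paper_params())
#' @export
competition_velocity <- function(x, condition, params) {
  conc <- as_concentrations(condition)
  if (!x %in% nucleotide_species()$species) {
    abort_invalid(paste0("Unknown acceptor species: ", x, "."))
  }
  row <- params$acceptors[params$acceptors$species == x, ]
  if (nrow(row) == 0L) {
    abort_missing_param(paste0("No acceptor parameters for species ", x, "."))
  }
  if (conc[[x]] == 0) return(0)
  D <- competition_denominator(conc, params)
  row$vmax_uM_min * (conc[[x]] / row$km_uM) / D *
    donor_saturation(conc[["ATP"]], params$km_donor_uM)
}

#' Forward acceptor-site occupancy profile
#'
#' Fractional saturation of the acceptor site under a condition: each bound
#' species occupies \eqn{\theta_i = ([i]/K_{m,i})/D} and the empty (apo) site
#' \eqn{\theta_{apo} = 1/D}. The profile sums to one. This is the forward
#' counterpart of the velocity-based occupancy deconvolution in
#' [deconvolve_km()].
#'
#' @inheritParams competition_denominator
#' @return A tibble with columns `species` (acceptors present plus `"apo"`)
#'   and `theta`.
#' @examples
#' occupancy_forward(c(ATP = 5000, GMP = 500), demo_truth())
#' @export
occupancy_forward <- function(condition, params) {
  conc <- as_concentrations(condition)
  D <- competition_denominator(conc, params)
  present <- names(conc)[conc > 0]
  km <- setNames(params$acceptors$km_uM, params$acceptors$species)
  theta <- (conc[present] / km[present]) / D
  tibble(
    species = c(present, "apo"),
    theta = c(as.numeric(theta), 1 / D)
  )
}
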