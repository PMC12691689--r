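# small hand-built parameter sets used across tests
fixture_params <- function() paper_params()

two_acceptor_params <- function(km_gmp = 50, vmax_gmp = 40) {
  kinetic_params(
    km_donor_uM = 82,
    acceptors = tibble::tibble(
      species = c("ATP", "GMP"),
      km_uM = c(1400, km_gmp),
      vmax_uM_min = c(114, vmax_gmp)
    )
  )
}

# draw a random but well-conditioned parameter set + two-acceptor condition;
# the competitor concentration is drawn relative to its Km so the occupancy
# deconvolution stays numerically meaningful
random_two_acceptor_case <- function() {
  x <- sample(c("ADP", "AMP", "GMP", "GDP", "GTP"), 1)
  km_d <- 10^stats::runif(1, 0.5, 3)
  km_atp <- 10^stats::runif(1, 2, 3.7)
  km_x <- 10^stats::runif(1, 0.5, 3.5)
  params <- kinetic_params(
    km_donor_uM = km_d,
    acceptors = tibble::tibble(
      species = c("ATP", x),
      km_uM = c(km_atp, km_x),
      vmax_uM_min = c(stats::runif(1, 20, 200), stats::runif(1, 5, 100))
    )
  )
  cond <- stats::setNames(
    c(10^stats::runif(1, 2, 4), km_x * 10^stats::runif(1, -1.5, 1.5)),
    c("ATP", x)
  )
  list(params = params, condition = cond, species_x = x, km_x = km_x)
}
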