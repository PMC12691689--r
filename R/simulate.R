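#' The published experimental design
#'
#' Returns the titration/competition design used to characterise the
#' synthetase: a donor-site block with GTP held saturating at 5 mM and ATP
#' varied from 0.03 to 1 mM (6 log-spaced points — the printed range with a
#' package-chosen spacing), an acceptor block with ATP alone from 0.5 to
#' 10 mM (7 points), competition blocks pairing 5 mM ATP with 5 mM ADP,
#' 5 mM AMP, or 0.5 mM GMP, and n = 2 technical replicates per point.
#'
#' @param replicates Technical replicates per condition (default 2).
#' @param cv Default multiplicative noise coefficient of variation for
#'   simulation from this design (default 0.05).
#' @param seed Optional seed recorded in the design and used by default when
#'   simulating from it.
#' @return A `design_spec` list with elements `donor_titration`,
#'   `acceptor_titration`, `competitions`, `replicates`, `cv`, `seed`.
#' @examples
#' paper_design()
#' @export
paper_design <- function(replicates = 2, cv = 0.05, seed = NULL) {
  if (replicates < 1 || cv < 0) {
    abort_invalid("replicates must be >= 1 and cv >= 0.")
  }
  structure(
    list(
      donor_titration = tibble(
        conc_ATP_uM = exp(seq(log(30), log(1000), length.out = 6)),
        conc_GTP_uM = 5000
      ),
      acceptor_titration = tibble(
        conc_ATP_uM = c(500, 1000, 2000, 3500, 5000, 7500, 10000)
      ),
      competitions = tibble(
        species = c("ADP", "AMP", "GMP"),
        conc_ATP_uM = 5000,
        conc_x_uM = c(5000, 5000, 500)
      ),
      replicates = as.integer(replicates),
      cv = cv,
      seed = seed
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat("  donor titration: ATP", paste(signif(range(x$donor_titration$conc_ATP_uM), 4),
                                      collapse = "-"),
      "uM at GTP", unique(x$donor_titration$conc_GTP_uM), "uM (",
      nrow(x$donor_titration), "points )\n")
  cat("  acceptor titration: ATP", paste(range(x$acceptor_titration$conc_ATP_uM),
                                         collapse = "-"),
      "uM (", nrow(x$acceptor_titration), "points )\n")
  cat("  competitions:", paste0(x$competitions$species, " ",
                                x$competitions$conc_x_uM, " uM",
                                collapse = "; "),
      "vs ATP", unique(x$competitions$conc_ATP_uM), "uM\n")
  cat("  replicates:", x$replicates, " cv:", x$cv, "\n")
  invisible(x)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) rep(1, n) else exp(rnorm(n, mean = 0, sd = log1p(cv)))
}

#' Simulate initial velocities under the competitive model
#'
#' Generates the velocity table a titration/competition experiment would
#' produce under a known truth: for every condition and replicate, the
#' model velocity is perturbed by multiplicative log-normal noise,
#' \eqn{v_{obs} = v \exp(\varepsilon)}, \eqn{\varepsilon \sim N(0,
#' \ln(1 + CV))}, so velocities stay positive across the three orders of
#' magnitude the designs span, and CV = 0 returns exact model values.
#' The donor block is simulated from the two-parameter donor hyperbola
#' (Vmax(pppGpp) x ATP Michaelis factor) — the model actually fitted to that
#' block — unless `donor_model = "full"`, which evaluates the complete
#' competitive model and requires a GTP entry in the truth's acceptor table.
#'
#' @param truth A [kinetic_params()] object covering every species in the
#'   design (e.g. [demo_truth()]).
#' @param design A [paper_design()]-style `design_spec`.
#' @param cv,replicates,seed Override the design's noise level, replicate
#'   count and seed.
#' @param blocks Which design blocks to simulate (subset of `"donor"`,
#'   `"acceptor"`, `"competition"`).
#' @param donor_model `"hyperbola"` (default) or `"full"`.
#' @return A long velocity tibble with columns `block`, `condition_id`,
#'   `conc_<species>_uM`, `product`, `velocity_uM_min`, `replicate_id`;
#'   the seed is recorded in the `seed` attribute.
#' @examples
#' simulate_velocities(demo_truth(), paper_design(), cv = 0)
#' @export
simulate_velocities <- function(truth, design = paper_design(),
                                cv = design$cv, replicates = design$replicates,
                                seed = design$seed,
                                blocks = c("donor", "acceptor", "competition"),
                                donor_model = c("hyperbola", "full")) {
  stopifnot(inherits(truth, "kinetic_params"), inherits(design, "design_spec"))
  donor_model <- match.arg(donor_model)
  blocks <- match.arg(blocks, several.ok = TRUE)
  if (cv < 0) abort_invalid("cv must be >= 0.")

  rows <- list()
  if ("donor" %in% blocks) {
    dt <- design$donor_titration
    v <- if (donor_model == "hyperbola") {
      if (is.null(truth$vmax_pppGpp_uM_min)) {
        abort_missing_param("truth carries no vmax_pppGpp_uM_min for the donor hyperbola.")
      }
      truth$vmax_pppGpp_uM_min *
        donor_saturation(dt$conc_ATP_uM, truth$km_donor_uM)
    } else {
      sapply(seq_len(nrow(dt)), function(i) {
        competition_velocity("GTP", c(ATP = dt$conc_ATP_uM[i],
                                      GTP = dt$conc_GTP_uM[i]), truth)
      })
    }
    rows <- c(rows, list(tibble(
      block = "donor",
      condition_id = sprintf("donor_%02d", seq_len(nrow(dt))),
      conc_ATP_uM = dt$conc_ATP_uM,
      conc_GTP_uM = dt$conc_GTP_uM,
      product = "pppGpp",
      velocity_true = v
    )))
  }
  if ("acceptor" %in% blocks) {
    at <- design$acceptor_titration
    v <- sapply(at$conc_ATP_uM, function(s) {
      competition_velocity("ATP", c(ATP = s), truth)
    })
    rows <- c(rows, list(tibble(
      block = "acceptor",
      condition_id = sprintf("acceptor_%02d", seq_len(nrow(at))),
      conc_ATP_uM = at$conc_ATP_uM,
      conc_GTP_uM = 0,
      product = "pppApp",
      velocity_true = v
    )))
  }
  if ("competition" %in% blocks) {
    cmp <- design$competitions
    for (i in seq_len(nrow(cmp))) {
      x <- cmp$species[i]
      cond <- setNames(c(cmp$conc_ATP_uM[i], cmp$conc_x_uM[i]), c("ATP", x))
      base <- tibble(
        block = "competition",
        condition_id = paste0("comp_", x),
        conc_ATP_uM = cmp$conc_ATP_uM[i],
        conc_GTP_uM = 0,
        product = c("pppApp", product_of(x)),
        velocity_true = c(competition_velocity("ATP", cond, truth),
                          competition_velocity(x, cond, truth))
      )
      base[[paste0("conc_", x, "_uM")]] <- cmp$conc_x_uM[i]
      rows <- c(rows, list(base))
    }
  }

  base <- bind_rows(rows)
  for (sp in nucleotide_species()$species) {
    col <- paste0("conc_", sp, "_uM")
    if (!col %in% names(base)) base[[col]] <- 0
    base[[col]][is.na(base[[col]])] <- 0
  }

  out <- tidyr::uncount(base, replicates, .id = "replicate_id")
  out$velocity_uM_min <- with_seed_maybe(
    seed, out$velocity_true * lognormal_noise(nrow(out), cv)
  )
  out <- out |>
    select("block", "condition_id",
           all_of(paste0("conc_", nucleotide_species()$species, "_uM")),
           "product", "velocity_uM_min", "replicate_id")
  attr(out, "seed") <- seed
  out
}

#' Simulate a paired set of coupled-assay traces
#'
#' Integrates the total AMP-releasing synthesis velocity of a condition
#' (every pyrophosphoryl transfer releases one AMP from the donor ATP)
#' into an A340 time course: absorbance falls by the extinction coefficient
#' per mM product until the NADH budget (default 0.5 mM, at the implicit
#' 2 NADH per AMP stoichiometry) is exhausted, after which the trace
#' plateaus. An optional background slope emulates ADP-producing side
#' activities; it appears in the complete trace and alone in the paired
#' minus-myokinase trace. Additive Gaussian read noise is applied per
#' reading.
#'
#' @param truth A [kinetic_params()] object.
#' @param condition Reaction condition; see [as_concentrations()].
#' @param duration_min,interval_min Sampling schedule (default 10 min read
#'   every 1 min).
#' @param noise_sd Additive A340 read noise SD (default 0).
#' @param seed Optional seed for the read noise.
#' @param with_background Include the background activity (default TRUE).
#' @param background_slope Background slope in A340/min (negative; default
#'   -0.005).
#' @param dilution_factor Enzyme-sample dilution: the in-well velocity is the
#'   truth velocity divided by this factor.
#' @param a0 Starting absorbance (default 1.0).
#' @param nadh_mM NADH budget (default 0.5 mM).
#' @param epsilon_per_mM Extinction coefficient per mM product (default 3.88).
#' @param condition_id Label used to derive the paired well ids.
#' @return A long trace tibble (two wells: complete and minus-myokinase)
#'   with the columns [reduce_traces()] consumes.
#' @examples
#' p <- kinetic_params(82, tibble::tibble(species = "ATP", km_uM = 1400,
#'                                        vmax_uM_min = 114))
#' tr <- simulate_trace(p, c(ATP = 5000))
#' reduce_traces(tr)
#' @export
simulate_trace <- function(truth, condition, duration_min = 10,
                           interval_min = 1, noise_sd = 0, seed = NULL,
                           with_background = TRUE, background_slope = -0.005,
                           dilution_factor = 1, a0 = 1.0, nadh_mM = 0.5,
                           epsilon_per_mM = 3.88, condition_id = "cond01") {
  if (duration_min <= 0 || interval_min <= 0) {
    abort_invalid("duration_min and interval_min must be positive.")
  }
  if (background_slope > 0) {
    abort_invalid("background_slope must be <= 0 (NADH is consumed).")
  }
  conc <- as_concentrations(condition)
  acceptors <- intersect(names(conc)[conc > 0], truth$acceptors$species)
  v_total <- sum(vapply(acceptors, function(x) {
    competition_velocity(x, conc, truth)
  }, numeric(1))) / dilution_factor

  times <- seq(0, duration_min, by = interval_min)
  eps_nadh <- epsilon_per_mM / 2      # A340 per mM NADH (2 NADH per product)
  bg_nadh_rate <- if (with_background) -background_slope / eps_nadh else 0
  synth_nadh_rate <- 2 * v_total / 1000

  trace_for <- function(nadh_rate, well_suffix, has_mk) {
    consumed <- pmin(nadh_rate * times, nadh_mM)
    tibble(
      well_id = paste0(condition_id, well_suffix),
      time_min = times,
      a340 = a0 - eps_nadh * consumed,
      has_myokinase = has_mk,
      dilution_factor = dilution_factor,
      condition_id = condition_id
    )
  }

  out <- bind_rows(
    trace_for(synth_nadh_rate + bg_nadh_rate, "_full", TRUE),
    trace_for(bg_nadh_rate, "_bg", FALSE)
  )
  if (noise_sd > 0) {
    out$a340 <- with_seed_maybe(
      seed, out$a340 + rnorm(nrow(out), sd = noise_sd)
    )
  }
  out
}
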