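# shared Levenberg-Marquardt controls: tight tolerances so noise-free
# recovery is limited by machine precision, not the stopping rule
nls_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, maxiter = 500)
}

new_mm_fit <- function(fit, data, terms, model, fixed = NULL) {
  structure(
    list(fit = fit, data = data, terms = terms, model = model, fixed = fixed),
    class = c(paste0(model, "_fit"), "mm_fit")
  )
}

check_identifiable <- function(km, s, what) {
  if (km > 20 * max(s) || km < min(s) / 20) {
    abort_fit(paste0(
      "Non-identifiable ", what, " fit: estimated Km (", signif(km, 4),
      " uM) lies far outside the sampled concentration range [",
      min(s), ", ", max(s), "] uM."
    ))
  }
}

#' Fit the Michaelis-Menten hyperbola
#'
#' Nonlinear least-squares fit of \eqn{v = V_{max} s / (K_m + s)} by
#' Levenberg-Marquardt with positivity bounds. Starting values are
#' \eqn{V_{max,0} = 1.2 \max(v)} and \eqn{K_{m,0} = \mathrm{median}(s)};
#' standard errors come from the fit covariance. Data-frame first: supply the
#' concentration and velocity columns by name.
#'
#' @param data Data frame of one titration.
#' @param conc,velocity Columns holding substrate concentration (uM) and
#'   velocity (uM/min); defaults `conc_uM`, `velocity_uM_min`.
#' @return An object of class `mm_fit` with [tidy()], [glance()], [coef()]
#'   and [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(conc_uM = c(30, 60, 125, 250, 500, 1000))
#' d$velocity_uM_min <- 110 * d$conc_uM / (82 + d$conc_uM)
#' tidy(fit_michaelis_menten(d))
#' @export
fit_michaelis_menten <- function(data, conc = conc_uM,
                                 velocity = velocity_uM_min) {
  s <- rlang::eval_tidy(rlang::enquo(conc), data)
  v <- rlang::eval_tidy(rlang::enquo(velocity), data)
  check_titration(s, v)
  d <- tibble(s = s, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * s / (km + s),
      data = d,
      start = list(vmax = 1.2 * max(v), km = median(s)),
      lower = c(vmax = 1e-12, km = 1e-12),
      control = nls_control()
    ),
    error = function(e) {
      abort_fit(paste0("Michaelis-Menten fit failed: ", conditionMessage(e),
                       " (n = ", length(s), ", conc range [", min(s), ", ",
                       max(s), "] uM)"))
    }
  )
  km <- coef(fit)[["km"]]
  check_identifiable(km, s, "Michaelis-Menten")
  new_mm_fit(fit, d, terms = c(vmax = "vmax_uM_min", km = "km_uM"),
             model = "michaelis_menten")
}

check_titration <- function(s, v, min_distinct = 3L) {
  if (length(s) != length(v)) {
    abort_invalid("Concentration and velocity vectors must have equal length.")
  }
  if (any(is.na(s)) || any(is.na(v)) || any(s < 0) || any(v < 0)) {
    abort_invalid("Concentrations and velocities must be non-negative and non-missing.")
  }
  if (dplyr::n_distinct(s) < min_distinct) {
    abort_fit(paste0("At least ", min_distinct,
                     " distinct concentrations are required; got ",
                     dplyr::n_distinct(s), "."))
  }
  if (all(v == 0)) {
    abort_fit("All velocities are zero; the hyperbola is degenerate.")
  }
  invisible(TRUE)
}

average_replicates <- function(velocities) {
  conc_cols <- intersect(paste0("conc_", nucleotide_species()$species, "_uM"),
                         names(velocities))
  velocities |>
    group_by(across(all_of(c("condition_id", conc_cols, "product")))) |>
    summarise(velocity_uM_min = mean(.data$velocity_uM_min), .groups = "drop")
}

conc_or_zero <- function(df, species) {
  col <- paste0("conc_", species, "_uM")
  if (col %in% names(df)) df[[col]] else rep(0, nrow(df))
}

#' Fit the donor-site Km from the saturating-GTP titration
#'
#' With GTP held at one saturating concentration and ATP varied at low
#' concentrations, pppGpp is the only detectable product and its initial
#' velocity follows a simple hyperbola in ATP whose Km is the donor-site
#' Michaelis constant and whose plateau is Vmax(pppGpp). Replicate
#' velocities are averaged (mean) per concentration before fitting.
#'
#' @param velocities Velocity table with columns `condition_id`,
#'   `conc_ATP_uM`, `conc_GTP_uM`, `product`, `velocity_uM_min`, and
#'   optionally `replicate_id`.
#' @return An `mm_fit` whose terms are `km_donor_uM` and
#'   `vmax_pppGpp_uM_min`.
#' @export
fit_donor_site <- function(velocities) {
  rows <- velocities |>
    filter(.data$product %in% c("pppGpp", "ppGpp"))
  if (nrow(rows) == 0L) {
    abort_design("No pppGpp velocities found for the donor-site titration.")
  }
  gtp <- conc_or_zero(rows, "GTP")
  if (dplyr::n_distinct(gtp) != 1L) {
    abort_design("The donor-site titration must share a single saturating GTP concentration.")
  }
  if (unique(gtp) <= 0) {
    abort_design("The donor-site titration requires GTP to be present.")
  }
  avg <- average_replicates(rows)
  fit <- fit_michaelis_menten(avg, conc = .data$conc_ATP_uM)
  fit$terms <- c(vmax = "vmax_pppGpp_uM_min", km = "km_donor_uM")
  fit$model <- "donor_site"
  class(fit) <- c("donor_site_fit", "mm_fit")
  fit
}

#' Fit the acceptor-site Km for ATP with the donor Km held fixed
#'
#' In reactions containing ATP as the only nucleotide, ATP occupies both the
#' donor and acceptor sites, so pppApp velocity follows the dual-saturation
#' model \eqn{v = V_{max} \cdot \frac{s}{K_a + s} \cdot \frac{s}{K_d + s}}
#' with the donor Km \eqn{K_d} fixed to the value from [fit_donor_site()].
#' The fitted \eqn{K_a} is the acceptor-site Km for ATP and the fitted
#' plateau is Vmax(pppApp).
#'
#' @param velocities Velocity table; only rows with `product == "pppApp"` and
#'   no acceptor other than ATP are used.
#' @param km_donor_uM Donor-site Km (uM) held fixed during the fit.
#' @return An `mm_fit` whose terms are `km_acceptor_atp_uM` and
#'   `vmax_pppApp_uM_min`.
#' @export
fit_acceptor_atp <- function(velocities, km_donor_uM) {
  if (!is.numeric(km_donor_uM) || length(km_donor_uM) != 1L || km_donor_uM < 0) {
    abort_invalid("km_donor_uM must be a single non-negative number.")
  }
  other <- setdiff(nucleotide_species()$species, "ATP")
  rows <- velocities |> filter(.data$product == "pppApp")
  if (nrow(rows)) {
    only_atp <- Reduce(`&`, lapply(other, function(sp) conc_or_zero(rows, sp) == 0))
    rows <- rows[only_atp, , drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    abort_design("No ATP-only pppApp velocities found for the acceptor-site titration.")
  }
  avg <- average_replicates(rows)
  s <- avg$conc_ATP_uM
  v <- avg$velocity_uM_min
  check_titration(s, v)
  d <- tibble(s = s, v = v)
  kd <- km_donor_uM
  start_vmax <- 1.2 * max(v) / max(donor_saturation(max(s), max(kd, 1e-12)), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * (s / (ka + s)) * (s / (kd + s)),
      data = cbind(d, kd = kd),
      start = list(vmax = start_vmax, ka = median(s)),
      lower = c(vmax = 1e-12, ka = 1e-12),
      control = nls_control()
    ),
    error = function(e) {
      abort_fit(paste0("Acceptor-site fit failed: ", conditionMessage(e),
                       " (n = ", length(s), ", conc range [", min(s), ", ",
                       max(s), "] uM)"))
    }
  )
  check_identifiable(coef(fit)[["ka"]], s, "acceptor-site")
  out <- new_mm_fit(fit, d,
                    terms = c(vmax = "vmax_pppApp_uM_min", ka = "km_acceptor_atp_uM"),
                    model = "acceptor_atp", fixed = c(km_donor_uM = kd))
  out
}

#' @export
coef.mm_fit <- function(object, ...) {
  est <- coef(object$fit)
  setNames(as.numeric(est), unname(object$terms[names(est)]))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = unname(x$terms[rownames(s)]),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' One-row summary of a kinetic fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A tibble with residual standard error, deviance, convergence
#'   diagnostics and the number of observations.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    sigma = s$sigma,
    deviance = sum(stats::residuals(x$fit)^2),
    df.residual = stats::df.residual(x$fit),
    nobs = nrow(x$data),
    isConv = x$fit$convInfo$isConv,
    finTol = x$fit$convInfo$finTol
  )
}

#' Plot a titration and its fitted curve
#'
#' @param object An `mm_fit` object.
#' @param ... Unused.
#' @return A ggplot object: observed velocities and the fitted model over a
#'   fine concentration grid.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(s = seq(0, max(d$s) * 1.05, length.out = 200))
  if (!is.null(object$fixed)) grid$kd <- object$fixed[["km_donor_uM"]]
  grid$v <- stats::predict(object$fit, newdata = grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s, y = .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "substrate (uM)", y = "velocity (uM/min)",
                  title = class(object)[1]) +
    ggplot2::theme_bw()
}
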