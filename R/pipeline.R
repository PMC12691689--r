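#' Run the full stepwise kinetic inference
#'
#' Reproduces the sequential inference that turns a velocity table into a
#' per-acceptor kinetic table: (1) fit the donor-site Km and Vmax(pppGpp)
#' from the saturating-GTP titration; (2) fit the acceptor-site Km for ATP
#' and Vmax(pppApp) from the ATP-alone titration with the donor Km fixed;
#' (3) for each two-acceptor competition, take the specificity constant
#' Vmax/Km from the product ratio and the competitor Km from the occupancy
#' deconvolution, giving Vmax(x) = (Vmax/Km)(x) x Km(x); (4) if an enzyme
#' concentration is supplied, convert Vmax(pppApp) to kcat and scale the
#' other acceptors commensurate with their Vmax. GDP competitions are never
#' quantified (its product co-elutes with pppApp on the anion-exchange
#' column) and appear only as a flagged row. Replicates are averaged (mean)
#' before any fitting. Deconvolution failures in one competition are
#' reported in that row's flag without aborting the others.
#'
#' @param velocities Long velocity table: `condition_id`, concentration
#'   columns `conc_<species>_uM`, `product`, `velocity_uM_min`, optionally
#'   `replicate_id` and `batch`. Mixing batches in one fit is refused.
#' @param enzyme_nM Optional enzyme concentration (nM) enabling the kcat
#'   columns.
#' @param n_boot Number of bootstrap resamples of replicates for empirical
#'   standard errors of the ratio/deconvolution-derived quantities
#'   (default 0: SEs come from fit covariance only, and derived quantities
#'   carry NA).
#' @param seed Seed for the bootstrap resampling.
#' @return A `kinetic_table` tibble: one row per acceptor with `km_uM`,
#'   `km_se_uM`, `vmax_uM_min`, `vmax_se_uM_min`, `vmax_over_km_min`,
#'   `kcat_min`, `kcat_over_km_min_uM` and `flag`; donor-site estimates are
#'   attached as attributes `km_donor_uM` and `km_donor_se_uM`.
#' @examples
#' v <- simulate_velocities(demo_truth(), paper_design(), cv = 0)
#' run_full_inference(v, enzyme_nM = 0.30)
#' @export
run_full_inference <- function(velocities, enzyme_nM = NULL, n_boot = 0,
                               seed = NULL) {
  required <- c("condition_id", "product", "velocity_uM_min")
  miss <- setdiff(required, names(velocities))
  if (length(miss)) {
    abort_design(paste0("Velocity table is missing columns: ",
                        paste(miss, collapse = ", "), "."))
  }
  if ("batch" %in% names(velocities) &&
      dplyr::n_distinct(velocities$batch) > 1L) {
    abort_design("Velocities from more than one enzyme batch cannot be mixed in one fit.")
  }
  velocities <- as_tibble(velocities)

  est <- infer_once(velocities, enzyme_nM = enzyme_nM)

  if (n_boot > 0) {
    boots <- with_seed_maybe(seed, {
      purrr::map(seq_len(n_boot), function(i) {
        resampled <- velocities |>
          group_by(.data$condition_id, .data$product) |>
          dplyr::slice_sample(prop = 1, replace = TRUE) |>
          ungroup()
        tryCatch(infer_once(resampled, enzyme_nM = enzyme_nM),
                 alarmkin_error = function(e) NULL)
      })
    })
    boots <- purrr::compact(boots)
    if (length(boots) >= 2L) {
      km_mat <- sapply(boots, function(b) b$table$km_uM)
      vm_mat <- sapply(boots, function(b) b$table$vmax_uM_min)
      est$table$km_se_uM <- apply(km_mat, 1, sd, na.rm = TRUE)
      est$table$vmax_se_uM_min <- apply(vm_mat, 1, sd, na.rm = TRUE)
    }
  }

  out <- est$table
  class(out) <- c("kinetic_table", class(out))
  attr(out, "km_donor_uM") <- est$km_donor_uM
  attr(out, "km_donor_se_uM") <- est$km_donor_se_uM
  attr(out, "enzyme_nM") <- enzyme_nM
  attr(out, "n_boot") <- n_boot
  out
}

# one pass of the sequential inference over a (possibly resampled) table
infer_once <- function(velocities, enzyme_nM = NULL) {
  species <- nucleotide_species()$species
  mv <- average_replicates(velocities)
  for (sp in species) {
    col <- paste0("conc_", sp, "_uM")
    if (!col %in% names(mv)) mv[[col]] <- 0
  }

  # --- donor block: pppGpp at fixed GTP, varying ATP ---
  donor_rows <- mv |>
    filter(.data$product %in% c("pppGpp", "ppGpp"), .data$conc_GTP_uM > 0)
  if (nrow(donor_rows) < 3L) {
    abort_design("Missing design block: donor-site titration (pppGpp at saturating GTP over >= 3 ATP concentrations).")
  }
  donor_fit <- fit_donor_site(donor_rows)
  dco <- coef(donor_fit)
  dse <- tidy(donor_fit)
  km_donor <- dco[["km_donor_uM"]]
  vmax_pppGpp <- dco[["vmax_pppGpp_uM_min"]]

  # --- acceptor block: pppApp with ATP as the only nucleotide ---
  other <- setdiff(species, "ATP")
  atp_only <- mv$product == "pppApp" &
    Reduce(`&`, lapply(other, function(sp) mv[[paste0("conc_", sp, "_uM")]] == 0))
  if (sum(atp_only) < 3L) {
    abort_design("Missing design block: ATP-alone titration (pppApp over >= 3 ATP concentrations).")
  }
  acc_fit <- fit_acceptor_atp(mv[atp_only, ], km_donor_uM = km_donor)
  aco <- coef(acc_fit)
  ase <- tidy(acc_fit)
  km_a <- aco[["km_acceptor_atp_uM"]]
  vmax_pppApp <- aco[["vmax_pppApp_uM_min"]]

  se_of <- function(td, term) {
    v <- td$std.error[td$term == term]
    if (length(v)) v else NA_real_
  }

  rows <- list(
    tibble(
      acceptor = "ATP", product = "pppApp",
      km_uM = km_a, km_se_uM = se_of(ase, "km_acceptor_atp_uM"),
      vmax_uM_min = vmax_pppApp,
      vmax_se_uM_min = se_of(ase, "vmax_pppApp_uM_min"),
      flag = NA_character_
    ),
    tibble(
      acceptor = "GTP", product = "pppGpp",
      km_uM = NA_real_, km_se_uM = NA_real_,
      vmax_uM_min = vmax_pppGpp,
      vmax_se_uM_min = se_of(dse, "vmax_pppGpp_uM_min"),
      flag = "Km not determined from these designs"
    )
  )

  # --- competition blocks: ATP + exactly one other acceptor, both products ---
  conc_cols <- paste0("conc_", species, "_uM")
  cond_tbl <- mv |>
    select("condition_id", all_of(conc_cols)) |>
    distinct(.data$condition_id, .keep_all = TRUE)
  n_other_acceptors <- rowSums(cond_tbl[paste0("conc_", other, "_uM")] > 0)
  with_pppApp <- mv |>
    filter(.data$product == "pppApp") |>
    pull(.data$condition_id)
  comp_ids <- cond_tbl$condition_id[
    cond_tbl$conc_ATP_uM > 0 & n_other_acceptors == 1L &
      cond_tbl$condition_id %in% with_pppApp
  ]

  for (id in comp_ids) {
    cond_rows <- mv |> filter(.data$condition_id == id)
    conc <- as_concentrations(cond_rows[1, ])
    x <- setdiff(names(conc)[conc > 0], "ATP")
    prod_x <- product_of(x)
    v_p <- cond_rows$velocity_uM_min[cond_rows$product == "pppApp"][1]
    v_x <- cond_rows$velocity_uM_min[cond_rows$product == prod_x]

    if (x == "GDP") {
      rows <- c(rows, list(tibble(
        acceptor = "GDP", product = "ppGpp",
        km_uM = NA_real_, km_se_uM = NA_real_,
        vmax_uM_min = NA_real_, vmax_se_uM_min = NA_real_,
        flag = "co-elution, not quantifiable"
      )))
      next
    }
    if (length(v_x) == 0L) {
      rows <- c(rows, list(tibble(
        acceptor = x, product = prod_x,
        km_uM = NA_real_, km_se_uM = NA_real_,
        vmax_uM_min = NA_real_, vmax_se_uM_min = NA_real_,
        flag = paste0("no ", prod_x, " velocity in condition ", id)
      )))
      next
    }

    row <- tryCatch({
      spec_const <- specificity_from_ratio(
        v_x[1], v_p, conc[[x]], conc[["ATP"]], vmax_pppApp, km_a
      )
      dec <- deconvolve_km(v_p, conc, vmax_pppApp, km_donor, km_a)
      tibble(
        acceptor = x, product = prod_x,
        km_uM = dec$km_x_uM, km_se_uM = NA_real_,
        vmax_uM_min = spec_const * dec$km_x_uM,
        vmax_se_uM_min = NA_real_,
        flag = NA_character_
      )
    }, alarmkin_error = function(e) {
      tibble(
        acceptor = x, product = prod_x,
        km_uM = NA_real_, km_se_uM = NA_real_,
        vmax_uM_min = NA_real_, vmax_se_uM_min = NA_real_,
        flag = conditionMessage(e)
      )
    })
    rows <- c(rows, list(row))
  }

  table <- bind_rows(rows) |>
    mutate(vmax_over_km_min = .data$vmax_uM_min / .data$km_uM)

  if (!is.null(enzyme_nM)) {
    kcat_ref <- vmax_pppApp / (enzyme_nM / 1000)
    scaled <- scale_kcats(
      kcat_ref,
      table |> select("species" = "acceptor", "vmax_uM_min")
    )
    table$kcat_min <- scaled$kcat_min
    table$kcat_over_km_min_uM <- table$kcat_min / table$km_uM
  } else {
    table$kcat_min <- NA_real_
    table$kcat_over_km_min_uM <- NA_real_
  }
  table <- table |>
    select("acceptor", "product", "km_uM", "km_se_uM", "vmax_uM_min",
           "vmax_se_uM_min", "vmax_over_km_min", "kcat_min",
           "kcat_over_km_min_uM", "flag")

  list(
    table = table,
    km_donor_uM = km_donor,
    km_donor_se_uM = se_of(dse, "km_donor_uM")
  )
}

#' @export
print.kinetic_table <- function(x, ...) {
  cat("<kinetic_table>\n")
  cat("  donor-site Km (ATP):", signif(attr(x, "km_donor_uM"), 4), "uM")
  se <- attr(x, "km_donor_se_uM")
  if (!is.na(se)) cat(" (SE", signif(se, 3), ")")
  cat("\n")
  if (!is.null(attr(x, "enzyme_nM"))) {
    cat("  enzyme:", attr(x, "enzyme_nM"), "nM\n")
  }
  NextMethod()
  invisible(x)
}

#' @method tidy kinetic_table
#' @export
tidy.kinetic_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "kinetic_table")
  as_tibble(out)
}

#' @method glance kinetic_table
#' @export
glance.kinetic_table <- function(x, ...) {
  tibble(
    km_donor_uM = attr(x, "km_donor_uM"),
    km_donor_se_uM = attr(x, "km_donor_se_uM"),
    enzyme_nM = attr(x, "enzyme_nM") %||% NA_real_,
    n_acceptors = sum(!is.na(x$km_uM) | !is.na(x$vmax_uM_min)),
    n_flagged = sum(!is.na(x$flag))
  )
}

#' Plot a kinetic table
#'
#' Specificity constants (kcat/Km when kcat is available, otherwise Vmax/Km)
#' per acceptor on a log scale.
#'
#' @param object A `kinetic_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinetic_table
#' @export
autoplot.kinetic_table <- function(object, ...) {
  d <- tidy(object)
  use_kcat <- any(!is.na(d$kcat_over_km_min_uM))
  d$value <- if (use_kcat) d$kcat_over_km_min_uM else d$vmax_over_km_min
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$acceptor, -.data$value),
                                  y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "PPi acceptor",
      y = if (use_kcat) "kcat/Km (1/min/uM)" else "Vmax/Km (1/min)"
    ) +
    ggplot2::theme_bw()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
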