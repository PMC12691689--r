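#' The nucleotide species vocabulary
#'
#' The model works over a closed set of six nucleotides. ATP is the only
#' pyrophosphate (PPi) donor; every species can occupy the acceptor site, and
#' pyrophosphoryl transfer onto each acceptor yields one specific alarmone
#' product (ATP -> pppApp, ADP -> ppApp, AMP -> pApp, GTP -> pppGpp,
#' GDP -> ppGpp, GMP -> pGpp).
#'
#' @return A tibble with columns `species`, `can_donate`, `can_accept`, and
#'   `product`.
#' @examples
#' nucleotide_species()
#' @export
nucleotide_species <- function() {
  tibble(
    species    = c("ATP", "ADP", "AMP", "GTP", "GDP", "GMP"),
    can_donate = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    can_accept = TRUE,
    product    = c("pppApp", "ppApp", "pApp", "pppGpp", "ppGpp", "pGpp")
  )
}

#' Map acceptor species to alarmone product names (and back)
#'
#' @param species Character vector of acceptor species names.
#' @param product Character vector of alarmone product names.
#' @return A character vector of product (or species) names.
#' @examples
#' product_of("GMP")
#' species_of_product("pppApp")
#' @export
product_of <- function(species) {
  tab <- nucleotide_species()
  idx <- match(species, tab$species)
  if (anyNA(idx)) {
    abort_invalid(paste0(
      "Unknown nucleotide species: ",
      paste(species[is.na(idx)], collapse = ", "),
      ". The vocabulary is closed to ", paste(tab$species, collapse = ", "), "."
    ))
  }
  tab$product[idx]
}

#' @rdname product_of
#' @export
species_of_product <- function(product) {
  tab <- nucleotide_species()
  idx <- match(product, tab$product)
  if (anyNA(idx)) {
    abort_invalid(paste0(
      "Unknown alarmone product: ",
      paste(product[is.na(idx)], collapse = ", "), "."
    ))
  }
  tab$species[idx]
}

#' Normalise a reaction condition to a full concentration vector
#'
#' Accepts either a named numeric vector of concentrations in uM (names drawn
#' from the species vocabulary) or a one-row data frame with `conc_<species>_uM`
#' columns, and returns a named numeric vector over all six species (absent
#' species at 0).
#'
#' @param condition Named numeric vector or one-row data frame.
#' @return Named numeric vector of concentrations (uM) over all six species.
#' @examples
#' as_concentrations(c(ATP = 5000, GMP = 500))
#' @export
as_concentrations <- function(condition) {
  species <- nucleotide_species()$species
  if (is.data.frame(condition)) {
    if (nrow(condition) != 1L) {
      abort_invalid("A condition data frame must have exactly one row.")
    }
    cols <- paste0("conc_", species, "_uM")
    out <- setNames(numeric(length(species)), species)
    for (i in seq_along(species)) {
      if (cols[i] %in% names(condition)) {
        out[species[i]] <- as.numeric(condition[[cols[i]]])
      }
    }
  } else if (is.numeric(condition)) {
    if (length(condition) && is.null(names(condition))) {
      abort_invalid("Concentration vectors must be named by species.")
    }
    bad <- setdiff(names(condition), species)
    if (length(bad)) {
      abort_invalid(paste0("Unknown species in condition: ",
                           paste(bad, collapse = ", "), "."))
    }
    out <- setNames(numeric(length(species)), species)
    out[names(condition)] <- as.numeric(condition)
  } else {
    abort_invalid("A condition must be a named numeric vector or a one-row data frame.")
  }
  if (anyNA(out) || any(out < 0)) {
    abort_invalid("All concentrations must be non-negative and non-missing.")
  }
  out
}
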