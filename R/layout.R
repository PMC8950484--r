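#' Four-compartment Golgi configuration
#'
#' Loads the Golgi layout: the ordered compartments (cis, medial, trans,
#' TGN), the per-compartment protein residence time (5.56 min, so the
#' simulation horizon is 4 x 5.56 = 22.24 min), compartment volume
#' (2.5 uL), the initial concentration of the root glycan (Tn antigen,
#' 100 umol/uL placed in cis), the clamped nucleotide-sugar donor
#' concentrations per compartment (uM), and the binary enzyme
#' localization matrix.
#'
#' Donors are zero in compartments where the corresponding sugar is not
#' donated, so any rule whose donor is absent from a compartment is
#' silently inactive there.
#'
#' @param path Path to a layout JSON file; default is the bundled
#'   configuration.
#' @return Object of class `"golgi_layout"`.
#' @examples
#' lay <- golgi_layout()
#' lay$tau * length(lay$compartments)   # 22.24 min horizon
#' lay$donors["UDP_GlcNAc", ]
#' @export
golgi_layout <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "golgi.json", package = "oglycosim",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- raw$compartments
  donors <- do.call(rbind, raw$donors)
  colnames(donors) <- comps
  loc <- do.call(rbind, raw$localization)
  colnames(loc) <- comps
  storage.mode(loc) <- "integer"
  stopifnot(length(comps) == 4L, all(donors >= 0), all(loc %in% c(0L, 1L)))
  structure(list(compartments = comps,
                 tau = raw$residence_time_min,
                 volume = raw$volume_uL,
                 initial_conc = raw$initial_root_concentration,
                 glycan_unit = raw$glycan_unit,
                 donors = donors,
                 localization = loc),
            class = "golgi_layout")
}

#' @export
print.golgi_layout <- function(x, ...) {
  cat("<golgi_layout> ", paste(x$compartments, collapse = " -> "),
      "; tau = ", x$tau, " min (horizon ", x$tau * length(x$compartments),
      " min); volume ", x$volume, " uL\n", sep = "")
  invisible(x)
}

#' Kinetic parameter set
#'
#' Bundles the kinetic constants of the Golgi model: per reaction rule a
#' turnover number `Kf` (1/min) and an acceptor half-saturation constant
#' `Km`; per enzyme a donor half-saturation constant `Kmd` (uM); and per
#' enzyme and compartment an enzyme concentration `E`.  `E` is forced to
#' zero wherever the layout's localization matrix is zero.
#'
#' @param Kf,Km Named numeric vectors (names = rule ids).
#' @param Kmd Named numeric vector (names = enzymes).
#' @param E Numeric matrix, enzymes x compartments (dimnames required).
#' @param layout A `"golgi_layout"` used to mask `E`.
#' @return Object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(Kf, Km, Kmd, E, layout = golgi_layout()) {
  stopifnot(identical(names(Kf), names(Km)),
            is.matrix(E), nrow(E) == 0L || !is.null(rownames(E)),
            all(Kf >= 0), all(Km > 0), all(Kmd > 0), all(E >= 0))
  if (nrow(E) > 0L) {
    mask <- layout$localization[rownames(E), colnames(E), drop = FALSE]
    E <- E * mask
  }
  structure(list(Kf = Kf, Km = Km, Kmd = Kmd, E = E), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> ", length(x$Kf), " rules, ", length(x$Kmd),
      " enzymes; ", sum(x$E > 0), " nonzero enzyme concentrations\n", sep = "")
  invisible(x)
}

#' Draw a random kinetic parameter set
#'
#' Log-uniform draws within `[lower, upper]` for every constant needed by
#' a network: `Kf`/`Km` per active rule, `Kmd` per enzyme, and `E` per
#' enzyme and localized compartment.  Used by the synthetic-profile
#' generator and by property tests.
#'
#' @param network A `"glyconet"`.
#' @param layout A `"golgi_layout"`.
#' @param ruleset The rule set the network was built from.
#' @param lower,upper Bounds (defaults 1e-6 and 1e5).
#' @return A `"kinetic_params"`.
#' @export
random_params <- function(network, layout = golgi_layout(),
                          ruleset = default_ruleset(),
                          lower = 1e-6, upper = 1e5) {
  ids <- network$active_rule_ids
  enz <- unique(vapply(ruleset$rules[ids], function(r) r$enzyme, character(1)))
  draw <- function(n) 10^stats::runif(n, log10(lower), log10(upper))
  Kf <- stats::setNames(draw(length(ids)), ids)
  Km <- stats::setNames(draw(length(ids)), ids)
  Kmd <- stats::setNames(draw(length(enz)), enz)
  E <- matrix(draw(length(enz) * 4L), nrow = length(enz),
              dimnames = list(enz, layout$compartments))
  kinetic_params(Kf, Km, Kmd, E, layout)
}
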