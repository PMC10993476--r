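#' Standard Gibbs free energies of formation
#'
#' Loads the packaged table of standard Gibbs free energies of formation
#' (kJ/mol at 298.15 K) together with charge, phase and elemental
#' composition for every chemical species the package knows about. The
#' table can be overridden with a user-supplied file in the same
#' tab-separated layout, e.g. to switch to a different constants
#' compilation.
#'
#' @param path Optional path to an alternative constants table. The file
#'   must be tab-separated with columns `species`, `charge`, `phase`,
#'   `dGf0_kJ_mol` and one column per balanced element (`Fe`, `N`, `O`,
#'   `H`); lines starting with `#` are ignored.
#' @return A data frame with one row per species.
#' @examples
#' fe <- formation_energies()
#' fe[fe$species == "Fe2+", ]
#' @export
formation_energies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "formation_energies.tsv", package = "ndfo")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("species", "charge", "phase", "dGf0_kJ_mol", "Fe", "N", "O", "H")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("constants table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$species)) {
    stop("constants table contains duplicated species")
  }
  h <- tab$dGf0_kJ_mol[tab$species == "H+"]
  if (length(h) == 1 && abs(h) > 1e-12) {
    stop("dGf0 of H+ must be 0 by convention")
  }
  tab
}

#' Define a balanced (redox) reaction
#'
#' A reaction is a signed stoichiometry over chemical species (products
#' positive, reactants negative) plus the number of electrons transferred
#' per formula unit. On construction the reaction is validated against the
#' constants table: every species must be known, and charge as well as
#' Fe/N/O/H element balances must hold.
#'
#' @param stoichiometry Named numeric vector; names are species identifiers
#'   as in [formation_energies()], values are signed coefficients.
#' @param n_electrons Electrons transferred per formula unit (mol e-);
#'   0 for non-redox reactions.
#' @param constants Constants table, see [formation_energies()].
#' @param check Validate balances (default `TRUE`).
#' @return An object of class `chem_reaction`.
#' @examples
#' chem_reaction(c("H2O" = -1, "H+" = 1, "OH-" = 1))
#' @export
chem_reaction <- function(stoichiometry, n_electrons = 0,
                          constants = formation_energies(), check = TRUE) {
  if (length(stoichiometry) > 0 &&
      (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))) {
    stop("stoichiometry must be a named numeric vector")
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (n_electrons < 0) stop("n_electrons must be >= 0")
  idx <- match(names(stoichiometry), constants$species)
  if (anyNA(idx)) {
    stop("no formation-energy constant for species: ",
         paste(names(stoichiometry)[is.na(idx)], collapse = ", "))
  }
  if (check && length(stoichiometry) > 0) {
    chg <- sum(stoichiometry * constants$charge[idx])
    if (abs(chg) > 1e-8) {
      stop("reaction is not charge balanced (net charge ", signif(chg, 4), ")")
    }
    for (el in c("Fe", "N", "O", "H")) {
      bal <- sum(stoichiometry * constants[[el]][idx])
      if (abs(bal) > 1e-8) {
        stop("reaction is not balanced in ", el, " (net ", signif(bal, 4), ")")
      }
    }
  }
  structure(
    list(stoichiometry = stoichiometry,
         n_electrons = n_electrons,
         phases = stats::setNames(constants$phase[idx], names(stoichiometry))),
    class = "chem_reaction"
  )
}

#' @export
print.chem_reaction <- function(x, ...) {
  s <- x$stoichiometry
  side <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                   paste0(abs(v), " ", names(v))),
                            collapse = " + ")
  cat(side(s[s < 0]), "->", side(s[s > 0]),
      sprintf(" [%g e-]\n", x$n_electrons))
  invisible(x)
}

#' One-electron nap-type nitrate-reducing iron-oxidation couple
#'
#' Fe2+ + 0.5 NO3- + H+ -> Fe3+ + 0.5 NO2- + 0.5 H2O, the catabolic couple
#' of a periplasmic-nitrate-reductase (nap) dependent iron oxidizer:
#' ferrous iron is the electron donor and nitrate is reduced only to
#' nitrite. One electron is transferred per formula unit.
#'
#' @param constants Constants table, see [formation_energies()].
#' @return A `chem_reaction`.
#' @export
reaction_nap_iron_oxidation <- function(constants = formation_energies()) {
  chem_reaction(
    c("Fe2+" = -1, "NO3-" = -0.5, "H+" = -1,
      "Fe3+" = 1, "NO2-" = 0.5, "H2O" = 0.5),
    n_electrons = 1, constants = constants
  )
}

#' Overall NDFO catabolic stoichiometry to ferrihydrite and dinitrogen
#'
#' 10 Fe2+ + 2 NO3- + 24 H2O -> 10 Fe(OH)3 + N2 + 18 H+: the classical
#' overall nitrate-dependent iron-oxidation catabolism with complete
#' denitrification and precipitation of the ferric iron as hydrous oxide.
#' Ten electrons are transferred (1 per Fe, 5 per N).
#'
#' @param constants Constants table, see [formation_energies()].
#' @return A `chem_reaction`.
#' @export
reaction_ndfo_catabolic <- function(constants = formation_energies()) {
  chem_reaction(
    c("Fe2+" = -10, "NO3-" = -2, "H2O" = -24,
      "Fe(OH)3" = 10, "N2" = 1, "H+" = 18),
    n_electrons = 10, constants = constants
  )
}

#' Water autoionization
#'
#' H2O -> H+ + OH-. Not a redox reaction; useful as a consistency check
#' of the constants table against Kw = 1e-14.
#'
#' @param constants Constants table, see [formation_energies()].
#' @return A `chem_reaction`.
#' @export
reaction_water_dissociation <- function(constants = formation_energies()) {
  chem_reaction(c("H2O" = -1, "H+" = 1, "OH-" = 1),
                n_electrons = 0, constants = constants)
}
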