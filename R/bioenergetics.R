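#' Standard Gibbs free energy of a reaction
#'
#' Sums standard formation energies over the signed stoichiometry
#' (products minus reactants). No pH referencing is applied; formation
#' energies are tabulated at 298.15 K.
#'
#' @param reaction A [chem_reaction()].
#' @param constants Constants table, see [formation_energies()].
#' @return Standard Gibbs free energy, kJ per mol reaction.
#' @examples
#' delta_g_standard(reaction_nap_iron_oxidation())
#' @export
delta_g_standard <- function(reaction, constants = formation_energies()) {
  s <- reaction$stoichiometry
  if (length(s) == 0) return(0)
  idx <- match(names(s), constants$species)
  if (anyNA(idx)) {
    stop("no formation-energy constant for species: ",
         paste(names(s)[is.na(idx)], collapse = ", "))
  }
  sum(s * constants$dGf0_kJ_mol[idx])
}

#' Re-reference a standard Gibbs energy to biological standard conditions
#'
#' Converts a whole-reaction standard Gibbs energy (unit H+ activity,
#' i.e. pH 0) to the biological standard referenced at `pH_ref`
#' (conventionally 7), and normalizes per electron-mol. The correction
#' adds `R T ln(10) pH_ref` per proton consumed by the reaction (and
#' subtracts it per proton produced).
#'
#' @param dG0 Standard Gibbs energy, kJ per mol reaction.
#' @param reaction A [chem_reaction()]; its H+ coefficient and
#'   `n_electrons` are used.
#' @param temperature Kelvin (default 298.15).
#' @param pH_ref Reference pH (default 7).
#' @return kJ per electron-mol at the reference pH.
#' @examples
#' rx <- reaction_nap_iron_oxidation()
#' adjust_to_biological_standard(delta_g_standard(rx), rx)
#' @export
adjust_to_biological_standard <- function(dG0, reaction,
                                          temperature = .T_STANDARD,
                                          pH_ref = 7) {
  n <- reaction$n_electrons
  if (n <= 0) stop("cannot normalize per electron-mol: n_electrons must be > 0")
  nu_h <- reaction$stoichiometry["H+"]
  nu_h <- if (is.na(nu_h)) 0 else unname(nu_h)
  (dG0 + .RGAS * temperature * .LN10 * pH_ref * (-nu_h)) / n
}

#' Standard Gibbs energy at biological standard conditions, per e-mol
#'
#' Convenience wrapper: [delta_g_standard()] followed by
#' [adjust_to_biological_standard()].
#'
#' @inheritParams adjust_to_biological_standard
#' @inheritParams delta_g_standard
#' @return kJ per electron-mol at `pH_ref`.
#' @export
delta_g_standard_biological <- function(reaction,
                                        constants = formation_energies(),
                                        temperature = .T_STANDARD,
                                        pH_ref = 7) {
  adjust_to_biological_standard(delta_g_standard(reaction, constants),
                                reaction, temperature, pH_ref)
}

#' In-situ thermodynamic conditions
#'
#' Bundles temperature, pH and species activities, applying a stated
#' substitution policy to censored (below-detection) species. Activities
#' are treated as molar concentrations (unit activity coefficients);
#' solids and water have unit activity and need not be listed.
#'
#' @param temperature Kelvin, > 0.
#' @param pH In (0, 14).
#' @param activities Named numeric vector of activities (mol/L for
#'   aqueous species), strictly positive.
#' @param censored Named numeric vector of detection limits (mol/L) for
#'   species observed only as "below detection"; their activity is
#'   substituted per `policy`.
#' @param policy Substitution for censored species: `"limit"` uses the
#'   detection limit (conservative default), `"half_limit"` uses half of
#'   it. Substituting zero is rejected because log-activities would be
#'   undefined.
#' @return An object of class `thermo_conditions`.
#' @examples
#' thermo_conditions(283.15, 7,
#'   activities = c("Fe2+" = 236e-6, "Fe3+" = 2e-18),
#'   censored = c("NO3-" = 1e-6, "NO2-" = 0.2e-6))
#' @export
thermo_conditions <- function(temperature, pH, activities = numeric(),
                              censored = numeric(),
                              policy = c("limit", "half_limit")) {
  policy <- match.arg(policy)
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  if (length(censored) > 0) {
    sub <- switch(policy, limit = censored, half_limit = censored / 2)
    activities[names(censored)] <- sub
  }
  if (any(activities <= 0)) {
    stop("activities must be strictly positive: ",
         paste(names(activities)[activities <= 0], collapse = ", "))
  }
  structure(
    list(temperature = temperature, pH = pH, activities = activities,
         censored = names(censored), policy = policy),
    class = "thermo_conditions"
  )
}

#' In-situ Gibbs free energy per electron-mol
#'
#' Applies the concentration correction `dG' = dG0' + R T ln Q` with the
#' reaction quotient built from in-situ activities and per-electron
#' normalized stoichiometric exponents. H+ and OH- are excluded from Q
#' (their contribution is carried by the pH-referenced `dG0_prime`); if
#' the in-situ pH differs from `pH_ref`, the proton term is re-referenced
#' through the H+ stoichiometry. Solids and liquid water take unit
#' activity; every other participating species must have an activity in
#' `conditions` (a missing aqueous activity is an error, never a silent
#' unit default).
#'
#' @param dG0_prime Biological-standard Gibbs energy, kJ per e-mol at
#'   `pH_ref` (see [adjust_to_biological_standard()]).
#' @param reaction A [chem_reaction()].
#' @param conditions A [thermo_conditions()].
#' @param pH_ref Reference pH of `dG0_prime` (default 7).
#' @param dG0 Optional whole-reaction standard Gibbs energy (kJ/mol) to
#'   carry along in the result.
#' @return An object of class `gibbs_result` with fields `dG0`,
#'   `dG0_prime`, `dG_prime` (kJ per e-mol), `lnQ` (per e-mol),
#'   `temperature` and `pH`.
#' @examples
#' rx <- reaction_nap_iron_oxidation()
#' cond <- thermo_conditions(283.15, 7,
#'   activities = c("Fe2+" = 236e-6, "Fe3+" = 236e-6 * 1e-16),
#'   censored = c("NO3-" = 1e-6, "NO2-" = 0.2e-6))
#' delta_g_insitu(35.2, rx, cond)
#' @export
delta_g_insitu <- function(dG0_prime, reaction, conditions, pH_ref = 7,
                           dG0 = NA_real_) {
  stopifnot(inherits(conditions, "thermo_conditions"))
  n <- reaction$n_electrons
  if (n <= 0) stop("n_electrons must be > 0 for per-e-mol normalization")
  s <- reaction$stoichiometry
  keep <- !(names(s) %in% c("H+", "OH-")) &
    !(reaction$phases %in% c("solid", "liquid"))
  lnQ <- 0
  for (sp in names(s)[keep]) {
    a <- unname(conditions$activities[sp])
    if (is.na(a)) {
      stop("no activity given for aqueous species '", sp,
           "'; unit activity is not assumed")
    }
    if (a <= 0) stop("activity of '", sp, "' must be strictly positive")
    lnQ <- lnQ + (s[[sp]] / n) * log(a)
  }
  nu_h <- if (is.na(s["H+"])) 0 else s[["H+"]]
  rt <- .RGAS * conditions$temperature
  ph_term <- rt * .LN10 * (nu_h / n) * (pH_ref - conditions$pH)
  res <- list(
    dG0 = dG0,
    dG0_prime = dG0_prime,
    dG_prime = dG0_prime + rt * lnQ + ph_term,
    lnQ = lnQ,
    temperature = conditions$temperature,
    pH = conditions$pH
  )
  class(res) <- "gibbs_result"
  res
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat(sprintf("Gibbs energy at %g K, pH %g\n", x$temperature, x$pH))
  cat(sprintf("  dG0'    %8.2f kJ/e-mol\n", x$dG0_prime))
  cat(sprintf("  ln Q    %8.2f (per e-mol)\n", x$lnQ))
  cat(sprintf("  dG'     %8.2f kJ/e-mol\n", x$dG_prime))
  invisible(x)
}

#' Dissolved ferric iron activity from mineral solubility
#'
#' Solves `{Fe3+}{OH-}^3 = Ksp` for the ferric activity in equilibrium
#' with an iron (oxyhydr)oxide at a given pH. Two hydroxide conventions
#' are supported: `"paper"` substitutes `{OH-} = 10^-pH` (the shortcut
#' used in the study this package models, which makes the result
#' `Ksp / 10^(-3 pH)`), while `"kw"` uses the thermodynamically standard
#' `{OH-} = Kw / 10^-pH` with `Kw = 1e-14`. The two differ by a constant
#' factor of `(1e14 * Kw)^-3` (400-fold for the default Kw... i.e. the
#' `paper` convention is the more conservative, higher estimate).
#'
#' @param Ksp Solubility product of the mineral (default 1e-39,
#'   amorphous ferrihydrite).
#' @param pH In (0, 14).
#' @param convention `"paper"` or `"kw"` (see above).
#' @param Kw Water ion product used by the `"kw"` convention.
#' @return Ferric iron activity, mol/L.
#' @examples
#' ferric_activity(1e-39, pH = 7.1)                     # ~2e-18 M
#' ferric_activity(1e-39, pH = 7.1, convention = "kw")  # ~5e-19 M
#' @export
ferric_activity <- function(Ksp = 1e-39, pH, convention = c("paper", "kw"),
                            Kw = .KW) {
  convention <- match.arg(convention)
  if (Ksp <= 0) stop("Ksp must be > 0")
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  oh <- switch(convention,
               paper = 10^(-pH),
               kw = Kw * 10^pH)
  Ksp / oh^3
}

#' Bioenergetic thresholds for proton translocation and ATP synthesis
#'
#' @param pmf_per_proton Minimum energy to translocate one proton across
#'   the cytoplasmic membrane, kJ/mol (default -15).
#' @param atp_synthesis Minimum energy to synthesize one ATP, kJ/mol
#'   (default -45).
#' @return An object of class `energy_thresholds`.
#' @export
energy_thresholds <- function(pmf_per_proton = -15, atp_synthesis = -45) {
  if (pmf_per_proton >= 0 || atp_synthesis >= 0) {
    stop("thresholds must be strictly negative (energy released)")
  }
  structure(list(pmf_per_proton = pmf_per_proton,
                 atp_synthesis = atp_synthesis),
            class = "energy_thresholds")
}

#' Proton translocation and ATP feasibility from an in-situ Gibbs energy
#'
#' Counts whole protons that can be pumped with the energy released per
#' electron-mol (`floor(|dG'| / |pmf|)` for exergonic reactions, 0
#' otherwise) and flags whether one ATP equivalent is affordable
#' (`dG' <= atp_synthesis`).
#'
#' @param dG_prime In-situ Gibbs energy, kJ per e-mol (vectorized).
#' @param thresholds An [energy_thresholds()].
#' @return Data frame with integer `protons` and logical `atp_feasible`.
#' @examples
#' proton_atp_yield(-66)   # 4 protons, ATP feasible
#' @export
proton_atp_yield <- function(dG_prime, thresholds = energy_thresholds()) {
  protons <- ifelse(dG_prime < 0,
                    floor(abs(dG_prime) / abs(thresholds$pmf_per_proton)),
                    0)
  data.frame(protons = as.integer(protons),
             atp_feasible = dG_prime <= thresholds$atp_synthesis)
}

#' Feasibility landscape over substrate/product log-ratio axes
#'
#' Evaluates the in-situ Gibbs energy of a 1-e redox couple on a grid of
#' `x = log10(Fe3+/Fe2+)` and `y = log10(NO2-/NO3-)` (or any analogous
#' product/substrate ratio pair present in the reaction), one layer per
#' intracellular pH. pH enters by re-referencing the biological-standard
#' energy through the reaction's H+ stoichiometry. For each
#' (threshold, pH) pair the closed-form contour line where `dG'` equals
#' the threshold is returned; reactor-condition marker points can be
#' attached.
#'
#' @param reaction A [chem_reaction()] containing both ratio pairs.
#' @param dG0_prime Biological-standard energy at `pH_ref`, kJ per e-mol.
#' @param temperature Kelvin.
#' @param pH Numeric vector of intracellular pH values (>= 1 value).
#' @param x_range,y_range Finite length-2 ranges of the log10 ratio axes.
#' @param n Grid points per axis (>= 2).
#' @param thresholds An [energy_thresholds()].
#' @param x_pair,y_pair Character pairs `c(product, substrate)` defining
#'   the axes (defaults `Fe3+/Fe2+` and `NO2-/NO3-`).
#' @param markers Optional data frame with columns `x`, `y` (and
#'   optionally `label`) of evaluated reactor conditions.
#' @param pH_ref Reference pH of `dG0_prime` (default 7).
#' @return Object of class `feasibility_grid`: a list with `grid`
#'   (long data frame `x`, `y`, `pH`, `dG`), `contours` (data frame
#'   `pH`, `threshold`, `y`, `x`), and `markers`.
#' @export
feasibility_grid <- function(reaction, dG0_prime, temperature,
                             pH = c(6, 7),
                             x_range = c(-30, 0), y_range = c(-4, 4),
                             n = 61,
                             thresholds = energy_thresholds(),
                             x_pair = c("Fe3+", "Fe2+"),
                             y_pair = c("NO2-", "NO3-"),
                             markers = NULL, pH_ref = 7) {
  if (length(pH) < 1) stop("at least one pH value is required")
  if (n < 2) stop("grid needs at least 2 points per axis")
  if (any(!is.finite(c(x_range, y_range)))) stop("axis ranges must be finite")
  s <- reaction$stoichiometry
  ne <- reaction$n_electrons
  if (ne <= 0) stop("n_electrons must be > 0")
  coef_of <- function(pair) {
    a <- s[pair[1]]; b <- s[pair[2]]
    if (is.na(a) || is.na(b)) {
      stop("reaction does not contain the ratio pair ",
           paste(pair, collapse = "/"))
    }
    if (abs(a + b) > 1e-8) {
      stop("ratio pair ", paste(pair, collapse = "/"),
           " must have opposite coefficients")
    }
    a / ne
  }
  xc <- coef_of(x_pair)
  yc <- coef_of(y_pair)
  nu_h <- if (is.na(s["H+"])) 0 else s[["H+"]]
  rt10 <- .RGAS * temperature * .LN10
  xs <- seq(x_range[1], x_range[2], length.out = n)
  ys <- seq(y_range[1], y_range[2], length.out = n)

  grid <- expand.grid(x = xs, y = ys, pH = pH, KEEP.OUT.ATTRS = FALSE)
  dG0p_at <- function(ph) dG0_prime + rt10 * (nu_h / ne) * (pH_ref - ph)
  grid$dG <- dG0p_at(grid$pH) + rt10 * (xc * grid$x + yc * grid$y)

  thr <- unlist(thresholds)
  contours <- do.call(rbind, lapply(pH, function(ph) {
    do.call(rbind, lapply(names(thr), function(tn) {
      data.frame(pH = ph, threshold = unname(thr[tn]), kind = tn, y = ys,
                 x = (thr[[tn]] - dG0p_at(ph)) / (rt10 * xc) - (yc / xc) * ys)
    }))
  }))
  structure(list(grid = grid, contours = contours, markers = markers,
                 dG0_prime = dG0_prime, temperature = temperature,
                 x_pair = x_pair, y_pair = y_pair),
            class = "feasibility_grid")
}

#' @export
print.feasibility_grid <- function(x, ...) {
  cat(sprintf(
    "Feasibility grid: %d cells, log10(%s/%s) vs log10(%s/%s), T = %g K\n",
    nrow(x$grid), x$x_pair[1], x$x_pair[2], x$y_pair[1], x$y_pair[2],
    x$temperature))
  cat(sprintf("  dG' range: [%.1f, %.1f] kJ/e-mol\n",
              min(x$grid$dG), max(x$grid$dG)))
  invisible(x)
}

#' @describeIn feasibility_grid Long-format export (x, y, pH, dG).
#' @param x A `feasibility_grid`.
#' @param ... Unused.
#' @export
as.data.frame.feasibility_grid <- function(x, ...) x$grid
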