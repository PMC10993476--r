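#' Operating-phase window of the reactor time series
#'
#' @param name Window name, conventionally `"nitrate_limited"` or
#'   `"iron_limited"`.
#' @param day_start,day_end Inclusive day range, within operation days
#'   0-120 and non-inverted.
#' @return Object of class `phase_window`.
#' @export
phase_window <- function(name, day_start, day_end) {
  if (day_end < day_start) stop("day_end must be >= day_start")
  structure(list(name = name, day_start = day_start, day_end = day_end),
            class = "phase_window")
}

#' Default operating phases of the pilot filter
#'
#' Nitrate-limited steady state on days 21-77 (the window over which the
#' steady-state water characteristics were averaged) and iron limitation
#' from day 106 onward, after stepwise nitrate dosing.
#'
#' @return Named list of [phase_window()]s.
#' @export
default_phase_windows <- function() {
  list(nitrate_limited = phase_window("nitrate_limited", 21, 77),
       iron_limited = phase_window("iron_limited", 106, 120))
}

.censor_substitute <- function(value, below, limit,
                               policy = c("zero", "limit", "half_limit")) {
  policy <- match.arg(policy)
  sub <- switch(policy,
                zero = 0,
                limit = limit,
                half_limit = limit / 2)
  ifelse(below, sub, value)
}

.series_check <- function(series) {
  needed <- c("day", "stream", "species", "value", "below_detection",
              "detection_limit")
  missing <- setdiff(needed, names(series))
  if (length(missing) > 0) {
    stop("reactor series is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(series$value < 0, na.rm = TRUE)) {
    stop("reactor series contains negative concentrations")
  }
  invisible(series)
}

#' Per-day removal of a species from a censored reactor series
#'
#' Computes influent minus effluent concentration per day within a phase
#' window. Below-detection values are substituted according to `policy`
#' before differencing (`"zero"` by default: a species consistently below
#' detection in the effluent is read as fully removed). Negative removals
#' (measurement noise) are clipped to zero; the number of clipped days is
#' recorded in the `n_clipped` attribute, never silently dropped.
#'
#' @param series Long-format reactor table with columns `day`, `stream`
#'   (`"influent"`/`"effluent"`), `species`, `value` (umol/L),
#'   `below_detection`, `detection_limit`.
#' @param species Species identifier, e.g. `"Fe2+"`.
#' @param window A [phase_window()]; `NULL` uses all days.
#' @param policy Censoring substitution: `"zero"`, `"limit"` or
#'   `"half_limit"`.
#' @return Data frame with columns `day`, `influent`, `effluent`,
#'   `removal`, `clipped`; attribute `n_clipped`.
#' @export
removal <- function(series, species, window = NULL,
                    policy = c("zero", "limit", "half_limit")) {
  policy <- match.arg(policy)
  .series_check(series)
  sp <- series[series$species == species, , drop = FALSE]
  if (!is.null(window)) {
    sp <- sp[sp$day >= window$day_start & sp$day <= window$day_end, ,
             drop = FALSE]
  }
  for (stream in c("influent", "effluent")) {
    if (!any(sp$stream == stream)) {
      stop("species '", species, "' has no ", stream,
           " records in the window")
    }
  }
  sp$value_sub <- .censor_substitute(sp$value, sp$below_detection,
                                     sp$detection_limit, policy)
  inf <- sp[sp$stream == "influent", c("day", "value_sub")]
  eff <- sp[sp$stream == "effluent", c("day", "value_sub")]
  m <- merge(inf, eff, by = "day", suffixes = c("_in", "_out"))
  m <- m[order(m$day), ]
  raw <- m$value_sub_in - m$value_sub_out
  out <- data.frame(day = m$day, influent = m$value_sub_in,
                    effluent = m$value_sub_out,
                    removal = pmax(raw, 0), clipped = raw < 0)
  attr(out, "n_clipped") <- sum(raw < 0)
  out
}

#' Observed Fe2+:NO3- consumption ratio
#'
#' Daily molar removal ratio of ferrous iron to nitrate over a phase
#' window. The headline estimator is the mean (and sd) of daily ratios,
#' the form in which reactor consumption ratios are conventionally
#' reported; the ratio of mean removals is returned alongside. Days with
#' zero nitrate removal are excluded and counted.
#'
#' @inheritParams removal
#' @param fe_species,no3_species Species identifiers of the donor and
#'   acceptor (defaults `"Fe2+"`, `"NO3-"`).
#' @return Object of class `removal_stats`: `mean_ratio`, `sd_ratio`,
#'   `n_days`, `fe_removed_mean`, `no3_removed_mean`, `ratio_of_means`,
#'   `n_excluded`, `n_clipped`.
#' @export
observed_ratio <- function(series, window = NULL,
                           policy = c("zero", "limit", "half_limit"),
                           fe_species = "Fe2+", no3_species = "NO3-") {
  policy <- match.arg(policy)
  fe <- removal(series, fe_species, window, policy)
  no3 <- removal(series, no3_species, window, policy)
  m <- merge(fe, no3, by = "day", suffixes = c("_fe", "_no3"))
  eligible <- m$removal_no3 > 0
  if (!any(eligible)) {
    stop("no days with positive ", no3_species, " removal in the window")
  }
  r <- m$removal_fe[eligible] / m$removal_no3[eligible]
  structure(list(
    mean_ratio = mean(r),
    sd_ratio = if (length(r) > 1) stats::sd(r) else 0,
    n_days = length(r),
    fe_removed_mean = mean(m$removal_fe[eligible]),
    no3_removed_mean = mean(m$removal_no3[eligible]),
    ratio_of_means = mean(m$removal_fe[eligible]) /
      mean(m$removal_no3[eligible]),
    n_excluded = sum(!eligible),
    n_clipped = attr(fe, "n_clipped") + attr(no3, "n_clipped"),
    policy = policy
  ), class = "removal_stats")
}

#' @export
print.removal_stats <- function(x, ...) {
  cat(sprintf("Fe2+:NO3- consumption ratio over %d day(s)\n", x$n_days))
  cat(sprintf("  mean of daily ratios: %.2f +/- %.2f mol/mol\n",
              x$mean_ratio, x$sd_ratio))
  cat(sprintf("  ratio of mean removals: %.2f mol/mol\n", x$ratio_of_means))
  cat(sprintf("  mean removals: Fe %.1f, NO3 %.1f umol/L (policy '%s')\n",
              x$fe_removed_mean, x$no3_removed_mean, x$policy))
  if (x$n_excluded > 0 || x$n_clipped > 0) {
    cat(sprintf("  excluded %d zero-NO3 day(s); clipped %d negative removal(s)\n",
                x$n_excluded, x$n_clipped))
  }
  invisible(x)
}

#' Catabolism-plus-growth yield model
#'
#' Parameters linking the catabolic Fe:NO3 stoichiometry to the observed
#' consumption ratio: 5 mol Fe2+ per mol NO3- from the overall catabolism
#' (10 Fe : 2 NO3, complete denitrification at 5 e- per N), and the
#' fraction `f_growth` of donor electrons invested in biomass rather than
#' catabolism.
#'
#' @param catabolic_fe_per_no3 mol Fe2+ per mol NO3- in pure catabolism
#'   (default 5).
#' @param f_growth Fraction of electrons to growth in `[0, 1)`
#'   (default 0.12).
#' @param electrons_per_fe,electrons_per_no3 Electron bookkeeping per mol
#'   of donor/acceptor (defaults 1 and 5).
#' @return Object of class `yield_model`.
#' @export
yield_model <- function(catabolic_fe_per_no3 = 5, f_growth = 0.12,
                        electrons_per_fe = 1, electrons_per_no3 = 5) {
  if (f_growth < 0 || f_growth >= 1) stop("f_growth must lie in [0, 1)")
  if (catabolic_fe_per_no3 <= 0) stop("catabolic ratio must be > 0")
  structure(list(catabolic_fe_per_no3 = catabolic_fe_per_no3,
                 f_growth = f_growth,
                 electrons_per_fe = electrons_per_fe,
                 electrons_per_no3 = electrons_per_no3),
            class = "yield_model")
}

#' Expected Fe2+:NO3- consumption ratio under a yield model
#'
#' With a fraction `f` of donor electrons diverted to biomass, only
#' `(1 - f)` of the iron oxidized feeds nitrate reduction, inflating the
#' consumption ratio to `catabolic / (1 - f)`: 5 / 0.88 = 5.68 for the
#' default 12% growth investment.
#'
#' @param model A [yield_model()].
#' @return mol Fe2+ per mol NO3-.
#' @examples
#' expected_ratio(yield_model())            # 5.68
#' expected_ratio(yield_model(f_growth = 0))  # 5, pure catabolism
#' @export
expected_ratio <- function(model = yield_model()) {
  stopifnot(inherits(model, "yield_model"))
  model$catabolic_fe_per_no3 / (1 - model$f_growth)
}

#' Upper bound on abiotic (oxygen-driven) iron oxidation
#'
#' Fraction of the observed iron removal attributable to chemical
#' oxidation by dissolved oxygen at its quantification limit, using the
#' 4 Fe2+ : 1 O2 stoichiometry of abiotic ferrous oxidation.
#'
#' @param o2_max Oxygen concentration bound, umol/L.
#' @param fe_removed Iron removal, umol/L (> 0).
#' @return Fraction (1 = 100%).
#' @examples
#' abiotic_o2_fraction(3, 58)   # 0.207
#' @export
abiotic_o2_fraction <- function(o2_max, fe_removed) {
  if (fe_removed <= 0) stop("fe_removed must be > 0")
  if (o2_max < 0) stop("o2_max must be >= 0")
  4 * o2_max / fe_removed
}

#' Iron accumulation closure
#'
#' Since no ferric iron leaves in the effluent, every mole of dissolved
#' iron removed accumulates in the reactor as solids. Sums the daily
#' dissolved-iron removal over a window and partitions the accumulated
#' iron over a stated solids composition (by default >= 94% ferrihydrite
#' and the remainder magnetite, the mineralogy observed in the filter).
#'
#' @inheritParams removal
#' @param solids Named fractions summing to 1 over which accumulated iron
#'   is partitioned.
#' @param fe_species Dissolved iron species (default `"Fe2+"`).
#' @return List with `per_day` (data frame), `total_accumulated` and
#'   `mean_daily` (umol/L), `partition` (named umol/L), and
#'   `negative_days`.
#' @export
iron_closure <- function(series, window = NULL,
                         solids = c(ferrihydrite = 0.94, magnetite = 0.06),
                         policy = c("zero", "limit", "half_limit"),
                         fe_species = "Fe2+") {
  policy <- match.arg(policy)
  if (abs(sum(solids) - 1) > 1e-8) stop("solids fractions must sum to 1")
  fe <- removal(series, fe_species, window, policy)
  neg <- fe$day[fe$clipped]
  if (length(neg) > 0) {
    warning("negative iron accumulation on day(s): ",
            paste(neg, collapse = ", "))
  }
  total <- sum(fe$removal)
  list(per_day = fe,
       total_accumulated = total,
       mean_daily = mean(fe$removal),
       partition = solids * total,
       negative_days = neg)
}
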