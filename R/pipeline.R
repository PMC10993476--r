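# Config handling ---------------------------------------------------------

.load_config <- function(config, allowed, defaults) {
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  out <- defaults
  for (k in names(config)) {
    # merge named-list blocks (partial overrides), replace everything else
    if (is.list(config[[k]]) && length(names(config[[k]])) &&
        is.list(out[[k]]) && length(names(out[[k]]))) {
      out[[k]] <- utils::modifyList(out[[k]], config[[k]])
    } else {
      out[[k]] <- config[[k]]
    }
  }
  out
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)), f)
  unname(tools::md5sum(f))
}

.report_meta <- function(config, seed = NULL) {
  list(package = "ndfo",
       version = as.character(utils::packageVersion("ndfo")),
       seed = seed,
       config_hash = .config_hash(config))
}

# Thermodynamics report ----------------------------------------------------

.default_thermo_scenarios <- function() {
  # Two named readings of the reactor condition: the conservative
  # order-of-magnitude ferric/ferrous ratio of 1e-16, and the ratio implied
  # by ferrihydrite solubility equilibrium at the operating pH.
  list(
    list(name = "reactor_conservative", temperature = 283.15, pH = 7.0,
         fe2 = 236e-6, no3 = 1e-6, no2 = 0.2e-6, fe3_fe2_ratio = 1e-16),
    list(name = "reactor_ksp_equilibrium", temperature = 283.15, pH = 7.1,
         fe2 = 236e-6, no3 = 1e-6, no2 = 0.2e-6)
  )
}

#' Thermodynamic feasibility report
#'
#' Computes, for the nap-type iron-oxidation couple, the standard Gibbs
#' energy, its biological-standard (pH 7) per-electron value, and the
#' in-situ value with proton/ATP yields for every scenario, under both
#' hydroxide conventions for solubility-derived ferric activities, plus
#' the feasibility grid. Scenarios either state a `fe3_fe2_ratio`
#' directly or have the ferric activity computed from `Ksp` at the
#' scenario pH (nitrate and nitrite entered at their detection limits
#' are treated as censored at those limits).
#'
#' @param config `NULL`, a list, or a YAML/JSON path with any of the
#'   keys `scenarios` (list of scenario blocks with `name`,
#'   `temperature` (K), `pH`, `fe2`, `no3`, `no2` (mol/L), optional
#'   `fe3_fe2_ratio`), `Ksp`, `thresholds` (`pmf_per_proton`,
#'   `atp_synthesis`), `grid` (`pH`, `x_range`, `y_range`, `n`), and
#'   `censoring_policy` (`"limit"` or `"half_limit"`).
#' @return Object of class `ndfo_thermo_report`: list with `meta`,
#'   `dG0`, `dG0_prime`, `scenarios` (data frame) and `grid`
#'   (a [feasibility_grid()]).
#' @export
run_thermo <- function(config = NULL) {
  cfg <- .load_config(
    config,
    allowed = c("scenarios", "Ksp", "thresholds", "grid",
                "censoring_policy"),
    defaults = list(
      scenarios = .default_thermo_scenarios(),
      Ksp = 1e-39,
      thresholds = list(pmf_per_proton = -15, atp_synthesis = -45),
      grid = list(pH = c(6, 7), x_range = c(-30, 0), y_range = c(-4, 4),
                  n = 61),
      censoring_policy = "limit"
    )
  )
  thr <- energy_thresholds(cfg$thresholds$pmf_per_proton,
                           cfg$thresholds$atp_synthesis)
  constants <- formation_energies()
  rx <- reaction_nap_iron_oxidation(constants)
  dG0 <- delta_g_standard(rx, constants)
  dG0p <- adjust_to_biological_standard(dG0, rx)

  rows <- list()
  for (sc in cfg$scenarios) {
    for (conv in c("paper", "kw")) {
      if (!is.null(sc$fe3_fe2_ratio)) {
        fe3 <- sc$fe3_fe2_ratio * sc$fe2
        ratio_source <- "stated_ratio"
        if (conv == "kw") next  # ratio given; convention plays no role
      } else {
        fe3 <- ferric_activity(cfg$Ksp, sc$pH, convention = conv)
        ratio_source <- paste0("ksp_", conv)
      }
      cond <- thermo_conditions(
        sc$temperature, sc$pH,
        activities = c("Fe2+" = sc$fe2, "Fe3+" = fe3),
        censored = c("NO3-" = sc$no3, "NO2-" = sc$no2),
        policy = cfg$censoring_policy
      )
      g <- delta_g_insitu(dG0p, rx, cond, dG0 = dG0)
      y <- proton_atp_yield(g$dG_prime, thr)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc$name, ratio_source = ratio_source,
        temperature = sc$temperature, pH = sc$pH,
        fe3_activity = fe3, fe3_fe2_ratio = fe3 / sc$fe2,
        lnQ = g$lnQ, dG_prime = g$dG_prime,
        protons = y$protons, atp_feasible = y$atp_feasible,
        stringsAsFactors = FALSE
      )
    }
  }
  scen <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scenario = character(), ratio_source = character(),
               temperature = numeric(), pH = numeric(),
               fe3_activity = numeric(), fe3_fe2_ratio = numeric(),
               lnQ = numeric(), dG_prime = numeric(), protons = integer(),
               atp_feasible = logical())
  markers <- if (nrow(scen)) {
    data.frame(x = log10(scen$fe3_fe2_ratio), y = log10(0.2),
               label = scen$scenario)
  } else NULL
  grid_T <- if (length(cfg$scenarios)) cfg$scenarios[[1]]$temperature else
    283.15
  grid <- feasibility_grid(
    rx, dG0p, temperature = grid_T,
    pH = cfg$grid$pH, x_range = unlist(cfg$grid$x_range),
    y_range = unlist(cfg$grid$y_range), n = cfg$grid$n, thresholds = thr,
    markers = markers
  )
  structure(list(meta = .report_meta(cfg), dG0 = dG0, dG0_prime = dG0p,
                 scenarios = scen, grid = grid),
            class = "ndfo_thermo_report")
}

# Reactor report -----------------------------------------------------------

#' Reactor mass-balance report
#'
#' Removal statistics per phase window, the observed-versus-expected
#' Fe2+:NO3- consumption ratio, the abiotic-oxygen upper bound and the
#' iron accumulation closure, on either a supplied/censored reactor
#' series, a simulation, or (default) the packaged steady-state fixture.
#'
#' @param config `NULL`, a list, or a YAML/JSON path with any of the
#'   keys `series` (a reactor data frame or delimited-file path),
#'   `simulate` (a [reactor_sim_config()] or `TRUE` for defaults),
#'   `windows` (list of [phase_window()]s), `policy`
#'   (censoring: `"zero"`, `"limit"`, `"half_limit"`), `f_growth`,
#'   `o2_max` (umol/L), `solids` (named fractions), `seed`.
#' @return Object of class `ndfo_reactor_report`: `meta`, per-window
#'   `stats` ([observed_ratio()] results), `expected_ratio`,
#'   `abiotic_o2_fraction` and `closure` per window.
#' @export
run_reactor <- function(config = NULL) {
  cfg <- .load_config(
    config,
    allowed = c("series", "simulate", "windows", "policy", "f_growth",
                "o2_max", "solids", "seed"),
    defaults = list(series = NULL, simulate = NULL, windows = NULL,
                    policy = "zero", f_growth = 0.12, o2_max = 3,
                    solids = c(ferrihydrite = 0.94, magnetite = 0.06),
                    seed = 1)
  )
  if (!is.null(cfg$simulate)) {
    sim_cfg <- if (isTRUE(cfg$simulate)) {
      reactor_sim_config(seed = cfg$seed)
    } else cfg$simulate
    series <- simulate_reactor(sim_cfg)
    if (is.null(cfg$windows)) {
      cfg$windows <- list(
        nitrate_limited = phase_window("nitrate_limited", 21, 77),
        iron_limited = phase_window("iron_limited", 106, 120)
      )
    }
  } else if (!is.null(cfg$series)) {
    series <- if (is.character(cfg$series)) {
      utils::read.delim(cfg$series, stringsAsFactors = FALSE)
    } else cfg$series
  } else {
    series <- pilot_fixture()$reactor
  }
  if (is.null(cfg$windows)) {
    cfg$windows <- list(
      nitrate_limited = phase_window("nitrate_limited", 21, 77)
    )
  }
  stats_w <- list(); abiotic <- list(); closure <- list()
  for (wn in names(cfg$windows)) {
    w <- cfg$windows[[wn]]
    st <- observed_ratio(series, w, policy = cfg$policy)
    stats_w[[wn]] <- st
    abiotic[[wn]] <- abiotic_o2_fraction(cfg$o2_max, st$fe_removed_mean)
    closure[[wn]] <- iron_closure(series, w, solids = cfg$solids,
                                  policy = cfg$policy)
  }
  structure(list(meta = .report_meta(cfg, seed = cfg$seed),
                 stats = stats_w,
                 expected_ratio = expected_ratio(
                   yield_model(f_growth = cfg$f_growth)),
                 abiotic_o2_fraction = unlist(abiotic),
                 closure = closure),
            class = "ndfo_reactor_report")
}

# Community report ----------------------------------------------------------

#' Community function report
#'
#' Genome-function calls (iron oxidation, denitrification steps, carbon
#' fixation, MIMAG quality, niche), phylum-level abundance aggregation,
#' top-n denitrification coverage with complementarity edges, and the
#' minimal covering genome set, on supplied tables or (default) the
#' packaged pilot community.
#'
#' @param config `NULL`, a list, or a YAML/JSON path with any of the
#'   keys `genes` (long `mag_id`/`gene` data frame or path), `mags`
#'   (metadata data frame or path), `top_n` (default 5),
#'   `require_all_subunits` (default `TRUE`).
#' @return Object of class `ndfo_community_report`: `meta`, `calls`,
#'   `phylum_abundance`, `niche_abundance`, `coverage`, `minimal_cover`.
#' @export
run_community <- function(config = NULL) {
  cfg <- .load_config(
    config,
    allowed = c("genes", "mags", "top_n", "require_all_subunits"),
    defaults = list(genes = NULL, mags = NULL, top_n = 5,
                    require_all_subunits = TRUE)
  )
  if (is.null(cfg$genes) || is.null(cfg$mags)) {
    fx <- pilot_fixture()
    if (is.null(cfg$genes)) cfg$genes <- fx$genes
    if (is.null(cfg$mags)) cfg$mags <- fx$mags
  }
  read_maybe <- function(x) {
    if (is.character(x)) utils::read.delim(x, comment.char = "#",
                                           stringsAsFactors = FALSE) else x
  }
  genes <- read_maybe(cfg$genes)
  mags <- read_maybe(cfg$mags)
  profile <- mags[, intersect(c("mag_id", "taxonomy", "phylum",
                                "relative_abundance"), names(mags))]
  calls <- call_functions(genes, mags,
                          require_all_subunits = cfg$require_all_subunits)
  structure(list(
    meta = .report_meta(cfg),
    calls = calls,
    phylum_abundance = aggregate_abundance(profile, "phylum"),
    niche_abundance = aggregate_abundance(profile, "niche", calls = calls),
    coverage = community_coverage(calls, profile, top_n = cfg$top_n),
    minimal_cover = minimal_denit_cover(calls)
  ), class = "ndfo_community_report")
}

#' Run the full analysis pipeline
#'
#' Chains the thermodynamics, reactor and community reports with a
#' single config and seed; by default every stage runs on the packaged
#' pilot fixture, requiring no external data.
#'
#' @param config `NULL`, a list, or a YAML/JSON path with optional
#'   blocks `thermo`, `reactor`, `community` (each passed to its
#'   `run_*()`) and `seed`.
#' @return List with elements `thermo`, `reactor`, `community` and
#'   `meta`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- .load_config(config,
                      allowed = c("thermo", "reactor", "community", "seed"),
                      defaults = list(thermo = NULL, reactor = NULL,
                                      community = NULL, seed = 1))
  list(thermo = run_thermo(cfg$thermo),
       reactor = run_reactor(cfg$reactor),
       community = run_community(cfg$community),
       meta = .report_meta(cfg, seed = cfg$seed))
}

#' @export
print.ndfo_thermo_report <- function(x, ...) {
  cat(sprintf("NDFO thermodynamics: dG0 = %.2f kJ/mol, dG0' = %.2f kJ/e-mol\n",
              x$dG0, x$dG0_prime))
  print(x$scenarios[, c("scenario", "ratio_source", "dG_prime", "protons",
                        "atp_feasible")], row.names = FALSE)
  invisible(x)
}

#' @export
print.ndfo_reactor_report <- function(x, ...) {
  cat("NDFO reactor mass balance\n")
  for (wn in names(x$stats)) {
    s <- x$stats[[wn]]
    cat(sprintf("  %s: ratio %.2f +/- %.2f (n = %d), abiotic O2 <= %.1f%%\n",
                wn, s$mean_ratio, s$sd_ratio, s$n_days,
                100 * x$abiotic_o2_fraction[[wn]]))
  }
  cat(sprintf("  expected ratio (yield model): %.2f mol/mol\n",
              x$expected_ratio))
  invisible(x)
}

#' @export
print.ndfo_community_report <- function(x, ...) {
  cat(sprintf("NDFO community: %d genomes, %d iron oxidizer(s)\n",
              nrow(x$calls), sum(x$calls$iron_oxidation)))
  cat("  phylum abundance (%):\n")
  print(round(x$phylum_abundance, 1))
  cat(sprintf("  top-%d denitrification complete: %s\n",
              length(x$coverage$mags), x$coverage$complete))
  invisible(x)
}
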