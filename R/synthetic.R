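# md5 of the packaged fixture files; guards against silent corruption
.FIXTURE_MD5 <- c(
  pilot_mags.tsv = "57282642dfd6f76170d38cc56891426d",
  pilot_mag_genes.tsv = "5ea7296bd9b475a8baf96403cf4f2f63",
  pilot_steady_state.tsv = "249221d30e3386f4ec8125f80ccad86a"
)

#' Packaged pilot-filter reference dataset
#'
#' Loads the packaged reconstruction of the pilot-scale groundwater
#' filter study data: the 13-MAG community table (taxonomy, abundance,
#' genome quality metrics), the per-MAG marker-gene sets encoding each
#' genome's published capabilities, the steady-state influent/effluent
#' water characteristics, and a constant daily reactor series built from
#' the steady-state means over the nitrate-limited window (days 21-77).
#' File checksums are verified on load.
#'
#' @return List with elements `mags` (genome metadata), `genes`
#'   (long `mag_id`/`gene` table), `profile` (`mag_id`, `taxonomy`,
#'   `phylum`, `relative_abundance`), `steady_state` (per-species stream
#'   summaries) and `reactor` (long censored reactor series, umol/L).
#' @examples
#' fx <- pilot_fixture()
#' nrow(fx$mags)   # 13
#' @export
pilot_fixture <- function() {
  paths <- vapply(names(.FIXTURE_MD5), function(f) {
    system.file("extdata", f, package = "ndfo")
  }, character(1))
  sums <- tools::md5sum(paths)
  bad <- names(.FIXTURE_MD5)[sums != .FIXTURE_MD5]
  if (length(bad) > 0) {
    stop("fixture integrity check failed for: ", paste(bad, collapse = ", "))
  }
  mags <- utils::read.delim(paths[["pilot_mags.tsv"]], comment.char = "#",
                            stringsAsFactors = FALSE)
  genes <- utils::read.delim(paths[["pilot_mag_genes.tsv"]],
                             comment.char = "#", stringsAsFactors = FALSE)
  ss <- utils::read.delim(paths[["pilot_steady_state.tsv"]],
                          comment.char = "#", stringsAsFactors = FALSE)
  list(
    mags = mags,
    genes = genes,
    profile = mags[, c("mag_id", "taxonomy", "phylum",
                       "relative_abundance")],
    steady_state = ss,
    reactor = steady_state_series(ss, days = 21:77)
  )
}

#' Expand a steady-state summary into a constant daily reactor series
#'
#' Builds a long-format censored reactor series holding every species at
#' its steady-state stream mean on each day (below-detection entries at
#' their detection limit, flagged). Species with non-molar units (DOC)
#' are carried through but typically excluded from molar ratio analyses.
#'
#' @param steady_state Data frame as in `pilot_fixture()$steady_state`.
#' @param days Integer vector of days to replicate.
#' @return Long reactor series data frame.
#' @export
steady_state_series <- function(steady_state, days = 21:77) {
  rows <- list()
  for (i in seq_len(nrow(steady_state))) {
    r <- steady_state[i, ]
    for (stream in c("influent", "effluent")) {
      bd <- r[[paste0(stream, "_below_detection")]]
      val <- r[[paste0(stream, "_mean")]]
      if (isTRUE(bd)) val <- r$detection_limit
      rows[[length(rows) + 1]] <- data.frame(
        day = days, stream = stream, species = r$species, value = val,
        below_detection = isTRUE(bd), detection_limit = r$detection_limit,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reactor simulation configuration
#'
#' Defaults emulate the pilot filter: constant groundwater Fe2+ of
#' 236 +/- 4 umol/L; influent nitrate at the natural 8.1 +/- 2.1 umol/L
#' during the nitrate-limited steady state (days 1-77), stepped up to
#' 13.5 +/- 1.5 and 20.2 +/- 2.4 (still nitrate-limited) and finally
#' 83.8 +/- 0.6 umol/L (iron-limited) over the 120-day run; a true
#' consumption ratio of 7.1 mol Fe2+ per mol NO3-; detection limits of
#' 1 (NO3-), 0.2 (NO2-) and 3 (O2) umol/L; and Gaussian effluent
#' measurement noise (sd 5 umol/L for Fe2+, 0.3 for NO3-).
#'
#' @param phases List of phase blocks, each a list with `name`
#'   (`"nitrate_limited"`/`"iron_limited"`), `days` (integer vector),
#'   `no3_mean`, `no3_sd`, `fe_mean`, `fe_sd` (umol/L).
#' @param true_ratio Underlying mol Fe2+ consumed per mol NO3- (> 0).
#' @param detection_limits Named umol/L detection limits.
#' @param effluent_noise_sd Named per-species Gaussian sd for effluent
#'   measurement noise (umol/L); sds must be >= 0.
#' @param seed Integer seed; mandatory for reproducible pipeline runs.
#' @return Object of class `reactor_sim_config`.
#' @export
reactor_sim_config <- function(
    phases = list(
      list(name = "nitrate_limited", days = 1:77,
           no3_mean = 8.1, no3_sd = 2.1, fe_mean = 236, fe_sd = 4),
      list(name = "nitrate_limited", days = 78:90,
           no3_mean = 13.5, no3_sd = 1.5, fe_mean = 236, fe_sd = 4),
      list(name = "nitrate_limited", days = 91:105,
           no3_mean = 20.2, no3_sd = 2.4, fe_mean = 236, fe_sd = 4),
      list(name = "iron_limited", days = 106:120,
           no3_mean = 83.8, no3_sd = 0.6, fe_mean = 236, fe_sd = 4)
    ),
    true_ratio = 7.1,
    detection_limits = c("NO3-" = 1, "NO2-" = 0.2, "O2" = 3),
    effluent_noise_sd = c("Fe2+" = 5, "NO3-" = 0.3),
    seed = 1) {
  if (true_ratio <= 0) stop("true_ratio must be > 0")
  for (p in phases) {
    if (length(p$days) < 1) stop("each phase needs at least one day")
    if (any(c(p$no3_sd, p$fe_sd) < 0)) stop("phase sds must be >= 0")
    if (any(c(p$no3_mean, p$fe_mean) < 0)) {
      stop("phase means must be >= 0")
    }
  }
  if (any(effluent_noise_sd < 0)) stop("noise sds must be >= 0")
  alldays <- unlist(lapply(phases, `[[`, "days"))
  if (anyDuplicated(alldays)) stop("phase day ranges overlap")
  structure(list(phases = phases, true_ratio = true_ratio,
                 detection_limits = detection_limits,
                 effluent_noise_sd = effluent_noise_sd, seed = seed),
            class = "reactor_sim_config")
}

# Gaussian draw truncated at zero (concentrations cannot be negative)
.rnorm_pos <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

#' Simulate a censored reactor time series
#'
#' Per day: draw influent NO3- and Fe2+ from the phase's truncated
#' Gaussians; apply limiting-nutrient logic (nitrate removal is capped
#' by the available iron at the true ratio; iron removal is
#' `true_ratio` times the nitrate removal); add Gaussian measurement
#' noise to the effluents; censor every value below its detection limit
#' (flagged, value set to the limit). The pre-noise, pre-censoring truth
#' is attached as the `"truth"` attribute so mass-balance construction
#' can be verified. Reproducible under the config seed.
#'
#' @param config A [reactor_sim_config()].
#' @return Long reactor series data frame (columns as in [removal()]
#'   plus `phase`), with attribute `truth`.
#' @export
simulate_reactor <- function(config = reactor_sim_config()) {
  stopifnot(inherits(config, "reactor_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dl <- config$detection_limits
  noise <- config$effluent_noise_sd
  rows <- list()
  truth <- list()
  for (p in config$phases) {
    nd <- length(p$days)
    no3_in <- .rnorm_pos(nd, p$no3_mean, p$no3_sd)
    fe_in <- .rnorm_pos(nd, p$fe_mean, p$fe_sd)
    no3_rem <- pmin(no3_in, fe_in / config$true_ratio)
    fe_rem <- config$true_ratio * no3_rem
    no3_eff <- no3_in - no3_rem
    fe_eff <- fe_in - fe_rem
    truth[[length(truth) + 1]] <- data.frame(
      day = p$days, phase = p$name, no3_influent = no3_in,
      fe_influent = fe_in, no3_removal = no3_rem, fe_removal = fe_rem,
      no3_effluent = no3_eff, fe_effluent = fe_eff
    )
    obs <- function(species, stream, value) {
      sdv <- if (stream == "effluent" && species %in% names(noise)) {
        noise[[species]]
      } else 0
      v <- .rnorm_pos(length(value), value, sdv)
      lim <- if (species %in% names(dl)) dl[[species]] else 0
      bd <- v < lim
      data.frame(day = p$days, stream = stream, species = species,
                 value = ifelse(bd, lim, v), below_detection = bd,
                 detection_limit = lim, phase = p$name,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- rbind(
      obs("NO3-", "influent", no3_in), obs("NO3-", "effluent", no3_eff),
      obs("Fe2+", "influent", fe_in), obs("Fe2+", "effluent", fe_eff),
      obs("NO2-", "influent", rep(0, nd)), obs("NO2-", "effluent", rep(0, nd)),
      obs("O2", "influent", rep(0, nd)), obs("O2", "effluent", rep(0, nd))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Community simulation configuration
#'
#' Emulates the statistical structure of the pilot community: abundances
#' from a symmetric Dirichlet-type draw (normalized gamma variates) and
#' independent per-function marker prevalences, whose defaults are the
#' observed frequencies among the 13 pilot MAGs.
#'
#' @param n_mags Number of genomes (>= 1).
#' @param concentration Dirichlet concentration parameter (> 0); small
#'   values give the skewed, few-dominants profile typical of
#'   enrichments.
#' @param prevalence Named probabilities in `[0, 1]` for
#'   `iron_oxidation`, the four denitrification steps and
#'   `carbon_fixation`.
#' @param seed Integer seed.
#' @return Object of class `community_sim_config`.
#' @export
community_sim_config <- function(
    n_mags = 13, concentration = 0.8,
    prevalence = c(iron_oxidation = 5 / 13, NO3_to_NO2 = 9 / 13,
                   NO2_to_NO = 9 / 13, NO_to_N2O = 3 / 13,
                   N2O_to_N2 = 3 / 13, carbon_fixation = 6 / 13),
    seed = 1) {
  if (n_mags < 1) stop("n_mags must be >= 1")
  if (concentration <= 0) stop("concentration must be > 0")
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  structure(list(n_mags = n_mags, concentration = concentration,
                 prevalence = prevalence, seed = seed),
            class = "community_sim_config")
}

#' Simulate a MAG community with marker genes
#'
#' Draws relative abundances from a symmetric Dirichlet (normalized to
#' 100%) and assigns marker genes per capability with the configured
#' prevalences (capabilities are encoded with their canonical markers:
#' cyc2 for iron oxidation, napAB / nirK / norBC / nosZ for the
#' denitrification steps, rbcL + prkB for carbon fixation). Genome
#' quality metrics are drawn uniformly over realistic ranges.
#' Deterministic under the config seed. With `fixture_mode = TRUE` the
#' packaged pilot reconstruction is returned instead of a random draw.
#'
#' @param config A [community_sim_config()].
#' @param fixture_mode Return the packaged pilot community
#'   (requires `n_mags = 13`).
#' @return List with `genes` (long table), `profile` and `mags`
#'   (metadata), as in [pilot_fixture()].
#' @export
simulate_community <- function(config = community_sim_config(),
                               fixture_mode = FALSE) {
  stopifnot(inherits(config, "community_sim_config"))
  if (fixture_mode) {
    if (config$n_mags != 13) {
      stop("fixture_mode reproduces the 13-genome pilot community")
    }
    fx <- pilot_fixture()
    return(list(genes = fx$genes, profile = fx$profile, mags = fx$mags))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_mags
  ids <- sprintf("SIM.%02d", seq_len(n))
  ab <- stats::rgamma(n, shape = config$concentration, rate = 1)
  ab <- 100 * ab / sum(ab)
  p <- config$prevalence
  markers <- list(iron_oxidation = "cyc2",
                  NO3_to_NO2 = c("K02567", "K02568"),
                  NO2_to_NO = "K00368",
                  NO_to_N2O = c("K04561", "K02305"),
                  N2O_to_N2 = "K00376",
                  carbon_fixation = c("K01601", "K00855"))
  genes <- list()
  for (i in seq_len(n)) {
    g <- character()
    for (cap in names(markers)) {
      prob <- if (cap %in% names(p)) p[[cap]] else 0
      if (stats::runif(1) < prob) g <- c(g, markers[[cap]])
    }
    if (length(g) > 0) {
      genes[[length(genes) + 1]] <- data.frame(mag_id = ids[i], gene = g,
                                               stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(mag_id = character(), gene = character())
  mags <- data.frame(
    mag_id = ids, taxonomy = NA_character_, phylum = NA_character_,
    relative_abundance = ab,
    completeness = stats::runif(n, 85, 99.5),
    contamination = stats::runif(n, 0, 6),
    rrna_5s = stats::runif(n) < 0.85,
    rrna_16s = stats::runif(n) < 0.85,
    rrna_23s = stats::runif(n) < 0.85,
    trna_count = sample(14:22, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(genes = genes,
       profile = mags[, c("mag_id", "taxonomy", "phylum",
                          "relative_abundance")],
       mags = mags)
}
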