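# In-code fixtures shared across test files.

# one-day (or multi-day constant) censored reactor series
constant_series <- function(days = 1,
                            fe_in = 236, fe_out = 178,
                            no3_in = 8.1, no3_out = 1,
                            no3_out_bd = TRUE) {
  rbind(
    data.frame(day = days, stream = "influent", species = "Fe2+",
               value = fe_in, below_detection = FALSE,
               detection_limit = 0.18),
    data.frame(day = days, stream = "effluent", species = "Fe2+",
               value = fe_out, below_detection = FALSE,
               detection_limit = 0.18),
    data.frame(day = days, stream = "influent", species = "NO3-",
               value = no3_in, below_detection = FALSE,
               detection_limit = 1),
    data.frame(day = days, stream = "effluent", species = "NO3-",
               value = no3_out, below_detection = no3_out_bd,
               detection_limit = 1)
  )
}

# marker vocabulary for property tests of rule monotonicity
marker_vocabulary <- function() {
  c("cyc2", "cyc1", "sulfocyanin", "mtoA", "mtoB", "foxA", "foxB", "foxC",
    "K02567", "K02568", "K00370", "K00371", "K00374", "K00368", "K15864",
    "K04561", "K02305", "K00376", "K01601", "K01602", "K00855", "xyzZ")
}

# capability profile of a gene set as a flat logical vector
capability_profile <- function(genes) {
  c(feox = call_iron_oxidation(genes),
    cfix = call_carbon_fixation(genes),
    stats::setNames(denit_steps() %in% call_denit_steps(genes),
                    denit_steps()))
}

# exhaustive minimal-cover oracle: enumerate all 2^n - 1 subsets
min_cover_oracle <- function(calls, steps = denit_steps()) {
  n <- nrow(calls)
  ids <- sort(calls$mag_id)
  steps_of <- stats::setNames(calls$denit_steps, calls$mag_id)
  # encode step sets as 4-bit masks
  mask_of <- vapply(steps_of[ids], function(s) {
    sum(2^(match(s, steps) - 1))
  }, numeric(1))
  full <- sum(2^(seq_along(steps) - 1))
  best <- Inf
  best_sets <- list()
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    m <- 0
    for (i in members) m <- bitwOr(m, mask_of[i])
    if (m == full) {
      if (length(members) < best) {
        best <- length(members)
        best_sets <- list(ids[members])
      } else if (length(members) == best) {
        best_sets[[length(best_sets) + 1]] <- ids[members]
      }
    }
  }
  list(size = best, sets = best_sets)
}
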