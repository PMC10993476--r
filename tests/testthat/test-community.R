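test_that("iron-oxidation calls honour the all-subunits rule", {
  expect_true(call_iron_oxidation(c("cyc2")))
  expect_false(call_iron_oxidation(character()))
  expect_false(call_iron_oxidation(c("mtoA")))
  expect_true(call_iron_oxidation(c("mtoA", "mtoB")))
  expect_true(call_iron_oxidation(c("foxA", "foxB", "foxC")))
  expect_false(call_iron_oxidation(c("foxA", "foxB")))
  # permissive any-subunit mode
  expect_true(call_iron_oxidation(c("mtoA"), require_all_subunits = FALSE))
  # normalization is case-insensitive
  expect_true(call_iron_oxidation(c("CYC2")))
})

test_that("denitrification step calls follow the KO rules", {
  expect_equal(call_denit_steps(c("K02567", "K02568")), "NO3_to_NO2")
  expect_equal(call_denit_steps(character()), character(0))
  expect_setequal(call_denit_steps(c("K00376", "K00368")),
                  c("NO2_to_NO", "N2O_to_N2"))
  # narGHI requires all three subunits
  expect_equal(call_denit_steps(c("K00370", "K00371", "K00374")),
               "NO3_to_NO2")
  expect_equal(call_denit_steps(c("K00370", "K00371")), character(0))
  # norBC requires both
  expect_equal(call_denit_steps(c("K04561")), character(0))
  expect_equal(call_denit_steps(c("K04561", "K02305")), "NO_to_N2O")
  # gene symbols resolve through the synonym map
  expect_equal(call_denit_steps(c("napA", "napB")), "NO3_to_NO2")
  expect_equal(call_denit_steps(c("nosZ")), "N2O_to_N2")
})

test_that("carbon-fixation calls require RuBisCO plus phosphoribulokinase", {
  expect_true(call_carbon_fixation(c("K01601", "K00855")))
  expect_true(call_carbon_fixation(c("K01602", "K00855")))
  expect_false(call_carbon_fixation(c("K01601")))
  expect_false(call_carbon_fixation(c("K00855")))
  expect_true(call_carbon_fixation(c("rbcL", "prkB")))
})

test_that("MIMAG tiers use strict inequalities with boundaries falling down", {
  expect_equal(classify_mimag(98.59, 1.73, TRUE, 20), "high")
  expect_equal(classify_mimag(88.95, 2.37, TRUE, 20), "medium")
  expect_equal(classify_mimag(40, 12, TRUE, 20), "contamination")
  expect_equal(classify_mimag(40, 5, TRUE, 20), "low")
  # boundary values
  expect_equal(classify_mimag(90, 1, TRUE, 20), "medium")   # not > 90
  expect_equal(classify_mimag(95, 5, TRUE, 20), "medium")   # not < 5
  expect_equal(classify_mimag(95, 1, TRUE, 17), "medium")   # < 18 tRNA
  expect_equal(classify_mimag(95, 1, FALSE, 20), "medium")  # rRNA missing
  expect_equal(classify_mimag(50, 9, TRUE, 20), "low")      # not > 50
  expect_error(classify_mimag(120, 1, TRUE, 20), "\\[0, 100\\]")
})

test_that("annotation hits are accepted only above both strict thresholds", {
  hits <- data.frame(
    query = paste0("q", 1:5),
    coverage = c(80, 70, 90, 71, 60),
    identity = c(40, 40, 35, 36, 90)
  )
  acc <- filter_annotation_hits(hits)
  expect_equal(acc$query, c("q1", "q4"))
  expect_equal(nrow(filter_annotation_hits(hits[2, ])), 0)  # boundary 70
})

test_that("capability calls are monotone under gene addition and removal", {
  vocab <- marker_vocabulary()
  set.seed(123)
  for (i in 1:25) {
    base <- sample(vocab, sample(0:length(vocab), 1))
    extra <- sample(setdiff(vocab, base),
                    sample(0:length(setdiff(vocab, base)), 1))
    small <- capability_profile(base)
    large <- capability_profile(c(base, extra))
    # adding genes never removes a capability
    expect_true(all(large[small]))
    # removing genes never adds one (contrapositive of the same check)
    expect_true(all(!small[!large]))
  }
})

test_that("niche classification separates autotrophic iron oxidizers", {
  fx <- pilot_fixture()
  calls <- call_functions(fx$genes, fx$mags)
  expect_equal(calls$niche[calls$mag_id == "MAG.13"],
               "autotrophic_iron_oxidizer")
  expect_equal(calls$niche[calls$mag_id == "MAG.18"],
               "organoheterotrophic_denitrifier")
  expect_equal(classify_niche(FALSE, FALSE, character()), "other")
})

test_that("the fixture community reproduces the published function calls", {
  fx <- pilot_fixture()
  calls <- call_functions(fx$genes, fx$mags)
  has_step <- function(s) {
    vapply(calls$denit_steps, function(x) s %in% x, logical(1))
  }
  expect_equal(sum(calls$iron_oxidation), 5)
  expect_equal(sum(has_step("NO3_to_NO2")), 9)
  expect_equal(sum(has_step("N2O_to_N2")), 3)
  expect_true(all(calls$n_denit_steps >= 1))
  # iron oxidizers all carry the carbon-fixation repertoire
  expect_true(all(calls$carbon_fixation[calls$iron_oxidation]))
  # MIMAG classes: 10 high, 3 medium
  expect_equal(sum(calls$mimag_class == "high"), 10)
  expect_equal(sum(calls$mimag_class == "medium"), 3)
  expect_equal(calls$mimag_class[calls$mag_id == "MAG.08"], "medium")
})

test_that("abundance aggregation sums exactly and conserves the total", {
  fx <- pilot_fixture()
  ph <- aggregate_abundance(fx$profile, "phylum")
  expect_equal(unname(ph["Proteobacteria"]), 51.6, tolerance = 1e-12)
  expect_equal(unname(ph["Chloroflexi"]), 1.4, tolerance = 1e-12)
  expect_equal(sum(ph), 66.8, tolerance = 1e-9)  # column sum of the table
  expect_equal(aggregate_abundance(fx$profile[0, ], "phylum"), 0)
  # partition by phylum conserves the total over all genomes
  expect_equal(sum(ph), sum(fx$profile$relative_abundance),
               tolerance = 1e-12)
  expect_equal(aggregate_abundance(fx$profile, "top_n", n = 13),
               sum(fx$profile$relative_abundance), tolerance = 1e-12)
})

test_that("top-n community coverage is nested and complete at the top five", {
  fx <- pilot_fixture()
  calls <- call_functions(fx$genes, fx$mags)
  cov5 <- community_coverage(calls, fx$profile, top_n = 5)
  expect_setequal(cov5$mags,
                  c("MAG.13", "MAG.26", "MAG.18", "MAG.19", "MAG.10"))
  expect_true(cov5$complete)
  expect_equal(cov5$steps_missing, character(0))

  # coverage can only grow with top_n
  all_steps <- community_coverage(calls, fx$profile)$steps_covered
  for (k in 1:13) {
    sk <- community_coverage(calls, fx$profile, top_n = k)$steps_covered
    expect_true(all(sk %in% all_steps))
    if (k > 1) expect_true(all(prev %in% sk))
    prev <- sk
  }

  # a single genome with no steps covers nothing
  lone_genes <- data.frame(mag_id = "X", gene = "cyc2")
  lone_calls <- call_functions(lone_genes)
  lone_prof <- data.frame(mag_id = "X", relative_abundance = 100)
  cov1 <- community_coverage(lone_calls, lone_prof)
  expect_equal(cov1$steps_covered, character(0))
  expect_false(cov1$complete)

  # mismatched ids name the offender
  bad_prof <- fx$profile
  bad_prof$mag_id[1] <- "MAG.99"
  expect_error(community_coverage(calls, bad_prof), "MAG.99")

  # complementarity edges connect producers to consumers of intermediates
  expect_true(all(c("NO2-", "NO", "N2O") %in% cov5$edges$intermediate))
  e <- cov5$edges[cov5$edges$intermediate == "N2O", ]
  expect_true("MAG.13" %in%
                cov5$edges$source_mag[cov5$edges$intermediate == "NO2-"])
  expect_true(all(e$source_mag != e$target_mag))
})

test_that("minimal denitrification cover matches the exhaustive-subset oracle", {
  fx <- pilot_fixture()
  calls <- call_functions(fx$genes, fx$mags)
  got <- minimal_denit_cover(calls)
  oracle <- min_cover_oracle(calls)
  expect_equal(length(got), oracle$size)
  steps_of <- stats::setNames(calls$denit_steps, calls$mag_id)
  expect_setequal(Reduce(union, steps_of[got], character()), denit_steps())
  expect_true(any(vapply(oracle$sets, function(s) setequal(s, got),
                         logical(1))))

  # also on a random simulated community
  sim <- simulate_community(community_sim_config(n_mags = 9, seed = 5))
  scalls <- call_functions(sim$genes)
  if (nrow(scalls) > 0 &&
      all(denit_steps() %in%
            Reduce(union, scalls$denit_steps, character()))) {
    expect_equal(length(minimal_denit_cover(scalls)),
                 min_cover_oracle(scalls)$size)
  }

  # insufficient community warns and returns empty
  lone <- call_functions(data.frame(mag_id = "X", gene = "K00376"))
  expect_warning(res <- minimal_denit_cover(lone), "cover")
  expect_equal(res, character(0))
})
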