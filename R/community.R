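# Marker-gene vocabulary -------------------------------------------------

# gene-symbol <-> KEGG orthology synonym map for the markers the rules use
.GENE_KO <- c(
  napa = "K02567", napb = "K02568",
  narg = "K00370", narh = "K00371", nari = "K00374",
  nirk = "K00368", nirs = "K15864",
  norb = "K04561", norc = "K02305",
  nosz = "K00376",
  rbcl = "K01601", rbcs = "K01602",
  prkb = "K00855"
)

# iron-oxidation markers: singletons and multi-subunit clusters
.FEOX_SINGLE <- c("cyc2", "cyc1", "sulfocyanin")
.FEOX_CLUSTERS <- list(
  foxABC = c("foxa", "foxb", "foxc"),
  foxEYZ = c("foxe", "foxy", "foxz"),
  pioABC = c("pioa", "piob", "pioc"),
  mtoAB = c("mtoa", "mtob")
)

#' Normalize marker-gene identifiers
#'
#' Case-insensitive normalization of a marker set: KEGG orthology
#' accessions (`K#####`) are upper-cased, gene symbols lower-cased, and
#' known synonyms added in both directions (e.g. `napA` implies `K02567`
#' and vice versa) so downstream rules can match either form. Unknown
#' identifiers are kept (and simply never match a rule); their count is
#' available as the `n_unknown` attribute.
#'
#' @param genes Character vector of gene symbols and/or KO accessions.
#' @return Normalized, deduplicated character vector.
#' @examples
#' normalize_gene_ids(c("NapA", "k02568", "cyc2"))
#' @export
normalize_gene_ids <- function(genes) {
  g <- trimws(as.character(genes))
  g <- g[nzchar(g)]
  is_ko <- grepl("^[Kk][0-9]{5}$", g)
  g[is_ko] <- toupper(g[is_ko])
  g[!is_ko] <- tolower(g[!is_ko])
  # synonym closure (symbol -> KO and KO -> symbol)
  extra <- unname(.GENE_KO[g[g %in% names(.GENE_KO)]])
  rev_map <- stats::setNames(names(.GENE_KO), unname(.GENE_KO))
  extra <- c(extra, unname(rev_map[g[g %in% names(rev_map)]]))
  out <- unique(c(g, extra))
  vocab <- c(names(.GENE_KO), unname(.GENE_KO), .FEOX_SINGLE,
             unlist(.FEOX_CLUSTERS))
  attr(out, "n_unknown") <- sum(!g %in% vocab)
  out
}

#' Call iron-oxidation capability from marker genes
#'
#' A genome is called an iron oxidizer if any of the canonical
#' iron-oxidase markers is present: cyc2, cyc1, sulfocyanin, or one of
#' the multi-subunit systems foxABC, foxEYZ, pioABC, mtoAB. By default a
#' multi-subunit system only counts when all of its subunits are present
#' (operon-cluster semantics); `require_all_subunits = FALSE` relaxes
#' this to any subunit.
#'
#' @param genes Character vector of markers (normalized internally).
#' @param require_all_subunits Require complete subunit sets for
#'   multi-subunit markers (default `TRUE`).
#' @return Logical flag.
#' @examples
#' call_iron_oxidation(c("cyc2"))            # TRUE
#' call_iron_oxidation(c("mtoA"))            # FALSE (mtoB missing)
#' call_iron_oxidation(c("mtoA", "mtoB"))    # TRUE
#' @export
call_iron_oxidation <- function(genes, require_all_subunits = TRUE) {
  g <- normalize_gene_ids(genes)
  if (any(.FEOX_SINGLE %in% g)) return(TRUE)
  if (require_all_subunits) {
    any(vapply(.FEOX_CLUSTERS, function(sub) all(sub %in% g), logical(1)))
  } else {
    any(unlist(.FEOX_CLUSTERS) %in% g)
  }
}

#' Call denitrification steps from marker genes
#'
#' Step rules (on KO accessions, with gene-symbol synonyms accepted):
#' NO3->NO2 requires napAB (K02567 and K02568) or narGHI (K00370, K00371
#' and K00374); NO2->NO requires nirK (K00368) or nirS (K15864);
#' NO->N2O requires norBC (K04561 and K02305); N2O->N2 requires nosZ
#' (K00376).
#'
#' @inheritParams call_iron_oxidation
#' @return Character vector, a subset of [denit_steps()].
#' @examples
#' call_denit_steps(c("K02567", "K02568"))   # NO3_to_NO2
#' @export
call_denit_steps <- function(genes) {
  g <- normalize_gene_ids(genes)
  has <- function(...) all(c(...) %in% g)
  steps <- c(
    NO3_to_NO2 = has("K02567", "K02568") || has("K00370", "K00371", "K00374"),
    NO2_to_NO = has("K00368") || has("K15864"),
    NO_to_N2O = has("K04561", "K02305"),
    N2O_to_N2 = has("K00376")
  )
  names(steps)[steps]
}

#' Call carbon-fixation capability (CBB cycle) from marker genes
#'
#' Requires a RuBisCO large or small subunit (rbcL, K01601, or rbcS,
#' K01602) together with phosphoribulokinase (prkB, K00855).
#'
#' @inheritParams call_iron_oxidation
#' @return Logical flag.
#' @examples
#' call_carbon_fixation(c("K01601", "K00855"))   # TRUE
#' call_carbon_fixation(c("K01601"))             # FALSE
#' @export
call_carbon_fixation <- function(genes) {
  g <- normalize_gene_ids(genes)
  (("K01601" %in% g) || ("K01602" %in% g)) && ("K00855" %in% g)
}

#' MIMAG genome quality classification
#'
#' Tiers follow the MIMAG standard with strict inequalities: high quality
#' requires completeness > 90%, contamination < 5%, full-length 5S, 16S
#' and 23S rRNA genes and >= 18 tRNAs; otherwise medium quality requires
#' completeness > 50% and contamination < 10%; otherwise low quality
#' requires contamination < 10%; anything else is classed as
#' contamination. Boundary values fall to the lower tier.
#'
#' @param completeness,contamination Percentages in `[0, 100]`
#'   (vectorized).
#' @param rrna_full Logical: all three rRNA genes full-length.
#' @param trna_count Integer tRNA count.
#' @return Character vector: `"high"`, `"medium"`, `"low"` or
#'   `"contamination"`.
#' @examples
#' classify_mimag(98.6, 1.7, TRUE, 20)    # "high"
#' classify_mimag(88.9, 2.4, TRUE, 20)    # "medium"
#' @export
classify_mimag <- function(completeness, contamination, rrna_full,
                           trna_count) {
  if (any(completeness < 0 | completeness > 100 |
          contamination < 0 | contamination > 100)) {
    stop("completeness and contamination must lie in [0, 100]")
  }
  out <- rep("contamination", length(completeness))
  out[contamination < 10] <- "low"
  out[completeness > 50 & contamination < 10] <- "medium"
  out[completeness > 90 & contamination < 5 & rrna_full &
        trna_count >= 18] <- "high"
  out
}

#' Filter annotation hits on coverage and identity
#'
#' Accepts an alignment-based annotation hit only if query coverage
#' exceeds 70% and sequence identity exceeds 35% (both strict).
#'
#' @param hits Data frame with numeric columns `coverage` and `identity`
#'   in `[0, 100]`.
#' @param min_coverage,min_identity Strict lower bounds.
#' @return The accepted subset of `hits`.
#' @export
filter_annotation_hits <- function(hits, min_coverage = 70,
                                   min_identity = 35) {
  stopifnot(all(c("coverage", "identity") %in% names(hits)))
  if (any(hits$coverage < 0 | hits$coverage > 100 |
          hits$identity < 0 | hits$identity > 100)) {
    stop("coverage and identity must lie in [0, 100]")
  }
  hits[hits$coverage > min_coverage & hits$identity > min_identity, ,
       drop = FALSE]
}

#' Classify the ecological niche of a genome
#'
#' `autotrophic_iron_oxidizer` if it can both oxidize iron and fix
#' carbon; `organoheterotrophic_denitrifier` if it cannot oxidize iron
#' but carries at least one denitrification step; `other` otherwise.
#'
#' @param iron_oxidation,carbon_fixation Logical flags.
#' @param denit_steps Character vector of called steps.
#' @return Niche label.
#' @export
classify_niche <- function(iron_oxidation, carbon_fixation, denit_steps) {
  if (iron_oxidation && carbon_fixation) {
    "autotrophic_iron_oxidizer"
  } else if (!iron_oxidation && length(denit_steps) > 0) {
    "organoheterotrophic_denitrifier"
  } else {
    "other"
  }
}

#' Genome-function calls for a set of MAGs
#'
#' Runs the full rule engine over a per-MAG gene table and genome
#' metadata: iron oxidation, denitrification steps, carbon fixation,
#' MIMAG quality and niche.
#'
#' @param genes Long data frame with columns `mag_id` and `gene` (one row
#'   per marker per genome).
#' @param meta Data frame with columns `mag_id`, `completeness`,
#'   `contamination`, `rrna_5s`, `rrna_16s`, `rrna_23s`, `trna_count`.
#'   Optional; MIMAG class is `NA` without it.
#' @param require_all_subunits Passed to [call_iron_oxidation()].
#' @return Data frame with one row per MAG: logical `iron_oxidation` and
#'   `carbon_fixation`, list-column `denit_steps`, `n_denit_steps`,
#'   `mimag_class`, `niche`.
#' @export
call_functions <- function(genes, meta = NULL, require_all_subunits = TRUE) {
  stopifnot(all(c("mag_id", "gene") %in% names(genes)))
  ids <- sort(unique(genes$mag_id))
  per <- lapply(ids, function(id) {
    g <- genes$gene[genes$mag_id == id]
    fe <- call_iron_oxidation(g, require_all_subunits)
    cf <- call_carbon_fixation(g)
    st <- call_denit_steps(g)
    data.frame(mag_id = id, iron_oxidation = fe, carbon_fixation = cf,
               n_denit_steps = length(st),
               niche = classify_niche(fe, cf, st),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, per)
  calls$denit_steps <- I(lapply(ids, function(id) {
    call_denit_steps(genes$gene[genes$mag_id == id])
  }))
  if (!is.null(meta)) {
    idx <- match(calls$mag_id, meta$mag_id)
    if (anyNA(idx)) {
      stop("genomes missing from metadata: ",
           paste(calls$mag_id[is.na(idx)], collapse = ", "))
    }
    calls$mimag_class <- classify_mimag(
      meta$completeness[idx], meta$contamination[idx],
      meta$rrna_5s[idx] & meta$rrna_16s[idx] & meta$rrna_23s[idx],
      meta$trna_count[idx]
    )
  } else {
    calls$mimag_class <- NA_character_
  }
  calls
}

.top_mags <- function(profile, top_n) {
  ord <- order(-profile$relative_abundance, profile$mag_id)
  profile$mag_id[ord][seq_len(min(top_n, nrow(profile)))]
}

#' Community-level denitrification coverage and complementarity
#'
#' Takes the union of denitrification steps over the `top_n` most
#' abundant genomes (ties broken by `mag_id`), lists missing steps,
#' computes the abundance-weighted capability per step, and builds the
#' complementarity edge list: one edge per (producer of an intermediate,
#' consumer of that intermediate) pair among the selected genomes.
#'
#' @param calls Output of [call_functions()].
#' @param profile Data frame with columns `mag_id` and
#'   `relative_abundance` (%).
#' @param top_n Number of most-abundant genomes to consider
#'   (default all).
#' @return List with `mags`, `steps_covered`, `steps_missing`,
#'   `complete` (all four steps covered), `step_abundance` (named %,
#'   summed over capable selected genomes) and `edges` (data frame
#'   `source_mag`, `intermediate`, `target_mag`).
#' @export
community_coverage <- function(calls, profile, top_n = nrow(profile)) {
  bad <- setdiff(profile$mag_id, calls$mag_id)
  bad2 <- setdiff(calls$mag_id, profile$mag_id)
  if (length(bad) > 0 || length(bad2) > 0) {
    stop("mag_ids do not match between calls and profile: ",
         paste(unique(c(bad, bad2)), collapse = ", "))
  }
  sel <- .top_mags(profile, top_n)
  steps_of <- stats::setNames(calls$denit_steps, calls$mag_id)
  covered <- Reduce(union, steps_of[sel], character())
  covered <- intersect(denit_steps(), covered)  # pathway order
  ab <- stats::setNames(profile$relative_abundance, profile$mag_id)
  step_ab <- vapply(denit_steps(), function(s) {
    sum(ab[sel][vapply(steps_of[sel], function(x) s %in% x, logical(1))])
  }, numeric(1))
  # producer -> consumer edges through each denitrification intermediate
  intermediates <- c(NO3_to_NO2 = "NO2-", NO2_to_NO = "NO",
                     NO_to_N2O = "N2O")
  consumes <- c("NO2-" = "NO2_to_NO", "NO" = "NO_to_N2O",
                "N2O" = "N2O_to_N2")
  edges <- list()
  for (prod_step in names(intermediates)) {
    mid <- intermediates[[prod_step]]
    cons_step <- consumes[[mid]]
    producers <- sel[vapply(steps_of[sel], function(x) prod_step %in% x,
                            logical(1))]
    consumers <- sel[vapply(steps_of[sel], function(x) cons_step %in% x,
                            logical(1))]
    if (length(producers) && length(consumers)) {
      e <- expand.grid(source_mag = producers, target_mag = consumers,
                       stringsAsFactors = FALSE)
      e <- e[e$source_mag != e$target_mag, , drop = FALSE]
      if (nrow(e)) {
        e$intermediate <- mid
        edges[[mid]] <- e[, c("source_mag", "intermediate", "target_mag")]
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source_mag = character(), intermediate = character(),
               target_mag = character())
  rownames(edges) <- NULL
  list(mags = sel,
       steps_covered = covered,
       steps_missing = setdiff(denit_steps(), covered),
       complete = setequal(covered, denit_steps()),
       step_abundance = step_ab,
       edges = edges)
}

#' Smallest set of genomes covering the full denitrification pathway
#'
#' Exact minimal set cover by exhaustive search over subset sizes
#' (feasible for community sizes up to ~20 genomes). Among covers of the
#' minimal size, the lexicographically first combination of `mag_id`s is
#' returned, making the result deterministic.
#'
#' @param calls Output of [call_functions()].
#' @param steps Steps to cover (default all four).
#' @return Character vector of `mag_id`s, or `character(0)` (with a
#'   warning) if the community cannot cover the steps.
#' @export
minimal_denit_cover <- function(calls, steps = denit_steps()) {
  ids <- sort(calls$mag_id)
  steps_of <- stats::setNames(calls$denit_steps, calls$mag_id)
  if (!all(steps %in% Reduce(union, steps_of[ids], character()))) {
    warning("community does not cover the requested steps")
    return(character(0))
  }
  for (k in seq_along(ids)) {
    combos <- utils::combn(ids, k, simplify = FALSE)
    for (cmb in combos) {
      if (all(steps %in% Reduce(union, steps_of[cmb], character()))) {
        return(cmb)
      }
    }
  }
  character(0)
}

#' Aggregate relative abundances
#'
#' Exact sums of relative abundance by phylum, over the `n` most
#' abundant genomes, or by ecological niche.
#'
#' @param profile Data frame with columns `mag_id`,
#'   `relative_abundance` and (for `by = "phylum"`) `phylum`.
#' @param by `"phylum"`, `"top_n"` or `"niche"`.
#' @param n Number of genomes for `by = "top_n"`.
#' @param calls [call_functions()] output, required for `by = "niche"`.
#' @return Named numeric vector of summed percentages (a single unnamed
#'   value for `"top_n"`).
#' @examples
#' prof <- pilot_fixture()$profile
#' aggregate_abundance(prof, "phylum")["Proteobacteria"]   # 51.6
#' @export
aggregate_abundance <- function(profile, by = c("phylum", "top_n", "niche"),
                                n = 5, calls = NULL) {
  by <- match.arg(by)
  if (nrow(profile) == 0) return(0)
  if (any(profile$relative_abundance < 0)) {
    stop("relative abundances must be >= 0")
  }
  switch(by,
    phylum = {
      s <- tapply(profile$relative_abundance, profile$phylum, sum)
      sort(stats::setNames(as.numeric(s), names(s)), decreasing = TRUE)
    },
    top_n = {
      sel <- .top_mags(profile, n)
      sum(profile$relative_abundance[profile$mag_id %in% sel])
    },
    niche = {
      if (is.null(calls)) stop("by = 'niche' requires function calls")
      idx <- match(profile$mag_id, calls$mag_id)
      if (anyNA(idx)) {
        stop("genomes missing from calls: ",
             paste(profile$mag_id[is.na(idx)], collapse = ", "))
      }
      s <- tapply(profile$relative_abundance, calls$niche[idx], sum)
      sort(stats::setNames(as.numeric(s), names(s)), decreasing = TRUE)
    }
  )
}
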