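#' Classify and analyze one well of droplet amplitudes
#'
#' Convenience composition: fit per-channel thresholds (unless supplied),
#' classify droplets into the four class counts, and run the full
#' Poisson-partition linkage analysis.
#'
#' @param amplitudes Amplitude tibble (from [read_amplitude_csv()] or
#'   [simulate_experiment()]).
#' @param config A [partition_config()].
#' @param thresholds Optional [channel_thresholds()]; fitted from the
#'   data when `NULL`.
#' @return A `linkage_result`.
#' @export
analyze_amplitudes <- function(amplitudes, config = partition_config(),
                               thresholds = NULL) {
  if (inherits(amplitudes, "drop_phase_sim")) amplitudes <- amplitudes$amplitudes
  if (is.null(thresholds)) thresholds <- fit_thresholds(amplitudes)
  estimate_linkage(classify_droplets(amplitudes, thresholds), config)
}

#' Synthetic trio phasing scenarios
#'
#' Fourteen duplex phasing assays: four SNP pairs spanning 1-40 kb
#' assayed across seven synthetic trios whose parental genotypes force
#' the child's phase by transmission (seven cis and seven trans
#' configurations). These are the study conditions of the trio
#' concordance experiment.
#'
#' @return A tibble with one row per assay: `assay`, `individual`,
#'   `distance_kb`, genotype columns (`father_1`, `father_2`, ...), and
#'   the generating `phase`.
#' @export
trio_scenarios <- function() {
  tibble::tribble(
    ~assay, ~individual, ~distance_kb, ~father_1, ~father_2, ~mother_1, ~mother_2, ~phase,
    1L,  "T1", 1,  "AA", "BB", "aa", "bb", "cis_AB",
    2L,  "T1", 10, "AA", "bb", "aa", "BB", "cis_Ab",
    3L,  "T2", 1,  "Aa", "bb", "aa", "BB", "cis_Ab",
    4L,  "T2", 25, "AA", "BB", "aa", "Bb", "cis_AB",
    5L,  "T3", 10, "Aa", "BB", "aa", "bb", "cis_AB",
    6L,  "T3", 40, "AA", "bb", "aa", "Bb", "cis_Ab",
    7L,  "T4", 25, "aa", "BB", "AA", "bb", "cis_Ab",
    8L,  "T4", 40, "AA", "Bb", "aa", "bb", "cis_AB",
    9L,  "T5", 1,  "aa", "bb", "AA", "BB", "cis_AB",
    10L, "T5", 40, "aa", "Bb", "AA", "bb", "cis_Ab",
    11L, "T6", 10, "AA", "BB", "aa", "bb", "cis_AB",
    12L, "T6", 25, "aa", "BB", "Aa", "bb", "cis_Ab",
    13L, "T7", 1,  "Aa", "Bb", "aa", "bb", "cis_AB",
    14L, "T7", 40, "AA", "bb", "Aa", "BB", "cis_Ab"
  )
}

#' Synthetic compound-heterozygote (CFTR-like) quad-duplex scenarios
#'
#' Thirteen heterozygous variant pairs across six synthetic cystic
#' fibrosis patients, at pairwise genomic separations of 11-116 kb,
#' each phased with the redundant quad-duplex design. The variant layout
#' and diplotypes are synthetic but mirror the structure of real
#' compound-heterozygote panels (a recessive gene of about 189 kb with
#' two to four heterozygous variants per patient). `phase` is the
#' arrangement of the two *variant* alleles: `"cis_AB"` when both sit on
#' the same haplotype.
#'
#' @return A tibble with one row per variant pair: `scenario`, `patient`,
#'   `locus1`, `locus2`, `distance_kb`, `phase`.
#' @export
cftr_scenarios <- function() {
  tibble::tribble(
    ~scenario, ~patient, ~locus1, ~locus2, ~distance_kb, ~phase,
    1L,  "P1", "F508del",  "G551D",    11,  "cis_Ab",
    2L,  "P2", "F508del",  "G551D",    11,  "cis_Ab",
    3L,  "P3", "F508del",  "G551D",    11,  "cis_Ab",
    4L,  "P4", "promoter", "R117H",    59,  "cis_AB",
    5L,  "P4", "R117H",    "polyT5",   11,  "cis_AB",
    6L,  "P4", "R117H",    "F508del",  22,  "cis_Ab",
    7L,  "P4", "polyT5",   "F508del",  11,  "cis_Ab",
    8L,  "P5", "polyT7",   "N1303K",   104, "cis_Ab",
    9L,  "P5", "polyT7",   "G1349D",   116, "cis_AB",
    10L, "P5", "N1303K",   "G1349D",   12,  "cis_Ab",
    11L, "P6", "R117H",    "polyT5",   11,  "cis_AB",
    12L, "P6", "R117H",    "F508del",  22,  "cis_Ab",
    13L, "P6", "polyT5",   "F508del",  11,  "cis_Ab"
  )
}

phase_to_diplotype <- function(phase, copies_per_ul = c(100, 100)) {
  switch(phase,
         cis_AB = cis_diplotype(copies_per_ul),
         cis_Ab = trans_diplotype(copies_per_ul),
         abort(paste0("unknown phase: ", phase)))
}

#' Run the simulated trio concordance suite
#'
#' For each of the fourteen [trio_scenarios()], simulates the child's
#' duplex well (probes targeting the `A` and `B` alleles), classifies
#' amplitudes, estimates linkage, calls cis/trans from the linked/
#' unlinked verdict, and compares the call with both the generating
#' configuration and the inheritance-derived phase
#' ([trio_expected_phase()]).
#'
#' @param mean_intact_kb Fragment-survival scale (kb).
#' @param n_droplets Droplets per well.
#' @param copies_per_ul Per-haplotype concentration (copies/uL); the
#'   default gives about 0.17 molecules per droplet per locus.
#' @param seed Base seed; assay `i` uses `seed + i`.
#' @param alpha,min_pct Verdict thresholds; see [call_pair_linkage()].
#' @return A tibble with one row per assay: expected phase, called
#'   phase, percent linkage, and concordance flags.
#' @export
run_trio_suite <- function(mean_intact_kb = 69, n_droplets = 20000L,
                           copies_per_ul = 100, seed = 1L,
                           alpha = 1e-3, min_pct = 2) {
  scen <- trio_scenarios()
  purrr::map_dfr(seq_len(nrow(scen)), function(i) {
    row <- scen[i, ]
    child <- c("Aa", "Bb")
    expected <- trio_expected_phase(c(row$father_1, row$father_2),
                                    c(row$mother_1, row$mother_2), child)
    cfg <- sim_config(
      dip = phase_to_diplotype(row$phase, copies_per_ul),
      assay = duplex_assay("A", "B"),
      n_droplets = n_droplets, distance_kb = row$distance_kb,
      mean_intact_kb = mean_intact_kb, seed = seed + i,
      well_id = sprintf("trio_%02d", row$assay)
    )
    res <- analyze_amplitudes(simulate_experiment(cfg),
                              partition_config(seed = seed + i))
    verdict <- call_pair_linkage(res, alpha = alpha, min_pct = min_pct)
    called <- if (verdict == "linked") "cis_AB" else "cis_Ab"
    tibble::tibble(
      assay = row$assay, individual = row$individual,
      distance_kb = row$distance_kb,
      expected_phase = expected, true_phase = row$phase,
      called_phase = called,
      percent_linkage = res$percent_linkage, log10_p = res$log10_p,
      concordant_inheritance = called == expected,
      concordant_truth = called == row$phase
    )
  })
}

#' Run the simulated compound-heterozygote quad-duplex suite
#'
#' For each of the thirteen [cftr_scenarios()], simulates all four
#' duplex wells of the quad from the same diplotype, classifies and
#' estimates linkage per duplex, and calls the diplotype from the joint
#' pattern ([call_diplotype()]).
#'
#' @inheritParams run_trio_suite
#' @return A tibble with one row per scenario: the generating phase, the
#'   called configuration, internal consistency, and correctness.
#' @export
run_cftr_suite <- function(mean_intact_kb = 72, n_droplets = 20000L,
                           copies_per_ul = 100, seed = 1L,
                           alpha = 1e-3, min_pct = 2) {
  scen <- cftr_scenarios()
  duplexes <- quad_duplexes()
  purrr::map_dfr(seq_len(nrow(scen)), function(i) {
    row <- scen[i, ]
    dip <- phase_to_diplotype(row$phase, copies_per_ul)
    quad <- purrr::imap_dfr(duplexes, function(assay, nm) {
      cfg <- sim_config(
        dip = dip, assay = assay, n_droplets = n_droplets,
        distance_kb = row$distance_kb, mean_intact_kb = mean_intact_kb,
        seed = seed + i * 10L + match(nm, names(duplexes)),
        well_id = sprintf("cftr_%02d_%s", row$scenario, nm)
      )
      res <- analyze_amplitudes(simulate_experiment(cfg),
                                partition_config(seed = cfg$seed))
      tibble::tibble(duplex = nm, percent_linkage = res$percent_linkage,
                     log10_p = res$log10_p)
    })
    call <- call_diplotype(quad, alpha = alpha, min_pct = min_pct)
    tibble::tibble(
      scenario = row$scenario, patient = row$patient,
      distance_kb = row$distance_kb,
      true_phase = row$phase, called = call$configuration,
      consistent = call$consistent,
      correct = call$consistent && call$configuration == row$phase
    )
  })
}

#' Run a suite of trans-configured (null) duplex wells
#'
#' Simulates trans-configured duplex wells -- no physically linked A-B
#' molecules -- through the full pipeline (partitioning, fluorescence,
#' classification, estimation) and reports the estimated percent linkage
#' per well. Summaries of this suite quantify the unlinked background.
#'
#' @param n_wells Number of seeded replicate wells.
#' @inheritParams run_trio_suite
#' @param distance_kb Locus separation (the truth is unlinked regardless).
#' @return A tibble with one row per well: `seed`, `percent_linkage`,
#'   `log10_p`.
#' @export
run_null_suite <- function(n_wells = 100L, n_droplets = 20000L,
                           copies_per_ul = 100, mean_intact_kb = 69,
                           distance_kb = 20, seed = 1L) {
  purrr::map_dfr(seq_len(n_wells), function(i) {
    cfg <- sim_config(
      dip = trans_diplotype(copies_per_ul), assay = duplex_assay("A", "B"),
      n_droplets = n_droplets, distance_kb = distance_kb,
      mean_intact_kb = mean_intact_kb, seed = seed + i,
      well_id = sprintf("null_%03d", i)
    )
    res <- analyze_amplitudes(simulate_experiment(cfg),
                              partition_config(seed = seed + i, ci_reps = 0L))
    tibble::tibble(seed = seed + i, percent_linkage = res$percent_linkage,
                   log10_p = res$log10_p)
  })
}

#' Run the mile-marker distance suite
#'
#' Simulates non-polymorphic "mile marker" duplex wells at a series of
#' genomic distances from an anchor locus (both chromosomal copies carry
#' the targets, modeled as one haplotype at double concentration), plus
#' cross-chromosome control wells (infinite separation, so no linked
#' molecules), and measures percent linkage per well.
#'
#' @param distances_kb Distances of the mile markers from the anchor.
#' @param reps Replicate wells per distance.
#' @param mean_intact_kb Generating fragment-survival scale (kb).
#' @param copies_per_ul Total target concentration (copies/uL).
#' @param n_droplets Droplets per well.
#' @param seed Base seed.
#' @param controls Include cross-chromosome control wells.
#' @return A tibble: `distance_kb`, `replicate`, `is_control`,
#'   `percent_linkage`, `ci_low`, `ci_high`, `log10_p`.
#' @export
run_milemarker_suite <- function(distances_kb = c(1, 10, 33, 60, 100, 150, 210),
                                 reps = 3L, mean_intact_kb = 69.16,
                                 copies_per_ul = 200, n_droplets = 20000L,
                                 seed = 1L, controls = TRUE) {
  grid <- tidyr::expand_grid(distance_kb = distances_kb,
                             replicate = seq_len(reps), is_control = FALSE)
  if (controls) {
    grid <- dplyr::bind_rows(
      grid,
      tibble::tibble(distance_kb = distances_kb, replicate = 1L,
                     is_control = TRUE))
  }
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    d <- if (g$is_control) Inf else g$distance_kb
    cfg <- sim_config(
      dip = diplotype(c("A", "B"), c("a", "b"),
                      copies_per_ul = c(copies_per_ul, 0)),
      assay = duplex_assay("A", "B"), n_droplets = n_droplets,
      distance_kb = d, mean_intact_kb = mean_intact_kb, seed = seed + i,
      well_id = sprintf("mm_%03.0f_%d%s", g$distance_kb, g$replicate,
                        if (g$is_control) "c" else "")
    )
    res <- analyze_amplitudes(simulate_experiment(cfg),
                              partition_config(seed = seed + i))
    tibble::tibble(distance_kb = g$distance_kb, replicate = g$replicate,
                   is_control = g$is_control,
                   percent_linkage = res$percent_linkage,
                   ci_low = res$ci_low, ci_high = res$ci_high,
                   log10_p = res$log10_p)
  })
}
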