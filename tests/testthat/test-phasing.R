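test_that("pair verdicts require both significance and magnitude", {
  linked <- list(percent_linkage = 40, log10_p = -50)
  expect_equal(call_pair_linkage(linked), "linked")
  # significant but tiny magnitude: unlinked
  expect_equal(call_pair_linkage(list(percent_linkage = 1.2, log10_p = -10)),
               "unlinked")
  # large magnitude but not significant: unlinked
  expect_equal(call_pair_linkage(list(percent_linkage = 30, log10_p = -1)),
               "unlinked")
  # exact-independence counts
  res <- estimate_linkage(droplet_counts(2500, 2500, 2500, 2500),
                          partition_config(ci_reps = 0L))
  expect_equal(call_pair_linkage(res), "unlinked")
})

test_that("simulated cis and trans duplexes are called correctly at study load", {
  cis <- analyze_amplitudes(
    simulate_experiment(sim_config(dip = cis_diplotype(), distance_kb = 11,
                                   mean_intact_kb = 72, seed = 41)),
    partition_config(ci_reps = 0L))
  expect_equal(call_pair_linkage(cis), "linked")
  expect_lt(cis$log10_p, -16)

  trans <- analyze_amplitudes(
    simulate_experiment(sim_config(dip = trans_diplotype(), distance_kb = 11,
                                   mean_intact_kb = 72, seed = 42)),
    partition_config(ci_reps = 0L))
  expect_equal(call_pair_linkage(trans), "unlinked")
  expect_lt(trans$percent_linkage, 2)
})

quad_rows <- function(pcts, log10_ps) {
  tibble::tibble(duplex = c("AB", "Ab", "aB", "ab"),
                 percent_linkage = pcts, log10_p = log10_ps)
}

test_that("diplotype calls follow the joint quad pattern", {
  hot <- -300; cold <- -0.2
  cis <- call_diplotype(quad_rows(c(70, 0, 0, 70), c(hot, cold, cold, hot)))
  expect_equal(cis$configuration, "cis_AB")
  expect_true(cis$consistent)
  expect_equal(cis$haplotypes, list(c("A", "B"), c("a", "b")))

  mirror <- call_diplotype(quad_rows(c(0, 70, 70, 0), c(cold, hot, hot, cold)))
  expect_equal(mirror$configuration, "cis_Ab")
  expect_equal(mirror$haplotypes, list(c("A", "b"), c("a", "B")))

  # all unlinked: fragmented DNA, indeterminate
  frag <- call_diplotype(quad_rows(c(0.5, 0.3, 0.2, 0.6), rep(cold, 4)))
  expect_equal(frag$configuration, "indeterminate")
  expect_match(frag$reason, "fragmented")

  # contradictory pattern never becomes a cis call
  contra <- call_diplotype(quad_rows(c(70, 70, 0, 70), c(hot, hot, cold, hot)))
  expect_equal(contra$configuration, "indeterminate")
  expect_match(contra$reason, "inconsistent")

  expect_error(call_diplotype(quad_rows(c(1, 1, 1, 1), rep(cold, 4))[1:3, ]),
               class = "dropphase_quad_input_error")
})

test_that("a trans compound heterozygote quad places the variants on opposite haplotypes", {
  # two deleterious alleles (A = variant at locus 1, B = variant at locus 2)
  # inherited in trans: the cross duplexes are linked
  dip <- trans_diplotype()
  quad <- purrr::imap_dfr(quad_duplexes(), function(assay, nm) {
    sim <- simulate_experiment(sim_config(dip = dip, assay = assay,
                                          distance_kb = 11, mean_intact_kb = 72,
                                          seed = 50 + match(nm, c("AB", "Ab", "aB", "ab"))))
    res <- analyze_amplitudes(sim, partition_config(ci_reps = 0L))
    tibble::tibble(duplex = nm, percent_linkage = res$percent_linkage,
                   log10_p = res$log10_p)
  })
  call <- call_diplotype(quad)
  expect_equal(call$configuration, "cis_Ab")
  expect_true(call$consistent)
  # complementarity: opposite alleles at both loci
  expect_false(call$haplotypes[[1]][1] == call$haplotypes[[2]][1])
  expect_false(call$haplotypes[[1]][2] == call$haplotypes[[2]][2])
})

test_that("trio transmission deduces phase when it is forced", {
  expect_equal(trio_expected_phase(c("AA", "BB"), c("aa", "bb"), c("Aa", "Bb")),
               "cis_AB")
  expect_equal(trio_expected_phase(c("AA", "bb"), c("aa", "BB"), c("Aa", "Bb")),
               "cis_Ab")
  expect_equal(trio_expected_phase(c("Aa", "Bb"), c("Aa", "Bb"), c("Aa", "Bb")),
               "unknown")
  # one ambiguous locus is enough to block deduction
  expect_equal(trio_expected_phase(c("AA", "Bb"), c("aa", "Bb"), c("Aa", "Bb")),
               "unknown")
  expect_error(trio_expected_phase(c("AA", "BB"), c("AA", "BB"), c("Aa", "Bb")),
               class = "dropphase_trio_error")
  expect_error(trio_expected_phase(c("AA", "BB"), c("aa", "bb"), c("AA", "Bb")),
               class = "dropphase_trio_error")
})

test_that("every scenario table phase matches its own trio deduction", {
  scen <- trio_scenarios()
  for (i in seq_len(nrow(scen))) {
    expect_equal(
      trio_expected_phase(c(scen$father_1[i], scen$father_2[i]),
                          c(scen$mother_1[i], scen$mother_2[i]),
                          c("Aa", "Bb")),
      scen$phase[i],
      info = paste("assay", scen$assay[i]))
  }
})
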