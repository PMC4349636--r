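test_that("diplotype construction enforces the double-heterozygote invariant", {
  expect_s3_class(cis_diplotype(), "diplotype")
  expect_error(diplotype(c("A", "B"), c("A", "b")), "opposite alleles")
  expect_error(diplotype(c("A", "X"), c("a", "b")), "allele pairs")
})

test_that("species mix follows the fragmentation split", {
  # zero distance: all haplotype mass is linked
  mix0 <- species_from_diplotype(cis_diplotype(), distance_kb = 0,
                                 mean_intact_kb = 72)
  expect_equal(sum(mix0$mean[mix0$kind == "free"]), 0)
  expect_equal(mix0$mean[mix0$species == "linked_AB"], 100 * 8.5e-4)

  # trans diplotype never produces a linked A-B species
  mixt <- species_from_diplotype(trans_diplotype(), distance_kb = 5,
                                 mean_intact_kb = 72)
  expect_false("linked_AB" %in% mixt$species[mixt$mean > 0])
  expect_true(all(c("linked_Ab", "linked_aB") %in% mixt$species))

  # calibrated intact probability: 42% at 60 kb
  expect_equal(intact_probability(60, 69.16), 0.420, tolerance = 1e-3)
  mix60 <- species_from_diplotype(cis_diplotype(), 60, 69.16)
  expect_equal(mix60$mean[mix60$species == "linked_AB"] / (100 * 8.5e-4),
               0.420, tolerance = 1e-3)
})

test_that("per-locus totals are conserved by fragmentation and digest", {
  for (d in c(0, 11, 60, 150, Inf)) {
    mix <- species_from_diplotype(cis_diplotype(c(120, 80)), d, 69)
    for (al in c("A", "a", "B", "b")) {
      hap_conc <- if (al %in% c("A", "B")) 120 else 80
      expect_equal(allele_rate(mix, al), hap_conc * 8.5e-4)
      expect_equal(allele_rate(apply_digest(mix), al), hap_conc * 8.5e-4)
    }
  }
})

test_that("digest moves linked mass to the constituent free species", {
  mix <- species_from_diplotype(cis_diplotype(), 11, 72)
  linked <- mix$mean[mix$species == "linked_AB"]
  expect_gt(linked, 0)
  dig <- apply_digest(mix)
  expect_equal(sum(dig$mean[dig$kind == "linked"]), 0)
  expect_equal(dig$mean[dig$species == "free_A"],
               mix$mean[mix$species == "free_A"] + linked)
  # a mix with no linked mass is unchanged
  expect_equal(apply_digest(dig), dig)
})

test_that("partitioning is Poisson and reproducible", {
  mix <- species_from_diplotype(cis_diplotype(), 11, 72)
  occ1 <- partition_droplets(mix, 20000, seed = 3)
  occ2 <- partition_droplets(mix, 20000, seed = 3)
  expect_identical(occ1, occ2)

  # per-species empirical means within 3 SE
  for (s in mix$species[mix$mean > 0]) {
    m <- mix$mean[mix$species == s]
    expect_lt(abs(mean(occ1[[s]]) - m), 3 * sqrt(m / 20000))
  }

  # empty fraction matches the Poisson zero class
  lambda_tot <- sum(mix$mean)
  empty <- mean(rowSums(occ1[, mix$species]) == 0)
  p0 <- exp(-lambda_tot)
  expect_lt(abs(empty - p0), 3 * sqrt(p0 * (1 - p0) / 20000))

  # all-zero mix leaves every droplet empty
  empty_mix <- mix
  empty_mix$mean <- 0
  occ0 <- partition_droplets(empty_mix, 100, seed = 1)
  expect_true(all(rowSums(occ0[, empty_mix$species]) == 0))
})

test_that("noise-free cross-reacting duplexes produce exactly 16 amplitude patterns", {
  grid <- tidyr::expand_grid(free_A = 0:1, free_a = 0:1, free_B = 0:1,
                             free_b = 0:1)
  occ <- dplyr::bind_cols(tibble::tibble(droplet = seq_len(nrow(grid))), grid)
  fm0 <- fluor_model(ch1_sd = 0, ch2_sd = 0)
  amp <- render_amplitudes(occ, duplex_assay("A", "B"), fm0, seed = 1)
  patterns <- unique(paste(amp$ch1_amplitude, amp$ch2_amplitude))
  expect_length(patterns, 16)
  # empty droplet sits at the empty-level pair
  empty_row <- which(rowSums(grid) == 0)
  expect_equal(amp$ch1_amplitude[empty_row], 1000)
  expect_equal(amp$ch2_amplitude[empty_row], 1000)
})

test_that("simulated experiments carry correct ground truth", {
  cfg <- sim_config(dip = cis_diplotype(), n_droplets = 20000,
                    distance_kb = 11, mean_intact_kb = 72, seed = 8)
  sim <- simulate_experiment(cfg)
  expect_equal(sim$truth$percent_linkage, 100 * exp(-11 / 72), tolerance = 1e-9)
  expect_equal(sim$counts$n_total, 20000)

  # empirical class fractions match the closed form within 3 SE
  fa <- sim$truth$lambda_A - sim$truth$lambda_AB
  fb <- sim$truth$lambda_B - sim$truth$lambda_AB
  f <- oracle_fractions(fa, fb, sim$truth$lambda_AB)
  obs <- c(sim$counts$n_pp, sim$counts$n_pn, sim$counts$n_np, sim$counts$n_nn)
  for (k in 1:4) {
    se <- sqrt(f[k] * (1 - f[k]) / 20000)
    expect_lt(abs(obs[k] / 20000 - f[k]), 3 * se)
  }

  # digest control abolishes linked molecules
  simd <- simulate_experiment(sim_config(dip = cis_diplotype(),
                                         n_droplets = 20000, distance_kb = 11,
                                         mean_intact_kb = 72, digest = TRUE,
                                         seed = 8))
  expect_equal(simd$truth$lambda_AB, 0)
  expect_equal(simd$truth$percent_linkage, 0)

  # trans quad: only the complementary duplex pair has linked species
  dip <- trans_diplotype()
  linked_means <- sapply(quad_duplexes(), function(assay) {
    s <- species_from_diplotype(dip, 11, 72)
    sum(s$mean[s$species == paste0("linked_", assay$duplex)])
  })
  expect_true(all(linked_means[c("Ab", "aB")] > 0))
  expect_equal(unname(linked_means[c("AB", "ab")]), c(0, 0))
})

test_that("fragment-scale mixtures average the intact probability", {
  p <- intact_probability(50, c(30, 120), weights = c(0.5, 0.5))
  expect_equal(p, 0.5 * exp(-50 / 30) + 0.5 * exp(-50 / 120))
  expect_equal(intact_probability(Inf, 69), 0)
})
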