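#' Two-locus diplotype
#'
#' The two haplotypes of a double heterozygote, written as allele pairs
#' at the two assayed loci. Locus 1 alleles are `"A"`/`"a"`, locus 2
#' alleles `"B"`/`"b"`. The two haplotypes must carry opposite alleles at
#' both loci.
#'
#' @param hap1,hap2 Length-2 character vectors, e.g. `c("A", "B")`.
#' @param copies_per_ul Per-haplotype copy concentration (copies/uL),
#'   length 2 (recycled if length 1). The default 100 copies/uL per
#'   haplotype gives about 0.17 molecules per 0.85 nL droplet per locus,
#'   the typical genomic DNA loading.
#' @return A `diplotype` object.
#' @examples
#' diplotype(c("A", "B"), c("a", "b"))  # cis arrangement of A and B
#' @export
diplotype <- function(hap1, hap2, copies_per_ul = c(100, 100)) {
  copies_per_ul <- rep_len(copies_per_ul, 2L)
  ok1 <- hap1[1] %in% c("A", "a") && hap1[2] %in% c("B", "b")
  ok2 <- hap2[1] %in% c("A", "a") && hap2[2] %in% c("B", "b")
  if (!ok1 || !ok2) {
    abort("haplotypes must be allele pairs over {A,a} x {B,b}")
  }
  if (hap1[1] == hap2[1] || hap1[2] == hap2[2]) {
    abort("haplotypes must carry opposite alleles at both loci (double heterozygote)")
  }
  if (any(copies_per_ul < 0)) abort("copy concentrations must be non-negative")
  structure(list(hap1 = hap1, hap2 = hap2, copies_per_ul = copies_per_ul),
            class = "diplotype")
}

#' @rdname diplotype
#' @export
cis_diplotype <- function(copies_per_ul = c(100, 100)) {
  diplotype(c("A", "B"), c("a", "b"), copies_per_ul)
}

#' @rdname diplotype
#' @export
trans_diplotype <- function(copies_per_ul = c(100, 100)) {
  diplotype(c("A", "b"), c("a", "B"), copies_per_ul)
}

#' @export
print.diplotype <- function(x, ...) {
  cat(sprintf("<diplotype> %s-%s / %s-%s (%.0f, %.0f copies/uL)\n",
              x$hap1[1], x$hap1[2], x$hap2[1], x$hap2[2],
              x$copies_per_ul[1], x$copies_per_ul[2]))
  invisible(x)
}

#' Fluorescence level model for cross-reacting allele probes
#'
#' Each channel's probe targets one allele but also responds, at reduced
#' intensity, to the non-targeted allele. A droplet therefore shows one of
#' four mean amplitudes per channel, ordered target-only > target +
#' non-target mixture > non-target only > empty. Default level means
#' (8000, 6000, 2500, 1000 arbitrary units, SD 300) reproduce the
#' qualitative geometry of real two-channel scatter plots.
#'
#' @param ch1_levels,ch2_levels Named numeric vectors with elements
#'   `empty`, `nontarget`, `mixture`, `target`, strictly increasing in
#'   that order.
#' @param ch1_sd,ch2_sd Gaussian amplitude noise SD per channel
#'   (non-negative; zero gives noise-free amplitudes).
#' @return A `fluor_model` object.
#' @export
fluor_model <- function(ch1_levels = c(empty = 1000, nontarget = 2500,
                                       mixture = 6000, target = 8000),
                        ch2_levels = ch1_levels,
                        ch1_sd = 300, ch2_sd = 300) {
  check_levels <- function(lv, ch) {
    need <- c("empty", "nontarget", "mixture", "target")
    if (!all(need %in% names(lv))) {
      abort(paste0(ch, "_levels must be named: ", paste(need, collapse = ", ")))
    }
    lv <- lv[need]
    if (any(diff(lv) <= 0)) {
      abort(paste0(ch, " level means must satisfy empty < nontarget < mixture < target"))
    }
    lv
  }
  if (ch1_sd < 0 || ch2_sd < 0) abort("amplitude noise SDs must be non-negative")
  structure(list(ch1_levels = check_levels(ch1_levels, "ch1"),
                 ch2_levels = check_levels(ch2_levels, "ch2"),
                 ch1_sd = ch1_sd, ch2_sd = ch2_sd),
            class = "fluor_model")
}

#' Duplex assay definition
#'
#' A duplex assay targets one allele at each locus: channel 1 (FAM) reads
#' the locus-1 allele, channel 2 (HEX) the locus-2 allele.
#'
#' @param ch1_target `"A"` or `"a"`.
#' @param ch2_target `"B"` or `"b"`.
#' @return A `duplex_assay` object with a `duplex` identity string such
#'   as `"AB"`.
#' @export
duplex_assay <- function(ch1_target = "A", ch2_target = "B") {
  if (!ch1_target %in% c("A", "a") || !ch2_target %in% c("B", "b")) {
    abort("ch1_target must be A/a and ch2_target B/b")
  }
  structure(list(ch1_target = ch1_target, ch2_target = ch2_target,
                 duplex = paste0(ch1_target, ch2_target)),
            class = "duplex_assay")
}

#' The four duplexes of a quad-duplex design
#'
#' @return A named list of the four [duplex_assay()] objects `AB`, `Ab`,
#'   `aB`, `ab`, covering every allele pairing of a compound heterozygote.
#' @export
quad_duplexes <- function() {
  out <- list(AB = duplex_assay("A", "B"), Ab = duplex_assay("A", "b"),
              aB = duplex_assay("a", "B"), ab = duplex_assay("a", "b"))
  out
}

#' Probability that two loci remain on one fragment
#'
#' Fragmentation is modeled as a Poisson break process along the
#' chromosome, so two sequences separated by `distance_kb` survive on a
#' single fragment with probability `exp(-distance_kb / mean_intact_kb)`.
#' A two-component mixture (e.g. two fragment-length populations from
#' different extraction chemistries) is supported via vector
#' `mean_intact_kb` and `weights`.
#'
#' @param distance_kb Genomic separation in kb (0 or more; `Inf` models
#'   loci on different chromosomes).
#' @param mean_intact_kb Mean intact fragment scale(s) L in kb.
#' @param weights Mixture weights (same length as `mean_intact_kb`);
#'   default single component.
#' @return Intact probability in \[0, 1\].
#' @examples
#' intact_probability(60, 69.16)  # about 0.42
#' @export
intact_probability <- function(distance_kb, mean_intact_kb, weights = NULL) {
  if (any(distance_kb < 0)) abort("distance must be non-negative")
  if (any(mean_intact_kb <= 0)) abort("mean intact length must be positive")
  if (is.null(weights)) weights <- rep(1 / length(mean_intact_kb),
                                       length(mean_intact_kb))
  if (length(weights) != length(mean_intact_kb) || any(weights < 0)) {
    abort("weights must be non-negative and match mean_intact_kb")
  }
  weights <- weights / sum(weights)
  sapply(distance_kb, function(d) sum(weights * exp(-d / mean_intact_kb)))
}

species_template <- function() {
  tibble::tibble(
    species = c("free_A", "free_a", "free_B", "free_b"),
    kind = "free",
    allele1 = c("A", "a", NA, NA),
    allele2 = c(NA, NA, "B", "b"),
    mean = 0
  )
}

#' Molecular species mix implied by a diplotype and fragmentation state
#'
#' Each haplotype of per-droplet mean occupancy `lambda_h` contributes
#' `lambda_h * P` to its intact two-locus (linked) species and
#' `lambda_h * (1 - P)` to each of its two free single-locus species,
#' where `P` is the intact probability at the given distance.
#'
#' @param dip A [diplotype()].
#' @param distance_kb Genomic separation of the two loci in kb.
#' @param mean_intact_kb Fragment-survival scale L in kb (vector for a
#'   mixture; see [intact_probability()]).
#' @param droplet_volume Droplet volume in uL.
#' @param weights Optional mixture weights for `mean_intact_kb`.
#' @return A `species_mix` tibble with columns `species`, `kind`,
#'   `allele1`, `allele2`, `mean` (per-droplet occupancy).
#' @export
species_from_diplotype <- function(dip, distance_kb, mean_intact_kb,
                                   droplet_volume = 8.5e-4, weights = NULL) {
  stopifnot(inherits(dip, "diplotype"))
  p_intact <- intact_probability(distance_kb, mean_intact_kb, weights)
  mix <- species_template()
  linked <- list()
  for (h in 1:2) {
    hap <- if (h == 1) dip$hap1 else dip$hap2
    lambda_h <- dip$copies_per_ul[h] * droplet_volume
    mix$mean[mix$species == paste0("free_", hap[1])] <-
      mix$mean[mix$species == paste0("free_", hap[1])] + lambda_h * (1 - p_intact)
    mix$mean[mix$species == paste0("free_", hap[2])] <-
      mix$mean[mix$species == paste0("free_", hap[2])] + lambda_h * (1 - p_intact)
    linked[[h]] <- tibble::tibble(
      species = paste0("linked_", hap[1], hap[2]),
      kind = "linked", allele1 = hap[1], allele2 = hap[2],
      mean = lambda_h * p_intact
    )
  }
  out <- dplyr::bind_rows(mix, linked)
  class(out) <- c("species_mix", class(out))
  out
}

#' Digest all linked species into their free constituents
#'
#' Models a restriction digest at a site between the two loci: every
#' linked species' mean moves to its two constituent free single-locus
#' species, conserving per-locus totals, and abolishing co-partitioning.
#'
#' @param mix A `species_mix` tibble.
#' @return The digested `species_mix`.
#' @export
apply_digest <- function(mix) {
  linked <- dplyr::filter(mix, .data$kind == "linked")
  out <- mix
  for (i in seq_len(nrow(linked))) {
    for (al in c(linked$allele1[i], linked$allele2[i])) {
      j <- which(out$species == paste0("free_", al))
      out$mean[j] <- out$mean[j] + linked$mean[i]
    }
  }
  out$mean[out$kind == "linked"] <- 0
  out
}

#' Total per-droplet rate of molecules carrying an allele
#'
#' @param mix A `species_mix` tibble.
#' @param allele One of `"A"`, `"a"`, `"B"`, `"b"`.
#' @return Summed mean occupancy over every species carrying the allele.
#' @export
allele_rate <- function(mix, allele) {
  sum(mix$mean[!is.na(mix$allele1) & mix$allele1 == allele]) +
    sum(mix$mean[!is.na(mix$allele2) & mix$allele2 == allele])
}

#' Partition a species mix into droplets
#'
#' Each species lands in each droplet as an independent Poisson draw with
#' the species' mean occupancy.
#'
#' @param mix A `species_mix` tibble.
#' @param n_droplets Number of droplets.
#' @param seed RNG seed; identical mix, count, and seed reproduce the
#'   table exactly.
#' @return A tibble with column `droplet` and one integer occupancy
#'   column per species.
#' @export
partition_droplets <- function(mix, n_droplets, seed = 1L) {
  stopifnot(n_droplets > 0)
  occ <- withr::with_seed(seed, {
    vapply(mix$mean, function(m) rpois(n_droplets, m), integer(n_droplets))
  })
  colnames(occ) <- mix$species
  dplyr::bind_cols(tibble::tibble(droplet = seq_len(n_droplets)),
                   tibble::as_tibble(occ))
}

# Per-droplet presence of each allele, parsed from species column names.
allele_presence <- function(occupancy) {
  cols <- setdiff(names(occupancy), "droplet")
  has <- function(allele) {
    carriers <- cols[vapply(cols, function(nm) {
      if (startsWith(nm, "free_")) substring(nm, 6) == allele
      else allele %in% strsplit(substring(nm, 8), "")[[1]]
    }, logical(1))]
    if (!length(carriers)) return(rep(FALSE, nrow(occupancy)))
    rowSums(occupancy[, carriers, drop = FALSE]) > 0
  }
  tibble::tibble(A = has("A"), a = has("a"), B = has("B"), b = has("b"))
}

channel_state <- function(target_present, nontarget_present) {
  # 1 empty, 2 non-target only, 3 mixture, 4 target only
  dplyr::case_when(
    target_present & !nontarget_present ~ 4L,
    target_present & nontarget_present ~ 3L,
    !target_present & nontarget_present ~ 2L,
    TRUE ~ 1L
  )
}

#' Render two-channel fluorescence amplitudes for an occupancy table
#'
#' Each droplet's channel state is set by presence/absence of the
#' targeted and non-targeted alleles at that channel's locus (four states
#' per channel); the amplitude is the state's mean plus Gaussian noise.
#' With two cross-reacting assays the noise-free amplitude pairs take at
#' most 16 distinct values.
#'
#' @param occupancy Per-droplet species table from [partition_droplets()].
#' @param assay A [duplex_assay()].
#' @param fm A [fluor_model()].
#' @param seed RNG seed for the amplitude noise.
#' @param well Well label written to the `well` column.
#' @return A tibble with columns `well`, `ch1_amplitude`, `ch2_amplitude`.
#' @export
render_amplitudes <- function(occupancy, assay, fm = fluor_model(),
                              seed = 1L, well = "A01") {
  pres <- allele_presence(occupancy)
  other <- c(A = "a", a = "A", B = "b", b = "B")
  s1 <- channel_state(pres[[assay$ch1_target]], pres[[other[[assay$ch1_target]]]])
  s2 <- channel_state(pres[[assay$ch2_target]], pres[[other[[assay$ch2_target]]]])
  n <- nrow(occupancy)
  amp <- withr::with_seed(seed, {
    cbind(unname(fm$ch1_levels)[s1] + rnorm(n, 0, fm$ch1_sd),
          unname(fm$ch2_levels)[s2] + rnorm(n, 0, fm$ch2_sd))
  })
  tibble::tibble(well = well, ch1_amplitude = amp[, 1], ch2_amplitude = amp[, 2])
}

#' Ground-truth droplet class counts from an occupancy table
#'
#' @param occupancy Per-droplet species table from [partition_droplets()].
#' @param assay A [duplex_assay()]; positivity means the droplet contains
#'   at least one molecule carrying the targeted allele.
#' @param well_id Optional well label.
#' @return A [droplet_counts()] object.
#' @export
true_counts <- function(occupancy, assay, well_id = NA_character_) {
  pres <- allele_presence(occupancy)
  p1 <- pres[[assay$ch1_target]]
  p2 <- pres[[assay$ch2_target]]
  droplet_counts(n_pp = sum(p1 & p2), n_pn = sum(p1 & !p2),
                 n_np = sum(!p1 & p2), n_nn = sum(!p1 & !p2),
                 well_id = well_id)
}

#' Simulation configuration
#'
#' @param dip A [diplotype()].
#' @param assay A [duplex_assay()].
#' @param fm A [fluor_model()].
#' @param n_droplets Droplets per well (default 20000, the typical
#'   droplet count of one well).
#' @param droplet_volume Droplet volume in uL (default 0.85 nL).
#' @param distance_kb Genomic separation of the loci in kb (`Inf` for
#'   different chromosomes).
#' @param mean_intact_kb Fragment-survival scale L in kb.
#' @param weights Optional fragment-scale mixture weights.
#' @param digest If `TRUE`, apply [apply_digest()] before partitioning
#'   (restriction-digest control).
#' @param seed RNG seed for the whole experiment.
#' @param well_id Well label.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dip = cis_diplotype(), assay = duplex_assay(),
                       fm = fluor_model(), n_droplets = 20000L,
                       droplet_volume = 8.5e-4, distance_kb = 11,
                       mean_intact_kb = 72, weights = NULL,
                       digest = FALSE, seed = 1L, well_id = "A01") {
  stopifnot(inherits(dip, "diplotype"), inherits(assay, "duplex_assay"),
            inherits(fm, "fluor_model"), n_droplets > 0,
            droplet_volume > 0, distance_kb >= 0,
            all(mean_intact_kb > 0))
  structure(list(dip = dip, assay = assay, fm = fm,
                 n_droplets = as.integer(n_droplets),
                 droplet_volume = droplet_volume, distance_kb = distance_kb,
                 mean_intact_kb = mean_intact_kb, weights = weights,
                 digest = digest, seed = as.integer(seed), well_id = well_id),
            class = "sim_config")
}

#' Simulate a complete Drop-Phase well
#'
#' Composes fragmentation, Poisson partitioning, and fluorescence
#' rendering, attaching per-droplet ground truth: the species mix, the
#' true droplet class counts, the assay's true species rates, and the
#' true percent linkage.
#'
#' @param cfg A [sim_config()].
#' @return A `drop_phase_sim` object: a list with `amplitudes` (tibble),
#'   `occupancy`, `counts` (ground-truth [droplet_counts()]), `species`,
#'   `truth` (true rates and percent linkage), and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_droplets = 5000, seed = 42))
#' sim$truth$percent_linkage
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mix <- species_from_diplotype(cfg$dip, cfg$distance_kb, cfg$mean_intact_kb,
                                cfg$droplet_volume, cfg$weights)
  if (cfg$digest) mix <- apply_digest(mix)
  occupancy <- partition_droplets(mix, cfg$n_droplets, seed = cfg$seed)
  amplitudes <- render_amplitudes(occupancy, cfg$assay, cfg$fm,
                                  seed = cfg$seed + 1L, well = cfg$well_id)
  counts <- true_counts(occupancy, cfg$assay, well_id = cfg$well_id)
  lambda_A <- allele_rate(mix, cfg$assay$ch1_target)
  lambda_B <- allele_rate(mix, cfg$assay$ch2_target)
  linked_id <- paste0("linked_", cfg$assay$ch1_target, cfg$assay$ch2_target)
  lambda_AB <- sum(mix$mean[mix$species == linked_id])
  anchor <- min(lambda_A, lambda_B)
  truth <- list(
    lambda_A = lambda_A, lambda_B = lambda_B, lambda_AB = lambda_AB,
    percent_linkage = if (anchor > 0) 100 * lambda_AB / anchor else NA_real_
  )
  structure(list(amplitudes = amplitudes, occupancy = occupancy,
                 counts = counts, species = mix, truth = truth, config = cfg),
            class = "drop_phase_sim")
}

#' @export
print.drop_phase_sim <- function(x, ...) {
  cat(sprintf("<drop_phase_sim> well %s: %d droplets, duplex %s, d = %s kb\n",
              x$config$well_id, x$config$n_droplets, x$config$assay$duplex,
              format(x$config$distance_kb)))
  cat(sprintf("  true %%linkage: %.2f%%  (lambda_A %.3f, lambda_B %.3f, lambda_AB %.4f)\n",
              x$truth$percent_linkage, x$truth$lambda_A, x$truth$lambda_B,
              x$truth$lambda_AB))
  invisible(x)
}
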