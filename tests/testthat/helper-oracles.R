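# Independent oracles used across tests. These are written from first
# principles (Poisson zero classes, direct per-droplet sampling) and do not
# call the estimator they are checking.

# Expected droplet class fractions for species means (fa, fb, lab):
# a droplet lacks target A iff it receives zero free-A and zero linked
# molecules, P(A-) = exp(-(fa + lab)); similarly for B; the double-negative
# class requires zero molecules of all three species.
oracle_fractions <- function(fa, fb, lab) {
  fa <- unname(fa); fb <- unname(fb); lab <- unname(lab)
  p_a0 <- exp(-(fa + lab))
  p_b0 <- exp(-(fb + lab))
  p_nn <- exp(-(fa + fb + lab))
  c(pp = 1 - p_a0 - p_b0 + p_nn,
    pn = p_b0 - p_nn,
    np = p_a0 - p_nn,
    nn = p_nn)
}

# Direct per-droplet Poisson sampling of the three species, tallied into
# the four classes (the sampling oracle for estimator consistency).
oracle_sample_counts <- function(fa, fb, lab, n, seed) {
  withr::with_seed(seed, {
    na <- rpois(n, fa); nb <- rpois(n, fb); nab <- rpois(n, lab)
    a_pos <- (na + nab) > 0
    b_pos <- (nb + nab) > 0
    droplet_counts(n_pp = sum(a_pos & b_pos), n_pn = sum(a_pos & !b_pos),
                   n_np = sum(!a_pos & b_pos), n_nn = sum(!a_pos & !b_pos))
  })
}

# Expected fractions pushed through droplet_counts (fractional counts are
# legal there precisely for this purpose).
expected_counts <- function(fa, fb, lab, n = 1) {
  f <- oracle_fractions(fa, fb, lab) * n
  droplet_counts(n_pp = f[["pp"]], n_pn = f[["pn"]],
                 n_np = f[["np"]], n_nn = f[["nn"]])
}
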