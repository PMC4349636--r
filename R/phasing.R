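#' Linked/unlinked verdict for one duplex measurement
#'
#' A duplex is called linked when the chi-square test rejects
#' independence at level `alpha` *and* the estimated percent linkage
#' reaches `min_pct`. The default `min_pct = 2` reflects the largest
#' percent linkage observed for truly unlinked allele pairs at typical
#' loading; the default `alpha = 1e-3` makes chance calls rare across a
#' quad of tests.
#'
#' @param result A `linkage_result` from [estimate_linkage()], or a list
#'   with elements `percent_linkage` and `log10_p` (or `p_value`).
#' @param alpha Significance level.
#' @param min_pct Minimum percent linkage for a linked call.
#' @return `"linked"` or `"unlinked"`.
#' @export
call_pair_linkage <- function(result, alpha = 1e-3, min_pct = 2) {
  log10_p <- result$log10_p %||% log10(result$p_value)
  if (is.null(log10_p) || is.null(result$percent_linkage)) {
    abort("result must carry percent_linkage and log10_p/p_value")
  }
  if (log10_p < log10(alpha) && result$percent_linkage >= min_pct) {
    "linked"
  } else {
    "unlinked"
  }
}

#' Diplotype call from a redundant quad-duplex experiment
#'
#' The four duplexes of a quad cover all allele pairings `AB`, `Ab`,
#' `aB`, `ab`. Given intact DNA, exactly one complementary pair of
#' duplexes is linked (revealing the diplotype) while the other pair is
#' unlinked (serving as internal negative control). The call uses the
#' joint pattern: any other pattern is indeterminate -- a single
#' discordant duplex forces indeterminate rather than a majority vote,
#' because the redundancy exists to critically check the call. All four
#' duplexes unlinked indicates DNA too fragmented between the loci to
#' establish phase.
#'
#' @param quad A tibble/data frame with columns `duplex` (exactly the
#'   four identities `AB`, `Ab`, `aB`, `ab`), `percent_linkage`, and
#'   `log10_p` (or `p_value`) -- e.g. four rows of
#'   `tidy(estimate_linkage(...))` plus a `duplex` column -- or a named
#'   list of four `linkage_result` objects.
#' @param alpha,min_pct Verdict thresholds; see [call_pair_linkage()].
#' @return A `diplotype_call` object with fields `configuration`
#'   (`"cis_AB"`, `"cis_Ab"`, or `"indeterminate"`), `haplotypes`,
#'   `consistent`, `verdicts` (named character), and `reason`.
#' @export
call_diplotype <- function(quad, alpha = 1e-3, min_pct = 2) {
  if (is.list(quad) && !is.data.frame(quad) &&
      all(vapply(quad, inherits, logical(1), "linkage_result"))) {
    quad <- purrr::imap_dfr(quad, function(r, nm) {
      tibble::tibble(duplex = nm, percent_linkage = r$percent_linkage,
                     log10_p = r$log10_p)
    })
  }
  stopifnot(is.data.frame(quad))
  need <- c("AB", "Ab", "aB", "ab")
  if (!setequal(quad$duplex, need) || nrow(quad) != 4L) {
    abort("quad must contain exactly the four duplex identities AB, Ab, aB, ab",
          class = "dropphase_quad_input_error")
  }
  if (is.null(quad$log10_p)) quad$log10_p <- log10(quad$p_value)
  verdicts <- vapply(need, function(d) {
    row <- quad[quad$duplex == d, ]
    call_pair_linkage(list(percent_linkage = row$percent_linkage,
                           log10_p = row$log10_p),
                      alpha = alpha, min_pct = min_pct)
  }, character(1))
  linked <- names(verdicts)[verdicts == "linked"]
  if (setequal(linked, c("AB", "ab"))) {
    configuration <- "cis_AB"
    haplotypes <- list(c("A", "B"), c("a", "b"))
    consistent <- TRUE
    reason <- "complementary duplexes AB and ab linked; Ab and aB unlinked"
  } else if (setequal(linked, c("Ab", "aB"))) {
    configuration <- "cis_Ab"
    haplotypes <- list(c("A", "b"), c("a", "B"))
    consistent <- TRUE
    reason <- "complementary duplexes Ab and aB linked; AB and ab unlinked"
  } else if (length(linked) == 0L) {
    configuration <- "indeterminate"
    haplotypes <- NULL
    consistent <- FALSE
    reason <- "no duplex shows linkage: DNA between the loci is likely too fragmented to phase"
  } else {
    configuration <- "indeterminate"
    haplotypes <- NULL
    consistent <- FALSE
    reason <- paste0("inconsistent linkage pattern (linked: ",
                     paste(linked, collapse = ", "),
                     "); redundant duplexes contradict each other")
  }
  if (!is.null(haplotypes)) {
    # complementarity is structural: the two haplotypes must carry
    # opposite alleles at both loci
    stopifnot(haplotypes[[1]][1] != haplotypes[[2]][1],
              haplotypes[[1]][2] != haplotypes[[2]][2])
  }
  structure(list(configuration = configuration, haplotypes = haplotypes,
                 consistent = consistent, verdicts = verdicts,
                 reason = reason, alpha = alpha, min_pct = min_pct,
                 quad = tibble::as_tibble(quad)),
            class = "diplotype_call")
}

#' @export
print.diplotype_call <- function(x, ...) {
  cat("<diplotype_call>", x$configuration, "\n")
  if (!is.null(x$haplotypes)) {
    cat(sprintf("  haplotypes: %s-%s / %s-%s\n",
                x$haplotypes[[1]][1], x$haplotypes[[1]][2],
                x$haplotypes[[2]][1], x$haplotypes[[2]][2]))
  }
  cat("  verdicts:", paste(names(x$verdicts), x$verdicts, sep = "=",
                           collapse = ", "), "\n")
  cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.diplotype_call <- function(x, ...) {
  tibble::tibble(
    configuration = x$configuration,
    hap1 = if (is.null(x$haplotypes)) NA_character_ else
      paste(x$haplotypes[[1]], collapse = "-"),
    hap2 = if (is.null(x$haplotypes)) NA_character_ else
      paste(x$haplotypes[[2]], collapse = "-"),
    consistent = x$consistent,
    verdict_AB = unname(x$verdicts["AB"]), verdict_Ab = unname(x$verdicts["Ab"]),
    verdict_aB = unname(x$verdicts["aB"]), verdict_ab = unname(x$verdicts["ab"]),
    reason = x$reason
  )
}

parse_genotype <- function(g, alleles, who, locus) {
  ch <- strsplit(g, "")[[1]]
  if (length(ch) != 2L || !all(ch %in% alleles)) {
    abort(paste0(who, " genotype at locus ", locus, " must be two of {",
                 paste(alleles, collapse = ","), "}: got '", g, "'"))
  }
  ch
}

#' Expected two-locus phase of a child from parental genotypes
#'
#' Deduces the child's cis/trans configuration by transmission when it is
#' uniquely determined (e.g. a parent homozygous at each locus pins down
#' which alleles travelled together). Returns `"unknown"` when
#' transmission is ambiguous, e.g. when both parents are double
#' heterozygotes.
#'
#' @param father,mother,child Length-2 character vectors of genotypes at
#'   the two loci, e.g. `c("Aa", "Bb")`; locus 1 uses alleles `A`/`a`,
#'   locus 2 `B`/`b`.
#' @return `"cis_AB"` (A and B on one haplotype), `"cis_Ab"` (A with b,
#'   i.e. A and B in trans), or `"unknown"`. Non-Mendelian genotypes are
#'   an error.
#' @examples
#' trio_expected_phase(c("AA", "BB"), c("aa", "bb"), c("Aa", "Bb"))  # cis_AB
#' trio_expected_phase(c("AA", "bb"), c("aa", "BB"), c("Aa", "Bb"))  # cis_Ab
#' @export
trio_expected_phase <- function(father, mother, child) {
  alleles <- list(c("A", "a"), c("B", "b"))
  f <- purrr::map2(father, 1:2, ~parse_genotype(.x, alleles[[.y]], "father", .y))
  m <- purrr::map2(mother, 1:2, ~parse_genotype(.x, alleles[[.y]], "mother", .y))
  k <- purrr::map2(child, 1:2, ~parse_genotype(.x, alleles[[.y]], "child", .y))
  if (any(vapply(k, function(g) g[1] == g[2], logical(1)))) {
    abort("child must be heterozygous at both loci for phase to be meaningful",
          class = "dropphase_trio_error")
  }
  # per locus: which child allele can be paternal?
  paternal_options <- purrr::pmap(list(f, m, k), function(fg, mg, kg) {
    opts <- character(0)
    for (pat in unique(kg)) {
      mat <- setdiff(kg, pat)
      if (length(mat) == 0L) mat <- pat  # both child alleles equal (excluded above)
      if (pat %in% fg && mat %in% mg) opts <- c(opts, pat)
    }
    unique(opts)
  })
  if (any(lengths(paternal_options) == 0L)) {
    abort("genotypes are not Mendelian-consistent",
          class = "dropphase_trio_error")
  }
  combos <- expand.grid(l1 = paternal_options[[1]], l2 = paternal_options[[2]],
                        stringsAsFactors = FALSE)
  phases <- unique(ifelse((combos$l1 == "A") == (combos$l2 == "B"),
                          "cis_AB", "cis_Ab"))
  if (length(phases) == 1L) phases else "unknown"
}
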