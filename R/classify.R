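# Fit up to max_levels fluorescence levels to one channel's amplitudes.
# Equal-variance 1-D Gaussian mixture, EM initialized from evenly spaced
# centers, number of components selected by BIC. Works on an evenly
# rank-spaced subset so the cost is independent of droplet count.
fit_channel_levels <- function(x, max_levels = 4L, subset_size = 2000L) {
  xs <- sort(x[is.finite(x)])
  if (!length(xs)) abort("no finite amplitudes in channel")
  sub <- xs[unique(round(seq(1, length(xs), length.out = min(subset_size, length(xs)))))]
  ux <- unique(sub)
  if (length(ux) <= max_levels) return(sort(unique(xs)))
  best <- NULL
  best_bic <- -Inf
  for (g in seq_len(max_levels)) {
    if (g == 1L) {
      ll <- sum(stats::dnorm(sub, mean(sub), stats::sd(sub), log = TRUE))
      bic <- 2 * ll - 2 * log(length(sub))
      if (bic > best_bic) {
        best_bic <- bic
        best <- mean(sub)
      }
      next
    }
    centers <- seq(min(sub), max(sub), length.out = g)
    assign0 <- max.col(-abs(outer(sub, centers, "-")))
    if (length(unique(assign0)) < g) next
    z <- mclust::unmap(assign0, groups = seq_len(g))
    fit <- tryCatch({
      ms <- mclust::mstepE(sub, z)
      mclust::emE(sub, ms$parameters)
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik)) next
    bic <- 2 * fit$loglik - 2 * g * log(length(sub))  # g means, g-1 props, 1 var
    if (bic > best_bic) {
      best_bic <- bic
      best <- fit$parameters$mean[fit$parameters$pro > 0.001]
    }
  }
  sort(unname(best))
}

# Positive/negative cut from sorted level means. With all four levels the
# cut separates {empty, non-target} from {mixture, target-only}; with
# fewer populated levels the widest gap separates negatives from
# positives; a single level means no positive droplets.
threshold_from_levels <- function(levels, x) {
  k <- length(levels)
  if (k >= 4) {
    mean(levels[2:3])
  } else if (k >= 2) {
    gaps <- diff(levels)
    i <- which.max(gaps)
    (levels[i] + levels[i + 1]) / 2
  } else {
    max(x) + 1
  }
}

#' Fit per-channel positivity thresholds from droplet amplitudes
#'
#' Cross-reacting allele probes produce up to four fluorescence levels
#' per channel (target-only, target + non-target mixture, non-target
#' only, empty). Phasing only requires separating droplets that contain
#' the targeted allele (the top two levels) from those that do not (the
#' bottom two). Levels are fitted per channel with an equal-variance
#' one-dimensional Gaussian mixture (EM from evenly spaced centers,
#' component count by BIC over 1..4); with four fitted levels the
#' threshold is the midpoint of the 2nd and 3rd sorted level means, with
#' two or three levels the midpoint of the widest gap, and with a single
#' level (e.g. an all-empty well) the threshold sits above the observed
#' maximum so every droplet is negative.
#'
#' @param amplitudes A tibble with columns `ch1_amplitude` and
#'   `ch2_amplitude` (as produced by [simulate_experiment()] or
#'   [read_amplitude_csv()]).
#' @param min_droplets Minimum droplets required for a stable fit.
#' @return A `channel_thresholds` object: list with `ch1`, `ch2`
#'   (numeric cuts) and `levels` (fitted level means per channel).
#' @export
fit_thresholds <- function(amplitudes, min_droplets = 1000L) {
  if (nrow(amplitudes) < min_droplets) {
    abort(paste0("need at least ", min_droplets, " droplets to fit thresholds"),
          class = "dropphase_insufficient_data")
  }
  l1 <- fit_channel_levels(amplitudes$ch1_amplitude)
  l2 <- fit_channel_levels(amplitudes$ch2_amplitude)
  channel_thresholds(threshold_from_levels(l1, amplitudes$ch1_amplitude),
                     threshold_from_levels(l2, amplitudes$ch2_amplitude),
                     levels = list(ch1 = l1, ch2 = l2))
}

#' Manually specified channel thresholds
#'
#' @param ch1,ch2 Amplitude cuts; a droplet is positive on a channel when
#'   its amplitude is strictly above the cut (droplets exactly on the cut
#'   are conservatively called negative).
#' @param levels Optional fitted level means (attached by
#'   [fit_thresholds()]).
#' @return A `channel_thresholds` object.
#' @export
channel_thresholds <- function(ch1, ch2, levels = NULL) {
  stopifnot(is.finite(ch1), is.finite(ch2))
  structure(list(ch1 = ch1, ch2 = ch2, levels = levels),
            class = "channel_thresholds")
}

#' @export
print.channel_thresholds <- function(x, ...) {
  cat(sprintf("<channel_thresholds> ch1 > %.1f, ch2 > %.1f\n", x$ch1, x$ch2))
  if (!is.null(x$levels)) {
    cat("  ch1 levels:", paste(round(x$levels$ch1, 1), collapse = ", "), "\n")
    cat("  ch2 levels:", paste(round(x$levels$ch2, 1), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-droplet positivity calls
#'
#' @param amplitudes Amplitude tibble (`ch1_amplitude`, `ch2_amplitude`).
#' @param thresholds A `channel_thresholds` object (from
#'   [fit_thresholds()] or [channel_thresholds()]).
#' @return A tibble with logical columns `ch1_positive`, `ch2_positive`.
#' @export
droplet_calls <- function(amplitudes, thresholds) {
  stopifnot(inherits(thresholds, "channel_thresholds"))
  tibble::tibble(
    ch1_positive = amplitudes$ch1_amplitude > thresholds$ch1,
    ch2_positive = amplitudes$ch2_amplitude > thresholds$ch2
  )
}

#' Classify droplets into the four class counts
#'
#' Applies the two per-channel cuts and tallies the four droplet classes
#' needed by [estimate_linkage()].
#'
#' @inheritParams droplet_calls
#' @param well_id Optional well label carried into the counts.
#' @return A [droplet_counts()] object; the four counts sum to the number
#'   of droplets.
#' @examples
#' sim <- simulate_experiment(sim_config(n_droplets = 5000, seed = 7))
#' thr <- fit_thresholds(sim$amplitudes)
#' classify_droplets(sim$amplitudes, thr)
#' @export
classify_droplets <- function(amplitudes, thresholds, well_id = NA_character_) {
  calls <- droplet_calls(amplitudes, thresholds)
  if (is.na(well_id) && "well" %in% names(amplitudes) && nrow(amplitudes)) {
    well_id <- as.character(amplitudes$well[1])
  }
  droplet_counts(
    n_pp = sum(calls$ch1_positive & calls$ch2_positive),
    n_pn = sum(calls$ch1_positive & !calls$ch2_positive),
    n_np = sum(!calls$ch1_positive & calls$ch2_positive),
    n_nn = sum(!calls$ch1_positive & !calls$ch2_positive),
    well_id = well_id
  )
}
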