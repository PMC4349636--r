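qx_header <- c("Ch1 Amplitude", "Ch2 Amplitude", "Well")

#' Read a droplet amplitude CSV (QX-export dialect)
#'
#' Expects the header `Ch1 Amplitude,Ch2 Amplitude,Well` (the `Well`
#' column optional), one row per droplet. Rows with non-numeric
#' amplitudes are dropped with a warning stating how many.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `well`, `ch1_amplitude`,
#'   `ch2_amplitude`.
#' @export
read_amplitude_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- tryCatch(
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(.default = "c"),
                                     progress = FALSE)),
    error = function(e) abort(paste0("cannot parse CSV: ", conditionMessage(e)),
                              class = "dropphase_format_error")
  )
  if (nrow(raw) == 0L && ncol(raw) == 0L) {
    abort("empty amplitude file", class = "dropphase_format_error")
  }
  if (!all(qx_header[1:2] %in% names(raw))) {
    abort(paste0("unrecognized amplitude header; expected columns: ",
                 paste(qx_header, collapse = ", ")),
          class = "dropphase_format_error")
  }
  out <- tibble::tibble(
    well = if ("Well" %in% names(raw)) raw[["Well"]] else NA_character_,
    ch1_amplitude = suppressWarnings(as.numeric(raw[["Ch1 Amplitude"]])),
    ch2_amplitude = suppressWarnings(as.numeric(raw[["Ch2 Amplitude"]]))
  )
  bad <- !complete.cases(out[c("ch1_amplitude", "ch2_amplitude")])
  if (any(bad)) {
    warn(paste0(sum(bad), " row(s) with non-numeric amplitudes dropped"))
    out <- out[!bad, ]
  }
  if (nrow(out) == 0L) {
    abort("no valid droplet rows in amplitude file",
          class = "dropphase_format_error")
  }
  out
}

#' Write droplet amplitudes in the QX-export CSV dialect
#'
#' @param amplitudes Amplitude tibble (columns `ch1_amplitude`,
#'   `ch2_amplitude`, optionally `well`) or a `drop_phase_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplitude_csv <- function(amplitudes, path) {
  if (inherits(amplitudes, "drop_phase_sim")) amplitudes <- amplitudes$amplitudes
  out <- tibble::tibble(
    `Ch1 Amplitude` = amplitudes$ch1_amplitude,
    `Ch2 Amplitude` = amplitudes$ch2_amplitude,
    Well = if ("well" %in% names(amplitudes)) amplitudes$well else "A01"
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a droplet counts CSV
#'
#' Columns: `well_id`, `n_total` (optional; recomputed), `n_pp`, `n_pn`,
#' `n_np`, `n_nn`. One row per well.
#'
#' @param path Path to the CSV file.
#' @return A tibble of counts, one row per well.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("n_pp", "n_pn", "n_np", "n_nn")
  if (!all(need %in% names(df))) {
    abort(paste0("counts CSV must contain columns: well_id, ",
                 paste(need, collapse = ", ")),
          class = "dropphase_format_error")
  }
  if (!"well_id" %in% names(df)) df$well_id <- as.character(seq_len(nrow(df)))
  df$n_total <- df$n_pp + df$n_pn + df$n_np + df$n_nn
  tibble::as_tibble(df[c("well_id", "n_total", need)])
}

#' Write a droplet counts CSV
#'
#' @param counts A [droplet_counts()], a list of them, or a data frame
#'   with the count columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  if (inherits(counts, "droplet_counts")) counts <- list(counts)
  if (!is.data.frame(counts)) {
    counts <- purrr::map_dfr(counts, ~tibble::as_tibble(as.data.frame(.x)))
  }
  readr::write_csv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a distance series CSV
#'
#' Columns: `distance_kb`, `percent_linkage`, optional `ci_low`,
#' `ci_high`, `is_control`.
#'
#' @param path Path to the CSV file.
#' @return A tibble suitable for [fit_fragment_survival()].
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("distance_kb", "percent_linkage")
  if (!all(need %in% names(df))) {
    abort(paste0("series CSV must contain columns: ",
                 paste(need, collapse = ", ")),
          class = "dropphase_format_error")
  }
  if (!"is_control" %in% names(df)) df$is_control <- FALSE
  tibble::as_tibble(df)
}

#' Write a linkage result (with provenance) to JSON
#'
#' The JSON embeds every result field plus the configuration, seed, and
#' package version, so the artifact can be re-derived from its own
#' metadata.
#'
#' @param result A `linkage_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage_json <- function(result, path) {
  stopifnot(inherits(result, "linkage_result"))
  payload <- list(
    result = as.list(tidy(result)),
    lambdas = unclass(result$lambdas)[],
    counts = as.list(as.data.frame(result$counts)),
    config = unclass(result$config)[],
    software = list(package = "dropphase",
                    version = as.character(utils::packageVersion("dropphase")))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Ground-truth sidecar JSON for a simulated well
#'
#' @param sim A `drop_phase_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "drop_phase_sim"))
  cfg <- sim$config
  payload <- list(
    truth = sim$truth,
    counts = as.list(as.data.frame(sim$counts)),
    species = as.list(sim$species[c("species", "mean")]),
    config = list(
      hap1 = paste(cfg$dip$hap1, collapse = "-"),
      hap2 = paste(cfg$dip$hap2, collapse = "-"),
      copies_per_ul = cfg$dip$copies_per_ul,
      duplex = cfg$assay$duplex,
      n_droplets = cfg$n_droplets,
      droplet_volume = cfg$droplet_volume,
      distance_kb = cfg$distance_kb,
      mean_intact_kb = cfg$mean_intact_kb,
      digest = cfg$digest,
      seed = cfg$seed,
      well_id = cfg$well_id
    ),
    software = list(package = "dropphase",
                    version = as.character(utils::packageVersion("dropphase")))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
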