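#' Generate a complete synthetic fixture set
#'
#' Writes three self-describing experiment suites under `outdir`, each
#' well as a QX-dialect amplitude CSV with a ground-truth JSON sidecar:
#'
#' * `milemarker/`: duplex wells at distances 1-210 kb from an anchor,
#'   three replicates per distance, plus cross-chromosome controls.
#' * `cftr/`: the thirteen quad-duplex compound-heterozygote scenarios
#'   of [cftr_scenarios()] (four wells each).
#' * `trio/`: the fourteen duplex assays of [trio_scenarios()], with the
#'   trio genotypes recorded in the sidecar.
#'
#' Every artifact embeds its generating configuration and seed, so the
#' whole set can be re-derived byte-identically.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Base seed.
#' @param n_droplets Droplets per well.
#' @param milemarker_L_kb,cftr_L_kb,trio_L_kb Fragment-survival scales
#'   used by each suite.
#' @return Invisibly, a tibble manifest of the files written.
#' @export
generate_fixtures <- function(outdir, seed = 1L, n_droplets = 20000L,
                              milemarker_L_kb = 69.16, cftr_L_kb = 72,
                              trio_L_kb = 69) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(cfg, subdir, stem, extra_truth = NULL) {
    dir.create(file.path(outdir, subdir), showWarnings = FALSE)
    sim <- simulate_experiment(cfg)
    csv <- file.path(outdir, subdir, paste0(stem, ".csv"))
    json <- file.path(outdir, subdir, paste0(stem, ".truth.json"))
    write_amplitude_csv(sim, csv)
    write_sim_truth_json(sim, json)
    if (!is.null(extra_truth)) {
      truth <- jsonlite::read_json(json)
      truth$scenario <- extra_truth
      jsonlite::write_json(truth, json, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      suite = subdir, well_id = cfg$well_id, csv = csv, truth = json)
  }

  # (a) mile-marker suite
  distances <- c(1, 10, 33, 60, 100, 150, 210)
  i <- 0L
  for (d in distances) for (rep in 1:3) {
    i <- i + 1L
    emit(sim_config(dip = diplotype(c("A", "B"), c("a", "b"),
                                    copies_per_ul = c(200, 0)),
                    assay = duplex_assay("A", "B"), n_droplets = n_droplets,
                    distance_kb = d, mean_intact_kb = milemarker_L_kb,
                    seed = seed + i,
                    well_id = sprintf("mm_%03d_%d", d, rep)),
         "milemarker", sprintf("mm_%03d_%d", d, rep))
  }
  for (d in distances) {
    i <- i + 1L
    emit(sim_config(dip = diplotype(c("A", "B"), c("a", "b"),
                                    copies_per_ul = c(200, 0)),
                    assay = duplex_assay("A", "B"), n_droplets = n_droplets,
                    distance_kb = Inf, mean_intact_kb = milemarker_L_kb,
                    seed = seed + i,
                    well_id = sprintf("mm_%03d_ctrl", d)),
         "milemarker", sprintf("mm_%03d_ctrl", d),
         extra_truth = list(is_control = TRUE, nominal_distance_kb = d))
  }

  # (b) compound-heterozygote quad-duplex suite
  scen <- cftr_scenarios()
  duplexes <- quad_duplexes()
  for (s in seq_len(nrow(scen))) {
    row <- scen[s, ]
    dip <- phase_to_diplotype(row$phase)
    for (nm in names(duplexes)) {
      emit(sim_config(dip = dip, assay = duplexes[[nm]],
                      n_droplets = n_droplets, distance_kb = row$distance_kb,
                      mean_intact_kb = cftr_L_kb,
                      seed = seed + 1000L + s * 10L + match(nm, names(duplexes)),
                      well_id = sprintf("cftr_%02d_%s", row$scenario, nm)),
           "cftr", sprintf("cftr_%02d_%s", row$scenario, nm),
           extra_truth = c(as.list(row), list(duplex = nm)))
    }
  }

  # (c) trio suite
  trio <- trio_scenarios()
  for (s in seq_len(nrow(trio))) {
    row <- trio[s, ]
    emit(sim_config(dip = phase_to_diplotype(row$phase),
                    assay = duplex_assay("A", "B"), n_droplets = n_droplets,
                    distance_kb = row$distance_kb, mean_intact_kb = trio_L_kb,
                    seed = seed + 2000L + s,
                    well_id = sprintf("trio_%02d", row$assay)),
         "trio", sprintf("trio_%02d", row$assay),
         extra_truth = as.list(row))
  }

  manifest <- dplyr::bind_rows(manifest)
  jsonlite::write_json(
    list(seed = seed, n_droplets = n_droplets,
         files = manifest$csv,
         software = list(package = "dropphase",
                         version = as.character(utils::packageVersion("dropphase")))),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
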