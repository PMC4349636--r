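#' Droplet class counts for a duplex reaction
#'
#' A Drop-Phase well yields four droplet classes once each channel has been
#' thresholded: double-positive (both targeted alleles present), A-only,
#' B-only, and double-negative. These four counts are the sufficient
#' statistic for all linkage estimation.
#'
#' Observed tallies are whole numbers, but fractional values are accepted
#' so that expected (model-implied) class counts can be pushed through the
#' estimator, e.g. to verify the estimator inverts the forward model.
#'
#' @param n_pp Count of double-positive (A+B+) droplets.
#' @param n_pn Count of A+B- droplets.
#' @param n_np Count of A-B+ droplets.
#' @param n_nn Count of double-negative (A-B-) droplets.
#' @param well_id Optional well label carried through to results.
#'
#' @return A `droplet_counts` object: a list with fields `n_pp`, `n_pn`,
#'   `n_np`, `n_nn`, `n_total`, and `well_id`.
#' @examples
#' droplet_counts(n_pp = 310, n_pn = 1190, n_np = 1205, n_nn = 17295)
#' @export
droplet_counts <- function(n_pp, n_pn, n_np, n_nn, well_id = NA_character_) {
  counts <- c(n_pp = unname(n_pp)[1], n_pn = unname(n_pn)[1],
              n_np = unname(n_np)[1], n_nn = unname(n_nn)[1])
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("droplet class counts must be finite and non-negative",
          class = "dropphase_invalid_counts")
  }
  # observed tallies are integers; fractional values are accepted so that
  # expected (model-implied) class counts can flow through the estimator
  if (all(abs(counts - round(counts)) < 1e-9)) {
    counts <- setNames(as.integer(round(counts)), names(counts))
  }
  n_total <- sum(counts)
  if (n_total == 0L) {
    abort("droplet counts sum to zero: no accepted droplets",
          class = "dropphase_invalid_counts")
  }
  structure(
    list(n_pp = counts[["n_pp"]], n_pn = counts[["n_pn"]],
         n_np = counts[["n_np"]], n_nn = counts[["n_nn"]],
         n_total = n_total, well_id = well_id),
    class = "droplet_counts"
  )
}

#' Coerce a data frame row or named vector to droplet counts
#'
#' @param x A `droplet_counts`, a named numeric vector, or a one-row data
#'   frame with columns `n_pp`, `n_pn`, `n_np`, `n_nn` (and optionally
#'   `well_id`).
#' @return A [droplet_counts()] object.
#' @export
as_droplet_counts <- function(x) {
  if (inherits(x, "droplet_counts")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      abort("expected a single row of counts; use linkage_table() for many wells")
    }
    x <- as.list(x)
  }
  x <- as.list(x)
  need <- c("n_pp", "n_pn", "n_np", "n_nn")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("missing count columns: ", paste(missing_cols, collapse = ", ")))
  }
  droplet_counts(
    n_pp = as.numeric(x$n_pp), n_pn = as.numeric(x$n_pn),
    n_np = as.numeric(x$n_np), n_nn = as.numeric(x$n_nn),
    well_id = if (!is.null(x$well_id)) as.character(x$well_id) else NA_character_
  )
}

#' @export
print.droplet_counts <- function(x, ...) {
  cat("<droplet_counts>", if (!is.na(x$well_id)) paste0("well ", x$well_id), "\n")
  m <- matrix(c(x$n_pp, x$n_pn, x$n_np, x$n_nn), 2, 2, byrow = TRUE,
              dimnames = list(c("A+", "A-"), c("B+", "B-")))
  print(m)
  cat("total:", x$n_total, "\n")
  invisible(x)
}

#' @export
as.data.frame.droplet_counts <- function(x, ...) {
  data.frame(well_id = x$well_id, n_total = x$n_total, n_pp = x$n_pp,
             n_pn = x$n_pn, n_np = x$n_np, n_nn = x$n_nn,
             stringsAsFactors = FALSE)
}

#' @exportS3Method generics::tidy
tidy.droplet_counts <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
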