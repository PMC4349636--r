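#' Predicted percent linkage at a genomic distance
#'
#' Under the Poisson-break fragmentation model, the fraction of molecules
#' keeping two sequences on one fragment decays exponentially with their
#' separation: `100 * exp(-d / L)`, where `L` is the mean intact fragment
#' scale. The curve is forced through 100% at zero distance.
#'
#' @param L_kb Fragment-survival scale in kb (positive).
#' @param distance_kb Genomic distance(s) in kb (non-negative).
#' @return Percent linkage, strictly decreasing in distance.
#' @examples
#' predict_percent_linkage(69.16, c(0, 60, 210))
#' @export
predict_percent_linkage <- function(L_kb, distance_kb) {
  if (!is.finite(L_kb) || L_kb <= 0) abort("L_kb must be positive")
  if (any(distance_kb < 0)) abort("distance must be non-negative")
  100 * exp(-distance_kb / L_kb)
}

#' Fit the fragment-survival scale to a distance series
#'
#' Nonlinear least squares of `percent = 100 * exp(-distance / L)` on
#' linked (non-control) measurements. Replicate measurements at a
#' distance are averaged before fitting; control points (e.g.
#' cross-chromosome pairs) and degenerate points (0% anywhere, or 100%
#' at positive distance) are excluded. With a single usable point the
#' closed form `L = d / log(100 / pct)` is used.
#'
#' @param series A data frame with columns `distance_kb` and
#'   `percent_linkage`, optionally `is_control` (logical) and any
#'   replicate structure (rows at repeated distances are averaged).
#' @param log_scale Fit on `log(percent)` instead of the percent scale
#'   (weights short distances less heavily).
#' @return A `fragment_survival_fit` object with `L_kb`, `fitted`,
#'   `residuals`, `r_squared`, `n_points`, `data` (the averaged points
#'   used), and `method`.
#' @examples
#' fit <- fit_fragment_survival(data.frame(distance_kb = 60, percent_linkage = 42))
#' fit$L_kb  # 69.16
#' @export
fit_fragment_survival <- function(series, log_scale = FALSE) {
  stopifnot(is.data.frame(series))
  pts <- tibble::as_tibble(series)
  if ("is_control" %in% names(pts)) {
    pts <- dplyr::filter(pts, !.data$is_control)
  }
  drop <- pts$percent_linkage <= 0 |
    (pts$percent_linkage >= 100 & pts$distance_kb > 0)
  if (any(drop)) {
    warn(paste0(sum(drop), " point(s) at 0% or 100% linkage excluded from the fit"))
    pts <- pts[!drop, ]
  }
  pts <- pts |>
    dplyr::group_by(.data$distance_kb) |>
    dplyr::summarise(percent_linkage = mean(.data$percent_linkage),
                     .groups = "drop") |>
    dplyr::arrange(.data$distance_kb)
  pts <- dplyr::filter(pts, .data$distance_kb > 0)
  if (nrow(pts) == 0L) {
    abort("no usable points: need at least one linked measurement strictly between 0 and 100%",
          class = "dropphase_fit_error")
  }
  closed_form <- function(d, pct) d / log(100 / pct)
  if (nrow(pts) == 1L) {
    L <- closed_form(pts$distance_kb, pts$percent_linkage)
    fitted_pct <- predict_percent_linkage(L, pts$distance_kb)
    method <- "closed-form (single point)"
  } else {
    L0 <- closed_form(median(pts$distance_kb),
                      pts$percent_linkage[which.min(abs(pts$distance_kb - median(pts$distance_kb)))])
    if (log_scale) {
      fit <- nls(log(percent_linkage) ~ log(100) - distance_kb / L,
                 data = pts, start = list(L = L0),
                 control = stats::nls.control(maxiter = 100, scaleOffset = 1))
    } else {
      fit <- nls(percent_linkage ~ 100 * exp(-distance_kb / L),
                 data = pts, start = list(L = L0),
                 control = stats::nls.control(maxiter = 100, scaleOffset = 1))
    }
    L <- unname(coef(fit)[["L"]])
    fitted_pct <- predict_percent_linkage(L, pts$distance_kb)
    method <- paste0("nls (", if (log_scale) "log" else "percent", " scale)")
  }
  res <- pts$percent_linkage - fitted_pct
  ss_tot <- sum((pts$percent_linkage - mean(pts$percent_linkage))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(list(L_kb = L, fitted = fitted_pct, residuals = res,
                 r_squared = r2, n_points = nrow(pts), data = pts,
                 method = method),
            class = "fragment_survival_fit")
}

#' @export
print.fragment_survival_fit <- function(x, ...) {
  cat("<fragment_survival_fit>\n")
  cat(sprintf("  L = %.2f kb  (%s, %d point%s, R^2 = %.4f)\n",
              x$L_kb, x$method, x$n_points, if (x$n_points > 1) "s" else "",
              x$r_squared))
  invisible(x)
}

#' @export
predict.fragment_survival_fit <- function(object, distance_kb, ...) {
  predict_percent_linkage(object$L_kb, distance_kb)
}

#' @exportS3Method generics::tidy
tidy.fragment_survival_fit <- function(x, ...) {
  tibble::tibble(term = "L_kb", estimate = x$L_kb)
}

#' @exportS3Method generics::glance
glance.fragment_survival_fit <- function(x, ...) {
  tibble::tibble(L_kb = x$L_kb, r_squared = x$r_squared,
                 n_points = x$n_points, method = x$method)
}
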