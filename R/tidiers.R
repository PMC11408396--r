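#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the cohort comparison result
#'
#' One row per comparison x organ with the cohort mean and standard
#' deviation of the percentage difference.
#'
#' @param x A `voxdose_comparison`.
#' @param per_phantom Return the per-phantom values instead of the cohort
#'   summary.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy voxdose_comparison
#' @export
tidy.voxdose_comparison <- function(x, per_phantom = FALSE, ...) {
  if (per_phantom) x$per_phantom else x$summary
}

#' @rdname tidy.voxdose_comparison
#' @method glance voxdose_comparison
#' @export
glance.voxdose_comparison <- function(x, ...) {
  tibble::tibble(
    n_comparisons = length(unique(x$summary$comparison)),
    n_organs = length(unique(x$summary$organ)),
    n_phantoms = max(x$per_phantom$phantom),
    max_abs_mean_pct = max(abs(x$summary$mean_pct)))
}

#' Tidy a cohort regression
#'
#' @param x A `voxdose_regression`.
#' @param ... Unused.
#' @return `tidy()`: one row per model term (estimate, std.error,
#'   statistic, p.value); `glance()`: one row with `r.squared` and `n`.
#' @method tidy voxdose_regression
#' @export
tidy.voxdose_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", x$predictor),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.voxdose_regression
#' @method glance voxdose_regression
#' @export
glance.voxdose_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n = x$n,
                 predictor = x$predictor, response = x$response)
}

#' Tidy a scenario dose table
#'
#' Long format: one row per organ x scenario.
#'
#' @param x A `voxdose_scenarios`.
#' @param ... Unused.
#' @return A tibble with `organ`, `scenario`, `dose`.
#' @method tidy voxdose_scenarios
#' @export
tidy.voxdose_scenarios <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[c("organ", "d_a", "d_b", "d_c", "d_d", "d_e")],
    -"organ", names_to = "scenario", values_to = "dose")
}
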