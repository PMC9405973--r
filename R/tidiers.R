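# broom-style tidiers and ggplot2 autoplot methods for the fitted-object
# classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ITC one-site fit
#'
#' @param x An `itc_onesite_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`.
#' @method tidy itc_onesite_fit
#' @export
tidy.itc_onesite_fit <- function(x, ...) x$estimates

#' @rdname tidy.itc_onesite_fit
#' @method glance itc_onesite_fit
#' @export
glance.itc_onesite_fit <- function(x, ...) {
  tibble::tibble(
    c_value = x$c_value,
    identifiability_warning = x$identifiability_warning,
    sigma = x$sigma, deviance = x$deviance, nobs = x$n_obs
  )
}

#' Tidy an ITC ternary fit
#'
#' @param x An `itc_ternary_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`.
#' @method tidy itc_ternary_fit
#' @export
tidy.itc_ternary_fit <- function(x, ...) x$estimates

#' @rdname tidy.itc_ternary_fit
#' @method glance itc_ternary_fit
#' @export
glance.itc_ternary_fit <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, kappa_se = x$kappa_se,
    degenerate = x$degenerate,
    sigma = x$sigma %||% NA_real_,
    deviance = x$deviance %||% NA_real_,
    nobs = x$n_obs %||% NA_integer_
  )
}

#' @rdname tidy.itc_onesite_fit
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) x$estimates

#' @rdname tidy.itc_onesite_fit
#' @method tidy fluor_fit
#' @export
tidy.fluor_fit <- function(x, ...) x$estimates

#' @rdname tidy.itc_onesite_fit
#' @method tidy cp_fit
#' @export
tidy.cp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dCp_cal", "dH_at_Tref_kcal"),
    estimate = c(x$dCp_cal, x$dH_at_Tref_kcal),
    std_error = c(x$dCp_err_cal, NA_real_)
  )
}

#' @rdname tidy.itc_onesite_fit
#' @method glance cp_fit
#' @export
glance.cp_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, nobs = x$n_points,
                 Tref_C = x$Tref_C)
}

#' Plot an ITC binding isotherm
#'
#' Normalized heat per mole of injectant against the cumulative
#' ligand:protein molar ratio.
#'
#' @param object An `itc_isotherm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itc_isotherm
#' @export
autoplot.itc_isotherm <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$molar_ratio,
                               .data$ndh_kcal_per_mol)) +
    ggplot2::geom_point(shape = 21, size = 2) +
    ggplot2::labs(x = "molar ratio ([L]/[P])",
                  y = "normalized heat (kcal/mol of injectant)") +
    ggplot2::theme_bw()
}

#' Plot a one-site fit over its data
#'
#' @param object An `itc_onesite_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itc_onesite_fit
#' @export
autoplot.itc_onesite_fit <- function(object, ...) {
  d <- tibble::tibble(
    molar_ratio = object$isotherm$molar_ratio,
    observed = object$isotherm$ndh_kcal_per_mol,
    fitted = object$fitted,
    used = object$keep
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$molar_ratio)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     shape = .data$used), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                guide = "none") +
    ggplot2::labs(x = "molar ratio ([L]/[P])",
                  y = "normalized heat (kcal/mol of injectant)") +
    ggplot2::theme_bw()
}

#' Plot the temperature dependence of the binding enthalpy
#'
#' @param object A `cp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cp_fit
#' @export
autoplot.cp_fit <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(.data$temperature_C, .data$dH_kcal)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "temperature (°C)", y = "dH (kcal/mol)",
      subtitle = sprintf("dCp = %.0f cal/mol/K", object$dCp_cal)) +
    ggplot2::theme_bw()
}

#' Plot a cooperativity table
#'
#' Bar chart of the free-energy, enthalpy and entropy couplings per
#' heterotropic effect, faceted by temperature.
#'
#' @param data A tibble from [cooperativity_table()].
#' @return A ggplot object.
#' @export
plot_cooperativity <- function(data) {
  long <- data |>
    tidyr::pivot_longer(c("dg_kcal", "dh_kcal", "minus_Tds_kcal"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$effect_label, .data$value,
                               fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~temperature_C) +
    ggplot2::labs(x = NULL, y = "coupling energy (kcal/mol)") +
    ggplot2::coord_flip() +
    ggplot2::theme_bw()
}
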