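#' Bland-Altman agreement between paired measurements
#'
#' Differences are taken as `reference - test` (for density validation the
#' reference is the nuclear-counterstain count and the test the calcein-based
#' count, so a positive bias means the calcein method under-counts). Reports
#' the bias (mean difference), the SD of differences, 95% limits of agreement
#' (bias +/- 1.96 SD, or a t-quantile when `t_limits = TRUE`), a t-based 95%
#' CI for the bias, and the Pearson correlation of the paired values.
#'
#' @param data A data frame holding the paired measurements.
#' @param reference,test Columns of `data` (tidy-eval) with the reference and
#'   test measurements.
#' @param conf_level Confidence level for the bias CI.
#' @param t_limits Use the t quantile instead of 1.96 for the limits of
#'   agreement.
#' @return A `bland_altman` object; `tidy()` gives per-pair plot data
#'   (mean, difference), `glance()` the agreement statistics, `autoplot()`
#'   the Bland-Altman plot.
#' @export
#' @examples
#' df <- tibble::tibble(hoechst = c(2500, 2600, 2700),
#'                      calcein = c(2300, 2400, 2500))
#' glance(bland_altman(df, hoechst, calcein))
bland_altman <- function(data, reference, test, conf_level = 0.95,
                         t_limits = FALSE) {
  ref <- dplyr::pull(data, {{ reference }})
  tst <- dplyr::pull(data, {{ test }})
  if (length(ref) != length(tst)) stop("paired vectors must have equal length",
                                       call. = FALSE)
  n <- length(ref)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- ref - tst
  bias <- mean(d)
  sd_d <- sd(d)
  mult <- if (t_limits) qt(1 - (1 - conf_level) / 2, n - 1) else
    qnorm(1 - (1 - conf_level) / 2)
  loa <- bias + c(-1, 1) * mult * sd_d
  se <- sd_d / sqrt(n)
  ci <- bias + c(-1, 1) * qt(1 - (1 - conf_level) / 2, n - 1) * se
  ct <- if (var(ref) > 0 && var(tst) > 0) cor.test(ref, tst) else NULL
  structure(
    list(n = n, bias = bias, sd_diff = sd_d, loa_low = loa[1],
         loa_high = loa[2], ci_low = ci[1], ci_high = ci[2],
         loa_multiplier = mult,
         pearson_r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
         pearson_p = if (is.null(ct)) NA_real_ else ct$p.value,
         pairs = tibble::tibble(reference = ref, test = tst,
                                mean = (ref + tst) / 2, difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n = ", x$n, ": bias ", round(x$bias, 2), " (95% CI ",
      round(x$ci_low, 2), " to ", round(x$ci_high, 2), "), LoA [",
      round(x$loa_low, 2), ", ", round(x$loa_high, 2), "], r = ",
      round(x$pearson_r, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman`.
#' @param ... Unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 pearson_r = x$pearson_r, pearson_p = x$pearson_p)
}

#' @rdname bland_altman
#' @param object A `bland_altman`.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$mean, .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mean of methods", y = "reference - test") +
    ggplot2::theme_minimal()
}

#' Pearson correlation between paired measurements
#'
#' Product-moment correlation with a two-sided p-value from the t transform,
#' as a tidy one-row tibble.
#'
#' @param data A data frame.
#' @param x,y Columns of `data` (tidy-eval).
#' @return A tibble: `r`, `p_value`, `n`, `conf_low`, `conf_high`.
#' @export
pearson_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (var(xv) == 0 || var(yv) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(xv, yv)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(xv), conf_low = ct$conf.int[1],
                 conf_high = ct$conf.int[2])
}
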