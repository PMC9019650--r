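#' Percent decline over a span of decades
#'
#' Expresses a per-decade slope as a percentage change over the full span,
#' relative to the starting (intercept) level:
#' `100 * (-slope) * (n_decades - 1) / intercept`. A span of `n_decades`
#' bins contains `n_decades - 1` decade intervals; positive values mean
#' decline.
#'
#' @param intercept Score at the first decade (must be positive).
#' @param slope Change per decade.
#' @param n_decades Number of decade bins spanned (default 21).
#' @return Percent decline (vectorized); rounded only for display.
#' @examples
#' percent_decline(3.13, -0.0067, 21)  # 4.28
#' percent_decline(3.04, -0.023, 21)   # 15.13
#' @export
percent_decline <- function(intercept, slope, n_decades = 21L) {
  if (any(intercept <= 0)) abort("Intercept must be positive.")
  if (any(n_decades < 2)) abort("Need at least 2 decades.")
  100 * (-slope) * (n_decades - 1) / intercept
}

#' Fit linear decade trends to narrative-score series
#'
#' Ordinary least squares of the score on the decade index (origin decade
#' maps to 0, the next to 1, ...), fitted separately for each framing. The
#' intercept is then interpretable as the score at the origin decade
#' (default 1810). The percent decline uses the number of decade bins in the
#' configured span.
#'
#' @param series Tibble with columns `framing`, `decade`, `cans` (see
#'   [cumulative_narrative_score()]).
#' @param origin Decade mapped to index 0 (default 1810).
#' @param n_decades Span used for the percent-decline summary; default the
#'   number of distinct decades in `series`.
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return A `trend_fit` object: a tibble with one row per framing
#'   (`framing`, `n`, `intercept`, `intercept_ci_low`, `intercept_ci_high`,
#'   `p_intercept`, `slope`, `se_slope`, `slope_ci_low`, `slope_ci_high`,
#'   `p_slope`, `percent_decline`, `r_squared`), carrying the underlying
#'   `lm` fits and data as attributes for plotting.
#' @export
fit_decade_trend <- function(series, origin = 1810L, n_decades = NULL,
                             conf_level = 0.95) {
  stopifnot(all(c("framing", "decade", "cans") %in% names(series)))
  n_decades <- n_decades %||% dplyr::n_distinct(series$decade)
  series <- series %>%
    mutate(t = (.data$decade - origin) / 10) %>%
    arrange(.data$framing, .data$decade)
  groups <- split(series, series$framing)
  qz <- function(df) qt(1 - (1 - conf_level) / 2, df)
  fits <- lapply(groups, function(g) {
    if (nrow(g) < 3) {
      abort(paste0("Framing '", g$framing[1], "' has fewer than 3 decades."))
    }
    if (var(g$t) == 0) abort("Degenerate series: no variance in decade index.")
    lm(cans ~ t, data = g)
  })
  rows <- purrr::imap(fits, function(fit, fr) {
    s <- summary(fit)$coefficients
    df <- fit$df.residual
    tibble(
      framing = fr,
      n = length(fit$residuals),
      intercept = s[1, 1],
      intercept_ci_low = s[1, 1] - qz(df) * s[1, 2],
      intercept_ci_high = s[1, 1] + qz(df) * s[1, 2],
      p_intercept = s[1, 4],
      slope = s[2, 1],
      se_slope = s[2, 2],
      slope_ci_low = s[2, 1] - qz(df) * s[2, 2],
      slope_ci_high = s[2, 1] + qz(df) * s[2, 2],
      p_slope = s[2, 4],
      percent_decline = percent_decline(s[1, 1], s[2, 1], n_decades),
      r_squared = summary(fit)$r.squared
    )
  })
  out <- bind_rows(rows)
  structure(out, class = c("trend_fit", class(out)),
            fits = fits, data = series, origin = origin,
            conf_level = conf_level, n_decades = n_decades)
}

#' @export
tidy.trend_fit <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.trend_fit <- function(x, ...) {
  tibble(n_framings = nrow(x), n_points = sum(x$n),
         n_decades = attr(x, "n_decades"), origin = attr(x, "origin"))
}

#' Plot narrative-score trends with confidence bands
#'
#' Scatter of the per-decade scores with the fitted lines and pointwise
#' confidence ribbons, one colour per framing.
#'
#' @param object A `trend_fit` from [fit_decade_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_fit <- function(object, ...) {
  data <- attr(object, "data")
  origin <- attr(object, "origin")
  conf <- attr(object, "conf_level")
  fits <- attr(object, "fits")
  bands <- purrr::imap(fits, function(fit, fr) {
    tt <- seq(min(data$t), max(data$t), length.out = 100)
    pr <- predict(fit, newdata = data.frame(t = tt), interval = "confidence",
                  level = conf)
    tibble(framing = fr, decade = origin + 10 * tt,
           fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
  }) %>% bind_rows()
  ggplot2::ggplot(data, ggplot2::aes(x = .data$decade, colour = .data$framing)) +
    ggplot2::geom_ribbon(
      data = bands,
      ggplot2::aes(ymin = .data$lwr, ymax = .data$upr, fill = .data$framing),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line(data = bands, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cans), size = 1.5) +
    ggplot2::labs(x = "Decade", y = "Cumulative narrative score (1-5)",
                  colour = "Framing", fill = "Framing") +
    ggplot2::theme_minimal()
}

#' Test whether two framings' decade slopes differ
#'
#' Pools both series into one regression with a group indicator, the decade
#' index, and their interaction; the slope-difference test is the F test of
#' the interaction coefficient (F equals the squared t), with 1 numerator
#' degree of freedom and `N_total - 4` denominator degrees of freedom under
#' the pooled homoscedastic error. Symmetric in group labels.
#'
#' @param series Tibble with columns `framing` (exactly 2 levels), `decade`,
#'   `cans`; alternatively pass the second framing's series as `series_b`
#'   and label-free tibbles (`decade`, `cans`) for both.
#' @param series_b Optional second series (`decade`, `cans`).
#' @param origin Decade mapped to index 0 (default 1810).
#' @return A one-row `slope_comparison` tibble: `F`, `df1`, `df2`, `p`,
#'   `slope_diff`.
#' @export
compare_slopes <- function(series, series_b = NULL, origin = 1810L) {
  if (!is.null(series_b)) {
    series <- bind_rows(
      mutate(series, framing = "a"),
      mutate(series_b, framing = "b")
    )
  }
  lv <- unique(series$framing)
  if (length(lv) != 2) abort("compare_slopes needs exactly 2 framings.")
  if (any(table(series$framing) < 3)) {
    abort("Each framing needs at least 3 decades.")
  }
  d <- mutate(series, t = (.data$decade - origin) / 10,
              g = as.integer(.data$framing == lv[2]))
  fit <- lm(cans ~ g * t, data = d)
  s <- summary(fit)$coefficients
  tval <- s["g:t", 3]
  df2 <- fit$df.residual
  out <- tibble(F = tval^2, df1 = 1L, df2 = as.integer(df2),
                p = 2 * pt(-abs(tval), df2), slope_diff = s["g:t", 1])
  structure(out, class = c("slope_comparison", class(out)))
}
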