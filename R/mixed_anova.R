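#' Partial eta squared
#'
#' Effect size for an ANOVA effect: `ss_effect / (ss_effect + ss_error)`,
#' where the error sum of squares is the one the effect is tested against.
#'
#' @param ss_effect,ss_error Non-negative sums of squares, not both zero.
#' @return The effect size in \[0, 1\].
#' @examples
#' partial_eta_squared(29, 71)  # 0.29
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0) || any(ss_error < 0)) {
    abort("Sums of squares must be non-negative.")
  }
  if (any(ss_effect + ss_error == 0)) {
    abort("Both sums of squares are zero: effect size undefined.")
  }
  ss_effect / (ss_effect + ss_error)
}

sse_of <- function(fit) sum(fit$residuals^2)

#' Two-way mixed-design ANOVA
#'
#' Classical mixed-model analysis of variance with one between-units factor
#' and one two-level within-units (repeated) factor. The between main effect
#' is tested against units-within-groups error; the within main effect and
#' the interaction are tested against the within-by-units-within-groups
#' error. Computation uses the exact mean/difference-score decomposition for
#' a two-level within factor, which reduces to the classical sums of squares
#' when balanced and to Type III-equivalent (unweighted-means) partitioning
#' when group sizes differ. Binary 0/1 responses are accepted and analyzed
#' with the same decomposition.
#'
#' With two groups and `N` complete units, every effect has degrees of
#' freedom `(1, N - 2)`.
#'
#' @param table Long-format tibble with one row per unit and within level.
#' @param unit,between,within,response Column names (defaults `"unit_id"`,
#'   `"framing"`, `"century"`, `"response"`).
#' @return A `mixed_anova` object: a tibble with one row per effect
#'   (`between`, `within`, `interaction`) and columns `effect`, `ss`,
#'   `ss_error`, `df1`, `df2`, `F`, `p`, `partial_eta_sq`.
#' @export
two_way_mixed_anova <- function(table, unit = "unit_id", between = "framing",
                                within = "century", response = "response") {
  d <- tibble(
    unit = as.character(table[[unit]]),
    g = as.character(table[[between]]),
    w = as.character(table[[within]]),
    y = as.numeric(table[[response]])
  )
  if (anyNA(d)) abort("Missing values in design columns or response.")
  if (any(duplicated(d[, c("unit", "w")]))) {
    abort("A unit has duplicate rows for the same within level.")
  }
  multi_g <- d %>% distinct(.data$unit, .data$g) %>% count(.data$unit) %>%
    filter(.data$n > 1)
  if (nrow(multi_g) > 0) {
    abort("A unit appears under more than one between level.")
  }
  wl <- sort(unique(d$w))
  if (length(wl) != 2) {
    abort("Exactly 2 within levels are supported (the repeated contrast).")
  }
  wide <- d %>%
    tidyr::pivot_wider(id_cols = c("unit", "g"), names_from = "w",
                       values_from = "y")
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warn(paste0(sum(!complete), " incomplete unit(s) dropped."))
    wide <- wide[complete, ]
  }
  if (length(unique(wide$g)) < 2) abort("Need at least 2 between levels.")
  if (any(table(wide$g) < 2)) abort("Each group needs at least 2 units.")

  y1 <- wide[[wl[1]]]
  y2 <- wide[[wl[2]]]
  m <- (y1 + y2) / 2
  dd <- y2 - y1
  gf <- factor(wide$g)
  N <- nrow(wide)
  G <- nlevels(gf)

  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fit_m <- lm(m ~ gf)
  fit_d <- lm(dd ~ gf)

  # original-metric sums of squares (k = 2 within levels)
  ss_A <- 2 * (sse_of(lm(m ~ 1)) - sse_of(fit_m))
  ss_S <- 2 * sse_of(fit_m)
  mse_d <- sse_of(fit_d) / fit_d$df.residual
  t_int <- summary(fit_d)$coefficients["(Intercept)", 3]
  ss_B <- if (is.finite(t_int)) t_int^2 * mse_d / 2 else 0
  ss_AB <- (sse_of(lm(dd ~ 1)) - sse_of(fit_d)) / 2
  ss_BS <- sse_of(fit_d) / 2

  df_eff <- c(G - 1, 1, G - 1)
  df_err <- c(N - G, N - G, N - G)
  ss_eff <- c(ss_A, ss_B, ss_AB)
  ss_err <- c(ss_S, ss_BS, ss_BS)
  # snap numerically-zero sums of squares (constant responses) to exact zero
  eps <- 1e-10 * (mean(abs(c(y1, y2)))^2 + 1)
  ss_eff[ss_eff < eps] <- 0
  ss_err[ss_err < eps] <- 0
  ms_eff <- ss_eff / df_eff
  ms_err <- ss_err / df_err
  Fv <- ifelse(ms_err > 0, ms_eff / ms_err, ifelse(ms_eff == 0, 0, Inf))
  pv <- ifelse(is.finite(Fv), pf(Fv, df_eff, df_err, lower.tail = FALSE), 0)
  pv[Fv == 0] <- 1
  eta <- ifelse(ss_eff + ss_err > 0, ss_eff / (ss_eff + ss_err), 0)

  out <- tibble(
    effect = c("between", "within", "interaction"),
    ss = ss_eff, ss_error = ss_err,
    df1 = as.integer(df_eff), df2 = as.integer(df_err),
    F = Fv, p = pv, partial_eta_sq = eta
  )
  structure(out, class = c("mixed_anova", class(out)),
            n_units = N, n_groups = G, within_levels = wl)
}

#' @export
tidy.mixed_anova <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.mixed_anova <- function(x, ...) {
  tibble(n_units = attr(x, "n_units"), n_groups = attr(x, "n_groups"))
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Two-way mixed ANOVA (%d units, %d groups, within: %s)\n",
              attr(x, "n_units"), attr(x, "n_groups"),
              paste(attr(x, "within_levels"), collapse = " vs ")))
  print(as_tibble(unclass(x)))
  invisible(x)
}
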