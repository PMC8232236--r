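#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and standard deviation, with the Lilliefors correction for the
#' fact that the reference parameters are estimated from the same sample (the
#' uncorrected test is severely conservative in this setting). The screen is
#' advisory and never gates downstream tests.
#'
#' @param x Numeric vector, length at least 5, nonconstant.
#' @return A tibble with `statistic` (the KS distance D), `p_value`, `n`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need at least 5 values", call. = FALSE)
  if (sd(x) == 0) stop("degenerate (zero-variance) sample", call. = FALSE)
  kt <- nortest::lillie.test(x)
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n = length(x))
}

#' One-way ANOVA with effect size
#'
#' Classical between/within decomposition with eta squared
#' (`SS_between / SS_total`).
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the response and the group
#'   factor.
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `eta_squared`, `n`.
#' @export
oneway_anova <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs at least 2 values", call. = FALSE)
  fit <- aov(v ~ g)
  tab <- summary(fit)[[1]]
  ssb <- tab["g", "Sum Sq"]; ssw <- tab["Residuals", "Sum Sq"]
  tibble::tibble(
    statistic = tab["g", "F value"],
    df_between = tab["g", "Df"],
    df_within = tab["Residuals", "Df"],
    p_value = tab["g", "Pr(>F)"],
    eta_squared = ssb / (ssb + ssw),
    n = length(v)
  )
}

#' Tukey honestly-significant-difference post hoc test
#'
#' Studentized-range pairwise comparisons after a one-way ANOVA. With two
#' groups the adjusted p-value coincides with the two-sided pooled t-test.
#'
#' @inheritParams oneway_anova
#' @param alpha Rejection level for the `reject` column (default 0.05).
#' @return A tibble with one row per pair: `contrast`, `estimate` (difference
#'   in means), `conf_low`, `conf_high`, `p_adj`, `reject`.
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs at least 2 values", call. = FALSE)
  tk <- TukeyHSD(aov(v ~ g), conf.level = 1 - alpha)$g
  tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"],
    reject = tk[, "p adj"] < alpha
  )
}

#' Bonferroni correction
#'
#' Rejects hypothesis i iff `p_i <= alpha / m`, `m` the family size.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble with `p_value`, `p_adj` (`min(1, m * p)`), `threshold`
#'   (`alpha / m`) and `reject`.
#' @export
bonferroni <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value list", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  tibble::tibble(
    p_value = p,
    p_adj = pmin(1, m * p),
    threshold = alpha / m,
    reject = p <= alpha / m
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval).
#' @return A one-row tibble: `r`, `n`, `statistic` (t, n-2 df), `p_value`
#'   (two-sided).
#' @export
pearson_corr <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(xv) == 0 || sd(yv) == 0) stop("constant input", call. = FALSE)
  ct <- cor.test(xv, yv, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), n = length(xv),
    statistic = unname(ct$statistic), p_value = ct$p.value
  )
}

# per-subject mean off-diagonal PDC in one band, from a long connectivity table
subject_band_means <- function(conn, band) {
  sub <- conn[conn$band == band & conn$source != conn$sink, ]
  dplyr::summarise(dplyr::group_by(sub, .data$subject_id, .data$group),
                   mean_pdc = mean(.data$pdc), .groups = "drop")
}

#' Per-group summary of band connectivity
#'
#' Mean and standard deviation, over the subjects of each group, of each
#' subject's mean off-diagonal PDC in one band.
#'
#' @param conn Long connectivity tibble (`subject_id`, `group`, `band`,
#'   `source`, `sink`, `pdc`), e.g. from [cohort_connectivity()].
#' @param band Band name (default `"alpha"`).
#' @return A tibble with `group`, `mean`, `sd`, `n`. Single-subject groups get
#'   `sd = NA` with a warning.
#' @export
group_summary <- function(conn, band = "alpha") {
  means <- subject_band_means(conn, band)
  if (!nrow(means)) stop("no subjects in that band", call. = FALSE)
  out <- dplyr::summarise(dplyr::group_by(means, .data$group),
                          mean = mean(.data$mean_pdc),
                          sd = sd(.data$mean_pdc),
                          n = dplyr::n(), .groups = "drop")
  if (any(out$n == 1)) {
    warning("group(s) with a single subject: sd undefined", call. = FALSE)
  }
  out
}

#' Band-wise group ANOVA on connectivity
#'
#' Two observation layouts are available. `"connection"` mirrors the reference
#' analysis's degrees of freedom: the observations are the per-group mean PDC
#' of each of the 64 directed channel pairs (diagonal included as zero), giving
#' df = (3, 252) for four groups. `"subject"` is the statistically conventional
#' layout: one observation per subject (that subject's mean off-diagonal PDC),
#' giving df = (3, 4n - 4).
#'
#' @param conn Long connectivity tibble.
#' @param band Band name.
#' @param layout `"connection"` (reproduction mode, default) or `"subject"`
#'   (inference mode).
#' @return A one-row tibble as from [oneway_anova()], plus `band` and `layout`.
#' @export
connectivity_anova <- function(conn, band = "delta",
                               layout = c("connection", "subject")) {
  layout <- match.arg(layout)
  if (layout == "connection") {
    sub <- conn[conn$band == band, ]
    obs <- dplyr::summarise(
      dplyr::group_by(sub, .data$group, .data$source, .data$sink),
      pdc = mean(.data$pdc), .groups = "drop"
    )
    # include the zero diagonal cells so each group contributes all 64 pairs
    labels <- unique(c(obs$source, obs$sink))
    diag_rows <- tidyr::expand_grid(group = unique(obs$group), label = labels)
    diag_rows <- tibble::tibble(group = diag_rows$group,
                                source = diag_rows$label,
                                sink = diag_rows$label, pdc = 0)
    have_diag <- any(obs$source == obs$sink)
    if (!have_diag) obs <- dplyr::bind_rows(obs, diag_rows)
    res <- oneway_anova(obs, .data$pdc, .data$group)
  } else {
    means <- subject_band_means(conn, band)
    res <- oneway_anova(means, .data$mean_pdc, .data$group)
  }
  res$band <- band
  res$layout <- layout
  res
}

#' Band-wise Tukey HSD on connectivity
#'
#' @inheritParams connectivity_anova
#' @param alpha Rejection level.
#' @return Pairwise table as from [tukey_hsd()], plus `band`.
#' @export
connectivity_tukey <- function(conn, band = "delta", alpha = 0.05) {
  means <- subject_band_means(conn, band)
  out <- tukey_hsd(means, .data$mean_pdc, .data$group, alpha = alpha)
  out$band <- band
  out
}

#' Correlation of connectivity with SIAS scores
#'
#' Pearson correlation between each subject's mean off-diagonal PDC in one
#' band and their SIAS score, per severity group and pooled.
#'
#' @param conn Long connectivity tibble.
#' @param subjects Subject tibble with `subject_id`, `group`, `sias` (e.g.
#'   `cohort$subjects`).
#' @param band Band name (default `"alpha"`, the band the reference correlation
#'   analysis focuses on).
#' @return A tibble with one row per group plus a `"pooled"` row: `group`, `r`,
#'   `n`, `statistic`, `p_value`.
#' @export
sias_correlation <- function(conn, subjects, band = "alpha") {
  means <- subject_band_means(conn, band)
  df <- dplyr::inner_join(means, subjects[, c("subject_id", "sias")],
                          by = "subject_id")
  per_group <- purrr::map_dfr(split(df, df$group, drop = TRUE), function(d) {
    res <- pearson_corr(d, .data$mean_pdc, .data$sias)
    res$group <- as.character(d$group[1])
    res
  })
  pooled <- pearson_corr(df, .data$mean_pdc, .data$sias)
  pooled$group <- "pooled"
  out <- dplyr::bind_rows(per_group, pooled)
  out$band <- band
  out[, c("group", "band", "r", "n", "statistic", "p_value")]
}
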