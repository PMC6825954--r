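# Evaluation statistics: size-factor correlations, repeated-measures and
# mixed ANOVA with lower-bound sphericity adjustment, Bonferroni post hoc
# comparisons, signed heat-map tables.

P_DISPLAY_FLOOR <- 1e-300  # display floor only; comparisons use raw values

#' Pearson correlation with two-sided p value
#'
#' Sample Pearson correlation; the p value comes from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (two-sided), as computed by [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length, n >= 3, both non-constant.
#' @return object of class `correlation_result`: `r`, `r_squared`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("sample-size error: need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("undefined correlation: constant input vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, r^2 = %.3f, p = %.3g, n = %d\n",
              x$r, x$r_squared, max(x$p, P_DISPLAY_FLOOR), x$n))
  invisible(x)
}

anova_row <- function(effect, ss_num, df_num, ss_den, df_den, eps_df = NULL) {
  ms_num <- ss_num / df_num
  ms_den <- ss_den / df_den
  if (ss_num <= 0 || !is.finite(ms_num)) {
    f <- 0; p <- 1; p_lb <- if (is.null(eps_df)) NA_real_ else 1
  } else if (ms_den <= 0) {
    f <- Inf; p <- 0; p_lb <- if (is.null(eps_df)) NA_real_ else 0
  } else {
    f <- ms_num / ms_den
    p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
    p_lb <- if (is.null(eps_df)) NA_real_ else
      stats::pf(f, eps_df[1], eps_df[2], lower.tail = FALSE)
  }
  data.frame(effect = effect, F = f, df_num = df_num, df_den = df_den,
             p_unadjusted = p, p_lower_bound = p_lb,
             stringsAsFactors = FALSE)
}

#' One-way repeated-measures ANOVA (age effect)
#'
#' Within-subject F = MS_age / MS_(age x subject) from a complete
#' animal-by-age matrix. Besides the unadjusted p value, the p value under
#' the lower-bound sphericity adjustment (epsilon = 1/(k-1), the most
#' conservative correction: numerator df 1, denominator df n-1) is
#' reported. If the age means are identical F = 0 and p = 1; if the error
#' mean square vanishes with a non-zero age effect, p underflows to 0 and
#' is floored only for display.
#'
#' @param values numeric matrix, rows = animals (subjects), columns = age
#'   points; no missing cells, >= 2 rows and >= 2 columns.
#' @return data frame of class `anova_result` with one row (effect "age").
#' @export
repeated_measures_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stopf("incomplete design: missing cells in the animal x age matrix")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stopf("need >= 2 animals and >= 2 age points")
  grand <- mean(values)
  subj_m <- rowMeans(values); age_m <- colMeans(values)
  ss_subj <- k * sum((subj_m - grand)^2)
  ss_age <- n * sum((age_m - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_age
  # numerical guard: exact-zero designs can leave tiny negative residual SS
  if (ss_err < 0 && ss_err > -1e-12 * max(ss_tot, 1)) ss_err <- 0
  out <- anova_row("age", ss_age, k - 1L, ss_err, (n - 1L) * (k - 1L),
                   eps_df = c(1, n - 1L))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Mixed (two-way repeated-measures) ANOVA: genotype x age
#'
#' One between-subject factor (genotype) crossed with one within-subject
#' factor (age). Animals missing any age point are dropped (complete-case
#' rule). Reports the within-subject effects (age, genotype x age) with
#' both unadjusted and lower-bound-adjusted p values (epsilon = 1/(k-1):
#' the numerator df collapses by the factor epsilon*(k-1) = 1 and the
#' denominator df scales by epsilon), and the between-subject genotype
#' effect tested against subjects-within-groups.
#'
#' @param data long-format data frame with one row per animal x age.
#' @param parameter name of the response column.
#' @param subject,within,between column names (defaults `animal_id`,
#'   `age_weeks`, `genotype`).
#' @return data frame of class `anova_result` with rows "age",
#'   "genotype:age", "genotype".
#' @export
mixed_anova <- function(data, parameter, subject = "animal_id",
                        within = "age_weeks", between = "genotype") {
  data <- complete_case_subset(as.data.frame(data), subject, within)
  y <- data[[parameter]]
  s <- factor(data[[subject]]); a <- factor(data[[within]])
  grp_of <- tapply(as.character(data[[between]]), s, function(v) v[1])
  g <- factor(grp_of[as.character(s)])
  if (nlevels(g) != 2L) stopf("design error: need exactly two genotype groups")
  if (any(table(g) == 0)) stopf("design error: empty genotype group")
  k <- nlevels(a)
  subj_m <- tapply(y, s, mean)
  grp <- factor(grp_of)                       # per-subject genotype
  N <- nlevels(s); n_g <- table(grp)
  grand <- mean(y)
  grp_m <- tapply(y, g, mean)
  age_m <- tapply(y, a, mean)
  cell_m <- tapply(y, list(g, a), mean)
  ss_between_subj <- k * sum((subj_m - grand)^2)
  ss_geno <- k * sum(n_g * (grp_m[levels(grp)] - grand)^2)
  ss_subj_within <- ss_between_subj - ss_geno
  ss_age <- N * sum((age_m - grand)^2)
  ss_cells <- sum(rep(n_g, times = k) * (cell_m - grand)^2)
  ss_inter <- ss_cells - ss_geno - ss_age
  ss_tot <- sum((y - grand)^2)
  ss_within_subj <- ss_tot - ss_between_subj
  ss_err_within <- ss_within_subj - ss_age - ss_inter
  guard <- function(ss) if (ss < 0 && ss > -1e-10 * max(ss_tot, 1)) 0 else ss
  ss_inter <- guard(ss_inter); ss_err_within <- guard(ss_err_within)
  ss_subj_within <- guard(ss_subj_within)
  df_err_w <- (N - 2L) * (k - 1L)
  out <- rbind(
    anova_row("age", ss_age, k - 1L, ss_err_within, df_err_w,
              eps_df = c(1, N - 2L)),
    anova_row("genotype:age", ss_inter, k - 1L, ss_err_within, df_err_w,
              eps_df = c(1, N - 2L)),
    anova_row("genotype", ss_geno, 1L, ss_subj_within, N - 2L))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' @export
print.anova_result <- function(x, ...) {
  y <- as.data.frame(x)
  y$p_unadjusted <- pmax(y$p_unadjusted, P_DISPLAY_FLOOR)
  y$p_lower_bound <- pmax(y$p_lower_bound, P_DISPLAY_FLOOR)
  print.data.frame(y, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Keep animals observed at every within-subject level
#'
#' @param data long-format data frame.
#' @param subject,within column names.
#' @return the complete-case subset (same class), attribute `n_dropped`
#'   records how many animals were removed.
#' @export
complete_case_subset <- function(data, subject = "animal_id", within = "age_weeks") {
  lev <- unique(data[[within]])
  tab <- table(data[[subject]], data[[within]]) > 0
  keep <- rownames(tab)[rowSums(tab) == length(lev)]
  out <- data[data[[subject]] %in% keep, , drop = FALSE]
  attr(out, "n_dropped") <- length(unique(data[[subject]])) - length(keep)
  out
}

#' Per-age-point genotype comparisons with Bonferroni correction
#'
#' Two-sided two-sample t tests (pooled variance) of transgenic vs
#' wild-type animal means at each age point; p values are Bonferroni
#' adjusted across age points (`min(1, p * n_ages)`). The sign records the
#' direction of the transgenic minus wild-type difference. Age points
#' where either group has fewer than two animals are flagged untestable.
#'
#' @param data animal-level long data frame.
#' @param parameter response column name.
#' @param tg_level genotype level treated as transgenic; default the
#'   level named "TG" if present, otherwise the second factor level.
#' @param subject,within,between column names as in [mixed_anova()].
#' @param welch use Welch's correction instead of pooled variance
#'   (default `FALSE`).
#' @return data frame of class `posthoc_table`: age, group means, mean
#'   difference (TG - WT), raw and adjusted p, sign, testable flag.
#' @export
bonferroni_posthoc <- function(data, parameter, tg_level = NULL,
                               subject = "animal_id", within = "age_weeks",
                               between = "genotype", welch = FALSE) {
  data <- as.data.frame(data)
  g <- factor(data[[between]])
  if (nlevels(g) != 2L) stopf("design error: need exactly two genotype groups")
  if (is.null(tg_level))
    tg_level <- if ("TG" %in% levels(g)) "TG" else levels(g)[2L]
  wt_level <- setdiff(levels(g), tg_level)
  ages <- sort(unique(data[[within]]))
  k <- length(ages)
  rows <- lapply(ages, function(ag) {
    d <- data[data[[within]] == ag, ]
    ytg <- d[[parameter]][d[[between]] == tg_level]
    ywt <- d[[parameter]][d[[between]] == wt_level]
    if (length(ytg) < 2L || length(ywt) < 2L)
      return(data.frame(age = ag, mean_wt = mean(ywt), mean_tg = mean(ytg),
                        mean_diff = mean(ytg) - mean(ywt), p_raw = NA_real_,
                        sign = NA_integer_, testable = FALSE))
    p <- if (stats::sd(c(ytg, ywt)) == 0) 1 else
      stats::t.test(ytg, ywt, var.equal = !welch)$p.value
    d_m <- mean(ytg) - mean(ywt)
    data.frame(age = ag, mean_wt = mean(ywt), mean_tg = mean(ytg),
               mean_diff = d_m, p_raw = p,
               sign = as.integer(sign(d_m)), testable = TRUE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * k)
  out <- out[, c("age", "mean_wt", "mean_tg", "mean_diff",
                 "p_raw", "p_adj", "sign", "testable")]
  attr(out, "tg_level") <- tg_level
  attr(out, "n_ages") <- k
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Signed-significance heat-map table
#'
#' Collapses a set of post hoc tables (one per gait parameter) into a
#' parameters x age matrix of `sign * (-log10(adjusted p))`: positive
#' (red) where the transgenic group is higher, negative (blue) where it
#' is lower, 0 where adjusted p = 1, `NA` for untestable cells.
#'
#' @param posthocs named list of `posthoc_table` objects.
#' @return numeric matrix of class `heatmap_table` (rows = parameters,
#'   columns = age points).
#' @export
heatmap_table <- function(posthocs) {
  stopifnot(is.list(posthocs), length(posthocs) >= 1L)
  ages <- sort(unique(unlist(lapply(posthocs, function(p) p$age))))
  m <- matrix(NA_real_, nrow = length(posthocs), ncol = length(ages),
              dimnames = list(names(posthocs), as.character(ages)))
  for (i in seq_along(posthocs)) {
    p <- posthocs[[i]]
    for (j in seq_len(nrow(p))) {
      if (!isTRUE(p$testable[j])) next
      padj <- max(p$p_adj[j], P_DISPLAY_FLOOR)
      s <- p$sign[j]
      m[i, as.character(p$age[j])] <- if (padj >= 1 || s == 0L) 0 else s * -log10(padj)
    }
  }
  class(m) <- c("heatmap_table", class(m))
  m
}

#' @rdname heatmap_table
#' @param x a `heatmap_table`; `path` output CSV file.
#' @param path output CSV file.
#' @export
write_heatmap_csv <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname heatmap_table
#' @param ... passed to [graphics::image()].
#' @export
plot.heatmap_table <- function(x, ...) {
  m <- unclass(x)
  lim <- max(abs(m), 1, na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(51)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "age point", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2)
  graphics::box()
  invisible(x)
}
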