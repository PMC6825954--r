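test_that("Pearson correlation matches the direct covariance formula", {
  x <- 1:10
  ct <- pearson_with_p(x, 2 * x + 1)
  expect_equal(ct$r, 1)
  expect_lt(ct$p, 1e-12)
  # orthogonalized residuals have exactly zero correlation
  set.seed(7)
  y0 <- rnorm(20); x0 <- rnorm(20)
  y_perp <- residuals(lm(y0 ~ x0))
  expect_equal(pearson_with_p(x0 - mean(x0), y_perp)$r, 0, tolerance = 1e-12)
  # random dataset against the brute-force formula oracle
  set.seed(13)
  a <- rnorm(8); b <- rnorm(8) + 0.4 * a
  got <- pearson_with_p(a, b)
  want <- oracle_pearson(a, b)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$r_squared, want$r^2, tolerance = 1e-12)
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_with_p(1:2, 2:3), "sample-size")
})

test_that("repeated-measures ANOVA handles degenerate designs per contract", {
  m <- matrix(rnorm(12), 4, 3)
  same <- m[, c(1, 1, 1)]
  res <- repeated_measures_anova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p_unadjusted, 1)
  # pure subject shifts with distinct age means: zero error, p underflows
  pure <- outer(c(0, 1, 2, 5), c(0, 3, 7), `+`)
  res2 <- repeated_measures_anova(pure)
  expect_true(is.infinite(res2$F))
  expect_equal(res2$p_unadjusted, 0)
  expect_error(repeated_measures_anova(matrix(c(1, NA, 2, 3), 2, 2)),
               "incomplete")
})

test_that("repeated-measures F and p match the aov error-stratum oracle", {
  set.seed(21)
  m <- matrix(rnorm(15) + rep(c(0, 0.5, 1), each = 5), 5, 3)
  res <- repeated_measures_anova(m)
  d <- data.frame(y = c(m), s = factor(rep(1:5, 3)), a = factor(rep(1:3, each = 5)))
  av <- summary(aov(y ~ a + Error(s/a), data = d))[["Error: s:a"]][[1]]
  expect_equal(res$F, av["a", "F value"], tolerance = 1e-10)
  expect_equal(res$p_unadjusted, av["a", "Pr(>F)"], tolerance = 1e-10)
  # lower bound: same F on (1, n-1) df
  expect_equal(res$p_lower_bound, pf(res$F, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # two age points: epsilon = 1, adjustment is the identity
  m2 <- m[, 1:2]
  res2 <- repeated_measures_anova(m2)
  expect_equal(res2$p_lower_bound, res2$p_unadjusted, tolerance = 1e-12)
})

make_mixed_data <- function(n1, n2, k, seed = 5, geno_shift = 0) {
  set.seed(seed)
  d <- expand.grid(animal_id = sprintf("a%02d", seq_len(n1 + n2)),
                   age_weeks = seq_len(k), stringsAsFactors = FALSE)
  d$genotype <- ifelse(as.integer(sub("a", "", d$animal_id)) <= n1, "WT", "TG")
  d$y <- rnorm(nrow(d)) + rep(rnorm(n1 + n2), k) +
    0.3 * d$age_weeks + geno_shift * (d$genotype == "TG")
  d
}

test_that("mixed ANOVA matches aov on balanced and unbalanced designs", {
  for (n12 in list(c(6, 6), c(6, 8))) {
    d <- make_mixed_data(n12[1], n12[2], 4, seed = 5 + n12[2], geno_shift = 0.5)
    res <- mixed_anova(d, "y")
    av <- summary(aov(y ~ genotype * factor(age_weeks) + Error(animal_id), data = d))
    between <- av[["Error: animal_id"]][[1]]
    within <- av[["Error: Within"]][[1]]
    expect_equal(res$F[res$effect == "genotype"],
                 between["genotype", "F value"], tolerance = 1e-10)
    expect_equal(res$F[res$effect == "age"],
                 within["factor(age_weeks)", "F value"], tolerance = 1e-10)
    expect_equal(res$F[res$effect == "genotype:age"],
                 within["genotype:factor(age_weeks)", "F value"], tolerance = 1e-10)
    expect_equal(res$p_unadjusted[res$effect == "age"],
                 within["factor(age_weeks)", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("lower-bound adjustment collapses within dfs; identity at k = 2", {
  d <- make_mixed_data(5, 5, 3, seed = 9)
  res <- mixed_anova(d, "y")
  age <- res[res$effect == "age", ]
  expect_equal(age$p_lower_bound, pf(age$F, 1, 8, lower.tail = FALSE),
               tolerance = 1e-12)
  d2 <- make_mixed_data(5, 5, 2, seed = 10)
  res2 <- mixed_anova(d2, "y")
  expect_equal(res2$p_lower_bound[res2$effect == "age"],
               res2$p_unadjusted[res2$effect == "age"], tolerance = 1e-12)
})

test_that("mixed ANOVA enforces two groups and complete cases", {
  d <- make_mixed_data(5, 5, 3, seed = 11)
  expect_error(mixed_anova(d[d$genotype == "WT", ], "y"), "design error")
  # animal with a missing age point is dropped, not propagated
  d_inc <- d[!(d$animal_id == "a01" & d$age_weeks == 2), ]
  res <- mixed_anova(d_inc, "y")
  res_ref <- mixed_anova(d[d$animal_id != "a01", ], "y")
  expect_equal(res$F, res_ref$F, tolerance = 1e-12)
  cc <- complete_case_subset(d_inc)
  expect_equal(attr(cc, "n_dropped"), 1L)
})

test_that("post hoc tests multiply p by the number of age points, capped at 1", {
  d <- make_mixed_data(6, 6, 5, seed = 12, geno_shift = 1.5)
  ph <- bonferroni_posthoc(d, "y")
  expect_equal(nrow(ph), 5L)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 5), tolerance = 1e-12)
  # cross-check one age point against t.test directly
  d1 <- d[d$age_weeks == 1, ]
  tt <- t.test(y ~ factor(genotype, c("TG", "WT")), data = d1, var.equal = TRUE)
  expect_equal(ph$p_raw[1], tt$p.value, tolerance = 1e-12)
  expect_equal(ph$mean_diff[1], mean(d1$y[d1$genotype == "TG"]) -
                 mean(d1$y[d1$genotype == "WT"]), tolerance = 1e-12)
  # monotone in the raw p and never above 1
  expect_true(all(diff(ph$p_adj[order(ph$p_raw)]) >= -1e-15))
  expect_true(all(ph$p_adj <= 1))
})

test_that("identical groups give p 1 and zero sign; small cells are untestable", {
  d <- expand.grid(animal_id = sprintf("a%d", 1:6), age_weeks = 1:2,
                   stringsAsFactors = FALSE)
  d$genotype <- rep(c("WT", "TG"), each = 3)[match(d$animal_id, sprintf("a%d", 1:6))]
  d$y <- 1
  ph <- bonferroni_posthoc(d, "y")
  expect_equal(ph$p_adj, c(1, 1))
  expect_equal(ph$sign, c(0L, 0L))
  d2 <- d[!(d$animal_id %in% c("a4", "a5") & d$age_weeks == 2), ]
  ph2 <- bonferroni_posthoc(d2, "y")
  expect_false(ph2$testable[2])
  expect_true(is.na(ph2$p_adj[2]))
})

test_that("heat-map table encodes signed log10 significance", {
  ph <- structure(data.frame(
    age = c(10, 26, 42), mean_wt = 1, mean_tg = c(0.5, 1, 2),
    mean_diff = c(-0.5, 0, 1), p_raw = c(0.01, 0.9, NA),
    p_adj = c(0.05, 1, NA), sign = c(-1L, 0L, NA), testable = c(TRUE, TRUE, FALSE)),
    class = c("posthoc_table", "data.frame"))
  m <- heatmap_table(list(stride = ph))
  expect_equal(m["stride", "10"], -log10(0.05) * -1, tolerance = 1e-12)
  expect_equal(round(m["stride", "10"], 3), -1.301)
  expect_equal(m["stride", "26"], 0)
  expect_true(is.na(m["stride", "42"]))
  f <- withr::local_tempfile(fileext = ".csv")
  write_heatmap_csv(m, f)
  expect_true(file.exists(f))
})
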