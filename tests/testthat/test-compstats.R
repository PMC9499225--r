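# Small-scale correctness checks for the statistical battery; the larger
# null-calibration simulations live in the acceptance suite.

make_ancova_data <- function(n_per = 10, k = 2, offsets = rep(0, k),
                             slope = 1, resid = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- factor(rep(seq_len(k), each = n_per))
  x <- runif(k * n_per, 1, 3)
  y <- offsets[g] + slope * x + rnorm(k * n_per, 0, resid)
  data.frame(y = y, g = g, x = x)
}

test_that("EMMs reproduce the adjusted-mean closed form", {
  d <- make_ancova_data(n_per = 12, k = 3, offsets = c(0, 1, 2), seed = 5)
  fit <- lm(y ~ g + x, data = d, contrasts = list(g = "contr.sum"))
  emm <- estimated_marginal_means(fit, "g")
  b <- coef(lm(y ~ g + x, data = d))[["x"]]
  for (l in levels(d$g)) {
    sub <- d[d$g == l, ]
    closed <- mean(sub$y) + b * (mean(d$x) - mean(sub$x))
    expect_equal(emm$emm_response[emm$level == l], closed,
                 tolerance = 1e-10)
  }
  # zero slope: EMMs are the raw group means
  d0 <- d; d0$y <- ave(d0$y, d0$g)   # constant within group
  emm0 <- estimated_marginal_means(lm(y ~ g + x, data = d0), "g")
  expect_equal(emm0$emm_response,
               as.vector(tapply(d0$y, d0$g, mean)), tolerance = 1e-10)
})

test_that("EMMs and their SEs agree with emmeans", {
  d <- make_ancova_data(n_per = 9, k = 3, offsets = c(0, 0.5, 2), seed = 9)
  fit <- lm(y ~ g + x, data = d, contrasts = list(g = "contr.sum"))
  mine <- estimated_marginal_means(fit, "g")
  ref <- as.data.frame(emmeans::emmeans(fit, "g"))
  expect_equal(mine$emm_response, ref$emmean, tolerance = 1e-8)
  expect_equal(mine$se_response, ref$SE, tolerance = 1e-8)
  # out-of-range evaluation warns rather than errors
  expect_warning(estimated_marginal_means(fit, "g", at = list(x = 50)),
                 "outside")
})

test_that("balanced centered covariate leaves EMMs at raw group means", {
  set.seed(31)
  g <- factor(rep(1:2, each = 10))
  x <- rep(seq(-1, 1, length.out = 10), 2)   # centered, identical per group
  y <- c(rep(0, 10), rep(3, 10)) + 0.7 * x + rnorm(20, 0, 0.3)
  d <- data.frame(y, g, x)
  fit <- lm(y ~ g + x, data = d, contrasts = list(g = "contr.sum"))
  emm <- estimated_marginal_means(fit, "g")
  expect_equal(emm$emm_response, as.vector(tapply(y, g, mean)),
               tolerance = 1e-10)
})

test_that("MANCOVA collapses to the univariate ANCOVA for one response", {
  d <- make_ancova_data(n_per = 10, k = 3, offsets = c(0, 1, 3), seed = 13)
  d$r1 <- d$y
  m <- fit_mancova(d, "r1", "g", "x")
  a <- ancova(d, "r1", "g", "x")
  expect_equal(m$multivariate$group$wilks$approx_F, a$group$F,
               tolerance = 1e-8)
  expect_equal(m$multivariate$group$wilks$p, a$group$p, tolerance = 1e-8)
  expect_equal(m$multivariate$group$pillai$approx_F, a$group$F,
               tolerance = 1e-8)
  # between-subjects table carries the same univariate test
  expect_equal(m$between_subjects$r1$group$F, a$group$F, tolerance = 1e-10)
})

test_that("MANCOVA multivariate criteria match car's summary on synthetic data", {
  d <- synth_morphometry(morpho_sim_spec(default_morpho_species(), seed = 21))
  m <- fit_mancova(d, c("eye_area", "facet_count", "facet_diameter_D"),
                   "species", "mesosoma_length")
  fit <- m$fit
  sm <- summary(car::Manova(fit, type = "III"),
                multivariate = TRUE)$multivariate.tests$.g
  eig <- Re(eigen(solve(sm$SSPE, sm$SSPH), only.values = TRUE)$values)
  wilks_ref <- prod(1 / (1 + eig))
  pillai_ref <- sum(eig / (1 + eig))
  expect_equal(m$multivariate$group$wilks$statistic, wilks_ref,
               tolerance = 1e-10)
  expect_equal(m$multivariate$group$pillai$statistic, pillai_ref,
               tolerance = 1e-10)
  expect_true(m$multivariate$group$wilks$statistic > 0 &&
                m$multivariate$group$wilks$statistic <= 1)
  expect_gte(m$multivariate$group$pillai$statistic, 0)
  # one row per group in the EMM table, one emm/se pair per response
  expect_equal(nrow(m$emm_table), 2L)
  expect_equal(sum(grepl("^emm_", names(m$emm_table))), 3L)
})

test_that("ANCOVA orthogonal covariate reduces the group F to one-way ANOVA", {
  set.seed(17)
  g <- factor(rep(1:3, each = 8))
  x <- rep(seq(-1, 1, length.out = 8), 3)   # identical per group: orthogonal
  y <- c(rep(0, 8), rep(1, 8), rep(2.5, 8)) + rnorm(24, 0, 0.8)
  d <- data.frame(y, g, x)
  a <- ancova(d, "y", "g", "x")
  f1 <- anova(lm(y ~ g + x, data = d))  # sequential; orthogonal so same SS
  expect_equal(a$group$F, f1["g", "F value"], tolerance = 1e-8)

  # perfect fit flagged with p = 0
  dp <- data.frame(y = rep(c(0, 5), each = 6) + rep(1:6, 2) * 0,
                   g = factor(rep(1:2, each = 6)), x = rep(1:6, 2))
  ap <- ancova(dp, "y", "g", "x")
  expect_true(ap$perfect_fit)
  expect_equal(ap$group$p, 0)
})

test_that("homogeneity-of-slopes interaction test is well calibrated at small scale", {
  set.seed(23)
  ps <- replicate(150, {
    d <- make_ancova_data(n_per = 8, k = 2)
    ancova(d, "y", "g", "x", test_slopes = TRUE)$interaction$p
  })
  # uniformity on the null: KS not rejected at 0.001
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("letter displays match the expected pattern and their own p matrix", {
  # clear separation
  r <- lsd_letters(c(g1 = 10, g2 = 10, g3 = 2), ses = 0.1, df = 20)
  expect_equal(unname(r$letters), c("a", "a", "b"))
  # all equal
  r2 <- lsd_letters(c(5, 5, 5), ses = 1, df = 10)
  expect_equal(unname(r2$letters), c("a", "a", "a"))
  # chained overlap: means 10,9,8,7 with se 0.5 and large df gives
  # significant pairs (1,3),(1,4),(2,4) -> a, ab, bc, c
  r3 <- lsd_letters(c(m1 = 10, m2 = 9, m3 = 8, m4 = 7), ses = 0.5,
                    df = 1000)
  expect_equal(unname(r3$letters), c("a", "ab", "bc", "c"))
  # consistency with the p matrix, brute force over all pairs
  p <- r3$p_matrix
  for (i in 1:3) for (j in (i + 1):4) {
    share <- length(intersect(strsplit(r3$letters[i], "")[[1]],
                              strsplit(r3$letters[j], "")[[1]])) > 0
    expect_equal(share, p[i, j] >= r3$alpha)
  }
})

test_that("Tukey HSD reduces to the two-sample t at k = 2 and matches q tables", {
  # k = 2: ptukey(q, 2, df) equals the two-sided t p-value with t = q/sqrt(2)
  means <- c(a = 1, b = 3); mse <- 2; df <- 18; ns <- 10
  r <- tukey_hsd(means, mse, df, ns)
  t2 <- abs(unname(diff(means))) / sqrt(mse * (1 / 10 + 1 / 10))
  expect_equal(r$p_matrix[1, 2], 2 * pt(t2, df, lower.tail = FALSE),
               tolerance = 1e-10)
  # equal means: no rejections
  re <- tukey_hsd(c(2, 2, 2), mse = 1, df = 12, ns = 5)
  expect_equal(unname(re$letters), c("a", "a", "a"))
  # critical q for k = 3, df = 12 at alpha .05 is 3.77 (2 dp)
  expect_equal(round(qtukey(0.95, 3, 12), 2), 3.77)
  # a pair exactly at the critical difference flips significance around q
  sed1 <- sqrt(1 / 2 * (1 / 5 + 1 / 5))
  dcrit <- qtukey(0.95, 3, 12) * sed1
  r3 <- tukey_hsd(c(0, dcrit * 1.01, 10), mse = 1, df = 12, ns = 5)
  expect_lt(r3$p_matrix[1, 2], 0.05)
  r4 <- tukey_hsd(c(0, dcrit * 0.99, 10), mse = 1, df = 12, ns = 5)
  expect_gt(r4$p_matrix[1, 2], 0.05)
})

test_that("exact r x c test matches enumeration oracles and fisher.test", {
  tabs <- list(
    matrix(c(9, 1, 0, 0, 13, 3), 2, byrow = TRUE),
    matrix(c(1, 0, 0, 1), 2),
    matrix(c(3, 2, 1, 4), 2),
    matrix(c(2, 3, 4, 5, 1, 0), 2, byrow = TRUE),
    matrix(c(1, 2, 3, 3, 2, 1, 2, 2, 2), 3, byrow = TRUE))
  for (tab in tabs) {
    mine <- fisher_exact_rxc(tab)
    expect_equal(mine$p, oracle_fisher_p(tab), tolerance = 1e-10)
    expect_equal(mine$p, fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  # random small tables against the brute-force oracle
  set.seed(29)
  for (rep in 1:25) {
    r <- sample(2:3, 1); cc <- sample(2:3, 1)
    tab <- matrix(rpois(r * cc, 1.5), r, cc)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_rxc(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
  # degenerate margins give p = 1
  expect_equal(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p, 1)
  # resource guard
  expect_error(fisher_exact_rxc(matrix(500, 5, 5), max_tables = 1e3),
               class = "ommatidics_resource_error")
})

test_that("Box's M is zero for identical groups and matches its formula", {
  set.seed(37)
  Y <- matrix(rnorm(40), 20, 2)
  d <- data.frame(a = c(Y[, 1], Y[, 1]), b = c(Y[, 2], Y[, 2]),
                  g = rep(c("u", "v"), each = 20))
  r <- box_m(d, c("a", "b"), "g")
  expect_equal(r$M, 0, tolerance = 1e-10)
  expect_equal(r$df, 3)          # (k-1) p (p+1) / 2
  expect_false(r$violated)
  # hand recomputation on unequal groups
  d2 <- data.frame(a = rnorm(40), b = rnorm(40),
                   g = rep(c("u", "v"), each = 20))
  d2$a[d2$g == "v"] <- d2$a[d2$g == "v"] * 3
  r2 <- box_m(d2, c("a", "b"), "g")
  S1 <- cov(as.matrix(d2[d2$g == "u", 1:2]))
  S2 <- cov(as.matrix(d2[d2$g == "v", 1:2]))
  Sp <- (19 * S1 + 19 * S2) / 38
  M_ref <- 38 * log(det(Sp)) - 19 * log(det(S1)) - 19 * log(det(S2))
  expect_equal(r2$M, M_ref, tolerance = 1e-10)
})

test_that("Levene's test uses mean-centered deviations", {
  set.seed(41)
  d <- data.frame(y = c(rnorm(15, 0, 1), rnorm(15, 0, 4)),
                  g = rep(c("a", "b"), each = 15))
  r <- levene(d, "y", "g")
  ref <- car::leveneTest(d$y, factor(d$g), center = mean)
  expect_equal(r$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # identical groups: F = 0
  d0 <- data.frame(y = rep(1:5, 2), g = rep(c("a", "b"), each = 5))
  expect_equal(levene(d0, "y", "g")$F, 0)
})

test_that("repeated-measures ANOVA reports Mauchly, within-F and Wilks", {
  Y <- synth_regional_D(region_effects = c(anterior = 0, dorsal = 0,
                                           lateral = 0, posterior = 0,
                                           ventral = 2),
                        resid_sd = 0.5, n_subjects = 14, seed = 43)
  r <- rm_anova(Y)
  expect_equal(r$mauchly$df, 9)         # k = 5 -> k(k-1)/2 - 1
  expect_equal(r$within$df_num, 4)
  expect_equal(r$within$df_den, 52)
  expect_lt(r$within$p, 0.001)
  # Mauchly agrees with stats::mauchly.test
  ref <- mauchly.test(lm(Y ~ 1), X = ~1)
  expect_equal(r$mauchly$W, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$mauchly$p, unname(ref$p.value), tolerance = 1e-10)
  # within-subjects F agrees with aov
  long <- data.frame(y = as.vector(Y),
                     s = factor(rep(1:14, 5)),
                     l = factor(rep(colnames(Y), each = 14)))
  avf <- summary(aov(y ~ l + Error(s), long))[["Error: Within"]][[1]]
  expect_equal(r$within$F, avf["l", "F value"], tolerance = 1e-10)
  # LSD letters rank ventral largest
  expect_equal(names(which.max(r$level_means)), "ventral")
  expect_equal(unname(r$lsd$letters["ventral"]), "a")
  # identical columns flag a degenerate covariance
  Yc <- matrix(20, 6, 4)
  rc <- rm_anova(Yc + rnorm(6))   # identical columns within subject
  expect_true(rc$degenerate)
  expect_equal(rc$within$F, 0)
  # incomplete cases dropped with a warning
  Y2 <- Y; Y2[1, 1] <- NA
  expect_warning(r2 <- rm_anova(Y2), "incomplete")
  expect_equal(r2$n, 13)
})

test_that("one-way ANOVA matches t-squared at two groups", {
  set.seed(47)
  d <- data.frame(y = c(rnorm(10, 0), rnorm(10, 1.5)),
                  g = rep(c("a", "b"), each = 10))
  r <- one_way_anova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  expect_error(one_way_anova(data.frame(y = 1:5, g = "a"), "y", "g"),
               "at least 2")
})

test_that("two-way ANCOVA reports type-III terms and Tukey letters", {
  set.seed(53)
  n <- 6
  d <- expand.grid(rep = 1:n, A = c("g1", "g2", "g3", "g4"),
                   B = c("noct", "diur"))
  d$x <- runif(nrow(d), 1, 2)
  # opposite-sign group difference: B effect +2 in g1, -2 in g2, 0 elsewhere
  delta <- ifelse(d$A == "g1", 2, ifelse(d$A == "g2", -2, 0))
  d$y <- 1 + 0.5 * d$x + delta * (d$B == "noct") + rnorm(nrow(d), 0, 0.8)
  r <- two_way_ancova(d, "y", "A", "B", "x")
  expect_lt(r$interaction$p, 0.01)
  expect_equal(length(r$tukey_A$letters), 4L)
  expect_true(all(names(r$tukey_A$emm)[1:2] == c("level", "emm_response")))
  # one factor with a single level collapses to the one-way ANCOVA
  d1 <- d[d$B == "noct", ]
  r1 <- two_way_ancova(d1, "y", "A", "B", "x")
  a1 <- ancova(d1, "y", "A", "x")
  expect_equal(r1$A$F, a1$group$F, tolerance = 1e-8)
  # empty cell triggers an estimability error
  d2 <- d[!(d$A == "g1" & d$B == "noct"), ]
  expect_error(two_way_ancova(d2, "y", "A", "B", "x"),
               class = "ommatidics_estimability_error")
})
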