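# Cultivar-comparison statistics and agronomic indices.

test_that("percent difference reproduces printed comparison cells and its inverse identity", {
  expect_equal(round_half_up(percent_difference(105.91, 92.33), 2), 14.71)
  expect_equal(round_half_up(percent_difference(9.82, 9.09), 2), 8.03)
  expect_equal(round_half_up(percent_difference(25.58, 21.31), 2), 20.04)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "non-zero")
  set.seed(21)
  for (k in 1:25) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    dab <- percent_difference(a, b); dba <- percent_difference(b, a)
    expect_equal((1 + dab / 100) * (1 + dba / 100), 1, tolerance = 1e-12)
  }
})

test_that("two-sample t-test matches hand computation and handles variants", {
  id <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t_statistic, 0)
  expect_equal(id$p_value, 1)
  # means differ by 1, pooled se = 1
  hand <- t_test_two_sample(1:5, 2:6, variant = "pooled")
  expect_equal(hand$t_statistic, -1)
  expect_equal(hand$df, 8)
  # Welch with one constant sample: se^2 = s_b^2/n_b, df by Welch-Satterthwaite
  w <- t_test_two_sample(c(2, 2, 2), c(1, 3, 5), variant = "welch")
  se <- sqrt(var(c(1, 3, 5)) / 3)
  expect_equal(w$t_statistic, (2 - 3) / se)
  expect_equal(w$df, 2)
  expect_error(t_test_two_sample(1, c(1, 2)), "at least 2")
})

test_that("two-way ANOVA reproduces a hand-computable textbook decomposition", {
  tab <- trait_table(rep(c("A1", "A2"), each = 4),
                     rep(rep(c("Y1", "Y2"), each = 2), 2),
                     rep(1:2, 4), "x",
                     c(10, 10, 20, 20, 30, 30, 40, 40))
  an <- anova_two_way(tab)
  expect_equal(an$ss, c(800, 200, 0, 0))
  expect_equal(an$df, c(1, 1, 1, 4))
  # degenerate: all cells identical -> zero SS everywhere, F undefined
  flat <- trait_table(rep(c("A1", "A2"), each = 4),
                      rep(rep(c("Y1", "Y2"), each = 2), 2),
                      rep(1:2, 4), "x", rep(7, 8))
  anf <- anova_two_way(flat)
  expect_equal(anf$ss, rep(0, 4))
  expect_true(all(is.nan(anf$f[1:3])))
})

test_that("ANOVA SS partition identity holds on random balanced tables", {
  set.seed(22)
  for (k in 1:100) {
    tab <- gen_trial_table("x", runif(1, 5, 20), runif(1, -2, 2),
                           setNames(runif(3, -2, 2), c("y1", "y2", "y3")),
                           n_reps = 3, sigma = 1, seed = k)
    an <- anova_two_way(tab)
    ss_total <- sum((tab$value - mean(tab$value))^2)
    expect_equal(sum(an$ss), ss_total, tolerance = 1e-9)
  }
})

test_that("ANOVA F for a 2-level factor equals the squared pooled t without a B effect", {
  set.seed(23)
  tab <- gen_trial_table("x", 10, 1.5, c(y1 = 0), n_reps = 8, sigma = 1,
                         seed = 9)
  an <- anova_two_way(tab)
  tt <- t_test_two_sample(tab$value[tab$cultivar == "YLY1"],
                          tab$value[tab$cultivar == "LYP9"])
  expect_equal(an$f[1], tt$t_statistic^2, tolerance = 1e-9)
})

test_that("ANOVA rejects unbalanced or incomplete designs", {
  tab <- gen_trial_table("x", 10, 1, c(y1 = 0, y2 = 1), n_reps = 3,
                         sigma = 1, seed = 1)
  expect_error(anova_two_way(tab[-1, ]), "unbalanced")
  expect_error(anova_two_way(tab[tab$cultivar == "YLY1" | tab$year == "y1", ]),
               "nbalanced|ncomplete")
  drop_cell <- tab[!(tab$cultivar == "YLY1" & tab$year == "y2"), ]
  expect_error(anova_two_way(drop_cell), "incomplete")
})

test_that("LSD letter groupings follow the greedy descending-mean rule", {
  # choose ms_error so that LSD = 1 exactly at df = 10, n = 2
  ms <- 2 * (1 / qt(0.975, 10))^2 / 2
  g <- lsd_groups(c(m1 = 10, m2 = 9.5, m3 = 7, m4 = 6.8),
                  ms_error = ms, df_error = 10, n_per_cell = 2)
  expect_equal(unname(g), c("a", "a", "b", "b"))
  g2 <- lsd_groups(c(hi = 10, lo = 5), ms_error = ms, df_error = 10,
                   n_per_cell = 2)
  expect_equal(unname(g2), c("a", "b"))
  g3 <- lsd_groups(c(a = 10, b = 10.3, c = 9.8), ms_error = ms,
                   df_error = 10, n_per_cell = 2)
  expect_true(all(g3 == "a"))
  # overlapping chain: middle mean shares letters with both neighbours
  g4 <- lsd_groups(c(x = 10, y = 9.2, z = 8.5), ms_error = ms,
                   df_error = 10, n_per_cell = 2)
  expect_equal(unname(g4), c("a", "ab", "b"))
  expect_error(lsd_groups(c(1, 2), 1, 0, 2), "df_error")
})

test_that("agronomic indices compute ratios with sanity flags", {
  expect_equal(harvest_index(50, 100), 0.5)
  expect_equal(harvest_index(0, 100), 0)
  expect_warning(hi <- harvest_index(60, 50), "> 1")
  expect_equal(hi, 1.2)
  expect_error(harvest_index(10, 0), "positive")

  expect_equal(unname(organ_partition(10, 10, 10, 10)), rep(25, 4))
  expect_equal(unname(organ_partition(1, 0, 0, 0)), c(100, 0, 0, 0))
  expect_equal(unname(organ_partition(3, 2, 4, 1)), c(30, 20, 40, 10))
  expect_equal(sum(organ_partition(1.1, 2.3, 3.7, 0.9)), 100)
  expect_error(organ_partition(0, 0, 0, 0), "positive")

  expect_equal(productive_tiller_pct(10, 20), 50)
  expect_equal(productive_tiller_pct(0, 20), 0)
  expect_equal(productive_tiller_pct(13, 16), 81.25)
  expect_warning(productive_tiller_pct(21, 20), "> 100")
  expect_error(productive_tiller_pct(5, 0), "positive")
})

test_that("cultivar comparison composes means, percent difference and the t-test", {
  tab <- trait_table(rep(c("YLY1", "LYP9"), each = 3), "2012", rep(1:3, 2),
                     "Pn", c(25.48, 25.58, 25.68, 21.21, 21.31, 21.41))
  cmp <- compare_cultivars(tab, "Pn", "2012", "YLY1", "LYP9")
  expect_equal(cmp$mean_a, 25.58)
  expect_equal(cmp$mean_b, 21.31)
  expect_equal(round_half_up(cmp$percent_difference, 2), 20.04)
  expect_identical(cmp$significant_at, "0.01")

  eq <- trait_table(rep(c("A", "B"), each = 3), "y", rep(1:3, 2), "x",
                    c(1, 2, 3, 3, 2, 1))
  cmpe <- compare_cultivars(eq, "x", "y", "A", "B")
  expect_equal(cmpe$percent_difference, 0)
  expect_equal(cmpe$p_value, 1)

  single <- trait_table(c("A", "B"), "y", 1, "x", c(12, 10))
  cmps <- compare_cultivars(single, "x", "y", "A", "B")
  expect_equal(cmps$percent_difference, 20)
  expect_true(is.na(cmps$p_value))
  expect_error(compare_cultivars(single, "x", "y", "A", "C"), "missing")
})
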