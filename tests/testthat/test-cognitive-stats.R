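make_small_cohort <- function(seed = 1, n = c(dementia = 10, MCI = 10, NCI = 10),
                              volume_effect = 1, noise = 1) {
  make_cohort(cohort_spec(group_n = n, volume_effect = volume_effect,
                          seed = seed))
}

test_that("group summaries use sample statistics with the n = 1 edge case", {
  rec <- tibble::tibble(group = c("a", "a", "b"),
                        v = c(3, 7, 5))
  gs <- group_summary(rec, "v")
  a <- gs[gs$group == "a", ]
  expect_equal(a$mean, 5)
  expect_equal(a$sd, abs(3 - 7) / sqrt(2))
  expect_true(is.na(gs$sd[gs$group == "b"]))
  expect_error(group_summary(tibble::tibble(v = 1)), class = "wmh_grouping_error")
})

test_that("generator group means are recovered within sampling error", {
  rec <- make_cohort(cohort_spec(group_n = c(dementia = 200, MCI = 200, NCI = 200),
                                 seed = 99))
  gs <- group_summary(rec, "wmh_volume")
  # log-normal group means: exp(mu + sigma^2/2)
  want <- exp(log(c(30000, 14000, 3000)) + c(0.5, 0.4, 0.5)^2 / 2)
  got <- gs$mean[match(c("dementia", "MCI", "NCI"), gs$group)]
  se <- gs$sd[match(c("dementia", "MCI", "NCI"), gs$group)] / sqrt(200)
  expect_true(all(abs(got - want) < 3 * se))
})

test_that("LSD pairwise comparisons match a brute-force ANOVA oracle", {
  y <- c(4.1, 5.2, 3.9, 4.8,   6.0, 6.4, 5.1, 6.8,   2.2, 3.1, 2.8, 2.4)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  rec <- tibble::tibble(group = g, score = y)
  out <- lsd_pairwise(rec, "score")
  # oracle computed from first principles
  ms <- tapply(y, g, mean)
  ss <- sum((y - ms[g])^2)
  mse <- ss / (12 - 3)
  se12 <- sqrt(mse * (1 / 4 + 1 / 4))
  d12 <- ms["g1"] - ms["g2"]
  row <- out[out$group_i == "g1" & out$group_j == "g2", ]
  expect_equal(row$difference, unname(d12))
  expect_equal(row$std_error, unname(se12))
  # p-value via numerical integration of the t density, df = 9
  tval <- abs(d12 / se12)
  dens <- function(x) dt(x, df = 9)
  p_num <- 2 * integrate(dens, tval, Inf)$value
  expect_equal(row$p_value, p_num, tolerance = 1e-6)
  # antisymmetry of differences, symmetry of SEs (exact)
  for (i in unique(g)) for (j in setdiff(unique(g), i)) {
    rij <- out[out$group_i == i & out$group_j == j, ]
    rji <- out[out$group_i == j & out$group_j == i, ]
    expect_identical(rij$difference, -rji$difference)
    expect_identical(rij$std_error, rji$std_error)
  }
})

test_that("LSD handles identical groups and degenerate sizes", {
  rec <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                        v = rep(c(1, 2, 3), 2))
  out <- lsd_pairwise(rec, "v")
  expect_equal(out$difference, c(0, 0))
  expect_equal(out$p_value, c(1, 1))
  expect_error(lsd_pairwise(tibble::tibble(group = c("a", "a", "b"), v = 1:3), "v"),
               class = "wmh_degenerate_error")
})

test_that("partial correlation reduces to Pearson and handles exact cases", {
  withr::with_seed(7, {
    x <- rnorm(60)
    y <- 2 * x + rnorm(60)
  })
  rec <- tibble::tibble(wmh_volume = x, s = y)
  got <- partial_correlation(rec, "s", covariates = character(0))
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  # y = -x is perfect anticorrelation
  rec2 <- tibble::tibble(wmh_volume = x, s = -x,
                         sex = rbinom(60, 1, 0.5), age = rnorm(60, 70),
                         education = rnorm(60, 10))
  got2 <- partial_correlation(rec2, "s")
  expect_equal(got2$r, -1, tolerance = 1e-8)
  expect_lt(got2$p_value, 1e-12)
  # collinear covariates are named
  rec3 <- tibble::tibble(wmh_volume = x, s = y, sex = 1, age = rnorm(60),
                         education = rnorm(60))
  expect_error(partial_correlation(rec3, "s"),
               class = "wmh_rank_error", regexp = "sex")
})

test_that("noiseless generator gives exactly linear scores after residualization", {
  spec <- cohort_spec(group_n = c(dementia = 10, MCI = 20, NCI = 20), seed = 3)
  spec$scores$sd <- 0
  spec$scores$lo <- -Inf
  spec$scores$hi <- Inf
  rec <- make_cohort(spec)
  pc <- partial_correlation(rec, "mmse")
  expect_equal(pc$r, -1, tolerance = 1e-9)
})

test_that("cohort analysis is permutation-sane and respects the generator", {
  rec <- make_small_cohort(seed = 11, n = c(dementia = 15, MCI = 15, NCI = 15))
  rep1 <- analyze_cohort(rec)
  expect_s3_class(rep1, "wmh_cohort_report")
  expect_equal(nrow(rep1$correlations), 10L)
  # pooled (group-free) statistics are invariant to shuffling group labels
  shuffled <- rec
  shuffled$group <- withr::with_seed(12, sample(rec$group))
  pool <- function(r) { r$group <- "all"; group_summary(r) }
  expect_equal(pool(rec), pool(shuffled))
  # report writer emits the three CSVs and text report
  dir <- withr::local_tempdir()
  write_cohort_report(rep1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("group_summary.csv", "lsd_pairwise.csv",
      "partial_correlations.csv", "report.txt")))))
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_equal(glance(rep1)$n_groups, 3L)
})
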