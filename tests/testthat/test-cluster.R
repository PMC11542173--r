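test_that("one-sample and two-sample t maps match hand formulas", {
  # one-sample on {1,2,3}: t = 2 sqrt(3), df 2
  tm <- electrode_t_map(paired_data(3, "Cz", c(1, 2, 3)), "paired")
  expect_equal(tm$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tm$df, 2)
  # two-sample {0,0,1,1} vs {1,1,2,2}: pooled t = -2.449, df 6
  dat <- independent_data(4, "Cz", c(0, 0, 1, 1, 1, 1, 2, 2))
  tm2 <- electrode_t_map(dat, "independent", groups = c("G1", "G2"))
  expect_equal(tm2$t, -2.449, tolerance = 1e-3)
  expect_equal(tm2$df, 6)
  # brute-force oracle via stats::t.test
  or <- t.test(c(0, 0, 1, 1), c(1, 1, 2, 2), var.equal = TRUE)
  expect_equal(tm2$t, unname(or$statistic), tolerance = 1e-12)
  # identical groups: zero everywhere (zero variance warns)
  dat0 <- independent_data(3, c("Cz", "Oz"), rep(1, 12))
  expect_warning(tm0 <- electrode_t_map(dat0, "independent"))
  expect_true(all(tm0$t == 0))
  # identical groups with variance: plain zero t, no warning
  dat1 <- independent_data(3, "Cz", rep(c(1, 2, 3), 2))
  dat1$value <- c(1, 2, 3, 1, 2, 3)
  expect_silent(tm1 <- electrode_t_map(dat1, "independent"))
  expect_equal(tm1$t, 0)
})

test_that("Cohen's d follows the pooled and difference-score conventions", {
  dat <- independent_data(4, "Cz", c(0, 0, 1, 1, 1, 1, 2, 2))
  d <- cohens_d(dat, "independent", groups = c("G1", "G2"))
  expect_equal(d$d, -sqrt(3), tolerance = 1e-9)
  dp <- cohens_d(paired_data(4, "Cz", c(1, 1, 1, -1)), "paired")
  expect_equal(dp$d, 0.5, tolerance = 1e-12)
  same <- independent_data(3, "Cz", rep(2, 6))
  expect_warning(d0 <- cohens_d(same, "independent"))
  expect_true(is.na(d0$d))
})

test_that("cluster formation splits by sign and connectivity", {
  adj <- build_adjacency(montage_line3())
  tm <- tibble::tibble(channel = c("A", "B", "C"), t = c(3, 3, -3))
  cl <- form_clusters(tm, adj, df = 10, cluster_alpha = 0.05)
  # threshold qt(.975, 10) = 2.23: {A,B} positive, {C} negative
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$channels[[which(cl$sign == 1)]], c("A", "B"))
  expect_equal(cl$mass[cl$sign == 1], 6)
  expect_equal(cl$mass[cl$sign == -1], -3)
  # nothing supra-threshold: no clusters
  tm0 <- tibble::tibble(channel = c("A", "B", "C"), t = c(1, -1, 0.5))
  expect_equal(nrow(form_clusters(tm0, adj, 10)), 0)
  # everything positive on a connected graph: one global cluster
  tm1 <- tibble::tibble(channel = c("A", "B", "C"), t = c(4, 4, 4))
  cl1 <- form_clusters(tm1, adj, 10)
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$n_channels, 3)
})

test_that("exhaustive paired enumeration has the expected size and p", {
  adj <- build_adjacency(montage_line3())
  dat <- paired_data(3, c("A", "B", "C"),
                     c(2, 2.5, 2.2, 2.1, 2.4, 2.3, 2.2, 2.0, 2.6))
  ex <- exhaustive_cluster_test(dat, adj, "paired")
  expect_equal(length(ex$null_max), 8)    # 2^3 sign patterns
  # strongly one-sided data: the all-positive labeling and its mirror
  # attain the maximum, p = 2 / 2^n
  expect_equal(tidy(ex)$p_value, 2 / 8)
  # independent 2 vs 2: choose(4, 2) = 6 relabelings
  dat2 <- independent_data(2, c("A", "B", "C"),
                           c(0, 0.1, -0.1, 0.2, 0.15, 0.05,
                             3, 3.1, 2.9, 3.2, 3.15, 3.05))
  ex2 <- exhaustive_cluster_test(dat2, adj, "independent")
  expect_equal(length(ex2$null_max), 6)
})

test_that("Monte Carlo p agrees with the exhaustive oracle", {
  adj <- build_adjacency(montage_line3())
  set.seed(40)
  ok <- 0
  for (r in 1:5) {
    dat <- paired_data(6, c("A", "B", "C"), rnorm(18, mean = 0.8))
    ex <- exhaustive_cluster_test(dat, adj, "paired")
    mc <- permutation_cluster_test(dat, adj, "paired",
                                   n_permutations = 2000, seed = r)
    pe <- tidy(ex)$p_value[1]
    pm <- tidy(mc)$p_value[1]
    if (is.na(pe)) { expect_true(is.na(pm)); ok <- ok + 1; next }
    se <- sqrt(pe * (1 - pe) / 2000)
    expect_lt(abs(pm - pe), max(2 * se, 2.5e-3) + 1 / 2001)
    ok <- ok + 1
  }
  expect_equal(ok, 5)
})

test_that("permutation tests are reproducible from the seed", {
  adj <- build_adjacency(montage_line3())
  set.seed(41)
  dat <- paired_data(8, c("A", "B", "C"), rnorm(24, 0.7))
  r1 <- permutation_cluster_test(dat, adj, "paired",
                                 n_permutations = 500, seed = 77)
  r2 <- permutation_cluster_test(dat, adj, "paired",
                                 n_permutations = 500, seed = 77)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$null_max, r2$null_max)
})

test_that("a strong localized effect is detected as a cluster", {
  adj <- build_adjacency(montage_16())
  chans <- adj$channels
  patch <- c("O1", "Oz", "O2", "Pz")
  set.seed(42)
  vals <- rnorm(26 * 2 * 16)
  dat <- tidyr::expand_grid(subject = sprintf("s%02d", 1:52),
                            channel = chans)
  dat$group <- rep(c("PD", "CTL"), each = 16 * 26)
  dat$value <- rnorm(nrow(dat)) +
    ifelse(dat$group == "PD" & dat$channel %in% patch, 1, 0)
  res <- permutation_cluster_test(dat, adj, "independent",
                                  groups = c("PD", "CTL"),
                                  n_permutations = 1000, seed = 1)
  td <- tidy(res)
  sig <- td[which(td$significant), ]
  expect_gte(nrow(sig), 1)
  expect_true(all(patch %in% unlist(sig$channels)))
})

test_that("no-cluster results report whole-scalp summaries", {
  adj <- build_adjacency(montage_line3())
  set.seed(43)
  dat <- paired_data(10, c("A", "B", "C"), rnorm(30, 0, 1) * 0.01)
  res <- permutation_cluster_test(dat, adj, "paired",
                                  n_permutations = 200, seed = 2)
  td <- tidy(res)
  if (all(is.na(td$cluster))) {
    expect_equal(td$channels[[1]], c("A", "B", "C"))
    expect_false(td$significant)
    expect_true(is.finite(td$t_max))
    expect_true(is.finite(td$d_mean))
  }
  gl <- glance(res)
  expect_equal(gl$kind, "paired")
  expect_s3_class(ggplot2::ggplot_build(autoplot(res))$plot, "ggplot")
})

test_that("adding a constant to every subject leaves independent t unchanged", {
  adj <- build_adjacency(montage_line3())
  set.seed(44)
  dat <- independent_data(6, c("A", "B", "C"), rnorm(36))
  t1 <- electrode_t_map(dat, "independent")
  dat$value <- dat$value + 100
  t2 <- electrode_t_map(dat, "independent")
  expect_equal(t1$t, t2$t, tolerance = 1e-9)
})

test_that("contrast builders extract the right designs", {
  spec <- cohort_spec(n_ctl = 3, n_pd = 3, channels = c("Cz", "Oz"),
                      seed = 19)
  coh <- generate_cohort(spec)
  params <- fit_cohort(coh$spectra)
  bp <- band_power_table(coh$spectra, params)
  meas <- measure_table(params, bp)
  con <- build_contrast(meas, "offset", "OFF_vs_CTL", condition = "EC")
  expect_equal(con$kind, "independent")
  expect_equal(sort(unique(con$data$group)), c("CTL", "PD"))
  expect_equal(nrow(con$data), 6 * 2)
  con2 <- build_contrast(meas, "exponent", "ON_vs_OFF", condition = "EC")
  expect_equal(con2$kind, "paired")
  expect_equal(nrow(con2$data), 3 * 2)
  con3 <- build_contrast(meas, "total_alpha", "EC_vs_EO", group = "CTL")
  expect_equal(con3$kind, "paired")
  expect_equal(nrow(con3$data), 3 * 2)
  expect_error(build_contrast(meas, "gamma_power", "OFF_vs_CTL"),
               "Unknown measure")
})
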