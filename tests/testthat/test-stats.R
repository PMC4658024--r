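test_that("signed-rank test matches its hand-derived examples", {
  expect_warning(res <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(res$p.value, 1)
  expect_equal(unname(res$statistic), 0)
  res2 <- wilcoxon_signed_rank(1:5, 2:6)
  expect_equal(res2$p.value, 2 / 32)
  expect_match(res2$method, "exact")
})

test_that("exact signed-rank branch equals full sign enumeration", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    x <- round(rnorm(n, sd = 2), 1)
    y <- round(rnorm(n, sd = 2), 1)
    if (all(x == y)) next
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p.value, enum_wilcoxon_p(x, y), tolerance = 1e-12,
                 info = paste(rep))
  }
})

test_that("signed-rank exact branch agrees with stats::wilcox.test sans ties", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(8)
    y <- rnorm(8)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("signed-rank approximation tracks the exact branch at n = 12", {
  # the exact two-sided p at n = 12 is a step function with steps up to
  # ~0.013, so 0.0138 (exhaustively computed over every possible W) is the
  # tightest uniform bound a continuous approximation can meet
  set.seed(99)
  diffs <- vapply(1:10, function(rep) {
    x <- rnorm(12)
    y <- rnorm(12)
    abs(wilcoxon_signed_rank(x, y, exact_max = 12)$p.value -
          wilcoxon_signed_rank(x, y, exact_max = 0)$p.value)
  }, numeric(1))
  expect_lt(max(diffs), 0.0138)
})

test_that("Mann-Whitney matches its hand-derived examples", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 2 / 6)
  expect_equal(mann_whitney_u(c(5, 6, 7), c(5, 6, 7))$p.value, 1)
  # extreme separation attains the minimal two-sided p for (n, m)
  res2 <- mann_whitney_u(c(100, 101, 102), c(1, 2, 3, 4))
  expect_equal(res2$p.value, 2 / choose(7, 3))
})

test_that("exact Mann-Whitney branch equals full labeling enumeration", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample(1:8, n, replace = TRUE)  # ties on purpose
    y <- sample(1:8, m, replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$p.value, enum_mwu_p(x, y), tolerance = 1e-12,
                 info = paste(rep))
  }
})

test_that("Mann-Whitney approximation is sane at larger n", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(25, 0.8)
  ours <- mann_whitney_u(x, y)
  expect_match(ours$method, "approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
})

test_that("null cohorts reject at the nominal 5% rate", {
  set.seed(2024)
  rejections <- 0
  for (i in 1:1000) {
    x <- rnorm(20)
    y <- rnorm(20)
    if (wilcoxon_signed_rank(x, y)$p.value < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 1000, 0.03)
  expect_lte(rejections / 1000, 0.07)
})

test_that("kappa matches hand-computed tables and the interpretation bands", {
  r1 <- c(0, 1, 2, 3, 4, 0, 1, 2)
  expect_equal(cohen_kappa(r1, r1)$kappa, 1)
  expect_equal(cohen_kappa(r1, r1)$band, "almost perfect")
  # 2x2 table with counts (4, 1, 1, 4): p_o = 0.8, p_e = 0.5, kappa = 0.6
  a <- c(rep(0, 5), rep(1, 5))
  b <- c(rep(0, 4), 1, 0, rep(1, 4))
  k <- cohen_kappa(a, b, levels = 0:1)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.5)
  expect_equal(kappa_band(0.73), "substantial")
  expect_equal(kappa_band(0.81), "almost perfect")
  expect_equal(kappa_band(0.15), "slight")
  expect_equal(kappa_band(-0.2), "poor")
  expect_warning(kd <- cohen_kappa(rep(2, 5), rep(2, 5)), "degenerate")
  expect_equal(kd$kappa, 1)
})

test_that("kappa stays within bounds on random tables", {
  set.seed(8)
  for (rep in 1:25) {
    r1 <- sample(0:4, 30, replace = TRUE)
    r2 <- sample(0:4, 30, replace = TRUE)
    k <- cohen_kappa(r1, r2)$kappa
    expect_gte(k, -1)
    expect_lte(k, 1)
    if (identical(r1, r2)) expect_equal(k, 1)
  }
})

test_that("simulated readers are calibrated and monotone", {
  scores <- tibble::tibble(
    case_id = sprintf("c%02d", 1:50),
    stratum = "hip",
    arm = "NOMAR",
    mean_score = sort(rgamma(50, 3, 1 / 5e4))
  )
  r0 <- simulate_readers(scores, list(probs = c(0.1, 0.35, 0.65, 0.9),
                                      flip_prob = 0), seed = 1)
  expect_equal(cohen_kappa(r0)$kappa, 1)
  expect_true(all(r0$reader1 >= 0 & r0$reader1 <= 4))
  expect_true(all(diff(r0$reader1) >= 0))  # monotone in the sorted scores
  r2 <- simulate_readers(scores, list(probs = c(0.1, 0.35, 0.65, 0.9),
                                      flip_prob = 0.2), seed = 2)
  k <- cohen_kappa(r2)$kappa
  expect_gt(k, 0)
  expect_lt(k, 1)
  # determinism under the seed
  r2b <- simulate_readers(scores, list(probs = c(0.1, 0.35, 0.65, 0.9),
                                       flip_prob = 0.2), seed = 2)
  expect_identical(r2, r2b)
})

test_that("arm comparison reproduces the report table shape", {
  set.seed(10)
  base <- rgamma(12, 4, 1 / 3e4)
  scores <- tidyr::expand_grid(case_id = sprintf("c%02d", 1:12),
                               arm = c("NOMAR", "IMAR", "DEMAR", "IMAR+DEMAR"))
  scores$stratum <- "hip"
  scores$mean_score <- rep(base, each = 4) *
    rep(c(1, 0.4, 0.8, 0.25), times = 12) *
    exp(rnorm(48, sd = 0.05))
  cmp <- compare_arms(scores, "hip")
  expect_equal(nrow(cmp$summary), 4)
  expect_named(cmp$summary,
               c("arm", "n", "mean", "sd", "median", "pct_vs_nomar",
                 "p_vs_nomar"))
  expect_equal(cmp$summary$pct_vs_nomar[cmp$summary$arm == "NOMAR"], 0)
  expect_equal(nrow(cmp$contrasts), 5)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  gl <- glance(cmp)
  expect_true(gl$ordering_holds)
  plt <- ggplot2::autoplot(cmp)
  expect_s3_class(plt, "ggplot")
  # degenerate cohort: identical arms everywhere
  same <- scores
  same$mean_score <- rep(base, each = 4)
  cmp0 <- suppressWarnings(compare_arms(same, "hip"))
  expect_true(all(cmp0$summary$pct_vs_nomar == 0))
  expect_true(all(cmp0$contrasts$p == 1))
  # missing arm errors name the problem
  expect_error(compare_arms(scores[scores$arm != "IMAR", ], "hip"),
               "IMAR")
})

test_that("ratings tables round-trip and validate", {
  r <- tibble::tibble(case_id = c("a", "b"), stratum = "hip",
                      arm = "NOMAR", reader1 = c(3L, 4L), reader2 = c(3L, 3L))
  f <- tempfile(fileext = ".csv")
  write_ratings(r, f)
  back <- read_ratings(f)
  expect_equal(back$reader1, r$reader1)
  bad <- r
  bad$reader1 <- c(5L, 2L)
  write_ratings(bad, f)
  expect_error(read_ratings(f), "0..4")
  unlink(f)
})
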