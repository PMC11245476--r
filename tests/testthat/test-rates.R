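test_that("cell numbers follow the 16S / operon-factor convention", {
  expect_equal(cells_from_16s(4.1e6), 1e6)
  expect_equal(cells_from_16s(0), 0)
  set.seed(12)
  copies <- runif(20, 1e3, 1e9)
  expect_equal(cells_from_16s(copies, 4.1), copies / 4.1)
  expect_error(cells_from_16s(10, 0), class = "nitrisphere_validation_error")
})

test_that("background subtraction zeroes t = 0 and is idempotent", {
  s <- make_series(0.25, baseline = 0.2) # pools 0.2, 1.2, 2.2
  out <- background_subtract(s)
  expect_equal(out$pool_umol_per_L, c(0, 1.0, 2.0))
  expect_equal(background_subtract(out)$pool_umol_per_L, out$pool_umol_per_L)

  # constant pools -> all zeros
  cst <- make_series(0, baseline = 5)
  expect_equal(background_subtract(cst)$pool_umol_per_L, c(0, 0, 0))

  # random series, hand subtraction
  set.seed(13)
  pools <- cumsum(runif(3))
  rnd <- make_series(0)
  rnd$pool_umol_per_L <- pools
  expect_equal(background_subtract(rnd)$pool_umol_per_L, pools - pools[1])

  # missing t = 0 falls back to the earliest point, with a message
  late <- make_series(0.5, baseline = 1, times = c(2, 4, 8))
  expect_message(out2 <- background_subtract(late), "earliest time")
  expect_equal(out2$pool_umol_per_L, c(0, 1, 3))

  # decreasing pools floored at zero with a warning
  dec <- make_series(0)
  dec$pool_umol_per_L <- c(2, 1, 3)
  expect_warning(out3 <- background_subtract(dec), "floored")
  expect_equal(out3$pool_umol_per_L, c(0, 0, 1))
})

test_that("tracer slopes equal closed-form OLS and degrade to finite differences", {
  # exact line
  expect_equal(
    tracer_slope(make_series(0.5))$slope_umol_per_L_h, 0.5,
    tolerance = 1e-12
  )
  # zero-variance response: slope 0, r2 defined as 1
  suppressMessages({
    cst <- tracer_slope(make_series(0, baseline = 0))
  })
  expect_equal(cst$slope_umol_per_L_h, 0)
  expect_equal(cst$fit_r2, 1)

  # noisy line vs independent closed-form OLS
  set.seed(14)
  t <- c(0, 4, 8)
  y <- 0.3 * t + rnorm(3, 0, 0.1)
  s <- make_series(0)
  s$pool_umol_per_L <- abs(y)
  fit <- tracer_slope(s)
  beta <- sum((t - mean(t)) * (abs(y) - mean(abs(y)))) / sum((t - mean(t))^2)
  expect_equal(fit$slope_umol_per_L_h, beta, tolerance = 1e-10)

  # two points: the finite difference
  two <- make_series(0, times = c(0, 8))
  two$pool_umol_per_L <- c(0.4, 2.0)
  expect_equal(
    tracer_slope(two)$slope_umol_per_L_h, (2.0 - 0.4) / 8,
    tolerance = 1e-12
  )

  one <- make_series(1, times = 4)
  expect_error(tracer_slope(one), class = "nitrisphere_validation_error")
})

test_that("slope estimator is unbiased on synthetic noisy lines", {
  set.seed(15)
  s_true <- 0.4
  sigma <- 0.05
  t <- c(0, 4, 8)
  ests <- replicate(200, {
    y <- pmax(s_true * t + rnorm(3, 0, sigma), 0)
    sr <- make_series(0)
    sr$pool_umol_per_L <- y
    tracer_slope(sr)$slope_umol_per_L_h
  })
  # |bias| below 3 sigma / sqrt(n Var(t)), the sampling sd of one estimate
  se <- sigma / sqrt(sum((t - mean(t))^2))
  expect_lt(abs(mean(ests) - s_true), 3 * se)
})

test_that("per-cell rates carry the unit conversion and scaling symmetries", {
  expect_equal(per_cell_rate(0.5, 0.05, 1e7), 2.5)
  expect_equal(per_cell_rate(0, 0.05, 1e7), 0)
  # linear in slope, inversely proportional to cells
  expect_equal(per_cell_rate(1.0, 0.05, 1e7), 2 * per_cell_rate(0.5, 0.05, 1e7))
  expect_equal(per_cell_rate(0.5, 0.05, 2e7), per_cell_rate(0.5, 0.05, 1e7) / 2)
  expect_error(per_cell_rate(0.5, 0.05, 0), class = "nitrisphere_undefined_rate")
  expect_error(per_cell_rate(0.5, 0, 1e7), class = "nitrisphere_validation_error")
})

test_that("fold changes use half-away-from-zero rounding at 1 decimal", {
  expect_equal(fold_change(3.5, 2.2), 1.6)
  expect_equal(fold_change(7, 7), 1.0)
  expect_equal(fold_change(4.7, 2.2, digits = NULL), 4.7 / 2.2, tolerance = 1e-12)
  # reciprocal identity for unrounded output
  set.seed(16)
  a <- runif(20, 0.5, 10)
  b <- runif(20, 0.5, 10)
  expect_equal(
    fold_change(a, b, digits = NULL) * fold_change(b, a, digits = NULL),
    rep(1, 20),
    tolerance = 1e-12
  )
  # half rounds away from zero (2.25 -> 2.3, not banker's 2.2)
  expect_equal(fold_change(2.25, 1), 2.3)
  expect_error(fold_change(1, 0), class = "nitrisphere_validation_error")
})

test_that("group comparison matches textbook one-way ANOVA", {
  # identical group patterns -> F = 0
  same <- tibble::tibble(
    group = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2)
  )
  cmp <- compare_groups(same, "y")
  expect_equal(glance(cmp)$f_statistic, 0)
  expect_true(all(grepl("a", tidy(cmp)$letters)))

  # two groups: F equals the square of the pooled t statistic
  set.seed(17)
  two <- tibble::tibble(
    group = rep(c("a", "b"), each = 6), y = c(rnorm(6, 0), rnorm(6, 1))
  )
  cmp2 <- compare_groups(two, "y")
  tt <- t.test(y ~ group, data = two, var.equal = TRUE)
  expect_equal(glance(cmp2)$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(glance(cmp2)$p_value, tt$p.value, tolerance = 1e-10)

  # 3-group data vs hand-computed sums of squares
  d <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 4),
    y = c(5.1, 4.9, 5.3, 5.0, 6.8, 7.1, 6.9, 7.2, 5.2, 5.0, 5.1, 5.3)
  )
  cmp3 <- compare_groups(d, "y")
  gm <- mean(d$y)
  ssb <- sum(tapply(d$y, d$group, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(d$y, d$group, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(glance(cmp3)$f_statistic, f_hand, tolerance = 1e-10)
  # b is clearly separated; a and c share a letter
  lt <- tidy(cmp3)
  expect_false(
    any(strsplit(lt$letters[lt$group == "b"], "")[[1]] %in%
      strsplit(lt$letters[lt$group == "a"], "")[[1]])
  )
  expect_true(
    any(strsplit(lt$letters[lt$group == "a"], "")[[1]] %in%
      strsplit(lt$letters[lt$group == "c"], "")[[1]])
  )
  # letters share a symbol iff Tukey-adjusted p >= alpha
  tk <- cmp3$tukey
  for (i in seq_len(nrow(tk))) {
    pair <- strsplit(tk$contrast[i], "-")[[1]]
    shared <- length(intersect(
      strsplit(lt$letters[lt$group == pair[1]], "")[[1]],
      strsplit(lt$letters[lt$group == pair[2]], "")[[1]]
    )) > 0
    expect_equal(shared, tk$`p adj`[i] >= 0.05)
  }

  expect_error(
    compare_groups(tibble::tibble(group = c("a", "b"), y = 1:2), "y"),
    class = "nitrisphere_validation_error"
  )
})

test_that("estimate_rates runs the full pipeline and downgrades without qPCR", {
  tracer <- make_series(0.5, baseline = 0.2)
  qpcr <- tibble::tibble(sample_id = "s1", gene = "16S", copies = 4.1e7)
  out <- estimate_rates(tracer, qpcr, volume = 0.05)
  # slope 0.5, 1e7 cells, 50 mL -> 2.5 fmol/cell/h
  expect_equal(out$rate_fmol_per_cell_h, 2.5, tolerance = 1e-12)
  expect_equal(out$cells, 1e7)

  expect_message(
    novol <- estimate_rates(tracer, NULL),
    "volumetric"
  )
  expect_true(is.na(novol$rate_fmol_per_cell_h))
  expect_equal(novol$slope_umol_per_L_h, 0.5, tolerance = 1e-12)
})
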