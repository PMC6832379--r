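# Coefficient of variation, group summaries, Welch comparisons.

test_that("coefficient of variation matches hand arithmetic and is scale invariant", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(100, 110, 120)), 10 / 110)
  set.seed(71)
  x <- runif(10, 50, 150)
  for (k in c(0.01, 3, 1000))
    expect_equal(coefficient_of_variation(k * x),
                 coefficient_of_variation(x), tolerance = 1e-12)
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-3, 1)), "mean must be positive")
})

test_that("reference-table aggregation reproduces the published subgroup rows", {
  tab <- load_reference_radii()
  # female whole-outline row: printed mean 1421, SD 255
  agg <- aggregate_groups(tab, by = c("sex", "structure"))
  f_out_whole <- agg[agg$sex == "F" & agg$structure == "outline" &
                       agg$part == "whole", ]
  expect_equal(f_out_whole$n, 5L)
  expect_equal(f_out_whole$mean, 1421, tolerance = 1 / 1421)
  expect_equal(f_out_whole$sd, 255, tolerance = 1 / 255)
  # pooled whole radius: printed 1318
  pooled <- aggregate_groups(tab)
  expect_equal(pooled$mean[pooled$part == "whole"], 1318.05, tolerance = 1e-6)
  expect_equal(pooled$n[pooled$part == "whole"], 20L)
})

test_that("the printed and canonical labelings differ exactly by the proximal/distal swap", {
  canon <- load_reference_radii("canonical")
  printed <- load_reference_radii("printed")
  expect_equal(canon$proximal_mm, printed$distal_mm)
  expect_equal(canon$distal_mm, printed$proximal_mm)
  expect_equal(canon$whole_mm, printed$whole_mm)
})

test_that("single-value groups report missing SD and empty tables error", {
  tab <- data.frame(subject = c("a", "b"), structure = "outline",
                    whole_mm = c(100, 120), proximal_mm = c(90, 95),
                    middle_mm = c(110, 115), distal_mm = c(80, 85))
  agg <- aggregate_groups(tab, by = "subject")
  expect_true(all(is.na(agg$sd)))
  expect_true(all(agg$n == 1L))
  expect_error(aggregate_groups(tab[0, ]), "non-empty")
  expect_error(aggregate_groups(tab, by = "nope"), "unknown grouping")
})

test_that("group comparison handles degenerate and separating cases", {
  x <- c(10, 12, 9, 11)
  same <- compare_groups(x, x)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_equal(compare_groups(c(1, 1), c(1, 1))$p_value, 1)
  ps <- vapply(c(0.1, 0.01, 0.001), function(eps) {
    set.seed(72)
    compare_groups(rnorm(4, 0, eps), rnorm(4, 1, eps))$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[3L], 1e-6)
})

test_that("Welch p agrees with a permutation oracle on same-distribution groups", {
  set.seed(73)
  for (k in 1:3) {
    a <- rnorm(15, 10, 2); b <- rnorm(15, 10, 2)
    got <- compare_groups(a, b)
    pool <- c(a, b)
    n <- length(pool)
    draws <- 1e5L
    welch_t <- function(x, y) {
      (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
    }
    tperm <- vapply(seq_len(draws), function(i) {
      idx <- sample.int(n, 15L)
      welch_t(pool[idx], pool[-idx])
    }, numeric(1))
    p_perm <- mean(abs(tperm) >= abs(got$t))
    expect_equal(got$p_value, p_perm, tolerance = 0.035)
  }
})

test_that("reliability report counts and bounds behave", {
  tab <- data.frame(subject = "s1", structure = "outline",
                    whole_mm = c(100, 100, 100), proximal_mm = c(50, 50, 50),
                    middle_mm = c(120, 120, 120), distal_mm = c(45, 45, 45))
  rep <- reliability_report(tab)
  expect_equal(nrow(rep$cv), 4L)
  expect_true(all(rep$cv$cv == 0))
  expect_equal(unname(rep$summary), c(0, 0, 0))
  one <- tab[1L, ]
  expect_error(reliability_report(one), "at least 2 repeats")
})

test_that("multiplicative lognormal jitter yields the predicted mean CV", {
  set.seed(74)
  cvs <- replicate(200L, {
    base <- runif(4, 400, 1500)
    tab <- do.call(rbind, lapply(1:3, function(r)
      data.frame(subject = "s", structure = "outline",
                 whole_mm = base[1L] * exp(rnorm(1, 0, 0.05)),
                 proximal_mm = base[2L] * exp(rnorm(1, 0, 0.05)),
                 middle_mm = base[3L] * exp(rnorm(1, 0, 0.05)),
                 distal_mm = base[4L] * exp(rnorm(1, 0, 0.05)))))
    reliability_report(tab)$summary[["mean"]]
  })
  expect_equal(mean(cvs), 0.05, tolerance = 0.2)
})

test_that("per-subject averaging is consistent with pooling for equal repeat counts", {
  set.seed(75)
  tab <- do.call(rbind, lapply(1:6, function(s)
    data.frame(subject = paste0("s", s), structure = "outline",
               whole_mm = rnorm(3, 1200, 100), proximal_mm = rnorm(3, 700, 80),
               middle_mm = rnorm(3, 1300, 90), distal_mm = rnorm(3, 600, 70))))
  raw <- aggregate_groups(tab)
  per_subject <- aggregate_groups(tab, by = "subject")
  for (p in c("whole", "proximal", "middle", "distal"))
    expect_equal(mean(per_subject$mean[per_subject$part == p]),
                 raw$mean[raw$part == p], tolerance = 1e-12)
})
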