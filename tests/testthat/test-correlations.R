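test_that("correlations hit their trivial anchors", {
  res <- simulate_trial(small_config(l = 10, e = 2), seed = 61)
  book <- res$book
  # a trait against itself
  book$plots$y2 <- book$plots$grain_yield
  book$traits <- rbind(book$traits,
                       data.frame(trait = "y2", units = "kg/ha",
                                  kind = "measured", derived_by = NA,
                                  lower = -Inf, upper = Inf))
  expect_equal(phenotypic_correlation(book, "grain_yield", "y2"), 1)
  expect_equal(genotypic_correlation(book, "grain_yield", "y2"), 1,
               tolerance = 1e-8, ignore_attr = TRUE)
  # against its own negation (phenotypic; genotypic variance is fine but
  # the covariance is exactly negative)
  book$plots$y3 <- -book$plots$grain_yield + 2 * mean(book$plots$grain_yield)
  book$traits <- rbind(book$traits,
                       data.frame(trait = "y3", units = "kg/ha",
                                  kind = "measured", derived_by = NA,
                                  lower = -Inf, upper = Inf))
  expect_equal(phenotypic_correlation(book, "grain_yield", "y3"), -1)
  expect_equal(genotypic_correlation(book, "grain_yield", "y3"), -1,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("zero-variance traits are refused", {
  res <- simulate_trial(small_config(l = 5, e = 2), seed = 62)
  book <- res$book
  book$plots$flat <- 1
  book$traits <- rbind(book$traits,
                       data.frame(trait = "flat", units = "", kind = "measured",
                                  derived_by = NA, lower = -Inf, upper = Inf))
  expect_error(phenotypic_correlation(book, "grain_yield", "flat"),
               "zero variance")
  expect_error(genotypic_correlation(book, "grain_yield", "flat"),
               "non-positive genetic variance")
})

test_that("sum-trait genetic covariance equals the cross-product identity", {
  res <- simulate_trial(small_config(l = 12, e = 3), seed = 63)
  p <- res$book$plots[res$book$plots$role == "testcross" &
                        !is.na(res$book$plots$pva), ]
  # direct mean-cross-product oracle
  cross_ms <- function(x, y, p) {
    hf <- factor(p$entry); ef <- factor(p$env)
    e_n <- nlevels(ef); n_h <- nlevels(hf)
    r_n <- nrow(p) / (e_n * n_h)
    mx_h <- tapply(x, hf, mean); my_h <- tapply(y, hf, mean)
    mx_he <- tapply(x, list(hf, ef), mean); my_he <- tapply(y, list(hf, ef), mean)
    mx_e <- tapply(x, ef, mean); my_e <- tapply(y, ef, mean)
    mcp_h <- e_n * r_n * sum((mx_h - mean(x)) * (my_h - mean(y))) / (n_h - 1)
    rx <- mx_he - outer(mx_h, rep(1, e_n)) - outer(rep(1, n_h), mx_e) + mean(x)
    ry <- my_he - outer(my_h, rep(1, e_n)) - outer(rep(1, n_h), my_e) + mean(y)
    mcp_ge <- r_n * sum(rx * ry) / ((n_h - 1) * (e_n - 1))
    (mcp_h - mcp_ge) / (r_n * e_n)
  }
  x <- p$grain_yield; y <- p$pva
  cov_direct <- cross_ms(x, y, p)
  vg <- function(v) lxtrial:::.genetic_variance(p, v)$variance
  cov_sum <- (vg(x + y) - vg(x) - vg(y)) / 2
  expect_equal(cov_sum, cov_direct, tolerance = 1e-8)
  # and the exported estimate uses exactly that covariance
  r_g <- genotypic_correlation(res$book, "grain_yield", "pva")
  expect_equal(r_g, cov_direct / sqrt(vg(x) * vg(y)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("independent genetic effects give a near-zero mean genotypic r", {
  cfg <- small_config(l = 40, e = 4, carotenoids = FALSE)
  est <- truth <- numeric(80)
  for (i in seq_along(est)) {
    res <- simulate_trial(cfg, seed = 7000 + i)
    # reps where a genetic variance estimate is non-positive are undefined
    est[i] <- tryCatch(genotypic_correlation(res$book, "grain_yield", "pht"),
                       error = function(e) NA_real_)
    truth[i] <- res$truth$genetic_correlations["grain_yield", "pht"]
  }
  expect_gt(mean(!is.na(est)), 0.9)
  expect_lt(abs(mean(est, na.rm = TRUE)), 0.08)
  expect_lt(abs(mean(truth)), 0.08)
})

test_that("a shared genetic factor is recovered by the genotypic r", {
  # the dilution coupling makes yield and total carotenoid share a factor
  cfg <- small_config(l = 40, e = 2)
  err <- numeric(60)
  for (i in seq_along(err)) {
    res <- simulate_trial(cfg, seed = 7500 + i)
    est <- genotypic_correlation(res$book, "grain_yield", "total_carotenoid")
    err[i] <- est - res$truth$genetic_correlations["grain_yield",
                                                   "total_carotenoid"]
  }
  expect_lt(abs(mean(err)), 0.1)
})

test_that("per-tester genetic variance is symmetric and recovers the truth", {
  # symmetry: identical testcross sets for both testers
  plots <- make_toy_plots(l = 6, t = 2, e = 2, r = 2,
                          f = function(i, j, e, r) 10 + i + 0.3 * e * i)
  book <- fieldbook(plots)
  v1 <- per_tester_genetic_variance(book, "T1", "y")
  v2 <- per_tester_genetic_variance(book, "T2", "y")
  expect_equal(v1$variance, v2$variance)
  expect_equal(v1$se, v2$se)

  # recovery: mean estimate within 3 MC standard errors of the truth. With
  # two testers the double-centered SCA contributes half its component to the
  # variance among one tester's testcrosses.
  cfg <- small_config(l = 20, e = 4, carotenoids = FALSE)
  v_true <- cfg$traits$grain_yield$v_gca_line +
    cfg$traits$grain_yield$v_sca / 2
  est <- numeric(80)
  for (i in seq_along(est)) {
    res <- simulate_trial(cfg, seed = 8000 + i)
    est[i] <- per_tester_genetic_variance(res$book, "T1", "grain_yield")$raw
  }
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - v_true), 3 * mc_se)
  expect_error(per_tester_genetic_variance(book, "T9", "y"), "no testcrosses")
})

test_that("per-tester variance SE shrinks as the line count grows", {
  mean_se <- sapply(c(15, 30, 60), function(l) {
    cfg <- small_config(l = l, e = 2, carotenoids = FALSE)
    se <- numeric(15)
    for (i in seq_along(se)) {
      res <- simulate_trial(cfg, seed = 9000 + 100 * l + i)
      se[i] <- per_tester_genetic_variance(res$book, "T1", "grain_yield")$se
    }
    mean(se)
  })
  expect_true(all(diff(mean_se) < 0))
})

test_that("tester summary is consistent with testcross means and GCA", {
  res <- simulate_trial(small_config(l = 8, e = 2), seed = 64)
  ts <- tester_summary(res$book, traits = c("grain_yield", "pva"))
  tm <- testcross_means(res$book, "grain_yield")
  ca <- gca_sca_effects(tm)
  row <- ts$stats[ts$stats$tester == "T1" & ts$stats$trait == "grain_yield", ]
  expect_equal(row$mean, mean(tm$means[, "T1"]))
  expect_equal(row$min, min(tm$means[, "T1"]))
  expect_equal(row$max, max(tm$means[, "T1"]))
  expect_equal(row$gca, unname(ca$gca_tester["T1"]))
  expect_true(row$min <= row$mean && row$mean <= row$max)
  expect_length(ts$notes, 2L)
})

test_that("a tester with uniformly shifted PVA is flagged as high-PVA", {
  plots <- make_toy_plots(l = 5, t = 2, e = 2, r = 2,
                          f = function(i, j, e, r) {
                            10 + 0.2 * i + if (j == 1) 2 else 0
                          })
  names(plots)[names(plots) == "y"] <- "pva"
  ts <- tester_summary(fieldbook(plots), traits = "pva",
                       target_traits = "pva")
  t1 <- ts$stats[ts$stats$tester == "T1", ]
  expect_gt(t1$gca, 0)
  expect_match(ts$notes[1L], "T1: positive GCA for pva")
})

test_that("single-testcross testers collapse min, mean and max", {
  plots <- make_toy_plots(l = 1, t = 1, e = 1, r = 2,
                          f = function(i, j, e, r) 4 + r)
  ts <- tester_summary(fieldbook(plots), traits = "y")
  expect_equal(ts$stats$min, ts$stats$mean)
  expect_equal(ts$stats$mean, ts$stats$max)
})

test_that("the correlation matrix carries both conventions", {
  res <- simulate_trial(small_config(l = 10, e = 2), seed = 65)
  cm <- trait_correlations(res$book, c("grain_yield", "pva", "pht"))
  expect_equal(diag(cm), c(grain_yield = 1, pva = 1, pht = 1))
  expect_equal(cm["pva", "grain_yield"],
               genotypic_correlation(res$book, "pva", "grain_yield"),
               ignore_attr = TRUE)
  expect_equal(cm["grain_yield", "pva"],
               phenotypic_correlation(res$book, "grain_yield", "pva"))
})
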