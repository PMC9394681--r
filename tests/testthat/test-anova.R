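test_that("single-environment toy ANOVA matches the least-squares oracle", {
  set.seed(31)
  for (i in 1:5) {
    book <- toy_book(l = 2, t = 2, e = 1, r = 2,
                     f = function(i, j, e, r) rnorm(1, 10 + i + 2 * j, 1))
    an <- combined_anova(book, "y")
    oracle <- seq_ss_oracle(book, "y")
    for (src in names(oracle)) {
      expect_equal(ss_of(an, src), unname(oracle[src]), tolerance = 1e-8,
                   label = paste("SS", src))
    }
  }
})

test_that("multi-environment balanced SS match the sequential lm oracle", {
  set.seed(32)
  for (i in 1:5) {
    l <- sample(2:4, 1)
    book <- toy_book(l = l, t = 2, e = 2, r = 2,
                     f = function(i, j, e, r) rnorm(1, 5 * e + i - j, 1))
    an <- combined_anova(book, "y")
    oracle <- seq_ss_oracle(book, "y")
    for (src in names(oracle)) {
      rel <- abs(ss_of(an, src) - oracle[[src]]) / max(oracle[[src]], 1e-12)
      expect_lt(rel, 1e-8, label = paste("relative SS error,", src))
    }
  }
})

test_that("sums of squares are additive and MS = SS/df on balanced books", {
  res <- simulate_trial(small_config(l = 8, e = 3), seed = 13)
  for (tr in c("grain_yield", "pva")) {
    an <- combined_anova(res$book, tr)
    expect_equal(ss_of(an, "Testcross"),
                 ss_of(an, "Line") + ss_of(an, "Tester") +
                   ss_of(an, "Line x Tester"), tolerance = 1e-8)
    # strata add to the total
    p <- res$book$plots[!is.na(res$book$plots[[tr]]), ]
    ss_total <- sum((p[[tr]] - mean(p[[tr]]))^2)
    strata <- c("Env", "Rep(Env)", "Block(Env x Rep)", "Hybrid",
                "Hybrid x Env", "Error")
    expect_equal(sum(an$ss[an$source %in% strata]), ss_total,
                 tolerance = 1e-8)
    has_df <- an$df > 0
    expect_equal(an$ms[has_df], an$ss[has_df] / an$df[has_df])
    # genetic df decomposition
    expect_equal(df_of(an, "Testcross"),
                 df_of(an, "Line") + df_of(an, "Tester") +
                   df_of(an, "Line x Tester"))
  }
})

test_that("environments without trait data are excluded; partial gaps abort", {
  res <- simulate_trial(small_config(l = 5, e = 4), seed = 17)
  an <- combined_anova(res$book, "pva")    # measured in 2 of 4 environments
  expect_equal(attr(an, "dims")[["e"]], 2L)
  book2 <- res$book
  idx <- which(!is.na(book2$plots$pva))[1L]
  book2$plots$pva[idx] <- NA
  expect_error(combined_anova(book2, "pva"), "missing 'pva' values")
})

test_that("unbalanced entry x environment cells are named in the error", {
  p <- make_toy_plots(l = 2, t = 2, e = 2, r = 2,
                      f = function(i, j, e, r) 10)
  p <- p[!(p$entry == "L1xT1" & p$env == "E2" & p$rep == 2L), ]
  expect_error(combined_anova(fieldbook(p), "y"),
               "unbalanced.*L1xT1.*E2")
})

test_that("zero error degrees of freedom are refused", {
  book <- toy_book(l = 2, t = 2, e = 1, r = 1,
                   f = function(i, j, e, r) i + j)
  expect_error(combined_anova(book, "y"), "zero error degrees of freedom")
})

test_that("Baker ratio reproduces its closed form and monotonicities", {
  expect_equal(round_report(baker_ratio(10025419, 21472764, 9365602)), 0.87)
  expect_equal(round_report(baker_ratio(1.14, 1.46, 0.69)), 0.88)
  expect_equal(round_report(baker_ratio(75.13, 367.23, 15.11)), 0.98)
  # pure-GCA limit
  expect_equal(baker_ratio(1, 1, 1e-12), 1, tolerance = 1e-10)
  expect_error(baker_ratio(0, 1, 1), "positive")
  expect_error(baker_ratio(1, 1, -1), "positive")
  # strictly increasing in the GCA mean squares, decreasing in SCA
  expect_gt(baker_ratio(2, 1, 1), baker_ratio(1, 1, 1))
  expect_gt(baker_ratio(1, 2, 1), baker_ratio(1, 1, 1))
  expect_lt(baker_ratio(1, 1, 2), baker_ratio(1, 1, 1))
})

test_that("CV% follows its definition", {
  book <- toy_book(l = 3, t = 2, e = 2, r = 2,
                   f = function(i, j, e, r) 20 + (r - 1.5))
  an <- combined_anova(book, "y")
  expect_equal(cv_percent(an),
               100 * sqrt(ms_of(an, "Error")) / attr(an, "grand_mean"))
  # hand case via a synthetic table: MS_error 4, grand mean 20 -> 10%
  fa <- fake_anova(ms = c(Error = 4), df = c(Error = 10),
                   dims = c(l = 2, t = 2, e = 2, r = 2))
  attr(fa, "grand_mean") <- 20
  expect_equal(cv_percent(fa), 10)
})

test_that("repeatability spans its closed-form limits", {
  expect_equal(repeatability(c(v_gca_line = 1), e = 4, r = 2), 1)
  expect_equal(repeatability(c(v_gca_line = 0, v_residual = 3), e = 4, r = 2), 0)
  expect_error(repeatability(c(v_gca_line = 0), e = 2, r = 2), "undefined")
  h <- repeatability(c(v_gca_line = 2, v_sca = 1, v_line_env = 3,
                       v_residual = 6), e = 3, r = 2)
  expect_equal(h, 3 / (3 + 3 / 3 + 6 / 6))
})

test_that("method-of-moments components invert the expected mean squares", {
  # deterministic check of the estimator algebra on a fabricated table
  dims <- c(l = 10, t = 2, e = 4, r = 2)
  v <- c(sca_env = 3, line_env = 5, tester_env = 7, sca = 11, line = 13,
         tester = 17, res = 2)
  ms <- c(
    "Line" = v[["res"]] + 2 * v[["sca_env"]] + 4 * v[["line_env"]] +
      16 * v[["line"]],
    "Tester" = v[["res"]] + 2 * v[["sca_env"]] + 20 * v[["tester_env"]] +
      80 * v[["tester"]],
    "Line x Tester" = v[["res"]] + 2 * v[["sca_env"]] + 8 * v[["sca"]],
    "Line x Env" = v[["res"]] + 2 * v[["sca_env"]] + 4 * v[["line_env"]],
    "Tester x Env" = v[["res"]] + 2 * v[["sca_env"]] + 20 * v[["tester_env"]],
    "Line x Tester x Env" = v[["res"]] + 2 * v[["sca_env"]],
    "Error" = v[["res"]]
  )
  fa <- fake_anova(ms, df = setNames(rep(10L, length(ms)), names(ms)), dims)
  vc <- variance_components(fa)
  est <- setNames(vc$estimate, vc$component)
  expect_equal(est[["v_gca_line"]], v[["line"]])
  expect_equal(est[["v_gca_tester"]], v[["tester"]])
  expect_equal(est[["v_sca"]], v[["sca"]])
  expect_equal(est[["v_line_env"]], v[["line_env"]])
  expect_equal(est[["v_tester_env"]], v[["tester_env"]])
  expect_equal(est[["v_sca_env"]], v[["sca_env"]])
  expect_equal(est[["v_residual"]], v[["res"]])
  expect_false(any(vc$truncated))
})

test_that("negative component estimates are truncated and flagged", {
  dims <- c(l = 10, t = 2, e = 4, r = 2)
  ms <- c("Line" = 1, "Tester" = 1, "Line x Tester" = 1, "Line x Env" = 5,
          "Tester x Env" = 5, "Line x Tester x Env" = 4, "Error" = 2)
  vc <- variance_components(
    fake_anova(ms, setNames(rep(10L, 7), names(ms)), dims))
  gl <- vc[vc$component == "v_gca_line", ]
  expect_true(gl$truncated)
  expect_equal(gl$estimate, 0)
  expect_lt(gl$raw, 0)
})

test_that("proportional contributions report both conventions", {
  res <- simulate_trial(small_config(l = 6, e = 2), seed = 23)
  an <- combined_anova(res$book, "grain_yield")
  pc <- proportional_contributions(an)
  expect_equal(sum(pc$ss_pct), 100, tolerance = 1e-9)
  expect_equal(sum(pc$varcomp_pct), 100, tolerance = 1e-9)

  # line-only variation: nearly all of the testcross SS is the line source
  cfg <- small_config(l = 8, e = 2, carotenoids = FALSE)
  for (tr in names(cfg$traits)) {
    cfg$traits[[tr]] <- zero_components(cfg$traits[[tr]])
    cfg$traits[[tr]]$v_residual <- cfg$traits[[tr]]$v_residual * 1e-6
  }
  cfg$traits$grain_yield$v_gca_line <- 1e6
  res2 <- simulate_trial(cfg, seed = 24)
  pc2 <- proportional_contributions(combined_anova(res2$book, "grain_yield"))
  expect_gt(pc2$ss_pct[pc2$source == "Line"], 99)

  # the documented SS-share arithmetic on the reported carotenoid table
  ref <- lxt_reference("carotenoid_anova_ms")
  sel <- match(c("Line", "Tester", "Line x Tester"), ref$source)
  ss <- ref$pva[sel] * ref$df[sel]
  expect_equal(round(100 * ss / sum(ss), 1), c(59.1, 33.1, 7.7))
})
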