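test_that("lattice layout is resolvable: every entry once per replicate", {
  lay <- alpha_lattice_layout(124, 4, 2, seed = 11)
  expect_length(lay, 2L)
  for (rep_blocks in lay) {
    expect_length(rep_blocks, 31L)
    expect_true(all(lengths(rep_blocks) == 4L))
    expect_setequal(unlist(rep_blocks), 1:124)
  }
  # replicates are re-randomized
  expect_false(identical(lay[[1L]], lay[[2L]]))

  single <- alpha_lattice_layout(4, 4, 1, seed = 1)
  expect_length(single[[1L]], 1L)
  expect_setequal(single[[1L]][[1L]], 1:4)

  expect_error(alpha_lattice_layout(10, 1, 2), "block_size")
  expect_error(alpha_lattice_layout(3, 4, 2), "at least block_size")

  # completeness holds for arbitrary dimensions, including ragged final blocks
  set.seed(2)
  for (i in 1:10) {
    n <- sample(5:40, 1); k <- sample(2:5, 1); r <- sample(1:3, 1)
    lay <- alpha_lattice_layout(n, k, r)
    for (rep_blocks in lay) expect_setequal(unlist(rep_blocks), seq_len(n))
  }
})

test_that("a fixed seed reproduces the simulation bit for bit", {
  cfg <- small_config(l = 6, e = 2)
  a <- simulate_trial(cfg, seed = 99)
  b <- simulate_trial(cfg, seed = 99)
  expect_identical(a$book$plots, b$book$plots)
  expect_identical(a$truth$genetic_values, b$truth$genetic_values)
  c <- simulate_trial(cfg, seed = 100)
  expect_false(identical(a$book$plots$grain_yield, c$book$plots$grain_yield))
  # the caller's RNG stream is left untouched
  set.seed(5); x1 <- rnorm(1)
  set.seed(5); invisible(simulate_trial(cfg, seed = 1)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("zero variance components collapse every plot to the grand mean", {
  cfg <- small_config(l = 4, e = 2)
  for (tr in names(cfg$traits)) {
    cfg$traits[[tr]] <- zero_components(cfg$traits[[tr]], keep = character())
  }
  for (nm in lxtrial:::.vc_names) cfg$carotenoids[[nm]] <- 0
  cfg$carotenoids$beta_branch_line_sd <- 0
  cfg$carotenoids$beta_branch_tester_shift <- 0
  res <- simulate_trial(cfg, seed = 1)
  p <- res$book$plots
  expect_true(all(abs(p$grain_yield - cfg$traits$grain_yield$mean) < 1e-9))
  expect_true(all(abs(p$pht - cfg$traits$pht$mean) < 1e-9))
  tc <- cfg$carotenoids$mean_total
  q <- cfg$carotenoids$beta_branch_mean
  caro <- p$total_carotenoid[!is.na(p$total_carotenoid)]
  expect_true(all(abs(caro - tc) < 1e-9))
  bc <- p$beta_carotene[!is.na(p$beta_carotene)]
  expect_true(all(abs(bc - q * cfg$carotenoids$beta_branch_weights[["beta_carotene"]] * tc) < 1e-9))
})

test_that("generated derived columns satisfy their formulas exactly", {
  res <- simulate_trial(small_config(l = 8, e = 3), seed = 4)
  p <- res$book$plots
  ok <- !is.na(p$pva)
  expect_identical(p$pva[ok],
                   (p$beta_carotene + 0.5 * (p$beta_cryptoxanthin +
                                               p$alpha_carotene))[ok])
})

test_that("ground-truth effects satisfy the zero-sum constraints exactly", {
  res <- simulate_trial(small_config(l = 7, e = 2), seed = 21)
  for (tr in names(res$truth$effects)) {
    ef <- res$truth$effects[[tr]]
    expect_lt(abs(sum(ef$gca_line)), 1e-10)
    expect_lt(abs(sum(ef$gca_tester)), 1e-10)
    expect_true(all(abs(rowSums(ef$sca)) < 1e-10))
    expect_true(all(abs(colSums(ef$sca)) < 1e-10))
  }
})

test_that("empirical effect variances converge to configured components", {
  cfg <- small_config(l = 400, e = 2, carotenoids = FALSE)
  res <- simulate_trial(cfg, seed = 8)
  for (tr in c("grain_yield", "pht", "dyanth")) {
    v_cfg <- cfg$traits[[tr]]$v_gca_line
    v_emp <- var(res$truth$effects[[tr]]$gca_line)
    # sampling sd of a variance at n = 400 is about v * sqrt(2/399)
    expect_lt(abs(v_emp - v_cfg), 4 * v_cfg * sqrt(2 / 399))
  }
})

test_that("default configuration matches the reported study conditions", {
  cfg <- default_trial_config()
  expect_equal(cfg$n_lines, 60L)
  expect_equal(cfg$n_testers, 2L)
  expect_equal(cfg$n_envs, 8L)
  expect_equal(cfg$n_carotenoid_envs, 4L)
  expect_equal(cfg$n_reps, 2L)
  expect_equal(cfg$block_size, 4L)

  ref <- lxt_reference("testcross_summary")
  # PVA grand mean inside the reported testcross range
  q <- cfg$carotenoids$beta_branch_mean *
    (cfg$carotenoids$beta_branch_weights[["beta_carotene"]] +
       0.5 * (cfg$carotenoids$beta_branch_weights[["beta_cryptoxanthin"]] +
                cfg$carotenoids$beta_branch_weights[["alpha_carotene"]]))
  pva_mean <- q * cfg$carotenoids$mean_total
  pva_ref <- ref[ref$trait == "pva", ]
  expect_gte(pva_mean, min(pva_ref$min))
  expect_lte(pva_mean, max(pva_ref$max))
  # yield mean inside the reported testcross span
  gy_ref <- ref[ref$trait == "grain_yield", ]
  expect_gte(cfg$traits$grain_yield$mean, min(gy_ref$min))
  expect_lte(cfg$traits$grain_yield$mean, max(gy_ref$max))
})

test_that("configuration validation rejects inconsistent settings", {
  cfg <- default_trial_config()
  cfg$traits$pht$v_sca <- -1
  expect_error(validate_trial_config(cfg), "negative variance")
  cfg2 <- default_trial_config()
  cfg2$block_size <- 1L
  expect_error(validate_trial_config(cfg2), "block_size")
  cfg3 <- default_trial_config()
  cfg3$carotenoids$beta_branch_weights <- c(beta_cryptoxanthin = 0.5,
                                            alpha_carotene = 0.5,
                                            beta_carotene = 0.5)
  expect_error(validate_trial_config(cfg3), "sum to 1")
})

test_that("configs round-trip through YAML", {
  skip_if_not_installed("yaml")
  cfg <- small_config(l = 9, e = 3)
  cfg$seed <- 77L
  path <- withr::local_tempfile(fileext = ".yml")
  write_trial_config(cfg, path)
  back <- read_trial_config(path)
  expect_equal(back$n_lines, 9L)
  expect_equal(back$seed, 77L)
  expect_equal(back$traits$grain_yield, cfg$traits$grain_yield)
  expect_identical(simulate_trial(back, seed = 3)$book$plots,
                   simulate_trial(cfg, seed = 3)$book$plots)
})
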