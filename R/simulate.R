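# Synthetic multi-environment line x tester trial generator.
#
# Plot values follow the additive random-effects decomposition assumed by the
# combined analysis:
#   y = mu + g_line + g_tester + s_(line,tester) + E_env + R_rep(env)
#       + B_block(rep,env) + (gE)_line,env + (gE)_tester,env
#       + (sE)_line,tester,env + eps_plot.
# Line GCA, tester GCA and the SCA matrix are centered (sum to zero, row and
# column sums of SCA zero) so the ground truth is identifiable; environment,
# replicate, block, the three x-environment interactions and the residual are
# drawn iid Gaussian at their configured variances, which keeps the classical
# balanced expected mean squares exact and the method-of-moments estimators
# unbiased.

`%||%` <- function(a, b) if (is.null(a)) b else a

.linear_traits <- c("grain_yield", "dyanth", "asi", "pht", "eht", "pasp", "easp")

.vc_names <- c("v_gca_line", "v_gca_tester", "v_sca", "v_env", "v_rep",
               "v_block", "v_line_env", "v_tester_env", "v_sca_env",
               "v_residual")

#' Simulation configuration for a line x tester trial
#'
#' Bundles the trial dimensions, per-trait grand means and variance
#' components, and the carotenoid-profile parameters (total-carotenoid
#' components, biosynthetic branch partition, and the dilution coefficient
#' linking genetic yield deviations to total carotenoid).
#'
#' @param n_lines,n_testers,n_envs,n_reps trial dimensions.
#' @param n_carotenoid_envs number of environments (the first ones) in which
#'   carotenoids are measured; at most `n_envs`.
#' @param block_size incomplete-block size of the lattice layout.
#' @param n_checks number of commercial check hybrids carried alongside the
#'   testcrosses and the inter-tester reference hybrid.
#' @param traits named list (names from `grain_yield`, `dyanth`, `asi`,
#'   `pht`, `eht`, `pasp`, `easp`); each element a list with `mean` and the
#'   ten variance components `v_gca_line`, `v_gca_tester`, `v_sca`, `v_env`,
#'   `v_rep`, `v_block`, `v_line_env`, `v_tester_env`, `v_sca_env`,
#'   `v_residual` (trait units squared).
#' @param carotenoids list with `mean_total` plus the same ten components for
#'   total carotenoid, branch parameters `beta_branch_mean`,
#'   `beta_branch_tester_shift`, `beta_branch_line_sd`,
#'   `beta_branch_weights` (beta_cryptoxanthin, alpha_carotene,
#'   beta_carotene), `alpha_branch_weights` (lutein, zeaxanthin) and
#'   `dilution` (ug/g per kg/ha of genetic yield deviation; negative gives
#'   the yield-provitamin A dilution correlation).
#' @param moisture_mean,moisture_sd harvest grain moisture distribution (%).
#' @param plot_area harvested plot area, m2.
#' @param seed default RNG seed used by [simulate_trial()].
#' @return Object of class `trial_config`.
#' @seealso [default_trial_config()] for the calibrated defaults.
#' @export
trial_config <- function(n_lines = 60, n_testers = 2, n_envs = 8,
                         n_carotenoid_envs = 4, n_reps = 2, block_size = 4,
                         n_checks = 3, traits, carotenoids,
                         moisture_mean = 20, moisture_sd = 2,
                         plot_area = 3.75, seed = NULL) {
  cfg <- structure(
    list(n_lines = as.integer(n_lines), n_testers = as.integer(n_testers),
         n_envs = as.integer(n_envs),
         n_carotenoid_envs = as.integer(n_carotenoid_envs),
         n_reps = as.integer(n_reps), block_size = as.integer(block_size),
         n_checks = as.integer(n_checks), traits = traits,
         carotenoids = carotenoids, moisture_mean = moisture_mean,
         moisture_sd = moisture_sd, plot_area = plot_area, seed = seed),
    class = "trial_config"
  )
  validate_trial_config(cfg)
}

#' @rdname trial_config
#' @param config object to validate.
#' @export
validate_trial_config <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  with(config, {
    if (n_lines < 1 || n_testers < 1 || n_envs < 1 || n_reps < 1)
      stop("trial dimensions must be positive", call. = FALSE)
    if (n_carotenoid_envs < 0 || n_carotenoid_envs > n_envs)
      stop("n_carotenoid_envs must be between 0 and n_envs", call. = FALSE)
    if (block_size <= 1) stop("block_size must exceed 1", call. = FALSE)
  })
  for (tr in names(config$traits)) {
    spec <- config$traits[[tr]]
    if (!tr %in% .linear_traits)
      stop("unknown simulated trait '", tr, "'", call. = FALSE)
    if (is.null(spec$mean)) stop("trait '", tr, "' needs a mean", call. = FALSE)
    v <- unlist(spec[.vc_names])
    if (length(v) != length(.vc_names) || anyNA(v))
      stop("trait '", tr, "' must declare all components: ",
           paste(.vc_names, collapse = ", "), call. = FALSE)
    if (any(v < 0)) stop("negative variance component for '", tr, "'",
                         call. = FALSE)
  }
  ca <- config$carotenoids
  v <- unlist(ca[.vc_names])
  if (any(v < 0)) stop("negative carotenoid variance component", call. = FALSE)
  if (abs(sum(ca$beta_branch_weights) - 1) > 1e-8 ||
      abs(sum(ca$alpha_branch_weights) - 1) > 1e-8)
    stop("branch weights must each sum to 1", call. = FALSE)
  invisible(config)
}

#' Default simulation configuration
#'
#' Dimensions and trait distributions calibrated to a published
#' multi-environment evaluation of 60 provitamin A-enriched tropical maize
#' inbred lines crossed to two inbred testers: 124 entries (120 testcrosses,
#' the inter-tester hybrid, 3 checks) in a 31 x 4 resolvable incomplete-block
#' layout with 2 replicates, 8 environments for agronomic traits and 4 for
#' carotenoids. Grand means sit at the reported testcross means (grain yield
#' about 6190 kg/ha, provitamin A about 11.5 ug/g DW) and residual variances
#' reproduce the reported coefficients of variation. The dilution coefficient
#' (-0.0037 ug/g per kg/ha) places the expected genotypic yield-provitamin A
#' correlation near -0.25.
#'
#' @param seed optional default seed stored in the configuration.
#' @return A [trial_config()] object.
#' @export
default_trial_config <- function(seed = NULL) {
  traits <- list(
    grain_yield = list(mean = 6190, v_gca_line = 180000, v_gca_tester = 12000,
                       v_sca = 40000, v_env = 800000, v_rep = 30000,
                       v_block = 60000, v_line_env = 60000,
                       v_tester_env = 15000, v_sca_env = 40000,
                       v_residual = 1100000),
    dyanth = list(mean = 56.97, v_gca_line = 1.6, v_gca_tester = 0.55,
                  v_sca = 0.25, v_env = 15, v_rep = 0.2, v_block = 0.3,
                  v_line_env = 0.25, v_tester_env = 0.1, v_sca_env = 0.15,
                  v_residual = 1.4),
    asi = list(mean = 1.55, v_gca_line = 0.15, v_gca_tester = 0.02,
               v_sca = 0.05, v_env = 0.5, v_rep = 0.05, v_block = 0.05,
               v_line_env = 0.05, v_tester_env = 0.01, v_sca_env = 0.05,
               v_residual = 0.8),
    pht = list(mean = 191.3, v_gca_line = 45, v_gca_tester = 9, v_sca = 12,
               v_env = 380, v_rep = 6, v_block = 10, v_line_env = 9,
               v_tester_env = 4, v_sca_env = 8, v_residual = 98),
    eht = list(mean = 92.9, v_gca_line = 30, v_gca_tester = 5.3, v_sca = 9,
               v_env = 140, v_rep = 5, v_block = 7, v_line_env = 6,
               v_tester_env = 1.5, v_sca_env = 5, v_residual = 70),
    pasp = list(mean = 2.53, v_gca_line = 0.035, v_gca_tester = 0.002,
                v_sca = 0.015, v_env = 0.05, v_rep = 0.005, v_block = 0.008,
                v_line_env = 0.008, v_tester_env = 0.003, v_sca_env = 0.008,
                v_residual = 0.19),
    easp = list(mean = 2.55, v_gca_line = 0.04, v_gca_tester = 0.0032,
                v_sca = 0.02, v_env = 0.12, v_rep = 0.006, v_block = 0.006,
                v_line_env = 0.006, v_tester_env = 0.002, v_sca_env = 0.006,
                v_residual = 0.16)
  )
  carotenoids <- list(
    mean_total = 31.4, v_gca_line = 20, v_gca_tester = 2, v_sca = 2,
    v_env = 25, v_rep = 1.5, v_block = 2, v_line_env = 1.5,
    v_tester_env = 1.5, v_sca_env = 1.2, v_residual = 12,
    beta_branch_mean = 0.442, beta_branch_tester_shift = 0.048,
    beta_branch_line_sd = 0.05,
    beta_branch_weights = c(beta_cryptoxanthin = 0.285,
                            alpha_carotene = 0.061, beta_carotene = 0.654),
    alpha_branch_weights = c(lutein = 0.452, zeaxanthin = 0.548),
    dilution = -0.0037
  )
  trial_config(traits = traits, carotenoids = carotenoids, seed = seed)
}

#' Resolvable incomplete-block layout
#'
#' Assigns `n_entries` entries to blocks of size `block_size` within each of
#' `n_reps` replicates, re-randomizing the assignment in every replicate, so
#' that each entry appears exactly once per replicate (a randomized
#' alpha-lattice-style resolvable layout; pairwise concurrences are not
#' optimized). When `block_size` does not divide `n_entries` the final block
#' of a replicate is smaller.
#'
#' @param n_entries number of entries.
#' @param block_size entries per incomplete block (> 1).
#' @param n_reps number of replicates.
#' @param seed optional RNG seed.
#' @return List with one element per replicate, each a list of integer
#'   vectors of entry indices (one per block).
#' @export
alpha_lattice_layout <- function(n_entries, block_size, n_reps, seed = NULL) {
  if (block_size <= 1) stop("block_size must exceed 1", call. = FALSE)
  if (n_entries < block_size) {
    stop("need at least block_size entries", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n_blocks <- ceiling(n_entries / block_size)
  lapply(seq_len(n_reps), function(rp) {
    ord <- sample.int(n_entries)
    split(ord, rep(seq_len(n_blocks), each = block_size,
                   length.out = n_entries))
  })
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(NULL)
}

# Center a vector to sum zero; double-center a matrix so every row and column
# sums to zero (projection onto the interaction space).
.center <- function(x) x - mean(x)
.double_center <- function(m) {
  m - outer(rowMeans(m), rep(1, ncol(m))) -
    outer(rep(1, nrow(m)), colMeans(m)) + mean(m)
}

# Row/column/grand-mean decomposition of an l x t matrix of cell values.
.decompose_cells <- function(m) {
  mu <- mean(m)
  list(mu = mu, gca_line = rowMeans(m) - mu, gca_tester = colMeans(m) - mu,
       sca = .double_center(m))
}

#' Simulate a line x tester multi-environment trial
#'
#' Draws every effect of the additive decomposition at its configured
#' variance and assembles a complete plot-level field book, together with the
#' ground truth (true GCA/SCA effects, configured variance components, and
#' realized genetic values per testcross cell and trait). Carotenoid
#' concentrations are generated as genotype-specific shares of a simulated
#' total-carotenoid value, the beta-branch share carrying the tester contrast
#' and line variation, so the provitamin A and total-carotenoid identities
#' hold exactly by construction; the genetic yield deviation of each cell
#' scales its total carotenoid through the dilution coefficient. Scores are
#' latent Gaussians clipped to [1, 5]; yields and concentrations are clipped
#' at zero (rare at the default variances). Days to silking is the sum of the
#' simulated days-to-anthesis and anthesis-silking-interval values, so the
#' derived interval reproduces the simulated one exactly.
#'
#' @param config a [trial_config()].
#' @param seed RNG seed; defaults to `config$seed`. A fixed seed makes the
#'   output bit-reproducible.
#' @return List with components `book` (a [fieldbook()] including derived
#'   trait columns) and `truth` (class `lxt_truth`): `effects` (per trait:
#'   `mu`, `gca_line`, `gca_tester`, `sca`), `varcomp` (configured
#'   components per simulated trait), `genetic_values` (testcross cell
#'   genetic means per trait, including derived carotenoid traits), and
#'   `genetic_correlations` (correlations of those cell values).
#' @export
simulate_trial <- function(config, seed = config$seed) {
  validate_trial_config(config)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  l <- config$n_lines; t_n <- config$n_testers; e_n <- config$n_envs
  r_n <- config$n_reps; k <- config$block_size; n_chk <- config$n_checks

  lines <- sprintf("L%02d", seq_len(l))
  testers <- sprintf("T%d", seq_len(t_n))
  tc_grid <- expand.grid(line = seq_len(l), tester = seq_len(t_n))
  tc_ids <- paste0(lines[tc_grid$line], "x", testers[tc_grid$tester])
  ref_id <- if (t_n >= 2) paste0(testers[1L], "x", testers[2L]) else NULL
  chk_ids <- if (n_chk > 0) sprintf("CHECK%d", seq_len(n_chk)) else character()
  other_ids <- c(ref_id, chk_ids)
  entry_ids <- c(tc_ids, other_ids)
  n_entries <- length(entry_ids)
  envs <- sprintf("E%d", seq_len(e_n))
  caro_envs <- envs[seq_len(config$n_carotenoid_envs)]

  entry_meta <- data.frame(
    entry = entry_ids,
    role = c(rep("testcross", length(tc_ids)),
             if (!is.null(ref_id)) "tester_cross",
             rep("check", n_chk)),
    line_parent = c(lines[tc_grid$line], rep(NA_character_, length(other_ids))),
    tester_parent = c(testers[tc_grid$tester],
                      rep(NA_character_, length(other_ids))),
    stringsAsFactors = FALSE
  )

  # ---- genetic and environmental effects per linear trait --------------
  draw_trait <- function(spec) {
    gl <- .center(stats::rnorm(l, 0, sqrt(spec$v_gca_line)))
    gt <- .center(stats::rnorm(t_n, 0, sqrt(spec$v_gca_tester)))
    sca <- .double_center(matrix(stats::rnorm(l * t_n, 0, sqrt(spec$v_sca)),
                                 l, t_n))
    if (t_n == 1L) { gt <- 0; sca <- matrix(0, l, 1L) }
    chk <- stats::rnorm(n_chk, 0, sqrt(spec$v_gca_line + spec$v_sca))
    env <- stats::rnorm(e_n, 0, sqrt(spec$v_env))
    rep_eff <- matrix(stats::rnorm(e_n * r_n, 0, sqrt(spec$v_rep)), e_n, r_n)
    le <- matrix(stats::rnorm(l * e_n, 0, sqrt(spec$v_line_env)), l, e_n)
    te <- matrix(stats::rnorm(t_n * e_n, 0, sqrt(spec$v_tester_env)), t_n, e_n)
    ste <- array(stats::rnorm(l * t_n * e_n, 0, sqrt(spec$v_sca_env)),
                 dim = c(l, t_n, e_n))
    v_he <- spec$v_line_env + spec$v_tester_env + spec$v_sca_env
    other_env <- matrix(stats::rnorm(length(other_ids) * e_n, 0, sqrt(v_he)),
                        length(other_ids), e_n)
    list(spec = spec, gl = gl, gt = gt, sca = sca, chk = chk, env = env,
         rep_eff = rep_eff, le = le, te = te, ste = ste,
         other_env = other_env)
  }
  eff <- lapply(config$traits, draw_trait)

  # entry-level genetic values (deviation from mu): testcrosses then others
  entry_gen <- function(ef) {
    g_tc <- ef$gl[tc_grid$line] + ef$gt[tc_grid$tester] +
      ef$sca[cbind(tc_grid$line, tc_grid$tester)]
    g_other <- c(if (!is.null(ref_id)) 0, ef$chk)
    c(g_tc, g_other)
  }
  # entry x env genetic interaction (n_entries x e_n)
  entry_ge <- function(ef) {
    ge_tc <- ef$le[tc_grid$line, , drop = FALSE] +
      ef$te[tc_grid$tester, , drop = FALSE] +
      matrix(ef$ste[cbind(rep(tc_grid$line, e_n),
                          rep(tc_grid$tester, e_n),
                          rep(seq_len(e_n), each = nrow(tc_grid)))],
             nrow(tc_grid), e_n)
    rbind(ge_tc, ef$other_env)
  }

  # ---- carotenoid machinery -------------------------------------------
  ca <- config$carotenoids
  do_caro <- config$n_carotenoid_envs > 0L && !is.null(ca)
  if (do_caro) {
    caro_spec <- ca[.vc_names]
    caro_spec$mean <- ca$mean_total
    caro_eff <- draw_trait(caro_spec)
    yield_gen <- if (!is.null(eff$grain_yield)) {
      entry_gen(eff$grain_yield)
    } else rep(0, n_entries)
    tc_gen <- entry_gen(caro_eff) + ca$dilution * yield_gen
    tc_ge <- entry_ge(caro_eff)

    beta_line <- stats::rnorm(l, 0, ca$beta_branch_line_sd)
    tester_shift <- if (t_n >= 2) {
      sh <- rep(0, t_n)
      sh[1L] <- ca$beta_branch_tester_shift
      sh[2L] <- -ca$beta_branch_tester_shift
      sh
    } else 0
    beta_cells <- pmin(pmax(ca$beta_branch_mean + tester_shift[tc_grid$tester] +
                              beta_line[tc_grid$line], 0.05), 0.95)
    beta_other <- pmin(pmax(ca$beta_branch_mean +
                              stats::rnorm(length(other_ids), 0,
                                           ca$beta_branch_line_sd), 0.05), 0.95)
    beta_entry <- c(beta_cells, beta_other)
  }

  # ---- assemble plots --------------------------------------------------
  rows <- vector("list", e_n * r_n)
  idx <- 0L
  for (ei in seq_len(e_n)) {
    layout <- alpha_lattice_layout(n_entries, k, r_n)
    for (ri in seq_len(r_n)) {
      blocks <- layout[[ri]]
      ord <- unlist(blocks, use.names = FALSE)
      blk <- rep(sprintf("B%02d", seq_along(blocks)),
                 times = lengths(blocks))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(env = envs[ei], rep = ri, block = blk,
                                entry_idx = ord, stringsAsFactors = FALSE)
    }
  }
  plots <- do.call(rbind, rows)
  n_plots <- nrow(plots)
  ei <- match(plots$env, envs)
  plots$entry <- entry_ids[plots$entry_idx]
  meta_i <- plots$entry_idx
  plots$role <- entry_meta$role[meta_i]
  plots$line_parent <- entry_meta$line_parent[meta_i]
  plots$tester_parent <- entry_meta$tester_parent[meta_i]

  block_key <- interaction(plots$env, plots$rep, plots$block, drop = TRUE)

  plot_values <- function(ef, gen, ge) {
    b_eff <- stats::rnorm(nlevels(block_key), 0, sqrt(ef$spec$v_block))
    ef$spec$mean + gen[meta_i] + ef$env[ei] +
      ef$rep_eff[cbind(ei, plots$rep)] + b_eff[as.integer(block_key)] +
      ge[cbind(meta_i, ei)] +
      stats::rnorm(n_plots, 0, sqrt(ef$spec$v_residual))
  }

  vals <- lapply(names(eff), function(tr) {
    plot_values(eff[[tr]], entry_gen(eff[[tr]]), entry_ge(eff[[tr]]))
  })
  names(vals) <- names(eff)

  if (!is.null(vals$grain_yield)) vals$grain_yield <- pmax(vals$grain_yield, 0)
  if (!is.null(vals$pasp)) vals$pasp <- pmin(pmax(vals$pasp, 1), 5)
  if (!is.null(vals$easp)) vals$easp <- pmin(pmax(vals$easp, 1), 5)
  if (!is.null(vals$dyanth)) vals$dyanth <- pmax(vals$dyanth, 0)

  if (!is.null(vals$dyanth)) plots$dyanth <- vals$dyanth
  if (!is.null(vals$dyanth) && !is.null(vals$asi)) {
    plots$dysk <- pmax(vals$dyanth + vals$asi, 0)
  }
  for (tr in intersect(c("pht", "eht", "pasp", "easp"), names(vals))) {
    plots[[tr]] <- vals[[tr]]
  }

  if (!is.null(vals$grain_yield)) {
    moisture <- pmin(pmax(stats::rnorm(n_plots, config$moisture_mean,
                                       config$moisture_sd), 5), 40)
    plots$grain_moisture <- moisture
    plots$grain_weight <- vals$grain_yield * config$plot_area / 10000 *
      85 / (100 - moisture)
  }

  if (do_caro) {
    tc_plot <- ca$mean_total + tc_gen[meta_i] + caro_eff$env[ei] +
      caro_eff$rep_eff[cbind(ei, plots$rep)] +
      stats::rnorm(nlevels(block_key), 0,
                   sqrt(ca$v_block))[as.integer(block_key)] +
      tc_ge[cbind(meta_i, ei)] +
      stats::rnorm(n_plots, 0, sqrt(ca$v_residual))
    tc_plot <- pmax(tc_plot, 0)
    beta_p <- beta_entry[meta_i]
    aw <- ca$alpha_branch_weights; bw <- ca$beta_branch_weights
    in_caro <- plots$env %in% caro_envs
    mk <- function(x) ifelse(in_caro, x, NA_real_)
    plots$lutein <- mk((1 - beta_p) * aw[["lutein"]] * tc_plot)
    plots$zeaxanthin <- mk((1 - beta_p) * aw[["zeaxanthin"]] * tc_plot)
    plots$beta_cryptoxanthin <- mk(beta_p * bw[["beta_cryptoxanthin"]] * tc_plot)
    plots$alpha_carotene <- mk(beta_p * bw[["alpha_carotene"]] * tc_plot)
    plots$beta_carotene <- mk(beta_p * bw[["beta_carotene"]] * tc_plot)
  }

  plots$entry_idx <- NULL
  book <- derive_traits(fieldbook(plots), plot_area = config$plot_area)

  # ---- ground truth ----------------------------------------------------
  n_tc <- nrow(tc_grid)
  cell_val <- function(gen) {
    matrix(gen[seq_len(n_tc)], l, t_n, dimnames = list(lines, testers))
  }
  effects <- lapply(names(eff), function(tr) {
    ef <- eff[[tr]]
    list(mu = ef$spec$mean,
         gca_line = stats::setNames(ef$gl, lines),
         gca_tester = stats::setNames(ef$gt, testers),
         sca = matrix(ef$sca, l, t_n, dimnames = list(lines, testers)))
  })
  names(effects) <- names(eff)
  # dysk inherits the sum of dyanth and asi effects
  if (!is.null(effects$dyanth) && !is.null(effects$asi)) {
    effects$dysk <- list(
      mu = eff$dyanth$spec$mean + eff$asi$spec$mean,
      gca_line = effects$dyanth$gca_line + effects$asi$gca_line,
      gca_tester = effects$dyanth$gca_tester + effects$asi$gca_tester,
      sca = effects$dyanth$sca + effects$asi$sca
    )
  }

  gen_vals <- sapply(names(effects), function(tr) {
    ef <- effects[[tr]]
    as.vector(ef$mu + outer(ef$gca_line, ef$gca_tester, `+`) + ef$sca)
  })
  if (do_caro) {
    # carotenoid genetic cell means: share x (mu_tc + genetic tc deviation)
    q_pva <- bw[["beta_carotene"]] +
      0.5 * (bw[["beta_cryptoxanthin"]] + bw[["alpha_carotene"]])
    tc_cell <- ca$mean_total + tc_gen[seq_len(n_tc)]
    caro_gen <- cbind(
      lutein = (1 - beta_cells) * aw[["lutein"]] * tc_cell,
      zeaxanthin = (1 - beta_cells) * aw[["zeaxanthin"]] * tc_cell,
      beta_cryptoxanthin = beta_cells * bw[["beta_cryptoxanthin"]] * tc_cell,
      alpha_carotene = beta_cells * bw[["alpha_carotene"]] * tc_cell,
      beta_carotene = beta_cells * bw[["beta_carotene"]] * tc_cell,
      pva = beta_cells * q_pva * tc_cell,
      total_carotenoid = tc_cell
    )
    gen_vals <- cbind(gen_vals, caro_gen)
    for (tr in c("pva", "total_carotenoid")) {
      effects[[tr]] <- .decompose_cells(
        matrix(caro_gen[, tr], l, t_n, dimnames = list(lines, testers)))
    }
  }
  rownames(gen_vals) <- tc_ids

  varcomp <- do.call(rbind, lapply(names(config$traits), function(tr) {
    data.frame(trait = tr, component = .vc_names,
               value = unlist(config$traits[[tr]][.vc_names]),
               row.names = NULL)
  }))

  truth <- structure(
    list(effects = effects, varcomp = varcomp, genetic_values = gen_vals,
         genetic_correlations = suppressWarnings(stats::cor(gen_vals)),
         beta_branch = if (do_caro) stats::setNames(beta_entry, entry_ids),
         config = config),
    class = "lxt_truth"
  )
  list(book = book, truth = truth)
}

#' @export
print.lxt_truth <- function(x, ...) {
  cat("Ground truth for a simulated line x tester trial\n")
  cat("  traits:", paste(names(x$effects), collapse = ", "), "\n")
  if (all(c("grain_yield", "pva") %in% colnames(x$genetic_correlations))) {
    cat(sprintf("  genetic yield-PVA correlation (realized): %.3f\n",
                x$genetic_correlations["grain_yield", "pva"]))
  }
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' Flat representation of a [trial_config()] for use with the command-line
#' wrapper. Requires the `yaml` package.
#'
#' @param path file path.
#' @param config a [trial_config()] (for writing).
#' @return [read_trial_config()] returns a `trial_config`;
#'   [write_trial_config()] returns `path` invisibly.
#' @export
read_trial_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  base <- default_trial_config()
  for (nm in intersect(names(raw), c("n_lines", "n_testers", "n_envs",
                                     "n_carotenoid_envs", "n_reps",
                                     "block_size", "n_checks",
                                     "moisture_mean", "moisture_sd",
                                     "plot_area", "seed"))) {
    base[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$traits)) {
    for (tr in names(raw$traits)) {
      base$traits[[tr]] <- utils::modifyList(
        base$traits[[tr]] %||% list(), raw$traits[[tr]])
    }
  }
  if (!is.null(raw$carotenoids)) {
    for (nm in names(raw$carotenoids)) {
      v <- raw$carotenoids[[nm]]
      if (nm %in% c("beta_branch_weights", "alpha_branch_weights")) {
        v <- unlist(v)
      }
      base$carotenoids[[nm]] <- v
    }
  }
  validate_trial_config(base)
}

#' @rdname read_trial_config
#' @export
write_trial_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write configuration files",
         call. = FALSE)
  }
  validate_trial_config(config)
  x <- unclass(config)
  x$carotenoids$beta_branch_weights <- as.list(x$carotenoids$beta_branch_weights)
  x$carotenoids$alpha_branch_weights <- as.list(x$carotenoids$alpha_branch_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}
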