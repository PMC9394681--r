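# Shared fixtures and independent oracles.

# Balanced testcross-only plot table with values from a function
# f(line, tester, env, rep); one block per replicate unless block_of is given.
make_toy_plots <- function(l = 2, t = 2, e = 1, r = 2, f,
                           block_of = NULL) {
  g <- expand.grid(line = seq_len(l), tester = seq_len(t),
                   env = seq_len(e), rep = seq_len(r))
  data.frame(
    env = paste0("E", g$env), rep = g$rep,
    block = if (is.null(block_of)) "B1" else block_of(g),
    entry = paste0("L", g$line, "xT", g$tester),
    role = "testcross",
    line_parent = paste0("L", g$line),
    tester_parent = paste0("T", g$tester),
    y = mapply(f, g$line, g$tester, g$env, g$rep),
    stringsAsFactors = FALSE
  )
}

toy_book <- function(..., f) fieldbook(make_toy_plots(..., f = f))

# Constrained least squares (zero-sum constraints via sum-to-zero contrasts)
# for the GCA/SCA decomposition of an l x t mean matrix.
ls_gca_sca_oracle <- function(m) {
  l <- nrow(m); t_n <- ncol(m)
  df <- expand.grid(line = factor(seq_len(l)), tester = factor(seq_len(t_n)))
  df$y <- as.vector(m)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(y ~ line * tester, data = df)
  cf <- stats::coef(fit)
  mu <- cf[["(Intercept)"]]
  gl <- cf[grep("^line\\d+$", names(cf))]
  gl <- c(gl, -sum(gl))
  gt <- cf[grep("^tester\\d+$", names(cf))]
  gt <- c(gt, -sum(gt))
  fitted_m <- matrix(stats::fitted(fit), l, t_n)
  sca <- fitted_m - mu - outer(gl, rep(1, t_n)) - outer(rep(1, l), gt)
  list(mu = mu, gca_line = unname(gl), gca_tester = unname(gt),
       sca = unname(sca))
}

# Sequential least-squares ANOVA on a balanced testcross-only book: Type I
# sums of squares from stats::lm / stats::anova, mapped onto the package's
# source labels.
seq_ss_oracle <- function(book, trait) {
  p <- book$plots[book$plots$role == "testcross", ]
  p$envf <- factor(p$env); p$repf <- factor(p$rep)
  p$linef <- factor(p$line_parent); p$testerf <- factor(p$tester_parent)
  y <- p[[trait]]
  if (nlevels(p$envf) == 1L) {
    fit <- stats::lm(y ~ repf + linef * testerf, data = p)
    a <- stats::anova(fit)
    ss <- a[["Sum Sq"]]
    names(ss) <- rownames(a)
    c("Rep(Env)" = unname(ss[["repf"]]),
      "Line" = unname(ss[["linef"]]),
      "Tester" = unname(ss[["testerf"]]),
      "Line x Tester" = unname(ss[["linef:testerf"]]),
      "Error" = unname(ss[["Residuals"]]))
  } else {
    fit <- stats::lm(y ~ envf + envf:repf + linef * testerf + envf:linef +
                       envf:testerf + envf:linef:testerf, data = p)
    a <- stats::anova(fit)
    ss <- a[["Sum Sq"]]
    names(ss) <- rownames(a)
    c("Env" = unname(ss[["envf"]]),
      "Rep(Env)" = unname(ss[["envf:repf"]]),
      "Line" = unname(ss[["linef"]]),
      "Tester" = unname(ss[["testerf"]]),
      "Line x Tester" = unname(ss[["linef:testerf"]]),
      "Line x Env" = unname(ss[["envf:linef"]]),
      "Tester x Env" = unname(ss[["envf:testerf"]]),
      "Line x Tester x Env" = unname(ss[["envf:linef:testerf"]]),
      "Error" = unname(ss[["Residuals"]]))
  }
}

ss_of <- function(an, source) an$ss[match(source, an$source)]
ms_of <- function(an, source) an$ms[match(source, an$source)]
df_of <- function(an, source) an$df[match(source, an$source)]

# Minimal ANOVA-shaped object with chosen mean squares, for SE arithmetic.
fake_anova <- function(ms, df, dims) {
  out <- data.frame(source = names(ms), df = unname(df), ss = unname(ms * df),
                    ms = unname(ms), f = NA_real_, p = NA_real_,
                    error_term = NA_character_, sig = "",
                    stringsAsFactors = FALSE)
  structure(out, class = c("lxt_anova", "data.frame"), dims = dims,
            grand_mean = 0, n_plots = 0L, trait = "fake")
}

# Small, fast simulation configuration (agronomic traits only unless
# carotenoids are requested).
small_config <- function(l = 10, e = 2, r = 2, carotenoids = TRUE,
                         overrides = list()) {
  cfg <- default_trial_config()
  cfg$n_lines <- as.integer(l)
  cfg$n_envs <- as.integer(e)
  cfg$n_reps <- as.integer(r)
  cfg$n_carotenoid_envs <- if (carotenoids) as.integer(min(e, 2L)) else 0L
  for (nm in names(overrides)) {
    cfg$traits[[nm]] <- utils::modifyList(cfg$traits[[nm]], overrides[[nm]])
  }
  validate_trial_config(cfg)
}

# Zero out one trait's genetic (or all) variance components.
zero_components <- function(spec, keep = "v_residual") {
  for (nm in setdiff(names(spec), c("mean", keep))) spec[[nm]] <- 0
  spec
}
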