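# Combined multi-environment line x tester analysis of variance.
#
# All factorial strata (environment, replicate within environment, hybrid,
# hybrid x environment, and the line/tester partition of the testcrosses) are
# computed by closed-form balanced-design sums of squares; the incomplete
# blocks and the residual are split by sequential least squares within each
# environment (blocks fitted after replicates and entries), which reproduces
# the published table layout for lattice trials without a mixed-model solver.

.anova_sources <- c("Env", "Rep(Env)", "Block(Env x Rep)", "Hybrid",
                    "Testcross", "Line", "Tester", "Line x Tester",
                    "Hybrid x Env", "Line x Env", "Tester x Env",
                    "Line x Tester x Env", "Error")

# Balance check: every entry present exactly once per (env, rep).
.check_balance <- function(p, trait) {
  tab <- table(p$entry, p$env, p$rep)
  bad <- which(tab != 1L, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cells <- apply(utils::head(bad, 5L), 1L, function(i) {
      paste0("(", dimnames(tab)[[1L]][i[1L]], ", ", dimnames(tab)[[2L]][i[2L]],
             ", rep ", dimnames(tab)[[3L]][i[3L]], ")")
    })
    stop("unbalanced data for trait '", trait,
         "': entry x environment x replicate cells with count != 1: ",
         paste(cells, collapse = ", "),
         if (nrow(bad) > 5L) paste0(" and ", nrow(bad) - 5L, " more"),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Genetic and interaction mean squares from cell means (no block adjustment).
# Returns SS, df for the factorial strata; used by combined_anova and by the
# faster entry-level routines.
.factorial_ss <- function(p, trait) {
  y <- p[[trait]]
  ef <- factor(p$env)
  rf <- factor(p$rep)
  hf <- factor(p$entry)
  e_n <- nlevels(ef); r_n <- nlevels(rf); h_n <- nlevels(hf)
  n <- length(y)
  gm <- mean(y)

  m_e <- tapply(y, ef, mean)
  m_er <- tapply(y, list(ef, rf), mean)
  m_h <- tapply(y, hf, mean)
  m_he <- tapply(y, list(hf, ef), mean)

  ss <- c(
    total = sum((y - gm)^2),
    env = h_n * r_n * sum((m_e - gm)^2),
    rep = h_n * sum((m_er - rep(m_e, times = r_n))^2),
    hybrid = e_n * r_n * sum((m_h - gm)^2),
    hyb_env = r_n * sum((m_he - outer(m_h, rep(1, e_n)) -
                           outer(rep(1, h_n), m_e) + gm)^2)
  )
  df <- c(total = n - 1L, env = e_n - 1L, rep = e_n * (r_n - 1L),
          hybrid = h_n - 1L, hyb_env = (h_n - 1L) * (e_n - 1L))

  # line x tester partition over the testcross subset
  tc <- p[p$role == "testcross", , drop = FALSE]
  lt <- NULL
  if (nrow(tc) > 0L) {
    lf <- factor(tc$line_parent)
    tf <- factor(tc$tester_parent)
    ef2 <- factor(tc$env)
    l_n <- nlevels(lf); t_n <- nlevels(tf)
    yt <- tc[[trait]]
    g <- mean(yt)
    m_ij <- tapply(yt, list(lf, tf), mean)
    m_i <- rowMeans(m_ij); m_j <- colMeans(m_ij)
    m_ie <- tapply(yt, list(lf, ef2), mean)
    m_je <- tapply(yt, list(tf, ef2), mean)
    m_ije <- tapply(yt, list(lf, tf, ef2), mean)
    m_e2 <- tapply(yt, ef2, mean)

    res3 <- m_ije
    for (k in seq_len(e_n)) {
      res3[, , k] <- m_ije[, , k] -
        outer(m_ie[, k], rep(1, t_n)) - outer(rep(1, l_n), m_je[, k]) -
        m_ij + outer(m_i, rep(1, t_n)) + outer(rep(1, l_n), m_j) +
        m_e2[k] - g
    }
    lt <- list(
      ss = c(
        testcross = e_n * r_n * sum((m_ij - g)^2),
        line = e_n * r_n * t_n * sum((m_i - g)^2),
        tester = e_n * r_n * l_n * sum((m_j - g)^2),
        lxt = e_n * r_n * sum((m_ij - outer(m_i, rep(1, t_n)) -
                                 outer(rep(1, l_n), m_j) + g)^2),
        line_env = r_n * t_n * sum((m_ie - outer(m_i, rep(1, e_n)) -
                                      outer(rep(1, l_n), m_e2) + g)^2),
        tester_env = r_n * l_n * sum((m_je - outer(m_j, rep(1, e_n)) -
                                        outer(rep(1, t_n), m_e2) + g)^2),
        lxt_env = r_n * sum(res3^2)
      ),
      df = c(
        testcross = l_n * t_n - 1L,
        line = l_n - 1L,
        tester = t_n - 1L,
        lxt = (l_n - 1L) * (t_n - 1L),
        line_env = (l_n - 1L) * (e_n - 1L),
        tester_env = (t_n - 1L) * (e_n - 1L),
        lxt_env = (l_n - 1L) * (t_n - 1L) * (e_n - 1L)
      ),
      dims = c(l = l_n, t = t_n)
    )
  }
  list(ss = ss, df = df, lt = lt, grand_mean = gm, n = n,
       dims = c(h = h_n, e = e_n, r = r_n))
}

# Sequential block / residual split within each environment: blocks (nested in
# env x rep) are fitted after replicate and entry effects. Replicates and
# entries are orthogonal on balanced data, so that fit is closed-form; the
# block fit uses a bare least-squares solve on indicator columns (rank
# pivoting handles the partial confounding of blocks with entries).
.block_error_ss <- function(p, trait) {
  ss_block <- 0; df_block <- 0L
  ss_err <- 0; df_err <- 0L
  env_f <- factor(p$env)
  y_all <- p[[trait]]
  for (env_i in levels(env_f)) {
    sel <- env_f == env_i
    y <- y_all[sel]
    rf <- factor(p$rep[sel])
    hf <- factor(p$entry[sel])
    n <- length(y); gm <- mean(y)
    m_r <- tapply(y, rf, mean); n_r <- tabulate(rf)
    m_h <- tapply(y, hf, mean); n_h <- tabulate(hf)
    rss0 <- sum((y - gm)^2) - sum(n_r * (m_r - gm)^2) -
      sum(n_h * (m_h - gm)^2)
    df0 <- n - 1L - (nlevels(rf) - 1L) - (nlevels(hf) - 1L)
    rb <- interaction(rf, p$block[sel], drop = TRUE)
    if (nlevels(rb) > nlevels(rf)) {
      ind <- function(f) {
        m <- matrix(0, length(f), nlevels(f))
        m[cbind(seq_along(f), as.integer(f))] <- 1
        m[, -1L, drop = FALSE]
      }
      X <- cbind(1, ind(rf), ind(hf), ind(rb))
      fit <- stats::lm.fit(X, y)
      rss1 <- sum(fit$residuals^2)
      df1 <- n - fit$rank
      ss_block <- ss_block + rss0 - rss1
      df_block <- df_block + df0 - df1
      ss_err <- ss_err + rss1
      df_err <- df_err + df1
    } else {
      ss_err <- ss_err + rss0
      df_err <- df_err + df0
    }
  }
  list(ss_block = ss_block, df_block = df_block,
       ss_error = ss_err, df_error = df_err)
}

#' Combined line x tester analysis of variance
#'
#' Partitions the plot-level variation of one trait across all environments in
#' which it was recorded into environment, replicate within environment,
#' incomplete block, hybrid (further split into testcross, line GCA, tester
#' GCA, and line x tester SCA), the hybrid x environment interactions with the
#' same genetic split, and error. Environments where the trait was not
#' recorded at all are excluded; within the retained environments the data
#' must be balanced (each entry once per replicate), otherwise the offending
#' cells are named. Genetic sources are tested against their corresponding
#' x environment interaction (environments are random); design terms and
#' interactions are tested against the pooled error. With a single
#' environment all genetic sources are tested against error.
#'
#' @param book a [fieldbook()].
#' @param trait trait name.
#' @return Object of class `lxt_anova`: a data.frame with columns `source`,
#'   `df`, `ss`, `ms`, `f`, `p`, `error_term`, `sig` and attributes
#'   `grand_mean`, `n_plots`, `dims` (l, t, e, r) and `trait`. Significance
#'   codes: `*` p < 0.05, `**` p < 0.01.
#' @export
combined_anova <- function(book, trait) {
  stopifnot(inherits(book, "fieldbook"))
  if (!trait %in% names(book$plots)) {
    stop("trait '", trait, "' not present in field book", call. = FALSE)
  }
  p <- book$plots[book$plots$role %in% c("testcross", "check", "tester_cross"),
                  , drop = FALSE]
  envs_with_data <- unique(p$env[!is.na(p[[trait]])])
  p <- p[p$env %in% envs_with_data, , drop = FALSE]
  if (nrow(p) == 0L) stop("no observations for trait '", trait, "'",
                          call. = FALSE)
  if (anyNA(p[[trait]])) {
    bad <- p[is.na(p[[trait]]), c("env", "rep", "entry")]
    stop("missing '", trait, "' values within measured environments: ",
         paste(utils::head(paste0("(", bad$env, ", rep ", bad$rep, ", ",
                                  bad$entry, ")"), 5L), collapse = ", "),
         "; complete cell means are required", call. = FALSE)
  }
  .check_balance(p, trait)

  fs <- .factorial_ss(p, trait)
  be <- .block_error_ss(p, trait)
  if (be$df_error <= 0L) {
    stop("zero error degrees of freedom: trial has no residual replication",
         call. = FALSE)
  }
  e_n <- fs$dims[["e"]]; r_n <- fs$dims[["r"]]
  lt <- fs$lt

  src <- c("Env", "Rep(Env)", "Block(Env x Rep)", "Hybrid")
  df <- c(fs$df[["env"]], fs$df[["rep"]], be$df_block, fs$df[["hybrid"]])
  ss <- c(fs$ss[["env"]], fs$ss[["rep"]], be$ss_block, fs$ss[["hybrid"]])
  if (!is.null(lt)) {
    src <- c(src, "Testcross", "Line", "Tester", "Line x Tester")
    df <- c(df, lt$df[["testcross"]], lt$df[["line"]], lt$df[["tester"]],
            lt$df[["lxt"]])
    ss <- c(ss, lt$ss[["testcross"]], lt$ss[["line"]], lt$ss[["tester"]],
            lt$ss[["lxt"]])
  }
  if (e_n > 1L) {
    src <- c(src, "Hybrid x Env")
    df <- c(df, fs$df[["hyb_env"]])
    ss <- c(ss, fs$ss[["hyb_env"]])
    if (!is.null(lt)) {
      src <- c(src, "Line x Env", "Tester x Env", "Line x Tester x Env")
      df <- c(df, lt$df[["line_env"]], lt$df[["tester_env"]],
              lt$df[["lxt_env"]])
      ss <- c(ss, lt$ss[["line_env"]], lt$ss[["tester_env"]],
              lt$ss[["lxt_env"]])
    }
  }
  src <- c(src, "Error")
  df <- c(df, be$df_error)
  ss <- c(ss, be$ss_error)

  ms <- ifelse(df > 0, ss / df, NA_real_)
  names(ms) <- names(ss) <- names(df) <- src

  # testcross x env pooled interaction (internal denominator for Testcross)
  tcxe <- if (e_n > 1L && !is.null(lt)) {
    list(ms = sum(lt$ss[c("line_env", "tester_env", "lxt_env")]) /
           sum(lt$df[c("line_env", "tester_env", "lxt_env")]),
         df = sum(lt$df[c("line_env", "tester_env", "lxt_env")]))
  }

  err_of <- function(source) {
    if (e_n == 1L) {
      if (source %in% c("Env", "Rep(Env)", "Block(Env x Rep)", "Error"))
        return(NULL)
      return(list(term = "Error", ms = ms[["Error"]], df = df[["Error"]]))
    }
    switch(source,
      "Hybrid" = list(term = "Hybrid x Env", ms = ms[["Hybrid x Env"]],
                      df = df[["Hybrid x Env"]]),
      "Testcross" = list(term = "Testcross x Env (pooled)", ms = tcxe$ms,
                         df = tcxe$df),
      "Line" = list(term = "Line x Env", ms = ms[["Line x Env"]],
                    df = df[["Line x Env"]]),
      "Tester" = list(term = "Tester x Env", ms = ms[["Tester x Env"]],
                      df = df[["Tester x Env"]]),
      "Line x Tester" = list(term = "Line x Tester x Env",
                             ms = ms[["Line x Tester x Env"]],
                             df = df[["Line x Tester x Env"]]),
      "Error" = NULL,
      list(term = "Error", ms = ms[["Error"]], df = df[["Error"]])
    )
  }

  f <- p_val <- rep(NA_real_, length(src))
  err_term <- rep(NA_character_, length(src))
  for (i in seq_along(src)) {
    den <- err_of(src[i])
    if (!is.null(den) && !is.na(ms[i]) && !is.na(den$ms) && den$ms > 0 &&
        den$df > 0 && df[i] > 0) {
      f[i] <- ms[i] / den$ms
      p_val[i] <- stats::pf(f[i], df[i], den$df, lower.tail = FALSE)
      err_term[i] <- den$term
    }
  }
  sig <- ifelse(is.na(p_val), "",
                ifelse(p_val < 0.01, "**", ifelse(p_val < 0.05, "*", "")))

  out <- data.frame(source = src, df = as.integer(df), ss = ss, ms = ms,
                    f = f, p = p_val, error_term = err_term, sig = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  dims <- c(l = if (!is.null(lt)) lt$dims[["l"]] else NA_integer_,
            t = if (!is.null(lt)) lt$dims[["t"]] else NA_integer_,
            e = e_n, r = r_n)
  structure(out, class = c("lxt_anova", "data.frame"),
            grand_mean = fs$grand_mean, n_plots = fs$n, dims = dims,
            trait = trait, envs = sort(envs_with_data),
            testcross_env_ms = if (!is.null(tcxe)) tcxe$ms,
            testcross_env_df = if (!is.null(tcxe)) tcxe$df)
}

#' @export
print.lxt_anova <- function(x, ...) {
  cat(sprintf("Combined line x tester ANOVA for '%s'\n", attr(x, "trait")))
  d <- attr(x, "dims")
  cat(sprintf("  %d lines x %d testers, %d environment(s), %d replicate(s); grand mean %.4g\n",
              d[["l"]], d[["t"]], d[["e"]], d[["r"]], attr(x, "grand_mean")))
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6); df$ms <- signif(df$ms, 6)
  df$f <- signif(df$f, 4); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# MS lookup helper
.ms_of <- function(anova, source) {
  i <- match(source, anova$source)
  if (is.na(i)) NA_real_ else anova$ms[i]
}
.df_of <- function(anova, source) {
  i <- match(source, anova$source)
  if (is.na(i)) NA_integer_ else anova$df[i]
}

#' Baker's predictability ratio
#'
#' `2 * (ms_line + ms_tester) / (2 * (ms_line + ms_tester) + ms_sca)`: the
#' share of combining-ability variation attributable to general combining
#' ability. Values near 1 mean hybrid performance is predictable from GCA
#' alone.
#'
#' @param ms_line,ms_tester,ms_sca mean squares for line GCA, tester GCA and
#'   line x tester SCA (all positive); vectors are recycled.
#' @return Ratio in (0, 1].
#' @export
#' @examples
#' baker_ratio(10025419, 21472764, 9365602) # 0.87
baker_ratio <- function(ms_line, ms_tester, ms_sca) {
  if (any(ms_line <= 0 | ms_tester <= 0 | ms_sca <= 0, na.rm = TRUE)) {
    stop("all mean squares must be positive", call. = FALSE)
  }
  ms_gca <- ms_line + ms_tester
  2 * ms_gca / (2 * ms_gca + ms_sca)
}

#' Coefficient of variation from a combined ANOVA
#'
#' `100 * sqrt(MS_error) / grand mean`.
#'
#' @param anova an [combined_anova()] result.
#' @return CV in percent.
#' @export
cv_percent <- function(anova) {
  stopifnot(inherits(anova, "lxt_anova"))
  gm <- attr(anova, "grand_mean")
  if (gm == 0) stop("grand mean is zero; CV undefined", call. = FALSE)
  100 * sqrt(.ms_of(anova, "Error")) / gm
}

#' Method-of-moments variance components for a line x tester trial
#'
#' Equates the observed mean squares of the combined analysis to their
#' balanced-design expectations: `v_sca = (MS_LxT - MS_LxTxE) / (r e)`,
#' `v_gca_line = (MS_Line - MS_LinexE) / (r t e)`,
#' `v_gca_tester = (MS_Tester - MS_TesterxE) / (r l e)`, the x environment
#' components from their contrasts with the three-way interaction, and
#' `v_residual = MS_error`. Negative estimates are truncated to zero and
#' flagged. Standard errors use the large-sample variance of linear
#' combinations of independent mean squares,
#' `Var(MS) = 2 MS^2 / (df + 2)`.
#'
#' @param x a [fieldbook()] or an [combined_anova()] result.
#' @param trait trait name (when `x` is a field book).
#' @param ... unused.
#' @return Object of class `lxt_varcomp`: data.frame with columns
#'   `component`, `estimate` (truncated), `raw`, `se`, `truncated`; attribute
#'   `dims`.
#' @export
variance_components <- function(x, ...) UseMethod("variance_components")

#' @rdname variance_components
#' @export
variance_components.fieldbook <- function(x, trait, ...) {
  variance_components(combined_anova(x, trait))
}

#' @rdname variance_components
#' @export
variance_components.lxt_anova <- function(x, ...) {
  d <- attr(x, "dims")
  l <- d[["l"]]; t_n <- d[["t"]]; e_n <- d[["e"]]; r_n <- d[["r"]]
  if (is.na(l)) stop("no testcross partition in this ANOVA", call. = FALSE)

  grab <- function(source) c(ms = .ms_of(x, source), df = .df_of(x, source))
  msL <- grab("Line"); msT <- grab("Tester"); msLT <- grab("Line x Tester")
  msE <- grab("Error")
  if (e_n > 1L) {
    msLE <- grab("Line x Env"); msTE <- grab("Tester x Env")
    msLTE <- grab("Line x Tester x Env")
  } else {
    msLE <- msTE <- msLTE <- msE
  }

  comp <- function(name, coefs) {
    # coefs: named list of (ms, df, weight)
    est <- sum(vapply(coefs, function(cc) cc$w * cc$ms, 0))
    se <- sqrt(sum(vapply(coefs, function(cc) {
      cc$w^2 * 2 * cc$ms^2 / (cc$df + 2)
    }, 0)))
    data.frame(component = name, raw = est, se = se)
  }
  pair <- function(a, b, div) {
    list(list(ms = a[["ms"]], df = a[["df"]], w = 1 / div),
         list(ms = b[["ms"]], df = b[["df"]], w = -1 / div))
  }

  rows <- rbind(
    comp("v_gca_line", pair(msL, msLE, r_n * t_n * e_n)),
    comp("v_gca_tester", pair(msT, msTE, r_n * l * e_n)),
    comp("v_sca", pair(msLT, msLTE, r_n * e_n)),
    if (e_n > 1L) comp("v_line_env", pair(msLE, msLTE, r_n * t_n)),
    if (e_n > 1L) comp("v_tester_env", pair(msTE, msLTE, r_n * l)),
    if (e_n > 1L) comp("v_sca_env", pair(msLTE, msE, r_n)),
    comp("v_residual",
         list(list(ms = msE[["ms"]], df = msE[["df"]], w = 1)))
  )
  rows$estimate <- pmax(rows$raw, 0)
  rows$truncated <- rows$raw < 0
  rows <- rows[c("component", "estimate", "raw", "se", "truncated")]
  structure(rows, class = c("lxt_varcomp", "data.frame"), dims = d,
            trait = attr(x, "trait"))
}

#' @export
print.lxt_varcomp <- function(x, ...) {
  cat(sprintf("Variance components (method of moments)%s\n",
              if (!is.null(attr(x, "trait")))
                paste0(" for '", attr(x, "trait"), "'") else ""))
  df <- as.data.frame(x)
  df$estimate <- signif(df$estimate, 5)
  df$raw <- signif(df$raw, 5)
  df$se <- signif(df$se, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

.vc_get <- function(vc, name) {
  i <- match(name, vc$component)
  if (is.na(i)) 0 else vc$estimate[i]
}

#' Entry-mean (broad-sense) repeatability
#'
#' `H = v_g / (v_g + v_ge / e + v_residual / (e r))` with
#' `v_g = v_gca_line + v_gca_tester + v_sca` and `v_ge` the sum of the three
#' x environment components: the proportion of variance among testcross means
#' across `e` environments and `r` replicates that is genetic.
#'
#' @param vc an [variance_components()] result, or a named numeric vector of
#'   components.
#' @param e,r numbers of environments and replicates; taken from `vc`'s
#'   dimensions when available.
#' @return Repeatability in \[0, 1\].
#' @export
repeatability <- function(vc, e = NULL, r = NULL) {
  if (inherits(vc, "lxt_varcomp")) {
    d <- attr(vc, "dims")
    if (is.null(e)) e <- d[["e"]]
    if (is.null(r)) r <- d[["r"]]
    v <- stats::setNames(vc$estimate, vc$component)
  } else {
    v <- vc
  }
  if (is.null(e) || is.null(r) || e < 1 || r < 1) {
    stop("numbers of environments and replicates are required", call. = FALSE)
  }
  g <- function(nm) if (nm %in% names(v)) max(v[[nm]], 0) else 0
  v_g <- g("v_gca_line") + g("v_gca_tester") + g("v_sca")
  v_ge <- g("v_line_env") + g("v_tester_env") + g("v_sca_env")
  v_res <- g("v_residual")
  denom <- v_g + v_ge / e + v_res / (e * r)
  if (denom == 0) {
    stop("all variance components are zero; repeatability undefined",
         call. = FALSE)
  }
  v_g / denom
}

#' Proportional contributions of line, tester and line x tester
#'
#' Primary definition: sums of squares of the three genetic sources as
#' percentages of the testcross sum of squares (they add to 100 exactly on
#' balanced data). Secondary definition: shares of the (truncated)
#' method-of-moments variance components. The two are reported side by side
#' and labeled distinctly; they generally differ.
#'
#' @param anova an [combined_anova()] result with the testcross partition.
#' @return data.frame with columns `source`, `ss_pct`, `varcomp_pct`.
#' @export
proportional_contributions <- function(anova) {
  stopifnot(inherits(anova, "lxt_anova"))
  i <- match(c("Testcross", "Line", "Tester", "Line x Tester"), anova$source)
  if (anyNA(i)) stop("ANOVA lacks the testcross partition", call. = FALSE)
  ss <- anova$ss[i]
  if (ss[1L] == 0) stop("testcross sum of squares is zero", call. = FALSE)
  ss_pct <- 100 * ss[2:4] / ss[1L]

  vc <- variance_components(anova)
  vg <- vapply(c("v_gca_line", "v_gca_tester", "v_sca"),
               function(nm) .vc_get(vc, nm), 0)
  vc_pct <- if (sum(vg) > 0) 100 * vg / sum(vg) else rep(NA_real_, 3L)

  data.frame(source = c("Line", "Tester", "Line x Tester"),
             ss_pct = ss_pct, varcomp_pct = unname(vc_pct),
             row.names = NULL)
}
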