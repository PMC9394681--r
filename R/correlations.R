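# Genotypic and phenotypic trait correlations and per-tester genetic
# variances, by method-of-moments ANOVA identities on testcross means.

# Environments in which a trait is recorded for every testcross plot.
.trait_envs <- function(book, trait) {
  p <- book$plots[book$plots$role == "testcross", , drop = FALSE]
  envs <- unique(p$env)
  envs[vapply(envs, function(ev) {
    v <- p[[trait]][p$env == ev]
    length(v) > 0L && !anyNA(v)
  }, TRUE)]
}

# Entry-level mean squares over a balanced entries x environments x reps
# layout: MS between entries and MS entry x environment. `values` may be any
# numeric vector aligned with `p` (a trait or a sum of traits).
.entry_ms <- function(p, values) {
  ef <- factor(p$env); hf <- factor(p$entry)
  e_n <- nlevels(ef); n_h <- nlevels(hf)
  r_n <- length(values) / (e_n * n_h)
  if (abs(r_n - round(r_n)) > 1e-9) {
    stop("unbalanced entry x environment data", call. = FALSE)
  }
  r_n <- round(r_n)
  gm <- mean(values)
  m_h <- tapply(values, hf, mean)
  m_e <- tapply(values, ef, mean)
  m_he <- tapply(values, list(hf, ef), mean)
  if (anyNA(m_he)) stop("unbalanced entry x environment data", call. = FALSE)
  ms_entry <- e_n * r_n * sum((m_h - gm)^2) / (n_h - 1L)
  ms_ge <- if (e_n > 1L) {
    r_n * sum((m_he - outer(m_h, rep(1, e_n)) -
                 outer(rep(1, n_h), m_e) + gm)^2) /
      ((n_h - 1L) * (e_n - 1L))
  } else NA_real_
  list(ms_entry = ms_entry, ms_ge = ms_ge,
       df_entry = n_h - 1L, df_ge = (n_h - 1L) * (e_n - 1L),
       e = e_n, r = r_n, n_entries = n_h)
}

# Genetic variance among entry means: (MS_entry - MS_entry_x_env) / (r e).
.genetic_variance <- function(p, values) {
  ms <- .entry_ms(p, values)
  if (ms$e < 2L) {
    stop("at least two environments are required for a genetic variance",
         call. = FALSE)
  }
  v <- (ms$ms_entry - ms$ms_ge) / (ms$r * ms$e)
  se <- sqrt((2 / (ms$r * ms$e)^2) *
               (ms$ms_entry^2 / (ms$df_entry + 2) +
                  ms$ms_ge^2 / (ms$df_ge + 2)))
  list(variance = v, se = se, ms = ms)
}

.common_env_testcross <- function(book, trait_x, trait_y) {
  envs <- intersect(.trait_envs(book, trait_x), .trait_envs(book, trait_y))
  if (length(envs) == 0L) {
    stop("no common environments with complete data for '", trait_x,
         "' and '", trait_y, "'", call. = FALSE)
  }
  p <- book$plots[book$plots$role == "testcross" & book$plots$env %in% envs,
                  , drop = FALSE]
  list(p = p, envs = envs)
}

#' Phenotypic correlation between two traits
#'
#' Product-moment correlation of testcross pooled means, computed over the
#' environments in which both traits are recorded.
#'
#' @param book a [fieldbook()].
#' @param trait_x,trait_y trait names.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
phenotypic_correlation <- function(book, trait_x, trait_y) {
  ce <- .common_env_testcross(book, trait_x, trait_y)
  mx <- tapply(ce$p[[trait_x]], ce$p$entry, mean)
  my <- tapply(ce$p[[trait_y]], ce$p$entry, mean)
  if (length(mx) < 3L) {
    stop("at least 3 testcross entries are required", call. = FALSE)
  }
  if (stats::sd(mx) == 0 || stats::sd(my) == 0) {
    stop("zero variance in entry means; correlation undefined", call. = FALSE)
  }
  unname(stats::cor(mx, my))
}

#' Genotypic correlation between two traits
#'
#' Method-of-moments estimate `r_g = cov_g / sqrt(v_g(x) v_g(y))` on the
#' common environments. Genetic variances come from the entry-level ANOVA
#' identity `v_g = (MS_entry - MS_entry_x_env) / (r e)`; the genetic
#' covariance applies the same identity to the sum trait `x + y`:
#' `cov_g = (v_g(x + y) - v_g(x) - v_g(y)) / 2`. Estimates with
#' `|r_g| > 1` (possible in small samples) are returned as computed with
#' attribute `out_of_bounds = TRUE`.
#'
#' @param book a [fieldbook()].
#' @param trait_x,trait_y trait names.
#' @return Genotypic correlation coefficient (attribute `out_of_bounds`).
#' @export
genotypic_correlation <- function(book, trait_x, trait_y) {
  ce <- .common_env_testcross(book, trait_x, trait_y)
  p <- ce$p
  gx <- .genetic_variance(p, p[[trait_x]])
  gy <- .genetic_variance(p, p[[trait_y]])
  if (gx$variance <= 0 || gy$variance <= 0) {
    stop("non-positive genetic variance; genotypic correlation undefined",
         call. = FALSE)
  }
  gs <- .genetic_variance(p, p[[trait_x]] + p[[trait_y]])
  cov_g <- (gs$variance - gx$variance - gy$variance) / 2
  r_g <- cov_g / sqrt(gx$variance * gy$variance)
  structure(unname(r_g), out_of_bounds = abs(r_g) > 1)
}

#' Genetic variance among one tester's testcrosses
#'
#' Combined entries x environments analysis of the testcross plots of a single
#' tester: `v_g = (MS_line - MS_line_x_env) / (r e)`, with the large-sample
#' standard error
#' `sqrt((2 / (r e)^2) (MS_line^2 / (df_line + 2) + MS_lxe^2 / (df_lxe + 2)))`.
#' Negative estimates are reported with a truncation flag.
#'
#' @param book a [fieldbook()].
#' @param tester tester entry id (matched against `tester_parent`).
#' @param trait trait name.
#' @return List with `variance` (truncated at zero), `raw`, `se`,
#'   `truncated`, `n_lines`, `envs`.
#' @export
per_tester_genetic_variance <- function(book, tester, trait) {
  p <- book$plots[book$plots$role == "testcross" &
                    book$plots$tester_parent == tester, , drop = FALSE]
  if (nrow(p) == 0L) {
    stop("no testcrosses for tester '", tester, "'", call. = FALSE)
  }
  envs <- .trait_envs(book, trait)
  p <- p[p$env %in% envs & !is.na(p[[trait]]), , drop = FALSE]
  if (length(unique(p$line_parent)) < 2L) {
    stop("at least 2 lines are required", call. = FALSE)
  }
  g <- .genetic_variance(p, p[[trait]])
  list(variance = max(g$variance, 0), raw = g$variance, se = g$se,
       truncated = g$variance < 0,
       n_lines = length(unique(p$line_parent)), envs = envs)
}

#' Genotypic (lower) and phenotypic (upper) correlation matrix
#'
#' Square matrix over the requested traits: genotypic correlations in the
#' lower triangle, phenotypic in the upper triangle, 1 on the diagonal.
#' Genotypic entries that are undefined (non-positive genetic variance) are
#' `NA`.
#'
#' @param book a [fieldbook()].
#' @param traits character vector of trait names.
#' @return Matrix of class `lxt_cor`.
#' @export
trait_correlations <- function(book, traits) {
  k <- length(traits)
  m <- diag(1, k)
  dimnames(m) <- list(traits, traits)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (i > j) {
        m[i, j] <- tryCatch(genotypic_correlation(book, traits[i], traits[j]),
                            error = function(e) NA_real_)
      } else {
        m[i, j] <- tryCatch(phenotypic_correlation(book, traits[i], traits[j]),
                            error = function(e) NA_real_)
      }
    }
  }
  structure(m, class = c("lxt_cor", "matrix"))
}

#' @export
print.lxt_cor <- function(x, digits = 2, ...) {
  cat("Trait correlations: genotypic below diagonal, phenotypic above\n")
  y <- unclass(x)
  print(round(y, digits))
  invisible(x)
}

#' Per-tester evaluation summary
#'
#' For each tester: minimum, mean and maximum of the testcross pooled means
#' per trait, the tester's GCA effect, and the genetic variance (with SE)
#' among its testcrosses. A textual note ranks the testers by positive GCA on
#' the target traits and by the genetic variance among their testcrosses.
#'
#' @param book a [fieldbook()].
#' @param traits trait names; defaults to all traits with data.
#' @param target_traits traits whose positive GCA marks a suitable tester
#'   (default grain yield and provitamin A where present).
#' @return Object of class `tester_evaluation`: list with `stats` (data.frame
#'   `tester`, `trait`, `min`, `mean`, `max`, `gca`, `v_g`, `v_g_se`,
#'   `truncated`) and `notes` (character).
#' @export
tester_summary <- function(book, traits = NULL, target_traits = NULL) {
  stopifnot(inherits(book, "fieldbook"))
  if (is.null(traits)) {
    traits <- book$traits$trait[vapply(book$traits$trait, function(tr) {
      any(!is.na(book$plots[[tr]][book$plots$role == "testcross"]))
    }, TRUE)]
  }
  if (is.null(target_traits)) {
    target_traits <- intersect(c("grain_yield", "pva"), traits)
  }
  testers <- sort(unique(book$entries$tester_parent[
    book$entries$role == "testcross"]))
  multi_env <- length(unique(book$plots$env)) > 1L

  stats_df <- do.call(rbind, lapply(traits, function(tr) {
    tm <- testcross_means(book, tr)
    ca <- gca_sca_effects(tm)
    do.call(rbind, lapply(testers, function(te) {
      v <- tm$means[, te]
      vg <- if (multi_env && sum(!is.na(v)) >= 2L) {
        tryCatch(per_tester_genetic_variance(book, te, tr),
                 error = function(e) NULL)
      } else NULL
      data.frame(tester = te, trait = tr,
                 min = min(v, na.rm = TRUE), mean = mean(v, na.rm = TRUE),
                 max = max(v, na.rm = TRUE),
                 gca = unname(ca$gca_tester[te]),
                 v_g = if (!is.null(vg)) vg$variance else NA_real_,
                 v_g_se = if (!is.null(vg)) vg$se else NA_real_,
                 truncated = if (!is.null(vg)) vg$truncated else NA,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }))

  notes <- vapply(testers, function(te) {
    dd <- stats_df[stats_df$tester == te, , drop = FALSE]
    pos <- dd$trait[dd$trait %in% target_traits & dd$gca > 0]
    vg_rank <- mean(rank(-stats_df$v_g[stats_df$trait %in% target_traits])
                    [stats_df$tester[stats_df$trait %in% target_traits] == te],
                    na.rm = TRUE)
    sprintf(
      "%s: positive GCA for %s; mean genetic-variance rank %.1f on target traits",
      te,
      if (length(pos) > 0L) paste(pos, collapse = ", ") else "none of the target traits",
      vg_rank)
  }, "")

  structure(list(stats = stats_df, notes = unname(notes), testers = testers),
            class = "tester_evaluation")
}

#' @export
print.tester_evaluation <- function(x, ...) {
  cat("Tester evaluation\n")
  df <- x$stats
  for (col in c("min", "mean", "max", "gca", "v_g", "v_g_se")) {
    df[[col]] <- signif(df[[col]], 4)
  }
  print(df, row.names = FALSE)
  cat("\n")
  for (n in x$notes) cat(" -", n, "\n")
  invisible(x)
}
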