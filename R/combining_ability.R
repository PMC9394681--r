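# GCA/SCA estimation from pooled testcross means.
#
# On balanced data the row/column/grand-mean decomposition of the l x t mean
# matrix coincides with constrained least squares under zero-sum constraints:
#   g_i = row mean - grand mean, g_j = column mean - grand mean,
#   s_ij = cell - row mean - column mean + grand mean,
# so mu + g_i + g_j + s_ij reconstructs every cell exactly.

#' General and specific combining ability effects
#'
#' Estimates line GCA, tester GCA and the SCA matrix from a complete matrix of
#' pooled testcross means. GCA vectors sum to zero; every SCA row and column
#' sums to zero; `mu + g_i + g_j + s_ij` reproduces the cell means exactly.
#' When a [combined_anova()] result is supplied, standard errors, t tests
#' (against each source's x environment mean square, the denominator of the
#' random-environment model) and significance codes are attached.
#'
#' @param means a [testcross_means()] result (pooled) or an l x t numeric
#'   matrix with line rownames and tester colnames.
#' @param anova optional [combined_anova()] for the same trait, used for
#'   standard errors and significance.
#' @return Object of class `combining_ability`: list with `mu`, `gca_line`,
#'   `gca_tester`, `sca`, and (when `anova` is given) `se` and `tests`
#'   (per-effect effect, SE, t, p, significance code).
#' @export
gca_sca_effects <- function(means, anova = NULL) {
  m <- if (inherits(means, "testcross_means")) {
    if (means$level != "pooled") {
      stop("pooled testcross means are required", call. = FALSE)
    }
    means$means
  } else {
    as.matrix(means)
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    cells <- paste0("(", rownames(m)[bad[, 1L]] %||% bad[, 1L], ", ",
                    colnames(m)[bad[, 2L]] %||% bad[, 2L], ")")
    stop("incomplete testcross mean matrix; missing cells: ",
         paste(utils::head(cells, 10L), collapse = ", "), call. = FALSE)
  }
  mu <- mean(m)
  gl <- rowMeans(m) - mu
  gt <- colMeans(m) - mu
  sca <- sweep(m, 1L, rowMeans(m)) - outer(rep(1, nrow(m)), colMeans(m)) + mu

  out <- structure(
    list(mu = mu, gca_line = gl, gca_tester = gt, sca = sca,
         se = NULL, tests = NULL),
    class = "combining_ability"
  )
  if (!is.null(anova)) {
    se <- effect_standard_errors(anova)
    star <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
    tt <- function(effect, s, df) {
      t_stat <- effect / s
      p <- 2 * stats::pt(-abs(t_stat), df)
      data.frame(effect = effect, se = s, t = t_stat, p = p,
                 sig = star(p), stringsAsFactors = FALSE)
    }
    out$se <- se
    out$tests <- list(
      gca_line = cbind(line = names(gl),
                       tt(unname(gl), se$se_gca_line, se$df_gca_line)),
      gca_tester = cbind(tester = names(gt),
                         tt(unname(gt), se$se_gca_tester, se$df_gca_tester)),
      sca = {
        idx <- expand.grid(line = rownames(sca), tester = colnames(sca),
                           stringsAsFactors = FALSE)
        cbind(idx, tt(as.vector(sca), se$se_sca, se$df_sca))
      }
    )
  }
  out
}

#' @export
print.combining_ability <- function(x, ...) {
  cat(sprintf("Combining ability estimates (grand mean %.4g)\n", x$mu))
  cat(sprintf("  %d lines, %d testers\n", length(x$gca_line),
              length(x$gca_tester)))
  cat("  tester GCA:", paste(sprintf("%s = %.4g", names(x$gca_tester),
                                     x$gca_tester), collapse = ", "), "\n")
  lr <- range(x$gca_line)
  cat(sprintf("  line GCA range: [%.4g, %.4g]\n", lr[1L], lr[2L]))
  sr <- range(x$sca)
  cat(sprintf("  SCA range: [%.4g, %.4g]\n", sr[1L], sr[2L]))
  if (!is.null(x$se)) {
    cat(sprintf("  SE(gca line) %.4g | SE(gca tester) %.4g | SE(sca) %.4g\n",
                x$se$se_gca_line, x$se$se_gca_tester, x$se$se_sca))
  }
  invisible(x)
}

#' Standard errors for GCA and SCA effects
#'
#' Standard line x tester formulas with the random-environment denominators:
#' `se_gca_line = sqrt(MS_LinexEnv / (r e t))`,
#' `se_gca_tester = sqrt(MS_TesterxEnv / (r e l))`,
#' `se_sca = sqrt(MS_LxTxEnv / (r e))`; with a single environment the pooled
#' error mean square is used throughout. The degrees of freedom of each
#' denominator accompany the SEs for t tests.
#'
#' @param anova an [combined_anova()] result.
#' @param dims optional named vector `c(l, t, e, r)` overriding the ANOVA's
#'   dimensions.
#' @return List with `se_gca_line`, `se_gca_tester`, `se_sca` and matching
#'   `df_*` entries.
#' @export
effect_standard_errors <- function(anova, dims = NULL) {
  stopifnot(inherits(anova, "lxt_anova"))
  d <- dims %||% attr(anova, "dims")
  l <- d[["l"]]; t_n <- d[["t"]]; e_n <- d[["e"]]; r_n <- d[["r"]]
  if (e_n > 1L) {
    msL <- .ms_of(anova, "Line x Env"); dfL <- .df_of(anova, "Line x Env")
    msT <- .ms_of(anova, "Tester x Env"); dfT <- .df_of(anova, "Tester x Env")
    msS <- .ms_of(anova, "Line x Tester x Env")
    dfS <- .df_of(anova, "Line x Tester x Env")
  } else {
    msL <- msT <- msS <- .ms_of(anova, "Error")
    dfL <- dfT <- dfS <- .df_of(anova, "Error")
  }
  if (any(c(dfL, dfT, dfS) <= 0)) {
    stop("zero degrees of freedom in the SE denominator", call. = FALSE)
  }
  list(
    se_gca_line = sqrt(msL / (r_n * e_n * t_n)), df_gca_line = dfL,
    se_gca_tester = sqrt(msT / (r_n * e_n * l)), df_gca_tester = dfT,
    se_sca = sqrt(msS / (r_n * e_n)), df_sca = dfS
  )
}

#' Additive vs non-additive genetic variance partition
#'
#' Additive share `= 2 (v_gca_line + v_gca_tester) /
#' (2 (v_gca_line + v_gca_tester) + v_sca)` in percent (the factor 2 converts
#' GCA variance to additive variance under the testcross model); the
#' non-additive share is the complement.
#'
#' @param vc an [variance_components()] result or named numeric vector with
#'   `v_gca_line`, `v_gca_tester`, `v_sca`.
#' @return Named numeric vector `c(additive_pct, nonadditive_pct)`.
#' @export
additive_nonadditive_partition <- function(vc) {
  v <- if (inherits(vc, "lxt_varcomp")) {
    stats::setNames(vc$estimate, vc$component)
  } else vc
  g <- function(nm) if (nm %in% names(v)) max(v[[nm]], 0) else 0
  gca2 <- 2 * (g("v_gca_line") + g("v_gca_tester"))
  sca <- g("v_sca")
  if (gca2 + sca == 0) {
    stop("all genetic variance components are zero; partition undefined",
         call. = FALSE)
  }
  add <- 100 * gca2 / (gca2 + sca)
  c(additive_pct = add, nonadditive_pct = 100 - add)
}
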