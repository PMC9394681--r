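# Standard heterosis against the inter-tester reference hybrid, and
# LSD-based comparison of entries with a check.

#' Standard heterosis
#'
#' `100 * (F1 - CK) / CK`: percentage superiority of a testcross over the
#' reference hybrid (the cross between the two testers). Scale-invariant in
#' the common unit of `f1` and `ck`.
#'
#' @param f1 testcross trait mean(s).
#' @param ck reference (check) trait mean; must be non-zero.
#' @return Heterosis in percent.
#' @export
standard_heterosis <- function(f1, ck) {
  if (any(ck == 0, na.rm = TRUE)) {
    stop("reference mean is zero; heterosis undefined", call. = FALSE)
  }
  100 * (f1 - ck) / ck
}

# Pooled entry means (over all plots) for a set of roles.
.entry_pooled_means <- function(book, trait,
                                roles = c("testcross", "check",
                                          "tester_cross"),
                                envs = NULL) {
  p <- book$plots[book$plots$role %in% roles, , drop = FALSE]
  if (!is.null(envs)) p <- p[p$env %in% envs, , drop = FALSE]
  p <- p[!is.na(p[[trait]]), , drop = FALSE]
  tapply(p[[trait]], p$entry, mean)
}

#' Standard heterosis table
#'
#' One record per testcross and trait: the testcross pooled mean (F1), the
#' reference-hybrid pooled mean (CK) and `H = 100 (F1 - CK) / CK`. Counts of
#' testcrosses with heterosis at or above each requested threshold are
#' attached per trait as attribute `counts`.
#'
#' @param book a [fieldbook()].
#' @param reference entry id of the reference hybrid; defaults to the entry
#'   with role `tester_cross`.
#' @param traits trait names; defaults to all traits with data.
#' @param thresholds numeric heterosis thresholds (percent) for the counts
#'   (default 0 and 10).
#' @return data.frame with columns `entry`, `tester`, `trait`, `f1`, `ck`,
#'   `h_percent`; attribute `counts`.
#' @export
heterosis_table <- function(book, reference = NULL, traits = NULL,
                            thresholds = c(0, 10)) {
  stopifnot(inherits(book, "fieldbook"))
  if (is.null(reference)) {
    reference <- book$entries$entry[book$entries$role == "tester_cross"]
    if (length(reference) != 1L) {
      stop("no unique tester_cross reference hybrid; supply `reference`",
           call. = FALSE)
    }
  }
  if (!reference %in% book$entries$entry) {
    stop("reference entry '", reference, "' not present", call. = FALSE)
  }
  if (is.null(traits)) {
    traits <- book$traits$trait[vapply(book$traits$trait, function(tr) {
      any(!is.na(book$plots[[tr]]))
    }, TRUE)]
  }
  tc_entries <- book$entries[book$entries$role == "testcross", , drop = FALSE]
  out <- do.call(rbind, lapply(traits, function(tr) {
    m <- .entry_pooled_means(book, tr)
    if (!reference %in% names(m) || is.na(m[[reference]])) {
      stop("reference entry has no '", tr, "' data", call. = FALSE)
    }
    ck <- m[[reference]]
    f1 <- m[tc_entries$entry]
    data.frame(entry = tc_entries$entry, tester = tc_entries$tester_parent,
               trait = tr, f1 = unname(f1), ck = ck,
               h_percent = unname(standard_heterosis(f1, ck)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  counts <- do.call(rbind, lapply(split(out, out$trait), function(dd) {
    do.call(rbind, lapply(thresholds, function(th) {
      data.frame(trait = dd$trait[1L], threshold = th,
                 n_at_least = sum(!is.na(dd$h_percent) & dd$h_percent >= th &
                                    (th > 0 | dd$h_percent > 0)),
                 row.names = NULL)
    }))
  }))
  rownames(counts) <- NULL
  structure(out, counts = counts)
}

#' Classify entries against a check by least significant difference
#'
#' Two-sided LSD at level `alpha` from the combined-analysis pooled error:
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 MS_error / (r e))`. Entries whose
#' pooled mean differs from the check mean by more than the LSD are classified
#' `higher` or `lower`; otherwise `equal`. No multiplicity correction is
#' applied.
#'
#' @param book a [fieldbook()].
#' @param check_id entry id of the check.
#' @param trait trait name.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `entry`, `mean`, `diff`, `class`;
#'   attributes `lsd`, `check_mean`.
#' @export
compare_to_check <- function(book, check_id, trait, alpha = 0.05) {
  stopifnot(inherits(book, "fieldbook"))
  if (!check_id %in% book$entries$entry) {
    stop("check entry '", check_id, "' not present", call. = FALSE)
  }
  an <- combined_anova(book, trait)
  d <- attr(an, "dims")
  ms_err <- .ms_of(an, "Error"); df_err <- .df_of(an, "Error")
  lsd <- stats::qt(1 - alpha / 2, df_err) *
    sqrt(2 * ms_err / (d[["r"]] * d[["e"]]))
  m <- .entry_pooled_means(book, trait)
  if (!check_id %in% names(m)) {
    stop("check entry has no '", trait, "' data", call. = FALSE)
  }
  ck <- m[[check_id]]
  entries <- setdiff(names(m), check_id)
  diffs <- m[entries] - ck
  cls <- ifelse(abs(diffs) <= lsd, "equal",
                ifelse(diffs > 0, "higher", "lower"))
  structure(
    data.frame(entry = entries, mean = unname(m[entries]),
               diff = unname(diffs), class = unname(cls),
               row.names = NULL, stringsAsFactors = FALSE),
    lsd = lsd, check_mean = ck, alpha = alpha
  )
}
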