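# Publication-style report bundle: every table is delimited text rendered
# from module outputs under one rounding rule (two decimals, half-to-even);
# the renderer never recomputes statistics.

.render_num <- function(df, digits = 2L) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- round_report(df[[col]], digits)
  }
  df
}

.write_tab <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

#' Run the full line x tester analysis and write a report bundle
#'
#' Runs the requested stages on a field book (or on a freshly simulated one
#' when a [trial_config()] is given instead) and writes delimited-text tables
#' to `out_dir`: per-trait combined ANOVA tables with significance codes,
#' a tester GCA table across traits, per-trait line GCA and SCA tables,
#' the standard-heterosis table, the genotypic/phenotypic correlation matrix,
#' the per-tester evaluation summary, and the additive/non-additive variance
#' partition. A `run_log.txt` records the package version, seed and settings,
#' so the bundle is regenerable from the configuration alone; rendered
#' numbers are module outputs rounded half-to-even at two decimals.
#'
#' @param book a [fieldbook()], or `NULL` to simulate from `config`.
#' @param out_dir output directory (created if needed).
#' @param traits traits to analyse; default all traits with data.
#' @param stages subset of `c("anova", "gca", "heterosis", "correlations",
#'   "testers", "partition")`.
#' @param reference reference hybrid id for heterosis (default the
#'   `tester_cross` entry).
#' @param config optional [trial_config()] used when `book` is `NULL`.
#' @param seed seed for the simulation stage.
#' @return Invisible list of written file paths and the in-memory results.
#' @export
run_report <- function(book = NULL, out_dir,
                       traits = NULL,
                       stages = c("anova", "gca", "heterosis",
                                  "correlations", "testers", "partition"),
                       reference = NULL, config = NULL, seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(book)) {
    if (is.null(config)) stop("supply a field book or a config", call. = FALSE)
    book <- simulate_trial(config, seed = seed %||% config$seed)$book
  }
  stopifnot(inherits(book, "fieldbook"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(traits)) {
    traits <- book$traits$trait[vapply(book$traits$trait, function(tr) {
      any(!is.na(book$plots[[tr]][book$plots$role == "testcross"]))
    }, TRUE)]
    # analyse on the derived scale, not the raw weight/moisture inputs
    traits <- setdiff(traits, c("grain_weight", "grain_moisture"))
  }
  files <- character()
  results <- list()

  anovas <- list()
  if (any(c("anova", "gca", "partition") %in% stages)) {
    for (tr in traits) {
      anovas[[tr]] <- combined_anova(book, tr)
    }
  }
  if ("anova" %in% stages) {
    for (tr in traits) {
      an <- anovas[[tr]]
      df <- as.data.frame(an)
      df$ms <- paste0(round_report(df$ms), df$sig)
      out <- df[c("source", "df", "ss", "ms", "f", "p", "error_term")]
      out$ss <- round_report(out$ss); out$f <- round_report(out$f)
      out$p <- signif(out$p, 3)
      extra <- data.frame(
        source = c("Grand mean", "CV (%)", "Repeatability", "Baker ratio"),
        df = NA, ss = NA,
        ms = round_report(c(attr(an, "grand_mean"), cv_percent(an),
                            repeatability(variance_components(an)),
                            baker_ratio(.ms_of(an, "Line"),
                                        .ms_of(an, "Tester"),
                                        .ms_of(an, "Line x Tester")))),
        f = NA, p = NA, error_term = NA)
      out <- rbind(out, extra)
      files <- c(files, .write_tab(out, file.path(out_dir,
                                                  paste0("anova_", tr, ".csv"))))
    }
    results$anova <- anovas
  }

  if ("gca" %in% stages) {
    tester_rows <- list()
    for (tr in traits) {
      ca <- gca_sca_effects(testcross_means(book, tr), anova = anovas[[tr]])
      gl <- .render_num(ca$tests$gca_line)
      files <- c(files, .write_tab(gl, file.path(out_dir,
                                                 paste0("gca_lines_", tr, ".csv"))))
      sc <- .render_num(ca$tests$sca)
      files <- c(files, .write_tab(sc, file.path(out_dir,
                                                 paste0("sca_", tr, ".csv"))))
      tg <- ca$tests$gca_tester
      tester_rows[[tr]] <- data.frame(
        trait = tr,
        t(stats::setNames(paste0(round_report(tg$effect), tg$sig), tg$tester)),
        check.names = FALSE)
      results$gca[[tr]] <- ca
    }
    files <- c(files, .write_tab(do.call(rbind, tester_rows),
                                 file.path(out_dir, "gca_testers.csv")))
  }

  if ("heterosis" %in% stages) {
    ht <- heterosis_table(book, reference = reference, traits = traits)
    files <- c(files, .write_tab(.render_num(as.data.frame(ht)),
                                 file.path(out_dir, "heterosis.csv")))
    results$heterosis <- ht
  }

  if ("correlations" %in% stages) {
    cm <- trait_correlations(book, traits)
    out <- data.frame(trait = rownames(cm),
                      round_report(unclass(cm)), check.names = FALSE)
    files <- c(files, .write_tab(out, file.path(out_dir, "correlations.csv")))
    results$correlations <- cm
  }

  if ("testers" %in% stages) {
    ts <- tester_summary(book, traits = traits)
    files <- c(files, .write_tab(.render_num(ts$stats),
                                 file.path(out_dir, "tester_summary.csv")))
    writeLines(ts$notes, file.path(out_dir, "tester_notes.txt"))
    files <- c(files, file.path(out_dir, "tester_notes.txt"))
    results$testers <- ts
  }

  if ("partition" %in% stages) {
    part <- do.call(rbind, lapply(traits, function(tr) {
      vc <- variance_components(anovas[[tr]])
      pp <- additive_nonadditive_partition(vc)
      pc <- proportional_contributions(anovas[[tr]])
      data.frame(trait = tr,
                 additive_pct = pp[["additive_pct"]],
                 nonadditive_pct = pp[["nonadditive_pct"]],
                 line_ss_pct = pc$ss_pct[1L], tester_ss_pct = pc$ss_pct[2L],
                 lxt_ss_pct = pc$ss_pct[3L], row.names = NULL)
    }))
    files <- c(files, .write_tab(.render_num(part),
                                 file.path(out_dir, "additive_partition.csv")))
    results$partition <- part
  }

  log_lines <- c(
    paste0("lxtrial version: ",
           as.character(utils::packageVersion("lxtrial"))),
    paste0("seed: ", seed %||% "none"),
    paste0("stages: ", paste(stages, collapse = ", ")),
    paste0("traits: ", paste(traits, collapse = ", ")),
    "rounding: 2 decimals, half-to-even",
    "significance: * p<0.05, ** p<0.01",
    sprintf("design: %d lines x %d testers, %d envs, %d reps",
            book$design$n_lines, book$design$n_testers,
            book$design$n_envs, book$design$n_reps)
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  files <- c(files, file.path(out_dir, "run_log.txt"))

  invisible(list(files = files, results = results))
}
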