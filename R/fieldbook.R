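#' @keywords internal
"_PACKAGE"

# Canonical trait registry: units, measured/derived status and legal ranges.
# Score traits (1-5 visual ratings) carry inclusive bounds; concentrations and
# moisture carry non-negativity / percentage constraints enforced at validation.
.trait_registry <- function() {
  data.frame(
    trait = c("grain_weight", "grain_moisture", "dyanth", "dysk", "pht", "eht",
              "pasp", "easp", "lutein", "zeaxanthin", "beta_cryptoxanthin",
              "alpha_carotene", "beta_carotene",
              "grain_yield", "asi", "pva", "total_carotenoid"),
    units = c("kg/plot", "%", "days", "days", "cm", "cm", "score 1-5",
              "score 1-5", rep("ug/g DW", 5),
              "kg/ha", "days", "ug/g DW", "ug/g DW"),
    kind = c(rep("measured", 13), rep("derived", 4)),
    derived_by = c(rep(NA_character_, 13),
                   "yield_at_15pct", "anthesis_silking_interval",
                   "provitamin_a", "total_carotenoid"),
    lower = c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0, -Inf, 0, 0),
    upper = c(Inf, 100, Inf, Inf, Inf, Inf, 5, 5, rep(Inf, 5),
              Inf, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

.roles <- c("line", "tester", "testcross", "check", "tester_cross")
.plot_key_cols <- c("env", "rep", "block", "entry")
.meta_cols <- c("env", "rep", "block", "entry", "role",
                "line_parent", "tester_parent")

#' Construct a line-by-tester field book
#'
#' A field book holds one row per plot of a multi-environment line x tester
#' trial: environment (location-year), replicate, incomplete block within
#' replicate, entry, the entry's role (`testcross`, `check`, or `tester_cross`
#' for the inter-tester reference hybrid), its parents, and one column per
#' trait. Missing trait values stay `NA` and are never silently zeroed.
#'
#' @param plots data.frame with columns `env`, `rep`, `block`, `entry`,
#'   `role`, optionally `line_parent` and `tester_parent`, plus numeric trait
#'   columns.
#' @param traits optional data.frame of trait specifications (`trait`,
#'   `units`, `kind`, `lower`, `upper`); unknown traits default to measured
#'   with unrestricted range.
#' @param validate logical; run [validate_fieldbook()] (default `TRUE`).
#' @return An object of class `fieldbook` with components `plots`, `entries`,
#'   `traits` and `design` (counts of lines, testers, environments, replicates
#'   and the block size).
#' @seealso [read_fieldbook()], [write_fieldbook()], [testcross_means()]
#' @export
fieldbook <- function(plots, traits = NULL, validate = TRUE) {
  stopifnot(is.data.frame(plots))
  plots <- as.data.frame(plots, stringsAsFactors = FALSE)
  need <- c("env", "rep", "block", "entry", "role")
  miss <- setdiff(need, names(plots))
  if (length(miss) > 0L) {
    stop("field book is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"line_parent" %in% names(plots)) plots$line_parent <- NA_character_
  if (!"tester_parent" %in% names(plots)) plots$tester_parent <- NA_character_
  for (col in c("env", "block", "entry", "role", "line_parent", "tester_parent")) {
    plots[[col]] <- as.character(plots[[col]])
  }
  plots$rep <- as.integer(plots$rep)

  trait_cols <- setdiff(names(plots), .meta_cols)
  for (col in trait_cols) {
    if (!is.numeric(plots[[col]])) {
      stop("trait column '", col, "' is not numeric", call. = FALSE)
    }
    plots[[col]] <- as.numeric(plots[[col]])
  }
  plots <- plots[c(.meta_cols, trait_cols)]

  if (is.null(traits)) {
    reg <- .trait_registry()
    traits <- data.frame(trait = trait_cols, stringsAsFactors = FALSE)
    idx <- match(trait_cols, reg$trait)
    traits$units <- ifelse(is.na(idx), "", reg$units[idx])
    traits$kind <- ifelse(is.na(idx), "measured", reg$kind[idx])
    traits$derived_by <- ifelse(is.na(idx), NA_character_, reg$derived_by[idx])
    traits$lower <- ifelse(is.na(idx), -Inf, reg$lower[idx])
    traits$upper <- ifelse(is.na(idx), Inf, reg$upper[idx])
  }

  entries <- unique(plots[c("entry", "role", "line_parent", "tester_parent")])
  rownames(entries) <- NULL

  tc <- entries[entries$role == "testcross", , drop = FALSE]
  design <- list(
    n_lines = length(unique(tc$line_parent[!is.na(tc$line_parent)])),
    n_testers = length(unique(tc$tester_parent[!is.na(tc$tester_parent)])),
    n_envs = length(unique(plots$env)),
    n_reps = length(unique(plots$rep)),
    block_size = if (nrow(plots) > 0L) {
      as.integer(round(stats::median(table(interaction(
        plots$env, plots$rep, plots$block, drop = TRUE)))))
    } else NA_integer_
  )

  book <- structure(
    list(plots = plots, entries = entries, traits = traits, design = design),
    class = "fieldbook"
  )
  if (validate) validate_fieldbook(book)
  book
}

#' Validate a field book against its structural invariants
#'
#' Checks plot-key uniqueness, role tokens, testcross parentage (both parents
#' present, parent pairs unique), a single inter-tester reference hybrid at
#' most, moisture within 0-100%, non-negative concentrations, and score traits
#' inside their declared 1-5 bounds.
#'
#' @param book a [fieldbook()] object.
#' @return `book`, invisibly; errors describe the offending rows or cells.
#' @export
validate_fieldbook <- function(book) {
  stopifnot(inherits(book, "fieldbook"))
  plots <- book$plots

  key <- interaction(plots$env, plots$rep, plots$block, plots$entry, drop = TRUE)
  if (anyDuplicated(key)) {
    dup <- which(key %in% key[duplicated(key)])
    stop("duplicate plot key (env, rep, block, entry) at rows: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  bad_role <- setdiff(unique(plots$role), .roles)
  if (length(bad_role) > 0L) {
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "),
         "; expected one of ", paste(.roles, collapse = ", "), call. = FALSE)
  }

  ent <- book$entries
  tc <- ent[ent$role == "testcross", , drop = FALSE]
  if (nrow(tc) > 0L) {
    orphan <- is.na(tc$line_parent) | is.na(tc$tester_parent)
    if (any(orphan)) {
      stop("testcross entries without both parents: ",
           paste(tc$entry[orphan], collapse = ", "), call. = FALSE)
    }
    pair <- paste(tc$line_parent, tc$tester_parent, sep = " x ")
    if (anyDuplicated(pair)) {
      stop("duplicate (line_parent, tester_parent) pairs among testcrosses: ",
           paste(unique(pair[duplicated(pair)]), collapse = ", "),
           call. = FALSE)
    }
  }
  if (sum(ent$role == "tester_cross") > 1L) {
    stop("more than one tester_cross reference hybrid present", call. = FALSE)
  }

  for (i in seq_len(nrow(book$traits))) {
    tr <- book$traits$trait[i]
    if (!tr %in% names(plots)) {
      stop("trait '", tr, "' declared but absent from plot table", call. = FALSE)
    }
    v <- plots[[tr]]
    lo <- book$traits$lower[i]; hi <- book$traits$upper[i]
    out <- which(!is.na(v) & (v < lo | v > hi))
    if (length(out) > 0L) {
      stop("trait '", tr, "' outside [", lo, ", ", hi, "] at rows: ",
           paste(utils::head(out, 10L), collapse = ", "), call. = FALSE)
    }
  }
  invisible(book)
}

#' @export
print.fieldbook <- function(x, ...) {
  d <- x$design
  cat("Line x tester field book\n")
  cat(sprintf("  %d plots | %d entries (%d testcrosses, %d checks, %d tester cross)\n",
              nrow(x$plots), nrow(x$entries),
              sum(x$entries$role == "testcross"),
              sum(x$entries$role == "check"),
              sum(x$entries$role == "tester_cross")))
  cat(sprintf("  design: %d lines x %d testers, %d environment(s), %d replicate(s), block size %s\n",
              d$n_lines, d$n_testers, d$n_envs, d$n_reps,
              ifelse(is.na(d$block_size), "?", d$block_size)))
  cat("  traits:", paste(x$traits$trait, collapse = ", "), "\n")
  invisible(x)
}

#' Read a field book from delimited text
#'
#' Expects a header row and one row per plot. Comma and tab delimiters are
#' auto-detected (comma default). Empty fields are read as missing trait
#' values. Non-numeric trait cells, duplicate plot keys and unknown role
#' tokens are rejected with their locations.
#'
#' @param path file path.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(env = "ENV", entry = "GEN")`.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @return A validated [fieldbook()].
#' @export
read_fieldbook <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      j <- match(schema[[canon]], names(raw))
      if (is.na(j)) {
        stop("schema column '", schema[[canon]], "' not found in file",
             call. = FALSE)
      }
      names(raw)[j] <- canon
    }
  }
  need <- c("env", "rep", "block", "entry", "role")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trait_cols <- setdiff(names(raw), .meta_cols)
  for (col in trait_cols) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0L) {
      stop("non-numeric value in trait column '", col, "' at data row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "),
           " (value '", v[bad[1L]], "')", call. = FALSE)
    }
    raw[[col]] <- num
  }
  if (!"line_parent" %in% names(raw)) raw$line_parent <- NA_character_
  if (!"tester_parent" %in% names(raw)) raw$tester_parent <- NA_character_
  fieldbook(raw)
}

#' Write a field book to delimited text
#'
#' Values are printed at full precision (17 significant digits) so that
#' [read_fieldbook()] inverts the file exactly; missing values become empty
#' fields.
#'
#' @param book a [fieldbook()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_fieldbook <- function(book, path, sep = ",") {
  stopifnot(inherits(book, "fieldbook"))
  out <- book$plots
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && col != "rep") {
      v <- ifelse(is.na(out[[col]]), "", sprintf("%.17g", out[[col]]))
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

# Internal: testcross plot subset for a trait, with env restriction.
.testcross_plots <- function(book, trait, envs = NULL) {
  p <- book$plots[book$plots$role == "testcross", , drop = FALSE]
  if (!trait %in% names(p)) {
    stop("trait '", trait, "' not present in field book", call. = FALSE)
  }
  if (!is.null(envs)) p <- p[p$env %in% envs, , drop = FALSE]
  p
}

#' Testcross mean matrix
#'
#' Arithmetic means of a trait per (line, tester) cell, either pooled across
#' environments or per environment. Pooled means are plot-level means by
#' default (`pooling = "plot"`); `pooling = "env_mean"` averages the
#' per-environment means instead. The two agree exactly on balanced data.
#' Cells with no observations are returned as `NA` and listed in the
#' `missing_cells` component rather than dropped.
#'
#' @param book a [fieldbook()].
#' @param trait trait name.
#' @param level `"pooled"` (default) for an l x t matrix, or
#'   `"per_environment"` for an l x t x e array.
#' @param pooling pooled-mean convention, `"plot"` or `"env_mean"`.
#' @return Object of class `testcross_means`: list with `means` (matrix or
#'   array), `counts` (cell support), `trait`, `level`, `pooling`,
#'   `missing_cells`.
#' @export
testcross_means <- function(book, trait,
                            level = c("pooled", "per_environment"),
                            pooling = c("plot", "env_mean")) {
  level <- match.arg(level)
  pooling <- match.arg(pooling)
  p <- .testcross_plots(book, trait)
  if (nrow(p) == 0L) stop("no testcross plots in field book", call. = FALSE)
  p <- p[!is.na(p[[trait]]), , drop = FALSE]
  lines <- sort(unique(book$entries$line_parent[book$entries$role == "testcross"]))
  testers <- sort(unique(book$entries$tester_parent[book$entries$role == "testcross"]))
  envs <- sort(unique(book$plots$env[book$plots$role == "testcross" &
                                       !is.na(book$plots[[trait]])]))

  lf <- factor(p$line_parent, levels = lines)
  tf <- factor(p$tester_parent, levels = testers)
  ef <- factor(p$env, levels = envs)

  if (level == "per_environment") {
    m <- tapply(p[[trait]], list(lf, tf, ef), mean)
    n <- tapply(p[[trait]], list(lf, tf, ef), length)
    n[is.na(n)] <- 0L
  } else if (pooling == "plot") {
    m <- tapply(p[[trait]], list(lf, tf), mean)
    n <- tapply(p[[trait]], list(lf, tf), length)
    n[is.na(n)] <- 0L
  } else {
    me <- tapply(p[[trait]], list(lf, tf, ef), mean)
    m <- apply(me, c(1, 2), mean, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    n <- apply(!is.na(me), c(1, 2), sum)
  }
  missing_cells <- which(n == 0L, arr.ind = TRUE)
  structure(
    list(means = m, counts = n, trait = trait, level = level,
         pooling = pooling, envs = envs,
         missing_cells = missing_cells),
    class = "testcross_means"
  )
}

#' @export
print.testcross_means <- function(x, ...) {
  cat(sprintf("Testcross means for '%s' (%s%s)\n", x$trait, x$level,
              if (x$level == "pooled") paste0(", ", x$pooling, " pooling") else ""))
  cat(sprintf("  %d lines x %d testers", dim(x$means)[1L], dim(x$means)[2L]))
  if (x$level == "per_environment") cat(sprintf(" x %d environments", dim(x$means)[3L]))
  cat("\n")
  if (nrow(x$missing_cells) > 0L) {
    cat("  ", nrow(x$missing_cells), "cell(s) with no observations\n")
  }
  invisible(x)
}
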