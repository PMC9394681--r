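# Deterministic per-plot derived traits.
#
# Provitamin A counts beta-carotene in full and the two mono-hydroxylated
# precursors (beta-cryptoxanthin, alpha-carotene) at half weight, reflecting
# their single provitamin-active ring; lutein and zeaxanthin have none.

#' Provitamin A concentration
#'
#' `beta_carotene + 0.5 * (beta_cryptoxanthin + alpha_carotene)`, all in
#' ug/g dry weight.
#'
#' @param beta_carotene,beta_cryptoxanthin,alpha_carotene concentrations
#'   (ug/g DW); vectors are recycled to a common length.
#' @return Provitamin A concentration, ug/g DW. `NA` propagates.
#' @export
#' @examples
#' provitamin_a(7.49, 4.59, 0.89) # 10.23
provitamin_a <- function(beta_carotene, beta_cryptoxanthin, alpha_carotene) {
  .check_nonneg(beta_carotene, "beta_carotene")
  .check_nonneg(beta_cryptoxanthin, "beta_cryptoxanthin")
  .check_nonneg(alpha_carotene, "alpha_carotene")
  beta_carotene + 0.5 * (beta_cryptoxanthin + alpha_carotene)
}

#' Total carotenoid concentration
#'
#' Sum of lutein, zeaxanthin, beta-cryptoxanthin, alpha-carotene and
#' beta-carotene concentrations (ug/g DW).
#'
#' @param lutein,zeaxanthin,beta_cryptoxanthin,alpha_carotene,beta_carotene
#'   concentrations (ug/g DW).
#' @return Total carotenoid concentration, ug/g DW.
#' @export
total_carotenoid <- function(lutein, zeaxanthin, beta_cryptoxanthin,
                             alpha_carotene, beta_carotene) {
  for (nm in c("lutein", "zeaxanthin", "beta_cryptoxanthin",
               "alpha_carotene", "beta_carotene")) {
    .check_nonneg(get(nm), nm)
  }
  lutein + zeaxanthin + beta_cryptoxanthin + alpha_carotene + beta_carotene
}

#' Anthesis-silking interval
#'
#' Days to silking minus days to anthesis. Negative values (protandry
#' reversed) are preserved.
#'
#' @param dysk days from planting to 50% silking.
#' @param dyanth days from planting to 50% anthesis.
#' @return Interval in days.
#' @export
anthesis_silking_interval <- function(dysk, dyanth) {
  .check_nonneg(dysk, "dysk")
  .check_nonneg(dyanth, "dyanth")
  dysk - dyanth
}

#' Grain yield adjusted to 15% moisture
#'
#' Converts plot grain weight to a per-hectare yield on a 15% moisture basis
#' with the standard dry-matter scaling `(100 - moisture) / 85` and the plot
#' area. The default area (3.75 m2) is a single 5 m row at 0.75 m spacing.
#'
#' @param grain_weight plot grain weight, kg.
#' @param moisture grain moisture at harvest, percent (0 <= m < 100).
#' @param plot_area harvested plot area, m2.
#' @return Yield in kg/ha.
#' @export
#' @examples
#' yield_at_15pct(2, 15, 3.75) # 5333.33 kg/ha
yield_at_15pct <- function(grain_weight, moisture, plot_area = 3.75) {
  .check_nonneg(grain_weight, "grain_weight")
  if (any(!is.na(moisture) & (moisture < 0 | moisture >= 100))) {
    stop("moisture must be in [0, 100)", call. = FALSE)
  }
  if (any(!is.na(plot_area) & plot_area <= 0)) {
    stop("plot_area must be positive", call. = FALSE)
  }
  grain_weight * (100 - moisture) / 85 * 10000 / plot_area
}

#' Add derived trait columns to a field book
#'
#' Computes `grain_yield` (from `grain_weight` and `grain_moisture`), `asi`
#' (from `dysk` and `dyanth`), `pva` and `total_carotenoid` (from the five
#' carotenoid columns) for every plot where the inputs are present. Existing
#' derived columns are recomputed.
#'
#' @param book a [fieldbook()].
#' @param plot_area harvested plot area in m2 for the yield conversion.
#' @return The field book with derived columns appended.
#' @export
derive_traits <- function(book, plot_area = 3.75) {
  stopifnot(inherits(book, "fieldbook"))
  p <- book$plots
  if (all(c("grain_weight", "grain_moisture") %in% names(p))) {
    p$grain_yield <- yield_at_15pct(p$grain_weight, p$grain_moisture, plot_area)
  }
  if (all(c("dysk", "dyanth") %in% names(p))) {
    p$asi <- anthesis_silking_interval(p$dysk, p$dyanth)
  }
  caro <- c("lutein", "zeaxanthin", "beta_cryptoxanthin",
            "alpha_carotene", "beta_carotene")
  if (all(caro %in% names(p))) {
    p$pva <- provitamin_a(p$beta_carotene, p$beta_cryptoxanthin,
                          p$alpha_carotene)
    p$total_carotenoid <- total_carotenoid(p$lutein, p$zeaxanthin,
                                           p$beta_cryptoxanthin,
                                           p$alpha_carotene, p$beta_carotene)
  }
  fieldbook(p)
}

.check_nonneg <- function(x, name) {
  if (any(!is.na(x) & x < 0)) {
    stop(name, " must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Round half-to-even at a fixed number of decimals
#'
#' The reporting convention used throughout rendered tables (two decimals,
#' banker's rounding), exposed so reports and tests share one rule.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_report <- function(x, digits = 2L) round(x, digits)
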