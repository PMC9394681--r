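#' Reference values from a published line x tester evaluation
#'
#' Summary tables reported by a published multi-environment evaluation of 60
#' provitamin A-enriched tropical maize inbred lines crossed to two inbred
#' testers (120 testcrosses plus the inter-tester hybrid and three commercial
#' checks; eight environments for agronomic traits, four for carotenoids).
#' Raw plot data were not published, so these printed summaries are the
#' available ground for closed-form cross-checks:
#'
#' * `carotenoid_anova_ms`: combined-ANOVA mean squares, repeatability, CV%
#'   and Baker ratio per carotenoid trait (four environments).
#' * `agronomic_anova_ms`: the same for grain yield and agronomic traits
#'   (eight environments).
#' * `testcross_summary`: per-tester minimum, maximum and mean of testcross
#'   performance.
#' * `tester_gca`: tester GCA effects with significance codes.
#'
#' @param table which table to load.
#' @return A data.frame.
#' @export
lxt_reference <- function(table = c("carotenoid_anova_ms",
                                    "agronomic_anova_ms",
                                    "testcross_summary", "tester_gca")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("reference_", table, ".csv"),
                      package = "lxtrial", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
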