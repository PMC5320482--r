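#' Bundled multi-residue validation dataset
#'
#' Reported validation results of a QuEChERS UHPLC--MS/MS method for five
#' post-harvest pesticides (2,4-D, carbendazim, thiabendazole, iprodione,
#' prochloraz) in eight fruit and vegetable matrices, shipped as
#' plain-text CSVs under `inst/extdata`:
#'
#' * `"calibration"` — solvent and matrix-matched calibration regressions
#'   (slope, intercept, R-squared) without (`ND`) and with 10-fold
#'   dilution (`D10`), plus the matrix effect as originally reported
#'   (`me_printed`, integer percent).
#' * `"recovery"` — mean spike recoveries with intra-day (n = 5) and
#'   inter-day (n = 15) RSDs at three spike levels (LOQ, 10xLOQ, 100xLOQ),
#'   plus the validated LOQ per analyte.
#' * `"uncertainty"` — the four relative uncertainty components
#'   (standards preparation, calibration, precision, recovery) per analyte.
#' * `"survey"` — one record per market sample (85 samples over eight
#'   commodities); blank or sub-LOQ samples carry `NA` analyte and
#'   concentration.
#'
#' @param table Which table to load.
#' @return A data frame. The `"survey"` table carries the per-commodity
#'   sample totals as attribute `"commodity_totals"` and the per-analyte
#'   LOQs as attribute `"loq"`.
#' @examples
#' cal <- validation_example("calibration")
#' head(cal)
#' @export
validation_example <- function(table = c("calibration", "recovery",
                                         "uncertainty", "survey")) {
  table <- match.arg(table)
  file <- c(calibration = "calibration_curves.csv",
            recovery = "recovery_results.csv",
            uncertainty = "uncertainty_components.csv",
            survey = "survey_samples.csv")[[table]]
  path <- system.file("extdata", file, package = "chemvalid", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (table == "survey") {
    df$analyte[df$analyte == ""] <- NA_character_
    counts <- base::table(df$commodity)  # arg `table` shadows base::table
    totals <- stats::setNames(as.integer(counts), names(counts))
    rec <- validation_example("recovery")
    loqs <- tapply(rec$loq_ugkg, rec$analyte, unique)
    attr(df, "commodity_totals") <- totals
    attr(df, "loq") <- stats::setNames(as.numeric(loqs), names(loqs))
  }
  df
}
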