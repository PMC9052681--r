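# Published per-animal and cohort summary statistics from the two-year
# Dungonab Bay reef manta acoustic monitoring programme. The raw telemetry is
# not publicly archived; these printed summaries are shipped as plain-text
# fixtures so that cohort-level statistics (residence indices, sex
# comparisons, filter-report arithmetic) can be recomputed and checked.

#' Published per-animal detection summary (Dungonab Bay cohort)
#'
#' Per-animal totals for the 19 analysed reef manta rays: wingspan, sex,
#' maturity, deployment date, total detections, track days (first to last
#' detection day), detection days, residence index, minimum distance
#' travelled and maximum consecutive days of absence.
#'
#' @return data.frame, one row per animal.
#' @export
dmnp_table2 <- function() {
  path <- system.file("extdata", "dmnp_table2.csv", package = "mantatrack",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$deployment_date <- as.Date(df$deployment_date)
  df
}

#' Published cohort-level counts (Dungonab Bay monitoring programme)
#'
#' Raw and stage-wise removed detection counts, cohort size, and
#' daily-presence coverage of the monitored window, as a named numeric
#' vector.
#' @export
dmnp_reported <- function() {
  path <- system.file("extdata", "dmnp_reported.csv", package = "mantatrack",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(df$value, df$quantity)
}
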