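#' Published reference tables for the Yangtze River Economic Belt, 2019
#'
#' Loads the reference values shipped with the package: the 2019
#' agglomeration table (HRAD, PAD, HRAD/PAD ratio and ranks for the five
#' indicators the published table reports, at province and reach level), the
#' entropy/utility/weight table at both levels, the 2019 TOPSIS distance and
#' composite-score table, and the 2013-2019 concentration-index series.
#'
#' These are printed, already-rounded values from a published provincial
#' yearbook analysis. The underlying yearbook panel is not distributed, so
#' only internally recomputable relationships can be checked against them:
#' ratio = HRAD/PAD, weight = (1-e)/sum(1-e), closeness = D-/(D+ + D-), the
#' rank columns, and the sign pattern of the CI series. The test suite and
#' the acceptance script use them exactly that way.
#'
#' @return A list with data.frames `agglomeration`, `entropy_weights`,
#'   `topsis`, `ci`.
#' @export
#'
#' @examples
#' ref <- yeb_reference_tables()
#' head(ref$agglomeration)
yeb_reference_tables <- function() {
  f <- function(name) {
    utils::read.csv(system.file("extdata", name, package = "hrequity",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
  }
  list(agglomeration = f("yeb2019_agglomeration.csv"),
       entropy_weights = f("yeb_entropy_weights.csv"),
       topsis = f("yeb2019_topsis.csv"),
       ci = f("yeb_ci_2013_2019.csv"))
}
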