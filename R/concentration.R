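#' Concentration curve and concentration index
#'
#' Regions are sorted by ascending per-capita GDP (ties broken by panel row
#' order), and the curve plots cumulative resource share Y against cumulative
#' population share X, starting from the origin. The area S under the curve
#' is evaluated by the trapezoid rule over the n region steps,
#' \deqn{S = \tfrac12 \sum_{i=0}^{n-1} (Y_i + Y_{i+1})(X_{i+1} - X_i)}
#' and the concentration index is twice the signed area between the
#' absolute-fairness diagonal and the curve,
#' \deqn{CI = 2 (0.5 - S) \in [-1, 1].}
#' A curve above the diagonal (resource accruing to poorer regions first)
#' gives S > 0.5 and CI < 0 ("pro-poor"); below the diagonal gives CI > 0
#' ("pro-rich"); exact per-capita proportionality gives the diagonal and
#' CI = 0.
#'
#' @param panel A [regional_panel()].
#' @param indicator Indicator id to evaluate.
#' @param year Year to evaluate; may be omitted for a single-year panel.
#' @return An object of class `concentration_result`: list with `indicator`,
#'   `year`, `points` (data.frame `region_id`, `X`, `Y`, ordered, origin row
#'   first), `area_S` and `ci`.
#' @export
#'
#' @examples
#' panel <- generate_panel(yeb_preset(seed = 1))
#' concentration_curve(panel, "general_practitioners", 2019)
concentration_curve <- function(panel, indicator, year = NULL) {
  if (!indicator %in% panel$indicators$id) {
    stop_schema("unknown indicator: ", indicator)
  }
  slice <- panel_slice(panel, year)
  total <- sum(slice[[indicator]])
  if (total <= 0) {
    stop_undefined("indicator '", indicator, "' totals zero in year ",
                   slice$year[1], "; concentration index undefined")
  }
  ord <- order(slice$gdp_per_capita, seq_len(nrow(slice)))
  s <- slice[ord, , drop = FALSE]
  X <- cumsum(s$population) / sum(s$population)
  Y <- cumsum(s[[indicator]]) / total
  points <- data.frame(region_id = c(NA_character_, s$region_id),
                       X = c(0, X), Y = c(0, Y),
                       stringsAsFactors = FALSE)
  S <- trapezoid_area(points$X, points$Y)
  structure(list(indicator = indicator, year = slice$year[1],
                 points = points, area_S = S, ci = 2 * (0.5 - S)),
            class = "concentration_result")
}

trapezoid_area <- function(X, Y) {
  n <- length(X)
  sum((Y[-n] + Y[-1]) * (X[-1] - X[-n])) / 2
}

#' @export
print.concentration_result <- function(x, digits = 3, ...) {
  cat("Concentration of '", x$indicator, "' (", x$year, "): S = ",
      round(x$area_S, digits), ", CI = ", round(x$ci, digits),
      if (x$ci > 0) "  (pro-rich)" else if (x$ci < 0) "  (pro-poor)" else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.concentration_result <- function(x, ...) {
  graphics::plot(x$points$X, x$points$Y, type = "l", lwd = 2,
                 xlab = "Cumulative population share (poorest first)",
                 ylab = "Cumulative resource share",
                 main = sprintf("%s, %d (CI = %.3f)", x$indicator, x$year,
                                x$ci),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::points(x$points$X, x$points$Y, pch = 19, cex = 0.6)
  invisible(x)
}

#' Concentration-index time series
#'
#' One CI per (indicator, year): the shape of a published multi-year
#' concentration-index table.
#'
#' @param panel A [regional_panel()].
#' @param indicators Indicator ids (default: all in the schema).
#' @param years Years to evaluate (default: all years in the panel).
#' @param wide If `TRUE` (default) return years in rows and indicators in
#'   columns; otherwise a long table with columns `year`, `indicator`,
#'   `area_S`, `ci`.
#' @return A data.frame; see `wide`.
#' @export
ci_timeseries <- function(panel, indicators = panel$indicators$id,
                          years = panel_years(panel), wide = TRUE) {
  have <- panel_years(panel)
  miss <- setdiff(years, have)
  if (length(miss)) {
    stop_validation("panel has no data for year(s): ",
                    paste(sort(miss), collapse = ", "))
  }
  long <- do.call(rbind, lapply(years, function(yr) {
    do.call(rbind, lapply(indicators, function(ind) {
      cc <- concentration_curve(panel, ind, yr)
      data.frame(year = yr, indicator = ind, area_S = cc$area_S, ci = cc$ci,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!wide) return(long)
  out <- data.frame(year = years)
  for (ind in indicators) {
    out[[ind]] <- long$ci[long$indicator == ind][match(years,
                                                       long$year[long$indicator == ind])]
  }
  out
}

#' Curve coordinates for several indicator-years
#'
#' Long table of concentration-curve points (the plottable output behind the
#' published curve figures).
#'
#' @inheritParams ci_timeseries
#' @return A data.frame with columns `year`, `indicator`, `order`,
#'   `region_id`, `X`, `Y` (order 0 is the origin).
#' @export
concentration_points <- function(panel, indicators = panel$indicators$id,
                                 years = panel_years(panel)) {
  do.call(rbind, lapply(years, function(yr) {
    do.call(rbind, lapply(indicators, function(ind) {
      p <- concentration_curve(panel, ind, yr)$points
      data.frame(year = yr, indicator = ind, order = seq_len(nrow(p)) - 1L,
                 region_id = p$region_id, X = p$X, Y = p$Y,
                 stringsAsFactors = FALSE)
    }))
  }))
}
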