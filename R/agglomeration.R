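#' Health-resource and population agglomeration degrees
#'
#' The health-resource agglomeration degree (HRAD) of a region is its share
#' of the parent territory's stock of a resource divided by its share of the
#' parent's land area:
#' \deqn{HRAD_i = \frac{HR_i/HR_n}{A_i/A_n} = \frac{HR_i/A_i}{HR_n/A_n}}
#' i.e. the region's resource density relative to the parent's. A value of 1
#' means density parity (geographically fair allocation); above 1 the
#' resource is geographically concentrated in the region. The population
#' agglomeration degree (PAD) is the same construction with population in
#' place of the resource. The percentage factors of the share form cancel, so
#' both are computed as pure share ratios.
#'
#' `compute_ratio()` forms HRAD/PAD, which algebraically equals the region's
#' per-capita resource relative to the parent's per-capita resource: the
#' fairness of allocation by population size. A ratio near 1 means the
#' resource tracks where people live; above 1 the region holds a surplus
#' relative to its population.
#'
#' @param panel A [regional_panel()].
#' @param indicator An indicator id present in the panel schema.
#' @param year Year to evaluate; may be omitted for a single-year panel.
#' @return For `compute_hrad`/`compute_pad`: a named numeric vector (one
#'   value per region, in panel row order). For `compute_ratio`: the
#'   element-wise ratio of the two.
#' @seealso [agglomeration_table()] for the full per-indicator table with
#'   ranks.
#' @export
compute_hrad <- function(panel, indicator, year = NULL) {
  if (!indicator %in% panel$indicators$id) {
    stop_schema("unknown indicator: ", indicator)
  }
  slice <- panel_slice(panel, year)
  tot <- parent_totals_for(panel, slice$year[1], slice)
  if (tot[[indicator]] <= 0) {
    stop_undefined("parent total for indicator '", indicator,
                   "' is zero; HRAD undefined")
  }
  share_r <- slice[[indicator]] / tot[[indicator]]
  share_a <- slice$area / tot$area
  stats::setNames(share_r / share_a, slice$region_id)
}

#' @rdname compute_hrad
#' @export
compute_pad <- function(panel, year = NULL) {
  slice <- panel_slice(panel, year)
  tot <- parent_totals_for(panel, slice$year[1], slice)
  share_p <- slice$population / tot$population
  share_a <- slice$area / tot$area
  stats::setNames(share_p / share_a, slice$region_id)
}

#' @param hrad,pad Named vectors as returned by `compute_hrad`/`compute_pad`.
#' @rdname compute_hrad
#' @export
compute_ratio <- function(hrad, pad) {
  if (length(hrad) != length(pad) ||
      !identical(names(hrad), names(pad))) {
    stop_schema("hrad and pad must cover the same regions in the same order")
  }
  if (any(pad <= 0)) {
    stop_undefined("PAD of zero; HRAD/PAD ratio undefined for region(s): ",
                   paste(names(pad)[pad <= 0], collapse = ", "))
  }
  hrad / pad
}

#' Descending rank with stable tie-breaking
#'
#' Largest value receives rank 1; ties are broken by input order, so ranks
#' are always a permutation of 1..n and reproducible for a fixed panel row
#' order.
#'
#' @param values Named numeric vector.
#' @return Integer ranks, same names and order as `values`.
#' @export
rank_descending <- function(values) {
  if (!length(values)) stop_validation("cannot rank an empty vector")
  ord <- order(-values, seq_along(values))
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  stats::setNames(r, names(values))
}

#' Agglomeration table for one year
#'
#' Computes HRAD, PAD, their ratio and descending ranks for every indicator,
#' mirroring the published per-province and per-reach agglomeration tables.
#'
#' @param panel A [regional_panel()].
#' @param year Year to evaluate; may be omitted for a single-year panel.
#' @param indicators Indicator ids to include (default: all in the schema).
#' @return A data.frame of class `agglomeration_table` with columns
#'   `region_id`, `year`, `indicator`, `hrad`, `hrad_rank`, `pad`, `ratio`,
#'   `ratio_rank`.
#' @export
#'
#' @examples
#' panel <- generate_panel(yeb_preset(seed = 1))
#' head(agglomeration_table(panel, year = 2019))
agglomeration_table <- function(panel, year = NULL,
                                indicators = panel$indicators$id) {
  slice <- panel_slice(panel, year)
  year <- slice$year[1]
  pad <- compute_pad(panel, year)
  out <- lapply(indicators, function(ind) {
    hrad <- compute_hrad(panel, ind, year)
    ratio <- compute_ratio(hrad, pad)
    data.frame(region_id = names(hrad), year = year, indicator = ind,
               hrad = unname(hrad),
               hrad_rank = unname(rank_descending(hrad)),
               pad = unname(pad),
               ratio = unname(ratio),
               ratio_rank = unname(rank_descending(ratio)),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("agglomeration_table", "data.frame"))
}

#' @export
print.agglomeration_table <- function(x, digits = 3, ...) {
  cat("Agglomeration table: ", length(unique(x$region_id)), " regions, ",
      length(unique(x$indicator)), " indicators, year ",
      paste(unique(x$year), collapse = "/"), "\n", sep = "")
  y <- as.data.frame(x)
  for (col in c("hrad", "pad", "ratio")) y[[col]] <- round(y[[col]], digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.agglomeration_table <- function(object, ...) {
  agg <- stats::aggregate(cbind(hrad, ratio) ~ indicator,
                          data = as.data.frame(object), FUN = stats::sd)
  names(agg) <- c("indicator", "sd_hrad", "sd_ratio")
  cat("Dispersion of agglomeration by indicator (sd across regions):\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}
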