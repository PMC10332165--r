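#' Regional yearbook panel
#'
#' A `regional_panel` holds one observation per (region, year): population,
#' land area, per-capita GDP and the value of every configured
#' medical-resource indicator, together with an optional grouping of regions
#' into larger blocks (e.g. the upstream/midstream/downstream reaches of a
#' river economic belt) and optional explicit parent totals.
#'
#' Validation is strict at ingest: population, area and per-capita GDP must be
#' strictly positive and indicator values non-negative, so downstream density
#' ratios can never silently divide by zero.
#'
#' @param data A data.frame with columns `region_id`, `region_name`, `year`,
#'   `population`, `area`, `gdp_per_capita` and one numeric column per
#'   indicator id. `region_name` defaults to `region_id` if absent.
#' @param grouping Optional: a named character vector mapping region_id to a
#'   group label, or a data.frame with columns `region_id` and `group`.
#'   When supplied it must cover every region in `data`.
#' @param parent_totals Optional data.frame of explicit higher-level totals,
#'   one row per year, with columns `year`, `population`, `area` and one per
#'   indicator. When supplied these replace the default column sums and must
#'   be strictly positive.
#' @param indicators Indicator schema, see [yeb_indicators()].
#'
#' @return An object of class `regional_panel`.
#' @export
regional_panel <- function(data, grouping = NULL, parent_totals = NULL,
                           indicators = yeb_indicators()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"region_name" %in% names(data) && "region_id" %in% names(data)) {
    data$region_name <- data$region_id
  }
  required <- c("region_id", "region_name", "year", "population", "area",
                "gdp_per_capita", indicators$id)
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop_schema("panel is missing required column(s): ",
                paste(missing, collapse = ", "))
  }
  data$region_id <- as.character(data$region_id)
  data$region_name <- as.character(data$region_name)

  num_cols <- c("year", "population", "area", "gdp_per_capita", indicators$id)
  for (col in num_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop_validation("non-numeric value in column '", col, "' at row ",
                        bad[1])
      }
      v <- vn
    }
    if (anyNA(v)) {
      stop_validation("missing value in column '", col, "' at row ",
                      which(is.na(v))[1])
    }
    data[[col]] <- v
  }
  for (col in c("population", "area", "gdp_per_capita")) {
    bad <- which(data[[col]] <= 0)
    if (length(bad)) {
      stop_validation("column '", col, "' must be strictly positive; ",
                      "offending row ", bad[1], " (region ",
                      data$region_id[bad[1]], ", year ", data$year[bad[1]], ")")
    }
  }
  for (col in indicators$id) {
    bad <- which(data[[col]] < 0)
    if (length(bad)) {
      stop_validation("negative value in indicator '", col, "' at row ",
                      bad[1], " (region ", data$region_id[bad[1]],
                      ", year ", data$year[bad[1]], ")")
    }
  }
  key <- paste(data$region_id, data$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_duplication("duplicate (region_id, year) record: ",
                     sub("\r", ", year ", d))
  }

  grouping <- normalize_grouping(grouping, unique(data$region_id))

  if (!is.null(parent_totals)) {
    parent_totals <- as.data.frame(parent_totals, stringsAsFactors = FALSE)
    need <- c("year", "population", "area", indicators$id)
    miss <- setdiff(need, names(parent_totals))
    if (length(miss)) {
      stop_schema("parent_totals missing column(s): ",
                  paste(miss, collapse = ", "))
    }
    vals <- parent_totals[, c("population", "area", indicators$id)]
    if (any(as.matrix(vals) <= 0)) {
      stop_validation("explicit parent totals must be strictly positive")
    }
  }

  structure(list(observations = data[, required, drop = FALSE],
                 grouping = grouping,
                 parent_totals = parent_totals,
                 indicators = indicators),
            class = "regional_panel")
}

normalize_grouping <- function(grouping, region_ids) {
  if (is.null(grouping)) return(NULL)
  if (is.data.frame(grouping)) {
    if (!all(c("region_id", "group") %in% names(grouping))) {
      stop_schema("grouping data.frame needs columns region_id and group")
    }
    grouping <- stats::setNames(as.character(grouping$group),
                                as.character(grouping$region_id))
  }
  uncovered <- setdiff(region_ids, names(grouping))
  if (length(uncovered)) {
    stop_validation("grouping does not cover region(s): ",
                    paste(uncovered, collapse = ", "))
  }
  grouping[region_ids]
}

#' @export
print.regional_panel <- function(x, ...) {
  obs <- x$observations
  cat("Regional panel: ", length(unique(obs$region_id)), " regions x ",
      length(unique(obs$year)), " years, ",
      nrow(x$indicators), " indicators\n", sep = "")
  if (!is.null(x$grouping)) {
    g <- table(x$grouping[unique(obs$region_id)])
    cat("Groups: ", paste(names(g), g, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  cat("Years: ", paste(sort(unique(obs$year)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.regional_panel <- function(x, ...) x$observations

#' Seasons of the panel: regions and years present
#' @param panel A `regional_panel`.
#' @name panel-accessors
#' @return `panel_years()` the sorted years; `panel_regions()` the region ids
#'   in panel row order.
#' @export
panel_years <- function(panel) sort(unique(panel$observations$year))

#' @rdname panel-accessors
#' @export
panel_regions <- function(panel) unique(panel$observations$region_id)

# single-year slice in stable row order
panel_slice <- function(panel, year = NULL) {
  obs <- panel$observations
  if (is.null(year)) {
    yrs <- unique(obs$year)
    if (length(yrs) > 1L) {
      stop_validation("panel spans years ", paste(sort(yrs), collapse = ", "),
                      "; specify `year`")
    }
    year <- yrs
  }
  out <- obs[obs$year == year, , drop = FALSE]
  if (!nrow(out)) stop_validation("panel has no observations for year ", year)
  out
}

# parent totals for one year: explicit row if supplied, else column sums
parent_totals_for <- function(panel, year, slice = NULL) {
  if (is.null(slice)) slice <- panel_slice(panel, year)
  ind <- panel$indicators$id
  if (!is.null(panel$parent_totals)) {
    row <- panel$parent_totals[panel$parent_totals$year == year, , drop = FALSE]
    if (nrow(row) == 1L) {
      return(as.list(row[, c("population", "area", ind)]))
    }
  }
  c(list(population = sum(slice$population), area = sum(slice$area)),
    as.list(colSums(slice[, ind, drop = FALSE])))
}

#' Read a regional panel from CSV
#'
#' Expects the wide yearbook layout: one row per (region, year), one column
#' per indicator. A long layout (columns `indicator`, `value`) can be
#' converted first with [pivot_panel_wide()].
#'
#' @param path CSV file path.
#' @param indicators Indicator schema, see [yeb_indicators()].
#' @param groups Optional path to a CSV with columns `region_id`, `group`, or
#'   a grouping object accepted by [regional_panel()].
#' @param parent_totals Optional parent-totals data.frame (see
#'   [regional_panel()]).
#' @return A validated [regional_panel()]; input row order is preserved, which
#'   fixes downstream rank tie-breaking.
#' @export
read_panel <- function(path, indicators = yeb_indicators(), groups = NULL,
                       parent_totals = NULL) {
  if (!file.exists(path)) stop_schema("panel file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(groups) && length(groups) == 1L) {
    if (!file.exists(groups)) stop_schema("groups file not found: ", groups)
    groups <- utils::read.csv(groups, stringsAsFactors = FALSE)
  }
  regional_panel(data, grouping = groups, parent_totals = parent_totals,
                 indicators = indicators)
}

#' Pivot a long panel table to the wide layout
#'
#' @param long A data.frame with columns `region_id`, `year`, `population`,
#'   `area`, `gdp_per_capita`, `indicator`, `value` (and optionally
#'   `region_name`).
#' @return A wide data.frame suitable for [regional_panel()].
#' @export
pivot_panel_wide <- function(long) {
  long <- as.data.frame(long, stringsAsFactors = FALSE)
  need <- c("region_id", "year", "population", "area", "gdp_per_capita",
            "indicator", "value")
  miss <- setdiff(need, names(long))
  if (length(miss)) {
    stop_schema("long panel missing column(s): ", paste(miss, collapse = ", "))
  }
  id_cols <- intersect(c("region_id", "region_name", "year", "population",
                         "area", "gdp_per_capita"), names(long))
  head <- unique(long[, id_cols, drop = FALSE])
  key <- function(d) paste(d$region_id, d$year, sep = "\r")
  if (anyDuplicated(key(head))) {
    stop_validation("inconsistent population/area/gdp within a (region, year)")
  }
  wide <- head
  for (ind in unique(long$indicator)) {
    sub <- long[long$indicator == ind, c("region_id", "year", "value")]
    wide[[ind]] <- sub$value[match(key(wide), paste(sub$region_id, sub$year,
                                                    sep = "\r"))]
  }
  wide
}

#' Aggregate provinces into their reach groups
#'
#' Sums population, area and every indicator over the member regions of each
#' group; per-capita GDP of a group is the population-weighted mean of its
#' members. Explicit parent totals carry over unchanged, so group-level
#' agglomeration degrees are measured against the same parent as the
#' member regions.
#'
#' @param panel A [regional_panel()] whose `grouping` is set.
#' @return A [regional_panel()] whose regions are the group labels (in order
#'   of first appearance).
#' @export
aggregate_reaches <- function(panel) {
  if (is.null(panel$grouping)) {
    stop_validation("panel has no grouping; supply one to aggregate reaches")
  }
  obs <- panel$observations
  ind <- panel$indicators$id
  obs$.group <- unname(panel$grouping[obs$region_id])
  group_order <- unique(obs$.group)
  rows <- list()
  for (year in unique(obs$year)) {
    ys <- obs[obs$year == year, , drop = FALSE]
    for (g in group_order) {
      m <- ys[ys$.group == g, , drop = FALSE]
      if (!nrow(m)) stop_validation("empty group '", g, "' in year ", year)
      row <- data.frame(region_id = g, region_name = g, year = year,
                        population = sum(m$population), area = sum(m$area),
                        gdp_per_capita =
                          sum(m$population * m$gdp_per_capita) / sum(m$population),
                        stringsAsFactors = FALSE)
      for (k in ind) row[[k]] <- sum(m[[k]])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  regional_panel(out,
                 grouping = stats::setNames(group_order, group_order),
                 parent_totals = panel$parent_totals,
                 indicators = panel$indicators)
}

#' Round half away from zero
#'
#' The rounding convention of published yearbook tables (0.5 rounds to 1,
#' -0.5 to -1), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so decimal halves stored just below .5
  # (e.g. 0.0355 * 1000 = 35.49999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Write a result table to CSV or JSON
#'
#' Numeric columns are rounded half-away-from-zero to `round_digits` on the
#' way out; the in-memory table keeps full precision.
#'
#' @param table A data.frame produced by a pipeline stage.
#' @param path Output file path; directories are created as needed.
#' @param round_digits Decimal places for numeric columns (default 3, the
#'   precision of published agglomeration tables). `NULL` disables rounding.
#' @param format `"csv"` (default) or `"json"`.
#' @return Invisibly, the rounded table that was written.
#' @export
write_table <- function(table, path, round_digits = 3,
                        format = c("csv", "json")) {
  format <- match.arg(format)
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!is.null(round_digits)) {
    for (col in names(table)) {
      if (is.numeric(table[[col]]) && !all(table[[col]] == floor(table[[col]]),
                                           na.rm = TRUE)) {
        table[[col]] <- round_half_away(table[[col]], round_digits)
      }
    }
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch(suppressWarnings({
    if (format == "csv") {
      utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE)
    }
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) {
    stop(errorCondition(paste0("cannot write table to '", path, "': ",
                               conditionMessage(ok)),
                        class = c("hrequity_io_error", "error")))
  }
  invisible(table)
}
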