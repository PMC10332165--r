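#' Run the full equity pipeline
#'
#' Orchestrates the three analysis stages over a panel and writes the
#' standard table bundle: per-year agglomeration tables (HRAD/PAD/ratio with
#' ranks), entropy-weight tables and TOPSIS score tables at the requested
#' level(s), the concentration-index time series, the concentration-curve
#' point coordinates, and a machine-readable run manifest (input hashes,
#' seed, package and R versions, output checksums). Outputs are
#' deterministic: rerunning with identical inputs and configuration
#' reproduces the bundle byte for byte.
#'
#' @param panel A [regional_panel()], or `NULL` to read/generate one.
#' @param input Path to a panel CSV (used when `panel` is `NULL`).
#' @param groups Optional groups CSV path, passed to [read_panel()].
#' @param preset If neither `panel` nor `input` is given, a
#'   [synthetic_config()] (e.g. [yeb_preset()]) to generate from.
#' @param years Years to analyse (default: all in the panel).
#' @param level `"province"`, `"reach"` or `"both"` for the scoring stage.
#' @param source Decision-matrix source for TOPSIS, `"hrad"` or `"raw"`.
#' @param round_digits Rounding for written tables (see [write_table()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of class `equity_run` with the in-memory tables
#'   (`agglomeration`, `weights`, `scores`, `ci`, `curves`) and `paths` of
#'   the written files. If any stage fails, files written by this run are
#'   removed and the error is re-signalled with the stage name.
#' @export
#'
#' @examples
#' \donttest{
#' run <- run_equity_pipeline(preset = yeb_preset(seed = 42),
#'                            out_dir = tempfile("equity"))
#' names(run$paths)
#' }
run_equity_pipeline <- function(panel = NULL, input = NULL, groups = NULL,
                                preset = NULL, years = NULL,
                                level = c("both", "province", "reach"),
                                source = c("hrad", "raw"), round_digits = 3,
                                out_dir = "equity-output") {
  level <- match.arg(level)
  source <- match.arg(source)
  if (is.null(panel)) {
    panel <- if (!is.null(input)) {
      read_panel(input, groups = groups)
    } else if (!is.null(preset)) {
      generate_panel(preset)
    } else {
      stop_schema("supply a panel, an input CSV path, or a preset")
    }
  }
  if (is.null(years)) years <- panel_years(panel)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  levels <- if (level == "both") c("province", "reach") else level
  if ("reach" %in% levels && is.null(panel$grouping)) {
    stop_validation("reach-level analysis needs a panel grouping")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)                       # no partial bundles
      stop(errorCondition(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = c("hrequity_pipeline_error", class(e)[1], "error")))
    })
  }
  emit <- function(table, file) {
    path <- file.path(out_dir, file)
    write_table(table, path, round_digits = round_digits)
    written <<- c(written, path)
    path
  }

  paths <- list()
  agg <- stage("agglomeration", {
    do.call(rbind, lapply(levels, function(lv) {
      p <- if (lv == "reach") aggregate_reaches(panel) else panel
      do.call(rbind, lapply(years, function(yr) {
        t <- agglomeration_table(p, yr)
        t$level <- lv
        as.data.frame(t)
      }))
    }))
  })
  paths$agglomeration <- emit(agg, "agglomeration.csv")

  et <- stage("entropy_topsis", {
    lapply(stats::setNames(levels, levels), function(lv) {
      lapply(stats::setNames(years, years), function(yr) {
        entropy_topsis(panel, yr, level = lv, source = source)
      })
    })
  })
  weights <- do.call(rbind, lapply(levels, function(lv) {
    do.call(rbind, lapply(as.character(years), function(yr) {
      w <- as.data.frame(et[[lv]][[yr]]$weights)
      cbind(level = lv, year = as.integer(yr), w)
    }))
  }))
  scores <- do.call(rbind, lapply(levels, function(lv) {
    do.call(rbind, lapply(as.character(years), function(yr) {
      s <- as.data.frame(et[[lv]][[yr]]$scores)
      cbind(level = lv, year = as.integer(yr), s)
    }))
  }))
  paths$weights <- emit(weights, "entropy_weights.csv")
  paths$scores <- stage("entropy_topsis", {
    # TOPSIS distances are conventionally printed at 5+ decimals
    p <- file.path(out_dir, "topsis_scores.csv")
    write_table(scores, p, round_digits = max(round_digits, 5))
    written <<- c(written, p)
    p
  })

  ci <- stage("concentration", ci_timeseries(panel, years = years,
                                             wide = FALSE))
  curves <- stage("concentration", concentration_points(panel, years = years))
  paths$ci <- emit(ci, "ci_timeseries.csv")
  paths$curves <- stage("concentration", {
    p <- file.path(out_dir, "curves.csv")
    write_table(curves, p, round_digits = 6)
    written <<- c(written, p)
    p
  })

  manifest <- stage("manifest", {
    inputs <- if (!is.null(input)) {
      as.list(tools::md5sum(c(input, if (is.character(groups)) groups)))
    } else list()
    m <- list(
      package = "hrequity",
      version = as.character(utils::packageVersion("hrequity")),
      r_version = R.version.string,
      seed = if (!is.null(preset)) preset$seed else NULL,
      years = years, level = level, source = source,
      round_digits = round_digits,
      input_md5 = inputs,
      n_regions = length(panel_regions(panel)),
      output_md5 = as.list(tools::md5sum(unlist(paths)))
    )
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(m, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, p)
    p
  })
  paths$manifest <- manifest

  invisible(structure(list(agglomeration = agg, weights = weights,
                           scores = scores, ci = ci, curves = curves,
                           paths = paths),
                      class = "equity_run"))
}

#' @export
print.equity_run <- function(x, ...) {
  cat("Equity pipeline run\n")
  cat("  agglomeration rows:", nrow(x$agglomeration), "\n")
  cat("  CI values:", nrow(x$ci), "\n")
  cat("  outputs:\n")
  for (p in unlist(x$paths)) cat("    ", p, "\n", sep = "")
  invisible(x)
}
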