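#' Medical-resource indicator schema
#'
#' An indicator definition table names the resource columns a panel must
#' carry and classifies each as material, human or financial. The default
#' schema is the ten-indicator set commonly used for provincial equity
#' analysis in China: institution and bed counts (material), five workforce
#' counts (human) and government health expenditure (financial).
#'
#' @param id Character vector of short machine-readable indicator codes.
#' @param label Display names, same length as `id`.
#' @param category One of `"material"`, `"human"`, `"financial"` per indicator.
#' @param units Free-text units (counts, persons, billion yuan).
#'
#' @return A `data.frame` with columns `id`, `label`, `category`, `units`.
#' @export
#'
#' @examples
#' yeb_indicators()
indicator_schema <- function(id, label = id, category = "material", units = "count") {
  if (anyDuplicated(id)) {
    stop_schema("indicator ids must be unique; duplicated: ",
                paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  category <- rep_len(category, length(id))
  bad <- setdiff(unique(category), c("material", "human", "financial"))
  if (length(bad)) {
    stop_schema("indicator category must be material, human or financial; got: ",
                paste(bad, collapse = ", "))
  }
  data.frame(id = as.character(id),
             label = rep_len(as.character(label), length(id)),
             category = category,
             units = rep_len(as.character(units), length(id)),
             stringsAsFactors = FALSE)
}

#' @rdname indicator_schema
#' @export
yeb_indicators <- function() {
  indicator_schema(
    id = c("health_institutions", "tcm_institutions", "beds", "grassroots_beds",
           "health_technicians", "physicians", "nurses",
           "primary_health_technicians", "general_practitioners",
           "gov_health_expenditure"),
    label = c("Medical and health institutions",
              "Traditional Chinese medicine institutions",
              "Beds in medical and health institutions",
              "Beds in primary medical and health institutions",
              "Health technicians",
              "Practicing (assistant) physicians",
              "Registered nurses",
              "Primary health technicians",
              "General practitioners",
              "Government health expenditure"),
    category = c("material", "material", "material", "material",
                 "human", "human", "human", "human", "human",
                 "financial"),
    units = c(rep("count", 4), rep("persons", 5), "billion yuan")
  )
}

# classed conditions so callers can distinguish failure modes
stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("hrequity_schema_error", "error")))
}
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("hrequity_validation_error", "error")))
}
stop_duplication <- function(...) {
  stop(errorCondition(paste0(...), class = c("hrequity_duplication_error", "error")))
}
stop_undefined <- function(...) {
  stop(errorCondition(paste0(...), class = c("hrequity_undefined_statistic", "error")))
}
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("hrequity_degenerate_error", "error")))
}
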