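#' Build the decision matrix for composite scoring
#'
#' Rows are regions (alternatives), columns indicators (criteria). The
#' default cell value is the region's HRAD for that indicator — the analysis
#' scores the *level of resource agglomeration* — but raw indicator values
#' can be requested. Orientation (benefit vs cost) is carried as an
#' attribute; all agglomeration indicators are benefit-type by default.
#'
#' @param panel A [regional_panel()].
#' @param year Year to evaluate; may be omitted for a single-year panel.
#' @param source `"hrad"` (default) or `"raw"`.
#' @param orientation Character vector, one of `"benefit"`/`"cost"` per
#'   indicator (recycled).
#' @param indicators Indicator ids to include.
#' @return A numeric matrix (regions x indicators) with an `orientation`
#'   attribute.
#' @export
decision_matrix <- function(panel, year = NULL, source = c("hrad", "raw"),
                            orientation = "benefit",
                            indicators = panel$indicators$id) {
  source <- match.arg(source)
  slice <- panel_slice(panel, year)
  if (source == "hrad") {
    cols <- lapply(indicators, function(ind) {
      unname(compute_hrad(panel, ind, slice$year[1]))
    })
    m <- do.call(cbind, cols)
  } else {
    m <- as.matrix(slice[, indicators, drop = FALSE])
  }
  dimnames(m) <- list(slice$region_id, indicators)
  as_decision_matrix(m, orientation)
}

as_decision_matrix <- function(m, orientation = "benefit") {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 1L) {
    stop_validation("decision matrix needs at least 2 alternatives and 1 criterion")
  }
  if (anyNA(m)) stop_validation("decision matrix contains missing cells")
  if (any(m < 0)) stop_validation("decision matrix contains negative cells")
  orientation <- rep_len(orientation, ncol(m))
  bad <- setdiff(unique(orientation), c("benefit", "cost"))
  if (length(bad)) {
    stop_schema("orientation must be benefit or cost; got: ",
                paste(bad, collapse = ", "))
  }
  attr(m, "orientation") <- orientation
  m
}

#' Entropy weights of decision criteria
#'
#' Objective criterion weighting by Shannon entropy of the column
#' proportions: for criterion j over n alternatives,
#' \deqn{p_{ij} = x_{ij}/\sum_i x_{ij}, \quad
#'       e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}, \quad
#'       d_j = 1 - e_j, \quad w_j = d_j/\sum_j d_j}
#' with the convention \eqn{0\,\ln 0 = 0}. A criterion whose values are
#' spread out across alternatives has low entropy, high information utility
#' d and hence high weight; a constant column carries no information
#' (e = 1, weight 0).
#'
#' @param matrix Numeric matrix, alternatives in rows (see
#'   [decision_matrix()]).
#' @param minmax If `TRUE`, min-max rescale each column to \[0, 1\] before
#'   forming proportions (an alternative normalization sometimes used when
#'   criteria mix scales; shifts zeros to the column minimum).
#' @return A data.frame of class `entropy_weights` with columns `indicator`,
#'   `entropy`, `utility`, `weight`; attribute `n_alternatives` records the n
#'   used in the 1/ln n constant.
#' @export
#'
#' @examples
#' m <- cbind(a = c(3, 1), b = c(1, 1))
#' entropy_weights(rbind(m, c(2, 5)))
entropy_weights <- function(matrix, minmax = FALSE) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L) stop_validation("entropy needs at least 2 alternatives")
  if (anyNA(m)) stop_validation("decision matrix contains missing cells")
  if (isTRUE(minmax)) {
    m <- apply(m, 2, function(x) {
      rng <- range(x)
      if (rng[1] == rng[2]) rep(1, length(x)) else (x - rng[1]) / diff(rng)
    })
  }
  cs <- colSums(m)
  if (any(cs <= 0)) {
    nm <- colnames(m)[cs <= 0]
    if (is.null(nm)) nm <- which(cs <= 0)
    stop_validation("zero column sum for criterion: ",
                    paste(nm, collapse = ", "))
  }
  n <- nrow(m)
  p <- sweep(m, 2, cs, "/")
  plogp <- p * log(p)
  plogp[p == 0] <- 0                       # 0 * log(0) := 0
  e <- -colSums(plogp) / log(n)
  e <- pmin(pmax(e, 0), 1)                 # clip fp noise at the boundaries
  d <- 1 - e
  d[d < 1e-12] <- 0                        # constant columns up to fp noise
  if (sum(d) <= 0) {
    stop_degenerate("all criteria are uniform across alternatives; ",
                    "entropy weights are degenerate")
  }
  w <- d / sum(d)
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0("c", seq_len(ncol(m)))
  structure(data.frame(indicator = cols, entropy = unname(e),
                       utility = unname(d), weight = unname(w),
                       stringsAsFactors = FALSE),
            n_alternatives = n,
            class = c("entropy_weights", "data.frame"))
}

#' @export
print.entropy_weights <- function(x, digits = 3, ...) {
  cat("Entropy weights over", attr(x, "n_alternatives"), "alternatives\n")
  y <- as.data.frame(x)
  for (col in c("entropy", "utility", "weight")) y[[col]] <- round(y[[col]], digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' TOPSIS composite scores
#'
#' Ranks alternatives by relative closeness to the ideal solution. Each
#' column is vector-normalized (\eqn{r_{ij} = x_{ij}/\sqrt{\sum_i x_{ij}^2}},
#' the classical TOPSIS normalization, which removes column scale) and
#' multiplied by its weight; the positive ideal takes the per-column max for
#' benefit criteria (min for cost), the negative ideal the opposite. With
#' Euclidean distances \eqn{D_i^+}, \eqn{D_i^-} to the two ideals, the
#' composite score (relative proximity) is
#' \deqn{C_i = \frac{D_i^-}{D_i^+ + D_i^-} \in [0, 1]}
#' and alternatives are ranked by descending \eqn{C_i}.
#'
#' @param matrix Numeric matrix, alternatives in rows (see
#'   [decision_matrix()]); an `orientation` attribute marks cost columns.
#' @param weights An [entropy_weights()] result or a numeric weight vector
#'   summing to 1 (matched to columns by name when both are named).
#' @return A data.frame of class `topsis_result` with columns `region_id`,
#'   `d_plus`, `d_minus`, `closeness`, `rank`.
#' @export
topsis_score <- function(matrix, weights) {
  m <- as.matrix(matrix)
  orientation <- attr(matrix, "orientation")
  if (is.null(orientation)) orientation <- rep("benefit", ncol(m))
  if (inherits(weights, "entropy_weights")) {
    w <- stats::setNames(weights$weight, weights$indicator)
  } else {
    w <- weights
  }
  if (!is.null(names(w)) && !is.null(colnames(m))) {
    if (!setequal(names(w), colnames(m))) {
      stop_schema("weight names do not match decision-matrix columns")
    }
    w <- w[colnames(m)]
  }
  if (length(w) != ncol(m)) {
    stop_schema("need one weight per criterion (", ncol(m), "), got ",
                length(w))
  }
  if (abs(sum(w) - 1) > 1e-8) {
    stop_validation("weights must sum to 1 (got ", format(sum(w)), ")")
  }
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) {
    nm <- colnames(m)[norms == 0]
    stop_validation("all-zero criterion column: ", paste(nm, collapse = ", "))
  }
  v <- sweep(sweep(m, 2, norms, "/"), 2, w, "*")
  hi <- apply(v, 2, max)
  lo <- apply(v, 2, min)
  if (all(hi == lo)) {
    stop_degenerate("every criterion is constant across alternatives; ",
                    "ideal and anti-ideal coincide")
  }
  pos <- ifelse(orientation == "benefit", hi, lo)
  neg <- ifelse(orientation == "benefit", lo, hi)
  d_plus <- sqrt(rowSums(sweep(v, 2, pos, "-")^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, neg, "-")^2))
  closeness <- d_minus / (d_plus + d_minus)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("alt", seq_len(nrow(m)))
  structure(data.frame(region_id = ids,
                       d_plus = unname(d_plus), d_minus = unname(d_minus),
                       closeness = unname(closeness),
                       rank = unname(rank_descending(closeness)),
                       stringsAsFactors = FALSE),
            class = c("topsis_result", "data.frame"))
}

#' @export
print.topsis_result <- function(x, digits = 5, ...) {
  cat("TOPSIS composite scores (", nrow(x), " alternatives)\n", sep = "")
  y <- as.data.frame(x)
  for (col in c("d_plus", "d_minus", "closeness")) y[[col]] <- round(y[[col]], digits)
  print(y[order(y$rank), ], row.names = FALSE, ...)
  invisible(x)
}

#' Entropy-weight TOPSIS scoring of a panel year
#'
#' Convenience wrapper running [decision_matrix()], [entropy_weights()] and
#' [topsis_score()] in sequence, at province level or after aggregation to
#' reach level. The entropy constant 1/ln n always uses the number of
#' alternatives actually scored (provinces and reaches are scored as
#' separate blocks with their own entropies).
#'
#' @inheritParams decision_matrix
#' @param level `"province"` scores the panel's regions as-is; `"reach"`
#'   aggregates with [aggregate_reaches()] first.
#' @param minmax Passed to [entropy_weights()].
#' @return A list of class `entropy_topsis` with elements `weights`
#'   ([entropy_weights()]) and `scores` ([topsis_score()]).
#' @export
#'
#' @examples
#' panel <- generate_panel(yeb_preset(seed = 1))
#' entropy_topsis(panel, year = 2019)
entropy_topsis <- function(panel, year = NULL,
                           level = c("province", "reach"),
                           source = c("hrad", "raw"), orientation = "benefit",
                           minmax = FALSE) {
  level <- match.arg(level)
  if (level == "reach") panel <- aggregate_reaches(panel)
  m <- decision_matrix(panel, year, source = source,
                       orientation = orientation)
  w <- entropy_weights(m, minmax = minmax)
  structure(list(weights = w, scores = topsis_score(m, w), level = level),
            class = "entropy_topsis")
}

#' @export
print.entropy_topsis <- function(x, ...) {
  cat("Entropy-weight TOPSIS,", x$level, "level\n\n")
  print(x$weights, ...)
  cat("\n")
  print(x$scores, ...)
  invisible(x)
}
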