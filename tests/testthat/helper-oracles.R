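# Independent oracles, coded straight from the defining formulas with plain
# loops. They deliberately share no code with the package internals.

# Grouped covariance form of the concentration index:
#   CI = (2/mu) * sum_i s_i * mu_i * (R_i - 1/2)
# with s_i the population share, mu_i the per-capita resource and R_i the
# population-weighted fractional rank after ordering by economic level.
ci_covariance_oracle <- function(population, resource, gdp) {
  ord <- order(gdp, seq_along(gdp))
  pop <- population[ord]
  res <- resource[ord]
  s <- pop / sum(pop)
  mu_i <- res / pop
  mu <- sum(res) / sum(pop)
  cum <- cumsum(s)
  R <- cum - s / 2
  total <- 0
  for (i in seq_along(s)) {
    total <- total + s[i] * mu_i[i] * (R[i] - 0.5)
  }
  2 * total / mu
}

# Straight-line entropy-weight computation.
entropy_oracle <- function(m) {
  n <- nrow(m)
  e <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    p <- m[, j] / sum(m[, j])
    acc <- 0
    for (i in seq_len(n)) {
      if (p[i] > 0) acc <- acc + p[i] * log(p[i])
    }
    e[j] <- -acc / log(n)
  }
  d <- 1 - e
  list(entropy = e, utility = d, weight = d / sum(d))
}

# Straight-line TOPSIS with vector normalization, all-benefit criteria.
topsis_oracle <- function(m, w) {
  v <- m
  for (j in seq_len(ncol(m))) {
    v[, j] <- w[j] * m[, j] / sqrt(sum(m[, j]^2))
  }
  pos <- apply(v, 2, max)
  neg <- apply(v, 2, min)
  dp <- dm <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    dp[i] <- sqrt(sum((v[i, ] - pos)^2))
    dm[i] <- sqrt(sum((v[i, ] - neg)^2))
  }
  list(d_plus = dp, d_minus = dm, closeness = dm / (dp + dm))
}

# Minimal single- or multi-indicator panel builder for hand-constructed cases.
toy_panel <- function(population, area, gdp, values, year = 2019,
                      grouping = NULL, ids = NULL) {
  if (!is.list(values)) values <- list(x = values)
  n <- length(population)
  if (is.null(ids)) ids <- paste0("r", seq_len(n))
  df <- data.frame(region_id = ids, region_name = ids, year = year,
                   population = population, area = area,
                   gdp_per_capita = gdp, stringsAsFactors = FALSE)
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  regional_panel(df, grouping = grouping,
                 indicators = indicator_schema(names(values)))
}

# Random multi-region single-indicator panel for property tests.
random_panel <- function(n = 8, year = 2019) {
  toy_panel(population = exp(stats::runif(n, 11, 16)),
            area = exp(stats::runif(n, 8, 13)),
            gdp = exp(stats::runif(n, 10, 12)),
            values = list(x = exp(stats::runif(n, 6, 12))),
            year = year)
}
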