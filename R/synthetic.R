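#' Population trajectory specification for the synthetic generator
#'
#' Describes how per-city population time series are drawn: the initial-size
#' distribution (log-normal by default, log-uniform as an alternative for
#' flat cross-sections) and the per-city geometric annual growth rate.
#'
#' @param dist Initial-size distribution: `"lognormal"` (meanlog/sdlog on the
#'   natural-log scale) or `"loguniform"` (uniform on the log10 scale between
#'   `log10_min` and `log10_max`).
#' @param meanlog,sdlog Parameters of the log-normal initial population
#'   (persons). Defaults emulate prefecture-level cities of roughly 4 million
#'   residents with moderate spread.
#' @param log10_min,log10_max Bounds of the log-uniform alternative.
#' @param growth_mean,growth_sd Mean and standard deviation of the per-city
#'   geometric annual growth rate (dimensionless; 0.005 means +0.5%/yr).
#' @return A list of class `"population_spec"`.
#' @export
population_spec <- function(dist = c("lognormal", "loguniform"),
                            meanlog = log(4e6), sdlog = 0.6,
                            log10_min = 5.5, log10_max = 7.5,
                            growth_mean = 0.005, growth_sd = 0.01) {
  dist <- match.arg(dist)
  stopifnot(sdlog >= 0, log10_max > log10_min, growth_sd >= 0)
  structure(list(dist = dist, meanlog = meanlog, sdlog = sdlog,
                 log10_min = log10_min, log10_max = log10_max,
                 growth_mean = growth_mean, growth_sd = growth_sd),
            class = "population_spec")
}

#' Driver effect specification for the synthetic generator
#'
#' Names a subset of the ten driver indicators as "active", each with a
#' monotone linear effect on the per-city allometric exponent; the remaining
#' drivers are pure nuisance. Effects apply to the driver min-max scaled to
#' [0, 1] across cities, so an effect of 0.5 moves the exponent by up to 0.5
#' between the least- and most-exposed city.
#'
#' @param active Named numeric vector of effect sizes (exponent units per
#'   scaled-driver unit); names must be driver feature names
#'   (see [driver_features()]). May be empty (null model).
#' @param baseline Exponent of a city with all scaled drivers at 0.
#' @param noise_sd Standard deviation of exponent-level noise across cities.
#' @return A list of class `"driver_spec"`.
#' @export
driver_spec <- function(active = c(pc_gdp = 0.6), baseline = 0.7, noise_sd = 0.05) {
  if (length(active)) {
    unknown <- setdiff(names(active), driver_features()$feature)
    if (length(unknown))
      stop("unknown driver(s) in effect specification: ",
           paste(unknown, collapse = ", "))
  }
  stopifnot(is.numeric(baseline), length(baseline) == 1, noise_sd >= 0)
  structure(list(active = active, baseline = baseline, noise_sd = noise_sd),
            class = "driver_spec")
}

#' Configuration of the synthetic city-panel generator
#'
#' Bundles every parameter of the generative model
#' \eqn{\ln M = \ln a + b \ln P + \varepsilon}: either a per-year exponent
#' schedule (for cross-sectional, "vertical" panels) or a per-city schedule
#' (for time-series, "horizontal" panels), the scale factor \eqn{a}, the
#' log-scale noise, the population model, and how the resource total is split
#' into institutions, beds and doctors.
#'
#' @param n_cities Number of cities (>= 3 so a cross-city slope is always
#'   identifiable).
#' @param years Inclusive integer vector of calendar years.
#' @param exponents_by_year Numeric vector of exponents, one per year
#'   (vertical mode). Exactly one of `exponents_by_year` /
#'   `exponents_by_city` must be supplied.
#' @param exponents_by_city Numeric vector of exponents, one per city
#'   (horizontal mode).
#' @param intercept Scale factor \eqn{a > 0}.
#' @param noise_sd Standard deviation of the additive noise on the
#'   natural-log scale (multiplicative log-normal on the raw scale); 0 gives
#'   exact power-law panels.
#' @param population A [population_spec()].
#' @param indicator_shares Three positive proportions summing to 1 splitting
#'   the resource total into institutions / beds / doctors.
#' @param drivers Optional [driver_spec()]; used by [generate_driver_panel()].
#' @param seed Integer seed; every random draw flows through it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_cities = 41,
                             years = 2000:2022,
                             exponents_by_year = NULL,
                             exponents_by_city = NULL,
                             intercept = 0.5,
                             noise_sd = 0,
                             population = population_spec(),
                             indicator_shares = c(institutions = 0.30,
                                                  beds = 0.35,
                                                  doctors = 0.35),
                             drivers = NULL,
                             seed = 1L) {
  if (n_cities < 3)
    stop("n_cities must be >= 3 (a cross-city slope needs at least 3 points)")
  years <- as.integer(years)
  if (anyNA(years) || length(years) < 1 || is.unsorted(years, strictly = TRUE))
    stop("years must be a strictly increasing integer vector")
  has_vy <- !is.null(exponents_by_year)
  has_vc <- !is.null(exponents_by_city)
  if (has_vy && has_vc)
    stop("exactly one of exponents_by_year / exponents_by_city must be set")
  if (!has_vy && !has_vc && is.null(drivers))
    stop("exactly one of exponents_by_year / exponents_by_city must be set",
         " (or a driver_spec, which sets per-city exponents itself)")
  if (has_vy && length(exponents_by_year) != length(years))
    stop("exponents_by_year must have one exponent per year (",
         length(years), " needed)")
  if (has_vc && length(exponents_by_city) != n_cities)
    stop("exponents_by_city must have one exponent per city (",
         n_cities, " needed)")
  if (!is.numeric(intercept) || intercept <= 0) stop("intercept must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(indicator_shares) != 3 || any(indicator_shares <= 0) ||
      abs(sum(indicator_shares) - 1) > 1e-8)
    stop("indicator_shares must be three positive proportions summing to 1")
  stopifnot(inherits(population, "population_spec"))
  if (!is.null(drivers)) stopifnot(inherits(drivers, "driver_spec"))
  structure(list(n_cities = as.integer(n_cities), years = years,
                 exponents_by_year = exponents_by_year,
                 exponents_by_city = exponents_by_city,
                 intercept = intercept, noise_sd = noise_sd,
                 population = population,
                 indicator_shares = indicator_shares,
                 drivers = drivers, seed = as.integer(seed)),
            class = "synthetic_config")
}

city_ids <- function(n) sprintf("C%02d", seq_len(n))

# n_cities x n_years matrix of strictly positive populations; draw order is
# fixed so a given (config, seed) always yields the same matrix.
draw_populations <- function(config) {
  n <- config$n_cities
  ny <- length(config$years)
  ps <- config$population
  p0 <- switch(ps$dist,
    lognormal  = exp(stats::rnorm(n, ps$meanlog, ps$sdlog)),
    loguniform = 10^stats::runif(n, ps$log10_min, ps$log10_max))
  g <- stats::rnorm(n, ps$growth_mean, ps$growth_sd)
  g <- pmax(g, -0.5)  # keep trajectories strictly positive and sane
  t_rel <- seq_len(ny) - 1L
  pop <- outer(p0, t_rel, function(p, t) p) * outer(1 + g, t_rel, `^`)
  dimnames(pop) <- list(city_ids(n), config$years)
  pop
}

split_indicators <- function(total, shares) {
  data.frame(institutions = total * shares[[1]],
             beds = total * shares[[2]],
             doctors = total * shares[[3]])
}

assemble_panel <- function(pop, total, config) {
  n <- nrow(pop); ny <- ncol(pop)
  out <- data.frame(
    city_id = rep(rownames(pop), times = ny),
    year = rep(config$years, each = n),
    prp = as.vector(pop),
    stringsAsFactors = FALSE)
  out <- cbind(out, split_indicators(as.vector(total), config$indicator_shares))
  rownames(out) <- NULL
  out[order(out$city_id, out$year), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Generate a per-year ("vertical") synthetic city panel
#'
#' For every year \eqn{t}, city resource totals follow
#' \eqn{\ln M = \ln a + b_t \ln P + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma)}, so a cross-city log-log regression in
#' year \eqn{t} recovers \eqn{b_t} exactly when `noise_sd = 0`. The total is
#' split into institutions / beds / doctors by `indicator_shares`.
#'
#' @param config A [synthetic_config()] with `exponents_by_year` set.
#' @return A long-format panel `data.frame` with columns `city_id`, `year`,
#'   `prp`, `institutions`, `beds`, `doctors`. Indicator values are
#'   continuous intensities (not rounded counts) so that noise-free panels
#'   satisfy the generating law to numerical precision.
#' @export
generate_vertical_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$exponents_by_year))
    stop("generate_vertical_panel needs a per-year exponent schedule")
  set.seed(config$seed)
  pop <- draw_populations(config)
  b <- matrix(config$exponents_by_year, nrow = nrow(pop), ncol = ncol(pop),
              byrow = TRUE)
  eps <- if (config$noise_sd > 0)
    matrix(stats::rnorm(length(pop), 0, config$noise_sd), nrow(pop)) else 0
  total <- exp(log(config$intercept) + b * log(pop) + eps)
  assemble_panel(pop, total, config)
}

#' Generate a per-city ("horizontal") synthetic city panel
#'
#' Within each city \eqn{i}, \eqn{\ln M_{it} = \ln a + b_i \ln P_{it} +
#' \varepsilon}, so a per-city over-time log-log regression recovers
#' \eqn{b_i} exactly when `noise_sd = 0`. Requires at least 3 years; a city
#' whose drawn log-population series is constant (slope unidentifiable) is
#' an error by construction.
#'
#' @param config A [synthetic_config()] with `exponents_by_city` set.
#' @return A long-format panel `data.frame`; see [generate_vertical_panel()].
#' @export
generate_horizontal_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$exponents_by_city))
    stop("generate_horizontal_panel needs a per-city exponent schedule")
  if (length(config$years) < 3)
    stop("horizontal panels need at least 3 years")
  set.seed(config$seed)
  pop <- draw_populations(config)
  flat <- apply(log(pop), 1, stats::var) == 0
  if (any(flat))
    stop("constant population series for city ",
         paste(rownames(pop)[flat], collapse = ", "),
         "; slope unidentifiable")
  b <- matrix(config$exponents_by_city, nrow = nrow(pop), ncol = ncol(pop))
  eps <- if (config$noise_sd > 0)
    matrix(stats::rnorm(length(pop), 0, config$noise_sd), nrow(pop)) else 0
  total <- exp(log(config$intercept) + b * log(pop) + eps)
  assemble_panel(pop, total, config)
}

# plausible cross-city driver ranges (constant within a city over years)
draw_driver_values <- function(n) {
  data.frame(
    pc_gdp          = exp(stats::rnorm(n, log(5e4), 0.5)),
    tertiary_share  = stats::runif(n, 35, 60),
    fiscal_ratio    = stats::runif(n, 40, 110),
    mh_invest_share = stats::runif(n, 4, 10),
    urban_rate      = stats::runif(n, 40, 92),
    pop_attraction  = stats::runif(n, 75, 135),
    pop_density     = exp(stats::rnorm(n, log(800), 0.7)),
    income_ratio    = stats::runif(n, 170, 310),
    mh_consum_share = stats::runif(n, 5, 13),
    aging_rate      = stats::runif(n, 8, 22))
}

scale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# raw component columns from which build_driver_table() recomputes each ratio
driver_components <- function(drv, prp) {
  gdp <- drv$pc_gdp * prp
  fiscal_expenditure <- 0.12 * gdp
  rural_income <- rep(20000, length(prp))
  living_expenses <- 0.65 * (drv$income_ratio / 100 * rural_income)
  data.frame(
    gdp = gdp,
    tertiary_va = drv$tertiary_share / 100 * gdp,
    fiscal_revenue = drv$fiscal_ratio / 100 * fiscal_expenditure,
    fiscal_expenditure = fiscal_expenditure,
    mh_gov_expenditure = drv$mh_invest_share / 100 * fiscal_expenditure,
    urban_pop = drv$urban_rate / 100 * prp,
    registered_pop = prp / (drv$pop_attraction / 100),
    admin_area = prp / drv$pop_density,
    urban_income = drv$income_ratio / 100 * rural_income,
    rural_income = rural_income,
    mh_consum_expenditure = drv$mh_consum_share / 100 * living_expenses,
    living_expenses = living_expenses,
    pop65 = drv$aging_rate / 100 * prp)
}

#' Generate a driver panel with known per-city exponents
#'
#' Draws the ten driver indicators per city, sets each city's true exponent
#' to `baseline + sum(effect_k * scaled driver_k) + noise` (each active
#' effect monotone in its driver), generates the resource series under those
#' exponents, and returns both the panel (with raw component columns so
#' [build_driver_table()] can recompute every ratio) and the ground truth —
#' the harness for driver-recovery experiments.
#'
#' @param config A [synthetic_config()] with `drivers` set (a
#'   [driver_spec()]); its `exponents_by_city`, if any, is ignored.
#' @return A list with `panel` (long-format panel including component
#'   columns), `truth` (`data.frame` of `city_id`, `b_true`, and the per-city
#'   driver values), and `effects` (the active effect vector).
#' @export
generate_driver_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$drivers))
    stop("generate_driver_panel needs a driver_spec in config$drivers")
  if (length(config$years) < 3)
    stop("driver panels need at least 3 years")
  ds <- config$drivers
  set.seed(config$seed)
  n <- config$n_cities
  drv <- draw_driver_values(n)
  b <- rep(ds$baseline, n)
  for (k in names(ds$active))
    b <- b + ds$active[[k]] * scale01(drv[[k]])
  if (ds$noise_sd > 0) b <- b + stats::rnorm(n, 0, ds$noise_sd)

  pop <- draw_populations(config)
  eps <- if (config$noise_sd > 0)
    matrix(stats::rnorm(length(pop), 0, config$noise_sd), nrow(pop)) else 0
  total <- exp(log(config$intercept) + matrix(b, n, ncol(pop)) * log(pop) + eps)
  panel <- assemble_panel(pop, total, config)

  comp <- driver_components(drv[match(panel$city_id, city_ids(n)), ,
                                drop = FALSE], panel$prp)
  panel <- cbind(panel, comp)
  rownames(panel) <- NULL
  truth <- cbind(data.frame(city_id = city_ids(n), b_true = b,
                            stringsAsFactors = FALSE), drv)
  list(panel = panel, truth = truth, effects = ds$active)
}

#' Packaged reference schedule of annual allometric exponents
#'
#' The published 2000-2022 annual scale indices, goodness-of-fit values and
#' allometric classifications for the 41-city Yangtze River Delta panel,
#' shipped as a plain-text fixture. Downstream modules use it as the exponent
#' schedule for noise-free self-consistency checks (generate a panel with
#' these exponents, re-estimate, compare) and to verify that the typology
#' reproduces the printed classification labels.
#'
#' @return A `data.frame` with columns `year` (2000-2022), `scale_index`,
#'   `goodness_of_fit`, and `classification` (printed label, e.g.
#'   `"Negative allometric level 1"`).
#' @export
yrd_annual_exponents <- function() {
  path <- system.file("extdata", "yrd_annual_exponents.csv",
                      package = "allohealth", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
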