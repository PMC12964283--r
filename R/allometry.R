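#' Fit an allometric scaling relation by log-log least squares
#'
#' Ordinary least squares of `ln M` on `ln P` for the power law
#' \eqn{M = a P^b}: the slope is the allometric exponent \eqn{b}, the
#' intercept \eqn{\ln a}, and the fit quality the regression's \eqn{R^2}.
#'
#' @param p Positive numeric vector (population, persons).
#' @param m Positive numeric vector (resource supply level), same length.
#' @param scope Optional named list describing what was fit (mode, year,
#'   city, period); stored verbatim.
#' @return A list of class `"allometric_fit"` with `exponent_b`, `ln_a`,
#'   `r_squared`, `n_obs`, `scope`.
#' @export
fit_allometry <- function(p, m, scope = list()) {
  if (length(p) != length(m)) stop("p and m must have equal length")
  if (length(p) < 3) stop("need at least 3 (P, M) pairs")
  bad <- which(!is.finite(p) | !is.finite(m) | p <= 0 | m <= 0)
  if (length(bad))
    stop("non-positive or non-finite P/M at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  lp <- log(p); lm_ <- log(m)
  if (stats::var(lp) == 0) stop("zero variance in ln P; slope unidentifiable")
  fit <- stats::lm.fit(cbind(1, lp), lm_)
  b <- unname(fit$coefficients[2])
  a0 <- unname(fit$coefficients[1])
  ssr <- sum(fit$residuals^2)
  sst <- sum((lm_ - mean(lm_))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  structure(list(exponent_b = b, ln_a = a0,
                 r_squared = min(max(r2, 0), 1),
                 n_obs = length(p), scope = scope),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("allometric fit: b = %.4f, ln a = %.4f, R^2 = %.4f, n = %d\n",
              x$exponent_b, x$ln_a, x$r_squared, x$n_obs))
  invisible(x)
}

# resolve the supply measure used as M in a regression
supply_values <- function(panel, composite, measure) {
  if (measure == "composite") {
    if (is.null(composite)) stop("measure = 'composite' needs a composite series")
    if (inherits(composite, "supply_index")) composite <- composite$series
    key <- paste(panel$city_id, panel$year)
    idx <- match(key, paste(composite$city_id, composite$year))
    if (anyNA(idx)) stop("composite series does not cover all panel rows")
    composite$m_index[idx]
  } else {
    need <- c("institutions", "beds", "doctors")
    miss <- setdiff(need, names(panel))
    if (length(miss)) stop("panel lacks indicator column(s): ",
                           paste(miss, collapse = ", "))
    panel$institutions + panel$beds + panel$doctors
  }
}

#' Per-year (vertical) allometric exponent series
#'
#' One cross-city log-log fit per year, tracking how the scaling exponent
#' between resource supply and population evolves over time.
#'
#' @param panel Panel `data.frame`.
#' @param composite Optional composite series ([supply_index()] result or its
#'   `series`); required when `measure = "composite"`.
#' @param measure Supply measure regressed on population: `"total"` (sum of
#'   the three raw indicators; preserves an exact generating power law) or
#'   `"composite"` (entropy-weighted index).
#' @param min_cities Minimum usable cities per year; years below it are
#'   dropped with a warning.
#' @return `data.frame` with one row per fitted year: `year`, `exponent_b`,
#'   `ln_a`, `r_squared`, `n_obs`, ordered by year.
#' @export
vertical_series <- function(panel, composite = NULL,
                            measure = c("total", "composite"),
                            min_cities = 3) {
  measure <- match.arg(measure)
  m <- supply_values(panel, composite, measure)
  years <- sort(unique(panel$year))
  rows <- list(); skipped <- integer()
  for (yr in years) {
    sel <- which(panel$year == yr & panel$prp > 0 & m > 0)
    if (length(sel) < min_cities) { skipped <- c(skipped, yr); next }
    f <- fit_allometry(panel$prp[sel], m[sel],
                       scope = list(mode = "vertical", year = yr))
    rows[[length(rows) + 1L]] <- data.frame(
      year = yr, exponent_b = f$exponent_b, ln_a = f$ln_a,
      r_squared = f$r_squared, n_obs = f$n_obs)
  }
  if (length(skipped))
    warning("year(s) with fewer than ", min_cities, " usable cities skipped: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-city (horizontal) allometric fits over a period window
#'
#' One over-time log-log fit per city within an inclusive year window. Cities
#' failing the preconditions (too few in-window years, non-positive values,
#' constant log-population) are reported in an exclusion table, never
#' silently dropped.
#'
#' @param panel Panel `data.frame`.
#' @param composite Optional composite series; see [vertical_series()].
#' @param period Inclusive `c(start, end)` year window.
#' @param measure `"total"` or `"composite"`.
#' @param min_years Minimum usable in-window years per city (default 3).
#' @return A list of class `"horizontal_fits"`: `fits` (`data.frame` of
#'   `city_id`, `start_year`, `end_year`, `exponent_b`, `ln_a`, `r_squared`,
#'   `n_obs`) and `excluded` (`data.frame` of `city_id`, `reason`).
#' @export
horizontal_fits <- function(panel, composite = NULL,
                            period = range(panel$year),
                            measure = c("total", "composite"),
                            min_years = 3) {
  measure <- match.arg(measure)
  stopifnot(length(period) == 2, period[1] <= period[2])
  m <- supply_values(panel, composite, measure)
  inwin <- panel$year >= period[1] & panel$year <= period[2]
  rows <- list(); excl <- list()
  for (ct in sort(unique(panel$city_id))) {
    sel <- which(inwin & panel$city_id == ct)
    usable <- sel[panel$prp[sel] > 0 & m[sel] > 0]
    if (length(usable) < min_years) {
      excl[[length(excl) + 1L]] <- data.frame(
        city_id = ct, reason = sprintf("only %d usable year(s) in window",
                                       length(usable)))
      next
    }
    if (stats::var(log(panel$prp[usable])) == 0) {
      excl[[length(excl) + 1L]] <- data.frame(
        city_id = ct, reason = "constant population series")
      next
    }
    f <- fit_allometry(panel$prp[usable], m[usable],
                       scope = list(mode = "horizontal", city = ct,
                                    period = period))
    rows[[length(rows) + 1L]] <- data.frame(
      city_id = ct, start_year = period[1], end_year = period[2],
      exponent_b = f$exponent_b, ln_a = f$ln_a,
      r_squared = f$r_squared, n_obs = f$n_obs, stringsAsFactors = FALSE)
  }
  fits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(city_id = character(), start_year = integer(),
               end_year = integer(), exponent_b = numeric(),
               ln_a = numeric(), r_squared = numeric(), n_obs = integer())
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(city_id = character(), reason = character())
  rownames(fits) <- rownames(excluded) <- NULL
  structure(list(fits = fits, excluded = excluded, period = period),
            class = "horizontal_fits")
}

#' Partition an annual exponent series into coordination stages
#'
#' Labels each year by where its exponent sits relative to the coordination
#' benchmarks: below 0.85 the population grows faster than resource supply
#' ("PRP expansion"); between 0.85 and 1 the two grow in step ("basic
#' coordination"); at 1 and above resource supply outpaces population
#' ("M&H expansion"). Consecutive years with the same label are merged into
#' contiguous ranges.
#'
#' @param series `data.frame` with `year` and `exponent_b` (e.g. from
#'   [vertical_series()]).
#' @return `data.frame` with `start_year`, `end_year`, `stage`; ranges are
#'   contiguous, non-overlapping, and cover the input years.
#' @export
stage_partition <- function(series) {
  if (is.null(series) || nrow(series) == 0) stop("empty exponent series")
  ord <- order(series$year)
  yr <- series$year[ord]; b <- series$exponent_b[ord]
  lab <- ifelse(b < 0.85, "PRP expansion",
                ifelse(b < 1, "basic coordination", "M&H expansion"))
  grp <- cumsum(c(1L, as.integer(lab[-1] != lab[-length(lab)])))
  out <- data.frame(
    start_year = tapply(yr, grp, min),
    end_year = tapply(yr, grp, max),
    stage = tapply(lab, grp, `[`, 1L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
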