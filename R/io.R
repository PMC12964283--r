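panel_required_cols <- c("city_id", "year", "prp",
                         "institutions", "beds", "doctors")

#' Read a city-year panel from CSV
#'
#' Long-format UTF-8 CSV with a header row and at least the columns
#' `city_id, year, prp, institutions, beds, doctors`; extra columns (driver
#' components) are kept. Validation failures report the offending rows.
#'
#' @param path File path.
#' @return Validated panel `data.frame`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  validate_panel(panel, where = path)
}

validate_panel <- function(panel, where = "panel") {
  miss <- setdiff(panel_required_cols, names(panel))
  if (length(miss))
    stop(where, ": missing required column(s): ", paste(miss, collapse = ", "))
  num_cols <- setdiff(panel_required_cols, "city_id")
  for (cc in num_cols) {
    if (!is.numeric(panel[[cc]]))
      stop(where, ": column '", cc, "' is not numeric")
    bad <- which(is.na(panel[[cc]]))
    if (length(bad))
      stop(where, ": missing/non-numeric values in '", cc, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(panel$city_id, panel$year)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(where, ": duplicate (city_id, year) at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  nonpos <- which(panel$prp <= 0)
  if (length(nonpos))
    stop(where, ": non-positive prp at row(s) ",
         paste(utils::head(nonpos, 5), collapse = ", "))
  panel
}

#' Write a city-year panel to CSV
#'
#' Numeric columns are serialized with 17 significant digits so that
#' [read_panel()] round-trips the panel exactly.
#'
#' @param panel Panel `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- panel
  for (cc in names(out))
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Fisher-Jenks natural breaks
#'
#' Exact dynamic-programming optimum of one-dimensional classification:
#' partitions the sorted values into `k` contiguous classes minimizing the
#' total within-class sum of squared deviations. Used for map-ready binning
#' of composite indices and exponents, never in the statistics themselves.
#'
#' @param values Numeric vector (at least `k` distinct values).
#' @param k Number of classes (>= 1).
#' @return A list of class `"jenks_breaks"`: `breaks` (length `k + 1`;
#'   first/last equal the data min/max, interior breaks are upper class
#'   bounds), `k`, `assignments` (class index per input value, 1-based), and
#'   `wss` (the minimized within-class sum of squares).
#' @export
jenks_breaks <- function(values, k) {
  if (any(!is.finite(values))) stop("non-finite values")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  n_distinct <- length(unique(values))
  if (k > n_distinct)
    stop("k (", k, ") exceeds number of distinct values (", n_distinct, ")")
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(a, b) { # within-class SSE of x[a..b]
    s <- cs[b] - if (a > 1) cs[a - 1] else 0
    s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    s2 - s^2 / (b - a + 1)
  }
  # dp[j, i]: minimal SSE of x[1..i] split into j classes
  dp <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (i in seq_len(n)) { dp[1, i] <- sse(1, i); back[1, i] <- 1L }
  if (k > 1) for (j in 2:k) for (i in j:n) {
    for (m in j:i) {
      cand <- dp[j - 1, m - 1] + sse(m, i)
      if (cand < dp[j, i]) { dp[j, i] <- cand; back[j, i] <- m }
    }
  }
  # recover class boundaries
  bounds <- integer(k + 1); bounds[k + 1] <- n
  i <- n
  for (j in k:1) { bounds[j] <- back[j, i] - 1L; i <- back[j, i] - 1L }
  breaks <- c(x[1], x[bounds[2:(k + 1)]])
  starts <- bounds[1:k] + 1L
  cls_sorted <- rep(seq_len(k), times = diff(bounds))
  assignments <- cls_sorted[match(values, x)]  # first match; ties share class
  structure(list(breaks = breaks, k = k, assignments = assignments,
                 wss = dp[k, n]), class = "jenks_breaks")
}

#' Pipeline configuration
#'
#' @param input A panel `data.frame`, a CSV path, or a [synthetic_config()]
#'   (generated at run time; a config with `drivers` set produces a driver
#'   panel, `exponents_by_city` a horizontal panel, otherwise vertical).
#' @param out_dir Output directory (created if absent).
#' @param epsilon Composite-index shift, see [supply_index()].
#' @param periods List of inclusive year windows for horizontal fits;
#'   default `list(c(2000, 2010), c(2011, 2022))`.
#' @param measure Supply measure for exponent fits, `"total"` or
#'   `"composite"`; see [vertical_series()].
#' @param brt A [brt_config()] (used only when the panel carries driver
#'   component columns).
#' @param jenks_k Class count for map-ready binning of the latest-year
#'   composite (default 5).
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input, out_dir,
                            epsilon = 1e-4,
                            periods = list(c(2000, 2010), c(2011, 2022)),
                            measure = "total",
                            brt = brt_config(),
                            jenks_k = 5,
                            seed = 1L) {
  stopifnot(length(periods) >= 1)
  for (p in periods) {
    if (length(p) != 2 || p[1] > p[2])
      stop("invalid period window: ", paste(p, collapse = "-"))
  }
  if (length(periods) > 1) {
    for (i in seq_len(length(periods) - 1))
      if (periods[[i]][2] >= periods[[i + 1]][1])
        stop("period windows must be non-overlapping and ordered")
  }
  structure(list(input = input, out_dir = out_dir, epsilon = epsilon,
                 periods = periods, measure = measure, brt = brt,
                 jenks_k = jenks_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_table <- function(df, path) {
  out <- df
  for (cc in names(out))
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Run the full coordination-analysis pipeline
#'
#' Composite index -> vertical exponent series and stage partition ->
#' horizontal fits per period -> typology and change analysis -> (when
#' driver components are present) boosted-tree driver decomposition; all
#' tables are written as CSV under the output directory together with a
#' JSON manifest (weights, seed, exclusions, stage partition, class
#' summaries). Rerunning with an identical config reproduces identical
#' files.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  panel <- stage("input", {
    inp <- config$input
    if (inherits(inp, "synthetic_config")) {
      if (!is.null(inp$drivers)) generate_driver_panel(inp)$panel
      else if (!is.null(inp$exponents_by_city)) generate_horizontal_panel(inp)
      else generate_vertical_panel(inp)
    } else if (is.character(inp)) read_panel(inp)
    else validate_panel(inp)
  })
  yr_range <- range(panel$year)
  for (p in config$periods)
    if (p[1] > yr_range[2] || p[2] < yr_range[1])
      stop("[config] period window ", p[1], "-", p[2],
           " lies outside panel years ", yr_range[1], "-", yr_range[2])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)

  idx <- stage("index", supply_index(panel, epsilon = config$epsilon))
  write_table(idx$series, outp("composite_index.csv"))

  vert <- stage("allometry-vertical",
                vertical_series(panel, idx, measure = config$measure))
  write_table(vert, outp("vertical_exponents.csv"))
  stages <- stage("allometry-vertical", stage_partition(vert))
  write_table(stages, outp("stage_partition.csv"))

  horiz <- list(); summaries <- list(); exclusions <- list()
  for (p in config$periods) {
    key <- paste0(p[1], "_", p[2])
    h <- stage("allometry-horizontal",
               horizontal_fits(panel, idx, period = p,
                               measure = config$measure))
    horiz[[key]] <- h
    cls <- classify_exponent(h$fits$exponent_b)
    out <- cbind(h$fits[c("city_id", "start_year", "end_year",
                          "exponent_b", "r_squared", "n_obs")],
                 cls[c("label", "rank", "long_label")])
    write_table(out, outp(paste0("horizontal_", key, ".csv")))
    exclusions[[key]] <- h$excluded
    write_table(h$excluded, outp(paste0("excluded_", key, ".csv")))
    s <- stage("typology", summarize_counts(h))
    summaries[[key]] <- list(positive = s$positive, negative = s$negative,
                             total = s$total)
    write_table(s$by_class, outp(paste0("class_counts_", key, ".csv")))
  }
  if (length(horiz) >= 2) {
    ch <- stage("typology", change_table(horiz[[1]], horiz[[2]]))
    write_table(ch, outp("change_table.csv"))
  }

  has_drivers <- all(unique(c(driver_features()$numerator,
                              driver_features()$denominator)) %in%
                       names(panel))
  brt_trees <- list()
  if (has_drivers) {
    for (key in names(horiz)) {
      p <- horiz[[key]]$period
      tab <- stage("drivers", build_driver_table(panel, horiz[[key]], p))
      res <- stage("drivers", fit_brt(tab, config$brt))
      write_table(relative_influence(res),
                  outp(paste0("influence_", key, ".csv")))
      profs <- do.call(rbind, lapply(res$features, function(ft)
        marginal_profile(res, ft)))
      write_table(profs, outp(paste0("profiles_", key, ".csv")))
      brt_trees[[key]] <- res$n_trees_used
    }
  }

  last_year <- max(panel$year)
  m_last <- idx$series$m_index[idx$series$year == last_year]
  jb <- stage("jenks", jenks_breaks(m_last, min(config$jenks_k,
                                                length(unique(m_last)))))
  jsonlite::write_json(list(year = last_year, k = jb$k, breaks = jb$breaks),
                       outp("jenks_breaks.json"), auto_unbox = TRUE,
                       digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("allohealth")),
    seed = config$seed,
    epsilon = idx$epsilon,
    weights = as.list(idx$weights),
    measure = config$measure,
    periods = config$periods,
    n_cities = length(unique(panel$city_id)),
    years = yr_range,
    n_vertical_fits = nrow(vert),
    stage_partition = stages,
    typology = summaries,
    exclusions = lapply(exclusions, function(e) e$city_id),
    brt_trees = brt_trees,
    drivers_fitted = has_drivers)
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(manifest)
}
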