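#' The ten driver indicators and their component columns
#'
#' Each driver of the per-city allometric exponent is a ratio of raw panel
#' columns, scaled to the field's customary unit (most are percentages;
#' per-capita GDP is yuan/person and population density persons/km^2).
#'
#' @return `data.frame` with `feature`, `factor_name` (human-readable
#'   influencing factor), `numerator`, `denominator` (panel column names),
#'   `scale` (100 for percentages, 1 otherwise), `unit`.
#' @export
driver_features <- function() {
  data.frame(
    feature = c("pc_gdp", "tertiary_share", "fiscal_ratio", "mh_invest_share",
                "urban_rate", "pop_attraction", "pop_density", "income_ratio",
                "mh_consum_share", "aging_rate"),
    factor_name = c("Economic development level", "Industrial structure",
                    "Fiscal self-sufficiency capacity", "Medical investment",
                    "Urban development level", "Population attraction",
                    "Population concentration", "Urban-rural income gap",
                    "Medical consumption", "Aging"),
    numerator = c("gdp", "tertiary_va", "fiscal_revenue",
                  "mh_gov_expenditure", "urban_pop", "prp", "prp",
                  "urban_income", "mh_consum_expenditure", "pop65"),
    denominator = c("prp", "gdp", "fiscal_expenditure", "fiscal_expenditure",
                    "prp", "registered_pop", "admin_area", "rural_income",
                    "living_expenses", "prp"),
    scale = c(1, 100, 100, 100, 100, 100, 1, 100, 100, 100),
    unit = c("yuan/person", "%", "%", "%", "%", "%", "person/km2", "%",
             "%", "%"),
    stringsAsFactors = FALSE)
}

#' Build the driver table for boosted-tree analysis
#'
#' One row per city: the ten driver indicators as period means of the annual
#' ratios computed from the panel's raw component columns, with the city's
#' horizontal allometric exponent for that period as the response.
#'
#' @param panel Panel `data.frame` carrying the raw component columns listed
#'   by [driver_features()].
#' @param fits [horizontal_fits()] result (or its `fits` frame) giving each
#'   city's exponent for the period.
#' @param period Inclusive `c(start, end)` year window over which annual
#'   ratios are averaged; defaults to the fits' period if available.
#' @return `data.frame`: `city_id`, the ten feature columns, and response
#'   `b`.
#' @export
build_driver_table <- function(panel, fits, period = NULL) {
  feats <- driver_features()
  f <- if (inherits(fits, "horizontal_fits")) {
    if (is.null(period)) period <- fits$period
    fits$fits
  } else fits
  if (is.null(period)) period <- range(panel$year)
  need <- unique(c(feats$numerator, feats$denominator))
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    affected <- feats$factor_name[feats$numerator %in% miss |
                                  feats$denominator %in% miss]
    stop("panel lacks component column(s) ", paste(miss, collapse = ", "),
         " needed for: ", paste(unique(affected), collapse = "; "))
  }
  inwin <- panel$year >= period[1] & panel$year <= period[2]
  if (!any(inwin)) stop("no panel rows inside period ",
                        period[1], "-", period[2])
  sub <- panel[inwin, , drop = FALSE]
  rows <- lapply(sort(unique(f$city_id)), function(ct) {
    s <- sub[sub$city_id == ct, , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    vals <- vapply(seq_len(nrow(feats)), function(j) {
      mean(feats$scale[j] * s[[feats$numerator[j]]] /
             s[[feats$denominator[j]]])
    }, numeric(1))
    out <- as.data.frame(as.list(stats::setNames(vals, feats$feature)))
    cbind(data.frame(city_id = ct, stringsAsFactors = FALSE), out,
          data.frame(b = f$exponent_b[f$city_id == ct][1]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$pc_gdp <= 0) || any(out$pop_density <= 0))
    stop("per-capita GDP and population density must be strictly positive")
  if (anyNA(out)) stop("missing values in driver table")
  out
}

#' Boosted-regression-tree configuration
#'
#' Stagewise gradient boosting with squared-error loss on depth-limited
#' trees: `tree_complexity` is the maximum interaction depth, and
#' `learning_rate` the shrinkage applied to each tree. The number of trees
#' is selected by `cv_folds`-fold cross-validation up to `max_trees`, with
#' rows subsampled at `bag_fraction` per tree.
#'
#' @param tree_complexity Maximum tree depth (default 3).
#' @param learning_rate Shrinkage in `(0, 1]` (default 0.01).
#' @param max_trees Upper bound on boosting iterations (default 10000;
#'   cross-validation stops early once held-out error stops improving).
#' @param cv_folds Number of CV folds (default 10).
#' @param bag_fraction Row subsample fraction per tree (default 0.75).
#' @param seed Integer seed controlling fold assignment and subsampling.
#' @return A list of class `"brt_config"`.
#' @export
brt_config <- function(tree_complexity = 3, learning_rate = 0.01,
                       max_trees = 10000, cv_folds = 10,
                       bag_fraction = 0.75, seed = 1L) {
  stopifnot(tree_complexity >= 1, learning_rate > 0, learning_rate <= 1,
            max_trees >= 1, cv_folds >= 2,
            bag_fraction > 0, bag_fraction <= 1)
  structure(list(tree_complexity = as.integer(tree_complexity),
                 learning_rate = learning_rate,
                 max_trees = as.integer(max_trees),
                 cv_folds = as.integer(cv_folds),
                 bag_fraction = bag_fraction, seed = as.integer(seed)),
            class = "brt_config")
}

#' Fit a boosted regression tree to the driver table
#'
#' Gradient boosting (squared-error loss, depth-limited trees, shrinkage,
#' row bagging) of the per-city exponent on the ten drivers. The tree count
#' is chosen by seeded k-fold cross-validation; identical table, config and
#' seed give an identical fit.
#'
#' @param table Driver table from [build_driver_table()] (>= 10 rows).
#' @param config A [brt_config()].
#' @return A list of class `"brt_result"`: `relative_influences` (named
#'   percentages summing to 100), `n_trees_used`, `model` (the fitted
#'   booster), `feature_means`, `feature_ranges`, `features`, `config`.
#' @export
fit_brt <- function(table, config = brt_config()) {
  stopifnot(inherits(config, "brt_config"))
  feats <- intersect(driver_features()$feature, names(table))
  if (length(feats) == 0) stop("driver table has no known feature columns")
  if (!"b" %in% names(table)) stop("driver table lacks response column 'b'")
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows to fit a boosted model")
  if (n < config$cv_folds)
    stop("fewer rows (", n, ") than cv_folds (", config$cv_folds, ")")
  y <- table$b
  if (any(!is.finite(y))) stop("non-finite response values")
  if (stats::var(y) == 0)
    stop("constant response: no structure to fit")
  X <- as.matrix(table[feats])
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(objective = "reg:squarederror",
                 max_depth = config$tree_complexity,
                 eta = config$learning_rate,
                 subsample = config$bag_fraction,
                 nthread = 1, seed = config$seed)
  set.seed(config$seed)
  idx <- sample(n)
  folds <- unname(split(idx, rep_len(seq_len(config$cv_folds), n)))
  cv <- xgboost::xgb.cv(params = params, data = dtrain,
                        nrounds = config$max_trees, folds = folds,
                        early_stopping_rounds = 50, verbose = 0)
  best <- cv$early_stop$best_iteration
  if (is.null(best)) best <- cv$niter
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = best, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  rel <- stats::setNames(rep(0, length(feats)), feats)
  rel[imp$Feature] <- imp$Gain * 100
  rng <- apply(X, 2, range)
  structure(list(relative_influences = rel, n_trees_used = best,
                 model = bst,
                 feature_means = colMeans(X),
                 feature_ranges = rng, features = feats,
                 config = config),
            class = "brt_result")
}

#' Relative influence (contribution rate) table
#'
#' Per-feature percentages of the boosted model's explanatory structure
#' (split-gain shares), summing to 100, ranked descending with ties broken
#' by feature name order.
#'
#' @param result A [fit_brt()] result.
#' @return `data.frame`: `feature`, `factor_name`, `percentage`, `rank`.
#' @export
relative_influence <- function(result) {
  stopifnot(inherits(result, "brt_result"))
  rel <- result$relative_influences
  feats <- driver_features()
  ord <- order(-rel, names(rel))
  out <- data.frame(
    feature = names(rel)[ord],
    factor_name = feats$factor_name[match(names(rel)[ord], feats$feature)],
    percentage = unname(rel[ord]),
    rank = seq_along(rel),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Marginal-effect profile of one driver
#'
#' Model predictions along an equally spaced grid over the feature's
#' observed range with every other feature pinned at its training mean — a
#' ceteris-paribus profile (not averaged partial dependence).
#'
#' @param result A [fit_brt()] result.
#' @param feature Feature name.
#' @param grid_size Number of grid points (default 100).
#' @return `data.frame`: `feature`, `grid_value`, `prediction`. Grid
#'   endpoints equal the observed feature minimum and maximum.
#' @export
marginal_profile <- function(result, feature, grid_size = 100) {
  stopifnot(inherits(result, "brt_result"))
  if (!feature %in% result$features)
    stop("unknown feature: ", feature)
  rng <- result$feature_ranges[, feature]
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  newx <- matrix(rep(result$feature_means, each = grid_size),
                 nrow = grid_size,
                 dimnames = list(NULL, result$features))
  newx[, feature] <- grid
  pred <- predict(result$model,
                  xgboost::xgb.DMatrix(newx, nthread = 1))
  data.frame(feature = feature, grid_value = grid, prediction = pred,
             stringsAsFactors = FALSE)
}
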