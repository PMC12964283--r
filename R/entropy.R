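#' Range-normalize an indicator matrix
#'
#' Min-max normalization over the pooled panel (all cities x all years):
#' `Z = (x - min) / (max - min)` per column, optionally followed by a small
#' positive shift `Z' = (Z + epsilon) / (1 + epsilon)` so every value is
#' strictly positive — needed when logs of the composite are taken
#' downstream. `epsilon = 0` disables the shift.
#'
#' @param x Numeric matrix or data.frame of indicator columns (one row per
#'   city-year observation).
#' @param epsilon Small positive shift; default 0.
#' @return Numeric matrix with values in `[0, 1]` (in `(0, 1]` after a
#'   positive shift), same dimnames as the input.
#' @export
range_normalize <- function(x, epsilon = 0) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("indicator matrix must be numeric")
  if (nrow(x) < 2) stop("need at least two observations to normalize")
  stopifnot(epsilon >= 0)
  rng <- apply(x, 2, range)
  flat <- rng[1, ] == rng[2, ]
  if (any(flat))
    stop("constant indicator column(s): ",
         paste(colnames(x)[flat], collapse = ", "),
         "; range normalization undefined")
  z <- sweep(sweep(x, 2, rng[1, ], `-`), 2, rng[2, ] - rng[1, ], `/`)
  if (epsilon > 0) z <- (z + epsilon) / (1 + epsilon)
  z
}

#' Entropy weights of indicator columns
#'
#' Objective weighting by information entropy: indicators whose normalized
#' values are more dispersed across observations (lower entropy) carry more
#' information and receive larger weights. With `p_ij = Z_ij / sum_i Z_ij`,
#' `e_j = -(1/ln n) sum_i p_ij ln p_ij` (taking `0 ln 0 = 0`) and
#' `w_j = (1 - e_j) / sum_k (1 - e_k)`.
#'
#' @param z Non-negative matrix of normalized indicator values, `n >= 2`
#'   rows, each column with at least one strictly positive entry.
#' @return Named numeric weight vector summing to 1.
#' @export
entropy_weights <- function(z) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2) stop("entropy weights need at least 2 observations")
  if (any(z < 0)) stop("normalized values must be non-negative")
  cs <- colSums(z)
  if (any(cs == 0)) stop("column(s) with no positive entry: ",
                         paste(colnames(z)[cs == 0], collapse = ", "))
  p <- sweep(z, 2, cs, `/`)
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(n)
  d <- 1 - e
  # numerical guard: entropy of a uniform column is exactly 1 in theory
  d[abs(d) < 1e-15] <- 0
  if (all(d == 0))
    stop("all indicators perfectly uniform after normalization; weights undefined")
  d / sum(d)
}

#' Composite supply index by weighted summation
#'
#' `M_i = sum_j Z_ij * w_j`: a convex combination of the normalized
#' indicators, so each composite value lies between the row minimum and
#' maximum of `z`.
#'
#' @param z Normalized indicator matrix.
#' @param w Weight vector, one weight per column of `z`.
#' @return Numeric vector of composite values, one per row.
#' @export
composite_index <- function(z, w) {
  z <- as.matrix(z)
  if (ncol(z) != length(w))
    stop("dimension mismatch: ", ncol(z), " indicator columns but ",
         length(w), " weights")
  as.vector(z %*% w)
}

#' Entropy-weighted supply index for a city panel
#'
#' Convenience wrapper running the full composite-index construction on a
#' panel's three resource indicators: pooled range normalization (with a
#' strictly-positive epsilon shift so logs are defined downstream), entropy
#' weighting, and weighted summation.
#'
#' @param panel Panel `data.frame` with `city_id`, `year`, `institutions`,
#'   `beds`, `doctors`.
#' @param epsilon Post-normalization shift; default `1e-4`. Recorded in the
#'   returned metadata.
#' @param per_year If `TRUE`, normalization and entropy are computed within
#'   each year instead of over the pooled panel. Default `FALSE` (pooled), so
#'   a single weight triple describes the whole study window.
#' @return A list of class `"supply_index"`: `series` (`data.frame` of
#'   `city_id`, `year`, `m_index`), `weights` (named, summing to 1; a
#'   year-by-indicator matrix when `per_year`), `epsilon`, and `scope`.
#' @export
supply_index <- function(panel, epsilon = 1e-4, per_year = FALSE) {
  cols <- c("institutions", "beds", "doctors")
  miss <- setdiff(cols, names(panel))
  if (length(miss)) stop("panel lacks indicator column(s): ",
                         paste(miss, collapse = ", "))
  if (!per_year) {
    z <- range_normalize(panel[cols], epsilon = epsilon)
    w <- entropy_weights(z)
    m <- composite_index(z, w)
  } else {
    m <- numeric(nrow(panel))
    wl <- list()
    for (yr in sort(unique(panel$year))) {
      sel <- panel$year == yr
      z <- range_normalize(panel[sel, cols], epsilon = epsilon)
      w <- entropy_weights(z)
      m[sel] <- composite_index(z, w)
      wl[[as.character(yr)]] <- w
    }
    w <- do.call(rbind, wl)
  }
  structure(list(
    series = data.frame(city_id = panel$city_id, year = panel$year,
                        m_index = m, stringsAsFactors = FALSE),
    weights = w, epsilon = epsilon,
    scope = if (per_year) "per-year" else "pooled"),
    class = "supply_index")
}
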