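#' The six-level allometric growth typology
#'
#' Half-open, lower-inclusive exponent intervals partitioning the real line
#' around the b = 0.85 coordination benchmark: three negative-allometry
#' levels (resource supply lagging population) and three positive levels
#' (supply keeping pace with or outpacing population). Ranks order the
#' classes from NAG3 (lowest) to PAG3 (highest), matching the field's
#' language of cities "upgrading" toward positive allometry.
#'
#' @return `data.frame` with `label` (`NAG3` ... `PAG3`), `rank` (0-5),
#'   `lower`, `upper` (half-open `[lower, upper)` bounds), and `long_label`
#'   (printed form, e.g. `"Negative allometric level 1"`).
#' @export
allometry_classes <- function() {
  data.frame(
    label = c("NAG3", "NAG2", "NAG1", "PAG1", "PAG2", "PAG3"),
    rank = 0:5,
    lower = c(-Inf, 0, 0.5, 0.85, 1, 3),
    upper = c(0, 0.5, 0.85, 1, 3, Inf),
    long_label = c("Negative allometric level 3",
                   "Negative allometric level 2",
                   "Negative allometric level 1",
                   "Positive allometric level 1",
                   "Positive allometric level 2",
                   "Positive allometric level 3"),
    stringsAsFactors = FALSE)
}

#' Classify allometric exponents
#'
#' Maps each finite exponent to its unique class by the lower-inclusive
#' intervals of [allometry_classes()]; in particular the benchmark value
#' b = 0.85 itself is positive allometric level 1.
#'
#' @param b Numeric vector of exponents (finite).
#' @return `data.frame` with `exponent_b`, `label`, `rank`, `long_label`.
#' @export
classify_exponent <- function(b) {
  if (any(!is.finite(b))) stop("non-finite exponent(s)")
  cls <- allometry_classes()
  idx <- findInterval(b, c(cls$lower[-1])) + 1L  # breaks 0, 0.5, 0.85, 1, 3
  data.frame(exponent_b = b, label = cls$label[idx], rank = cls$rank[idx],
             long_label = cls$long_label[idx], stringsAsFactors = FALSE)
}

#' Classify the change in a city's allometric type between two periods
#'
#' A rank increase between the first- and second-period classes is an
#' upgrade, a decrease a downgrade; within the same class the sign of the
#' exponent change decides improvement vs decline, with changes below `tol`
#' in magnitude treated as stable.
#'
#' @param fit1,fit2 `"allometric_fit"` objects for the same city in two
#'   periods (scopes must carry matching `city` entries), or bare numeric
#'   exponents.
#' @param city_id City identifier (required when bare exponents are given).
#' @param tol Stability tolerance on `delta_b` (default `1e-9`).
#' @return One-row `data.frame`: `city_id`, `class_p1`, `class_p2`,
#'   `delta_b`, `change_kind` in
#'   `{upgraded, improved-within-level, stable, declined-within-level, downgraded}`.
#' @export
change_type <- function(fit1, fit2, city_id = NULL, tol = 1e-9) {
  get_b <- function(f) if (inherits(f, "allometric_fit")) f$exponent_b else f
  get_city <- function(f)
    if (inherits(f, "allometric_fit")) f$scope$city else NULL
  c1 <- get_city(fit1); c2 <- get_city(fit2)
  if (!is.null(c1) && !is.null(c2) && !identical(c1, c2))
    stop("change_type: fits are for different cities (", c1, " vs ", c2, ")")
  if (is.null(city_id)) city_id <- if (!is.null(c1)) c1 else NA_character_
  b1 <- get_b(fit1); b2 <- get_b(fit2)
  k1 <- classify_exponent(b1); k2 <- classify_exponent(b2)
  delta <- b2 - b1
  kind <- if (k2$rank > k1$rank) "upgraded"
          else if (k2$rank < k1$rank) "downgraded"
          else if (delta > tol) "improved-within-level"
          else if (delta < -tol) "declined-within-level"
          else "stable"
  data.frame(city_id = city_id, class_p1 = k1$label, class_p2 = k2$label,
             delta_b = delta, change_kind = kind, stringsAsFactors = FALSE)
}

#' Change table across all cities of two horizontal-fit sets
#'
#' @param fits1,fits2 [horizontal_fits()] results (or their `fits` frames)
#'   for two periods; only cities present in both are compared.
#' @param tol Passed to [change_type()].
#' @return `data.frame`, one row per shared city.
#' @export
change_table <- function(fits1, fits2, tol = 1e-9) {
  f1 <- if (inherits(fits1, "horizontal_fits")) fits1$fits else fits1
  f2 <- if (inherits(fits2, "horizontal_fits")) fits2$fits else fits2
  shared <- intersect(f1$city_id, f2$city_id)
  out <- do.call(rbind, lapply(shared, function(ct)
    change_type(f1$exponent_b[f1$city_id == ct],
                f2$exponent_b[f2$city_id == ct], city_id = ct, tol = tol)))
  rownames(out) <- NULL
  out
}

# round half away from zero (so 24/41 -> 58.54, not banker's rounding)
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Class counts and percentage shares of a set of per-city fits
#'
#' @param fits [horizontal_fits()] result, its `fits` frame, or any
#'   `data.frame` with `exponent_b` (and optionally `city_id`).
#' @return A list of class `"typology_summary"`: `by_class` (`data.frame` of
#'   `label`, `long_label`, `count`, `share`), `positive` / `negative`
#'   (lists of `count`, `share` over the PAG / NAG classes), `total`. Shares
#'   are percentages rounded half-up to 2 decimals.
#' @export
summarize_counts <- function(fits) {
  f <- if (inherits(fits, "horizontal_fits")) fits$fits else fits
  if (is.null(f) || nrow(f) == 0) stop("no fits to summarize")
  k <- classify_exponent(f$exponent_b)
  cls <- allometry_classes()
  count <- vapply(cls$label, function(l) sum(k$label == l), integer(1))
  total <- nrow(f)
  by_class <- data.frame(label = cls$label, long_label = cls$long_label,
                         count = unname(count),
                         share = round_half_up(100 * unname(count) / total),
                         stringsAsFactors = FALSE)
  pos <- sum(count[c("PAG1", "PAG2", "PAG3")])
  neg <- sum(count[c("NAG1", "NAG2", "NAG3")])
  structure(list(
    by_class = by_class,
    positive = list(count = pos, share = round_half_up(100 * pos / total)),
    negative = list(count = neg, share = round_half_up(100 * neg / total)),
    total = total), class = "typology_summary")
}

#' @export
print.typology_summary <- function(x, ...) {
  cat(sprintf("%d cities: %d positive (%.2f%%), %d negative (%.2f%%)\n",
              x$total, x$positive$count, x$positive$share,
              x$negative$count, x$negative$share))
  print(x$by_class, row.names = FALSE)
  invisible(x)
}
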