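#' Rank units by importance
#'
#' Importance is the absolute total effect \eqn{|r_{jy}|}: the closer to 1,
#' the more important the unit is to the activity. Ties keep the input
#' column order (stable sort).
#'
#' @param decomp a `path_decomposition`.
#' @return data frame `unit`, `total`, `rank`, ordered by descending
#'   `|total|`.
#' @export
rank_units <- function(decomp) {
  stopifnot(inherits(decomp, "path_decomposition"))
  ord <- order(-abs(decomp$total))  # radix sort: stable on ties
  data.frame(unit = decomp$units[ord],
             total = unname(decomp$total[ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Classify a unit's influence mode
#'
#' A unit mainly *directly* regulates the activity when its absolute direct
#' effect exceeds the absolute sum of its indirect effects (by more than
#' `margin`); otherwise its influence is mainly *indirect*, i.e. routed
#' through correlated units.
#'
#' @param decomp a `path_decomposition`.
#' @param unit single unit name, or `NULL` for all units.
#' @param margin nonnegative dominance margin, default 0.
#' @return `"direct"` or `"indirect"`; a named character vector when `unit`
#'   is `NULL`.
#' @export
classify_influence <- function(decomp, unit = NULL, margin = 0) {
  stopifnot(inherits(decomp, "path_decomposition"), margin >= 0)
  modes <- ifelse(abs(decomp$direct) > abs(decomp$indirect_sum) + margin,
                  "direct", "indirect")
  names(modes) <- decomp$units
  if (is.null(unit)) return(modes)
  if (!unit %in% decomp$units) {
    pathsar_abort(sprintf("unknown unit '%s'", unit), "pathsar_lookup_error")
  }
  unname(modes[unit])
}

#' Assign importance categories from total effects
#'
#' Category 1 collects the units whose \eqn{|r_{jy}|} is at least the first
#' boundary, category 2 those between the second and first boundary, and so
#' on (k boundaries give k + 1 categories). Boundaries are inclusive on the
#' upper side. The defaults (0.88, 0.70) reproduce a three-way split into
#' major / medium / minor units; they are a configurable convention, not a
#' law.
#'
#' @param decomp a `path_decomposition`.
#' @param boundaries strictly descending thresholds in (0, 1).
#' @return named integer vector, one category per unit.
#' @export
categorize_importance <- function(decomp, boundaries = c(0.88, 0.70)) {
  stopifnot(inherits(decomp, "path_decomposition"))
  if (length(boundaries) < 1L || any(boundaries <= 0) || any(boundaries >= 1) ||
      is.unsorted(rev(boundaries), strictly = TRUE)) {
    pathsar_abort("`boundaries` must be strictly descending values in (0, 1)",
                  "pathsar_config_error")
  }
  at <- abs(decomp$total)
  cat_of <- function(a) {
    hit <- which(a >= boundaries)
    if (length(hit)) hit[1L] else length(boundaries) + 1L
  }
  stats::setNames(vapply(at, cat_of, integer(1L)), decomp$units)
}

#' Per-unit assessment table
#'
#' Collects total/direct/indirect-sum, importance rank, direction of the
#' total effect, influence mode and importance category for every unit.
#'
#' @param decomp a `path_decomposition`.
#' @param boundaries passed to [categorize_importance()].
#' @param margin passed to [classify_influence()].
#' @return data frame, one row per unit in input column order.
#' @export
assess_units <- function(decomp, boundaries = c(0.88, 0.70), margin = 0) {
  stopifnot(inherits(decomp, "path_decomposition"))
  rk <- rank_units(decomp)
  rank <- stats::setNames(rk$rank, rk$unit)[decomp$units]
  data.frame(
    unit = decomp$units,
    total = unname(decomp$total),
    direct = unname(decomp$direct),
    indirect_sum = unname(decomp$indirect_sum),
    rank = unname(rank),
    direction = ifelse(decomp$total >= 0, "positive", "negative"),
    influence_mode = unname(classify_influence(decomp, margin = margin)),
    category = unname(categorize_importance(decomp, boundaries)),
    stringsAsFactors = FALSE)
}

#' Compare the effect of every unit across two activities
#'
#' Side-by-side totals, directions, influence modes and categories for two
#' decompositions over the same units (e.g. antioxidant vs anti-diabetes).
#' A unit's overall category is the better (smaller) of its per-activity
#' categories, so a unit that is major for either activity is listed as
#' major overall.
#'
#' @param d1,d2 `path_decomposition` objects over identical unit sets.
#' @param boundaries,margin passed through to the per-activity assessments.
#' @return object of class `activity_comparison`: a data frame `table` with
#'   per-activity columns plus `overall_category`, `direction_differs`,
#'   `mode_differs`; and `major_units`, the overall category-1 units.
#' @export
compare_activities <- function(d1, d2, boundaries = c(0.88, 0.70), margin = 0) {
  stopifnot(inherits(d1, "path_decomposition"),
            inherits(d2, "path_decomposition"))
  if (!identical(d1$units, d2$units)) {
    pathsar_abort("the two decompositions cover different unit sets",
                  "pathsar_contract_error")
  }
  a1 <- assess_units(d1, boundaries, margin)
  a2 <- assess_units(d2, boundaries, margin)
  tab <- data.frame(
    unit = a1$unit,
    total_1 = a1$total, direct_1 = a1$direct, indirect_sum_1 = a1$indirect_sum,
    direction_1 = a1$direction, mode_1 = a1$influence_mode,
    category_1 = a1$category,
    total_2 = a2$total, direct_2 = a2$direct, indirect_sum_2 = a2$indirect_sum,
    direction_2 = a2$direction, mode_2 = a2$influence_mode,
    category_2 = a2$category,
    stringsAsFactors = FALSE)
  tab$overall_category <- pmin(tab$category_1, tab$category_2)
  tab$direction_differs <- tab$direction_1 != tab$direction_2
  tab$mode_differs <- tab$mode_1 != tab$mode_2
  structure(
    list(table = tab,
         activities = c(d1$activity, d2$activity),
         major_units = tab$unit[tab$overall_category == 1L]),
    class = "activity_comparison")
}

#' @export
print.activity_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("<activity_comparison> %s vs %s; major units: %s\n",
              x$activities[1L], x$activities[2L],
              paste(x$major_units, collapse = ", ")))
  df <- x$table
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits)
  print(df)
  invisible(x)
}
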