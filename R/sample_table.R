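#' Construct a sample table of component abundances and activities
#'
#' The basic data container: an \eqn{n \times m} matrix of component
#' abundances (one column per monomer unit or other mixture component), plus
#' one or more named activity vectors measured on the same \eqn{n} samples.
#'
#' @param values numeric matrix, samples in rows, components in columns;
#'   column names are the unit names.
#' @param units optional character vector of unit names (defaults to
#'   `colnames(values)`) or a data frame with columns `name` and `position`.
#'   Positions (`"terminal"`, `"extension"`, `"unspecified"`) are annotation
#'   only and never enter any computation; when not given they are inferred
#'   from a trailing `"t"`/`"e"` in the name.
#' @param activities named list of numeric vectors, each of length `n`.
#' @param design optional grouping vector of length `n` (e.g. the
#'   polymerization-degree fraction each sample belongs to).
#'
#' @return an object of class `sample_table` with fields `values`, `units`
#'   (data frame `name`/`position`), `activities`, `n_samples`, `design`.
#'
#' @details Invariants enforced: no missing entries, at least 3 samples,
#'   strictly positive variance in every unit column, unique non-empty unit
#'   names, all activity vectors of length `n`.
#' @export
sample_table <- function(values, units = NULL, activities = list(),
                         design = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    pathsar_abort("`values` must be a numeric matrix", "pathsar_parse_error")
  }
  n <- nrow(values)
  m <- ncol(values)
  if (n < 3L) {
    pathsar_abort(sprintf("need at least 3 samples, got %d", n),
                  "pathsar_degenerate_data")
  }
  if (anyNA(values)) {
    pathsar_abort("missing entries in component abundance matrix",
                  "pathsar_parse_error")
  }
  units <- as_unit_frame(units %||% colnames(values), m)
  colnames(values) <- units$name

  zero_var <- apply(values, 2L, function(x) var(x) <= 0 || !is.finite(var(x)))
  if (any(zero_var)) {
    pathsar_abort(
      sprintf("zero-variance unit column(s): %s",
              paste(units$name[zero_var], collapse = ", ")),
      "pathsar_degenerate_data")
  }

  if (length(activities)) {
    if (is.null(names(activities)) || any(!nzchar(names(activities)))) {
      pathsar_abort("activities must be a named list", "pathsar_parse_error")
    }
    for (a in names(activities)) {
      v <- activities[[a]]
      if (!is.numeric(v) || length(v) != n || anyNA(v)) {
        pathsar_abort(
          sprintf("activity '%s' must be a complete numeric vector of length %d",
                  a, n),
          "pathsar_parse_error")
      }
      activities[[a]] <- as.numeric(v)
    }
  }
  if (!is.null(design) && length(design) != n) {
    pathsar_abort("`design` must have one entry per sample",
                  "pathsar_parse_error")
  }

  structure(
    list(values = values, units = units, activities = activities,
         n_samples = n, design = design),
    class = "sample_table")
}

# name list -> data.frame(name, position); positions are metadata only
as_unit_frame <- function(units, m) {
  if (is.data.frame(units)) {
    if (!all(c("name", "position") %in% names(units))) {
      pathsar_abort("unit data frame needs columns 'name' and 'position'",
                    "pathsar_parse_error")
    }
    units <- data.frame(name = as.character(units$name),
                        position = as.character(units$position),
                        stringsAsFactors = FALSE)
  } else {
    units <- as.character(units)
    if (length(units) == 0L || any(is.na(units))) {
      pathsar_abort("unit names are required (set colnames or pass `units`)",
                    "pathsar_parse_error")
    }
    units <- data.frame(name = units,
                        position = infer_position(units),
                        stringsAsFactors = FALSE)
  }
  if (nrow(units) != m) {
    pathsar_abort(sprintf("%d unit labels for %d columns", nrow(units), m),
                  "pathsar_contract_error")
  }
  if (any(!nzchar(units$name)) || anyDuplicated(units$name)) {
    pathsar_abort("unit names must be non-empty and unique",
                  "pathsar_parse_error")
  }
  ok <- units$position %in% c("terminal", "extension", "unspecified")
  if (!all(ok)) {
    pathsar_abort("unit positions must be terminal/extension/unspecified",
                  "pathsar_parse_error")
  }
  units
}

# suffix convention: trailing "t" = terminal unit, "e" = extension unit
infer_position <- function(names) {
  suffix <- substring(names, nchar(names))
  ifelse(suffix == "t", "terminal",
         ifelse(suffix == "e", "extension", "unspecified"))
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d units; activities: %s\n",
              x$n_samples, nrow(x$units),
              if (length(x$activities)) paste(names(x$activities), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Read a sample table from CSV
#'
#' Samples are rows; a header row is required. Unicode minus signs
#' (\code{"−"}) are normalized to ASCII `-` before numeric conversion.
#'
#' @param path CSV file path.
#' @param unit_columns character vector of column names holding component
#'   abundances, in the desired order.
#' @param activity_columns character vector of activity column names (may be
#'   empty).
#' @return a [sample_table()].
#' @export
read_sample_table <- function(path, unit_columns, activity_columns = character()) {
  if (!file.exists(path)) {
    pathsar_abort(sprintf("input file not found: %s", path), "pathsar_io_error")
  }
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  wanted <- c(unit_columns, activity_columns)
  missing <- setdiff(wanted, names(raw))
  if (length(missing)) {
    pathsar_abort(sprintf("column(s) not in %s: %s", path,
                          paste(missing, collapse = ", ")),
                  "pathsar_config_error")
  }
  if (anyDuplicated(wanted)) {
    pathsar_abort("unit and activity column names must be distinct",
                  "pathsar_config_error")
  }
  num <- lapply(wanted, function(col) parse_numeric_column(raw[[col]], col))
  names(num) <- wanted
  values <- do.call(cbind, num[unit_columns])
  colnames(values) <- unit_columns
  activities <- num[activity_columns]
  sample_table(values, units = unit_columns, activities = activities)
}

parse_numeric_column <- function(x, col) {
  x <- gsub("−", "-", trimws(x))
  bad <- !nzchar(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- bad | is.na(out)
  if (any(bad)) {
    pathsar_abort(
      sprintf("non-numeric or empty cell in column '%s', row %d",
              col, which(bad)[1L]),
      "pathsar_parse_error")
  }
  out
}

#' Write a sample table to CSV
#'
#' Inverse of [read_sample_table()]: unit columns first, then activities.
#' Values are written at full precision so read/write round-trips exactly.
#'
#' @param table a [sample_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  df <- as.data.frame(table$values, check.names = FALSE)
  for (a in names(table$activities)) df[[a]] <- table$activities[[a]]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess a sample table
#'
#' The correlations consumed downstream are invariant to any positive affine
#' per-column rescaling, so the default is to do nothing; an explicit
#' elementwise `log10(value + offset)` transform is offered for data whose
#' magnitudes differ by orders of magnitude and where a *nonlinear*
#' compression is actually wanted.
#'
#' @param table a [sample_table()].
#' @param mode `"none"` (default) or `"log10_offset"`.
#' @param offset nonnegative shift added before taking log10.
#' @return a [sample_table()] with transformed unit and activity columns;
#'   metadata (unit labels, design) is preserved.
#' @export
preprocess <- function(table, mode = c("none", "log10_offset"), offset = 0) {
  stopifnot(inherits(table, "sample_table"))
  mode <- match.arg(mode)
  if (mode == "none") return(table)
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0) {
    pathsar_abort("`offset` must be a single nonnegative number",
                  "pathsar_config_error")
  }
  tf <- function(x, what) {
    shifted <- x + offset
    if (any(shifted <= 0)) {
      i <- which(shifted <= 0)[1L]
      pathsar_abort(
        sprintf("log10_offset undefined: %s, entry %d has value %g (+ offset %g <= 0)",
                what, i, x[i], offset),
        "pathsar_domain_error")
    }
    log10(shifted)
  }
  values <- table$values
  for (j in seq_len(ncol(values))) {
    values[, j] <- tf(values[, j], sprintf("unit column '%s'", colnames(values)[j]))
  }
  activities <- table$activities
  for (a in names(activities)) {
    activities[[a]] <- tf(activities[[a]], sprintf("activity '%s'", a))
  }
  sample_table(values, units = table$units, activities = activities,
               design = table$design)
}

#' Standardize a vector to mean 0, sd 1
#'
#' Uses the unbiased (n-1 denominator) standard deviation. Downstream
#' correlations are identical under the n and n-1 conventions, so the choice
#' is cosmetic; the conventional unbiased form is used.
#'
#' @param column numeric vector, length >= 2, positive variance.
#' @return numeric vector with sample mean 0 and sample sd 1.
#' @export
standardize <- function(column) {
  if (!is.numeric(column) || length(column) < 2L || anyNA(column)) {
    pathsar_abort("standardize() needs a complete numeric vector, length >= 2",
                  "pathsar_degenerate_data")
  }
  s <- sd(column)
  if (!is.finite(s) || s <= 0) {
    pathsar_abort("zero variance: cannot standardize", "pathsar_degenerate_data")
  }
  (column - mean(column)) / s
}

#' Standardize a sample table for one activity
#'
#' @param table a [sample_table()].
#' @param activity name of the activity column to standardize alongside the
#'   unit columns.
#' @return list with `z_values` (n x m), `z_activity` (length n), and the
#'   source `center`/`scale` of every column, retained for traceability.
#' @export
standardize_table <- function(table, activity) {
  stopifnot(inherits(table, "sample_table"))
  y <- get_activity(table, activity)
  z <- apply(table$values, 2L, standardize)
  structure(
    list(z_values = z,
         z_activity = standardize(y),
         center = c(colMeans(table$values), activity = mean(y)),
         scale = c(apply(table$values, 2L, sd), activity = sd(y)),
         units = table$units,
         activity = activity),
    class = "standardized_table")
}

get_activity <- function(table, activity) {
  if (!activity %in% names(table$activities)) {
    pathsar_abort(sprintf("no activity named '%s' (have: %s)", activity,
                          paste(names(table$activities), collapse = ", ")),
                  "pathsar_lookup_error")
  }
  table$activities[[activity]]
}

#' Combine several assay columns into one activity
#'
#' Optional helper for activities measured by more than one assay (e.g. two
#' antioxidant assays): the combined activity is the mean of the
#' standardized assay columns. Off by default everywhere; callers must ask
#' for it explicitly.
#'
#' @param table a [sample_table()].
#' @param assay_names activities to combine.
#' @param new_name name of the combined activity.
#' @return the table with the combined activity appended.
#' @export
combine_activities <- function(table, assay_names, new_name) {
  stopifnot(inherits(table, "sample_table"), length(assay_names) >= 2L)
  zs <- vapply(assay_names, function(a) standardize(get_activity(table, a)),
               numeric(table$n_samples))
  table$activities[[new_name]] <- rowMeans(zs)
  table
}
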