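#' Read two-sample data in long format
#'
#' Reads a delimited text file with one row per observation: a numeric value
#' column and a grouping column with exactly two labels.  Row order is
#' irrelevant.  The first group label (in factor-level order, or
#' \code{group_order} if supplied) becomes the first sample.
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected from the
#'   extension; override with \code{sep}).
#' @param value_col,group_col Column names; defaults \code{"value"} and
#'   \code{"group"}.
#' @param group_order Optional length-2 character vector fixing which label is
#'   the first sample.
#' @param sep Field separator; default \code{","} for \code{.csv}, tab
#'   otherwise.
#' @return A list with \code{x}, \code{y} (observation vectors) and
#'   \code{labels}.
#' @export
read_long_format <- function(path, value_col = "value", group_col = "group",
                             group_order = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c(value_col, group_col))
    if (!cl %in% names(d)) stop(sprintf("column '%s' not found in %s", cl, path))
  vals <- d[[value_col]]
  if (!is.numeric(vals)) stop("value column must be numeric")
  g <- factor(d[[group_col]], levels = group_order %||% sort(unique(d[[group_col]])))
  if (anyNA(g)) stop("group_order does not cover all group labels in the file")
  if (nlevels(g) != 2L)
    stop(sprintf("expected exactly 2 groups, found %d", nlevels(g)))
  lv <- levels(g)
  x <- vals[g == lv[1]]; y <- vals[g == lv[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  list(x = x, y = y, labels = lv)
}

#' Read two-sample data from a group-by-category frequency table
#'
#' Reads a delimited text file whose rows are the two groups and whose
#' remaining columns are ordered categories holding non-negative integer
#' counts.  Each row is expanded into a vector of category codes (the numeric
#' value of the column name, or the column position if the name is not
#' numeric), so downstream rank methods see the ordinal data with its ties.
#'
#' @param path Path to the CSV/TSV file.  First column: group label.
#' @param group_order Optional length-2 character vector fixing which row is
#'   the first sample.
#' @param sep As in [read_long_format()].
#' @return A list with \code{x}, \code{y} and \code{labels}; total sizes equal
#'   the row sums.
#' @export
read_frequency_table <- function(path, group_order = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) != 2L) stop(sprintf("expected exactly 2 group rows, found %d", nrow(d)))
  labs <- as.character(d[[1L]])
  counts <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  codes <- suppressWarnings(as.numeric(colnames(counts)))
  if (anyNA(codes)) codes <- seq_len(ncol(counts))
  if (!is.null(group_order)) {
    ord <- match(group_order, labs)
    if (anyNA(ord)) stop("group_order labels not found in table")
    counts <- counts[ord, , drop = FALSE]
    labs <- labs[ord]
  }
  expand <- function(row) rep(codes, row)
  x <- expand(counts[1, ]); y <- expand(counts[2, ])
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations (check for all-zero rows)")
  list(x = x, y = y, labels = labs)
}

#' Bundled example datasets
#'
#' \code{shoulder_pain_data()} returns the shoulder-tip-pain trial data
#' (randomized comparison of a post-laparoscopy suction procedure against
#' control; pain scored 1 = none to 5 = severe on day 2): a 2 x 5 frequency
#' table expanded to observation vectors, 22 treatment and 19 control
#' patients.  The first sample is the treatment (suction) group, so
#' \eqn{\theta > 1/2} means control scores tend to be larger, i.e. the
#' treatment reduces pain.
#'
#' \code{demo_outcomes_data()} returns a small artificial dataset (10 + 7
#' metric observations) whose Brunner-Munzel interval exceeds 1, illustrating
#' why range-preserving intervals matter.  The first sample is "Group 2", so
#' the effect measures the tendency of "Group 1" toward larger values.
#'
#' @return A list with \code{x}, \code{y} and \code{labels}.
#' @name example_data
#' @examples
#' d <- shoulder_pain_data()
#' estimate_effect(d$x, d$y)$theta
NULL

#' @rdname example_data
#' @export
shoulder_pain_data <- function() {
  read_frequency_table(
    system.file("extdata", "shoulder_pain.csv", package = "mweffect",
                mustWork = TRUE),
    group_order = c("suction", "control"))
}

#' @rdname example_data
#' @export
demo_outcomes_data <- function() {
  read_long_format(
    system.file("extdata", "demo_outcomes.csv", package = "mweffect",
                mustWork = TRUE),
    group_order = c("Group 2", "Group 1"))
}
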