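#' Region-by-year count panels
#'
#' A `region_year_panel` holds a rectangular panel of strictly positive counts
#' (such as annual doctor counts) indexed by region and calendar year. Years
#' must be contiguous (step 1); the region order given at construction is
#' preserved and used by all downstream decompositions.
#'
#' @param counts numeric matrix, regions in rows and years in columns, all
#'   entries strictly positive. Counts are typically integers but corrected
#'   cells may be real-valued.
#' @param years integer vector of calendar years, one per column, strictly
#'   increasing with step 1.
#' @param regions character or integer vector of region labels, one per row.
#'   Labels are opaque: no spatial ordering or adjacency is assumed.
#' @return An object of class `region_year_panel` with fields `regions`,
#'   `years` and `counts`.
#' @examples
#' m <- matrix(exp(seq(5, 6.9, length.out = 20)), nrow = 4)
#' p <- region_year_panel(m, years = 2001:2005, regions = paste0("R", 1:4))
#' dim(p$counts)
#' @export
region_year_panel <- function(counts, years, regions = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(counts)))
  regions <- as.character(regions)
  years <- as.integer(years)
  if (nrow(counts) != length(regions) || ncol(counts) != length(years))
    stop_structural("counts must be length(regions) x length(years) (got %dx%d)",
                    nrow(counts), ncol(counts))
  if (anyDuplicated(regions))
    stop_value("duplicate region labels: %s",
               paste(unique(regions[duplicated(regions)]), collapse = ", "))
  if (length(years) >= 2 && !all(diff(years) == 1L))
    stop_structural("years must be contiguous with step 1")
  if (nrow(counts) < 2L)
    stop_structural("panel needs at least 2 regions (got %d)", nrow(counts))
  if (length(years) < 4L)
    stop_structural("panel needs at least 4 years (got %d)", length(years))
  if (!is.numeric(counts) || anyNA(counts))
    stop_value("counts must be numeric with no missing cells")
  if (any(counts <= 0))
    stop_value("all counts must be strictly positive")
  dimnames(counts) <- list(regions, years)
  structure(list(regions = regions, years = years, counts = counts),
            class = "region_year_panel")
}

#' @export
print.region_year_panel <- function(x, ...) {
  cat(sprintf("region_year_panel: %d regions x %d years (%d-%d)\n",
              length(x$regions), length(x$years),
              min(x$years), max(x$years)))
  cat(sprintf("  counts in [%.6g, %.6g]\n", min(x$counts), max(x$counts)))
  invisible(x)
}

#' Read a panel from CSV
#'
#' Two layouts are supported. `wide`: a header row `year,<region>,...` with one
#' row per year; `long`: columns `region,year,count` with one row per cell.
#'
#' @param path path to a CSV file.
#' @param layout `"wide"` (default) or `"long"`.
#' @return A [region_year_panel()].
#' @export
read_panel <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_value("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (ncol(df) < 2L) stop_structural("wide layout needs a year column plus region columns")
    years <- df[[1L]]
    ord <- order(years)
    years <- years[ord]
    counts <- t(as.matrix(df[ord, -1L, drop = FALSE]))
    region_year_panel(counts, years = years, regions = colnames(df)[-1L])
  } else {
    need <- c("region", "year", "count")
    if (!all(need %in% names(df)))
      stop_structural("long layout needs columns region, year, count")
    key <- paste(df$region, df$year)
    if (anyDuplicated(key))
      stop_value("duplicate (region, year) pairs in long input")
    regions <- unique(as.character(df$region))
    years <- sort(unique(as.integer(df$year)))
    counts <- matrix(NA_real_, length(regions), length(years),
                     dimnames = list(regions, years))
    counts[cbind(match(as.character(df$region), regions),
                 match(as.integer(df$year), years))] <- df$count
    if (anyNA(counts)) stop_structural("long input does not cover the full region x year grid")
    region_year_panel(counts, years = years, regions = regions)
  }
}

#' Write a panel to CSV
#'
#' Values are written with 15 significant digits so that a read/write
#' round trip reproduces the panel to at least 12 significant digits.
#'
#' @param panel a [region_year_panel()].
#' @param path output path.
#' @param layout `"wide"` or `"long"` (see [read_panel()]).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(panel, "region_year_panel"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (layout == "wide") {
    df <- data.frame(year = panel$years, check.names = FALSE)
    for (i in seq_along(panel$regions)) df[[panel$regions[i]]] <- fmt(panel$counts[i, ])
  } else {
    df <- data.frame(
      region = rep(panel$regions, times = length(panel$years)),
      year = rep(panel$years, each = length(panel$regions)),
      count = fmt(as.vector(panel$counts)))
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    stop(errorCondition(sprintf("cannot write to %s", path),
                        class = c("fpca_io_error", "fpca_error")))
  invisible(path)
}

#' Restrict a panel to a span of years
#'
#' @param panel a [region_year_panel()].
#' @param start_year,end_year inclusive year bounds; defaults keep the ends.
#' @return A [region_year_panel()] covering the requested span.
#' @export
window_panel <- function(panel, start_year = NULL, end_year = NULL) {
  stopifnot(inherits(panel, "region_year_panel"))
  if (is.null(start_year)) start_year <- min(panel$years)
  if (is.null(end_year)) end_year <- max(panel$years)
  keep <- panel$years >= start_year & panel$years <= end_year
  if (!any(keep)) stop_value("no years in [%d, %d]", start_year, end_year)
  region_year_panel(panel$counts[, keep, drop = FALSE],
                    years = panel$years[keep], regions = panel$regions)
}

#' Rank regions by a baseline value and assign codes
#'
#' Regions are ranked by decreasing baseline value (for the doctors panel, the
#' population in the first observed year) and assigned integer codes starting
#' at 1. Ties keep the input order (stable sort).
#'
#' @param region_names character vector of unique region names.
#' @param baseline_values positive numeric vector, same length.
#' @return A named integer vector: `code[name]`.
#' @examples
#' rank_and_encode_regions(c("A", "B", "C"), c(10, 30, 20))
#' @export
rank_and_encode_regions <- function(region_names, baseline_values) {
  if (length(region_names) != length(baseline_values))
    stop_value("names and baseline values must have equal length")
  if (anyDuplicated(region_names))
    stop_value("duplicate region names")
  if (any(baseline_values <= 0)) stop_value("baseline values must be positive")
  ord <- order(-baseline_values)          # radix sort: stable for ties
  codes <- integer(length(region_names))
  codes[ord] <- seq_along(region_names)
  names(codes) <- region_names
  codes
}
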