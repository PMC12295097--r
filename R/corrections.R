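#' Correction rules for reporting artefacts
#'
#' Panels assembled from official statistics occasionally contain reporting
#' errors (e.g. an unexplained one- or two-year dip later corrected). Two rule
#' kinds repair such spans before modelling:
#'
#' * `linear_interpolation`: the interior years between two anchor years are
#'   replaced by values linear in the year between the panel's values at the
#'   anchors, on the raw count scale.
#' * `manual_override`: a single cell is set to a given positive value.
#'
#' @param region_code region label (must match a panel region).
#' @param kind `"linear_interpolation"` or `"manual_override"`.
#' @param anchor_years for interpolation, the pair of years bracketing the
#'   corrected span; for an override, the single target year.
#' @param override_value positive replacement value (override only).
#' @return A `correction_rule` object.
#' @examples
#' correction_rule("R8", "manual_override", 2019, override_value = 2090)
#' correction_rule("R8", "linear_interpolation", c(2018, 2021))
#' @export
correction_rule <- function(region_code,
                            kind = c("linear_interpolation", "manual_override"),
                            anchor_years, override_value = NULL) {
  kind <- match.arg(kind)
  anchor_years <- as.integer(anchor_years)
  if (kind == "linear_interpolation") {
    if (length(anchor_years) != 2L || diff(anchor_years) < 2L)
      stop_value("interpolation needs two anchor years spanning at least 2 years")
  } else {
    if (length(anchor_years) != 1L)
      stop_value("manual_override takes a single year")
    if (is.null(override_value) || override_value <= 0)
      stop_value("manual_override needs a positive override_value")
  }
  structure(list(region_code = as.character(region_code), kind = kind,
                 anchor_years = anchor_years,
                 override_value = override_value),
            class = "correction_rule")
}

#' Apply correction rules to a panel
#'
#' Returns a new panel; cells outside the rule spans are untouched.
#' Interpolation is linear on the raw count scale.
#'
#' @param panel a [region_year_panel()].
#' @param rules a list of [correction_rule()] objects (may be empty).
#' @return A corrected [region_year_panel()].
#' @export
apply_corrections <- function(panel, rules) {
  stopifnot(inherits(panel, "region_year_panel"))
  counts <- panel$counts
  for (rule in rules) {
    if (!inherits(rule, "correction_rule"))
      rule <- do.call(correction_rule, rule)
    r <- match(rule$region_code, panel$regions)
    if (is.na(r)) stop_value("unknown region in rule: %s", rule$region_code)
    if (!all(rule$anchor_years %in% panel$years))
      stop_value("anchor year(s) %s not in panel",
                 paste(setdiff(rule$anchor_years, panel$years), collapse = ", "))
    if (rule$kind == "manual_override") {
      counts[r, match(rule$anchor_years, panel$years)] <- rule$override_value
    } else {
      y0 <- rule$anchor_years[1L]; y1 <- rule$anchor_years[2L]
      c0 <- counts[r, match(y0, panel$years)]
      c1 <- counts[r, match(y1, panel$years)]
      interior <- panel$years[panel$years > y0 & panel$years < y1]
      counts[r, match(interior, panel$years)] <-
        c0 + (c1 - c0) * (interior - y0) / (y1 - y0)
    }
  }
  region_year_panel(counts, years = panel$years, regions = panel$regions)
}

#' Read correction rules from YAML or JSON
#'
#' The file holds a list of records with fields `region_code`, `kind`,
#' `anchor_years` and (for overrides) `override_value`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of [correction_rule()] objects.
#' @export
read_corrections <- function(path) {
  if (!file.exists(path)) stop_value("file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(raw, function(rec) do.call(correction_rule, rec))
}
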