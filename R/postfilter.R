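#' Filter a LipidSearch-style results table
#'
#' Keeps rows with retention time strictly above `rt_min`, peak area
#' strictly above `area_min` and score strictly below `score_max` — the
#' inequalities are strict, so rows sitting exactly on a threshold are
#' removed. Row order is preserved and the input is not modified; a
#' machine-readable report of how many rows each criterion removed is
#' attached as the `"filter_report"` attribute (see [filter_report()]).
#'
#' The score column is a generic per-identification quality score with
#' keep-if-smaller semantics; its name (like the others) is configurable
#' through `cols` for exports with different headers.
#'
#' @param table A data frame of identifications.
#' @param rt_min Minimum retention time in minutes (default 2).
#' @param area_min Minimum peak area (default 1000).
#' @param score_max Maximum score (default 0.5).
#' @param cols Named character vector mapping the roles `rt`, `area`,
#'   `score` to column names in `table`.
#' @return The kept rows as a tibble, with a `filter_report` attribute.
#' @export
#' @examples
#' tab <- tibble::tibble(lipid_ion = c("a", "b"), rt = c(5, 1.5),
#'                       area = c(2e4, 2e4), score = c(0.1, 0.1))
#' apply_filters(tab)
apply_filters <- function(table, rt_min = 2, area_min = 1000,
                          score_max = 0.5,
                          cols = c(rt = "rt", area = "area",
                                   score = "score")) {
  missing <- setdiff(unname(cols), names(table))
  if (length(missing) > 0) {
    abort(paste0("results table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  table <- as_tibble(table)
  rt_ok <- table[[cols[["rt"]]]] > rt_min
  area_ok <- table[[cols[["area"]]]] > area_min
  score_ok <- table[[cols[["score"]]]] < score_max
  keep <- rt_ok & area_ok & score_ok
  keep[is.na(keep)] <- FALSE
  out <- table[keep, ]
  report <- list(
    total = nrow(table),
    kept = sum(keep),
    removed = nrow(table) - sum(keep),
    removed_rt = sum(!rt_ok, na.rm = TRUE),
    removed_area = sum(!area_ok, na.rm = TRUE),
    removed_score = sum(!score_ok, na.rm = TRUE),
    thresholds = list(rt_min = rt_min, area_min = area_min,
                      score_max = score_max)
  )
  attr(out, "filter_report") <- report
  out
}

#' @rdname apply_filters
#' @param x A table returned by [apply_filters()].
#' @export
filter_report <- function(x) {
  attr(x, "filter_report")
}

#' Restrict a results table to allowed adducts
#'
#' Rows whose adduct is parseable but not in `allowed` are removed. Rows
#' whose adduct string cannot be parsed at all are kept and flagged in an
#' `adduct_flag` column rather than silently dropped, so they can be
#' audited.
#'
#' @param table A data frame with an adduct column.
#' @param allowed Allowed adduct labels (default `c("-H", "-2H")`).
#' @param col Adduct column name (default `"adduct"`).
#' @return A tibble of kept rows, with `adduct_flag` set to
#'   `"unparseable"` where the adduct could not be interpreted.
#' @export
#' @examples
#' restrict_adducts(tibble::tibble(adduct = c("-H", "+H", "-2H")))
restrict_adducts <- function(table, allowed = c("-H", "-2H"),
                             col = "adduct") {
  if (!col %in% names(table)) {
    abort(paste0("results table is missing column: ", col))
  }
  table <- as_tibble(table)
  x <- gsub("\\s", "", table[[col]])
  parseable <- grepl("^[+-][0-9]*[A-Za-z][A-Za-z0-9]*$", x)
  keep <- (parseable & x %in% allowed) | !parseable
  out <- table[keep, ]
  out$adduct_flag <- ifelse(parseable[keep], NA_character_, "unparseable")
  out
}
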