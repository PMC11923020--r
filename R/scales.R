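#' Define a questionnaire scale
#'
#' A scale definition names the items belonging to one (unidimensional)
#' scale, which of them are reverse-keyed, and whether the observed score is
#' the sum or the mean of the item categories. Item categories are 0-based
#' integers; reverse-keying maps category `c` to `max_cat - c` before
#' scoring.
#'
#' @param items Character vector of item column names (>= 1).
#' @param reverse_keyed Character vector, subset of `items`.
#' @param scoring `"sum"` or `"mean"`.
#' @param n_categories Number of response categories shared by the items;
#'   if `NULL` the observed maximum category across the scale's items is
#'   used when reverse-keying.
#' @param name Optional scale label carried through result tables.
#' @return An object of class `scale_def`.
#' @export
scale_def <- function(items, reverse_keyed = character(), scoring = c("sum", "mean"),
                      n_categories = NULL, name = NULL) {
  scoring <- match.arg(scoring)
  items <- as.character(items)
  if (length(items) < 1L) abort("`items` must name at least one item.")
  if (anyDuplicated(items)) abort("`items` contains duplicates.")
  if (!all(reverse_keyed %in% items)) {
    abort("`reverse_keyed` must be a subset of `items`.")
  }
  structure(
    list(items = items, reverse_keyed = as.character(reverse_keyed),
         scoring = scoring, n_categories = n_categories,
         name = name %||% "scale"),
    class = "scale_def"
  )
}

#' @export
print.scale_def <- function(x, ...) {
  cat("<scale_def> ", x$name, ": ", length(x$items), " items, ",
      x$scoring, "-scored", sep = "")
  if (length(x$reverse_keyed)) {
    cat(", reverse-keyed: ", paste(x$reverse_keyed, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

check_item_columns <- function(data, items) {
  missing <- setdiff(items, names(data))
  if (length(missing)) {
    abort(paste0("Item column(s) not found in `data`: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(data)
}

#' Score a scale from item-level data
#'
#' Applies reverse-keying and the scale's scoring rule to produce one
#' observed score per respondent.
#'
#' @param data Data frame with integer item columns (0-based categories) and
#'   a group column.
#' @param sdef A [scale_def()].
#' @param group_col Name of the two-level group column.
#' @return A tibble with columns `score` and `group`.
#' @export
score_scale <- function(data, sdef, group_col = "group") {
  stopifnot(inherits(sdef, "scale_def"))
  check_item_columns(data, c(sdef$items, group_col))
  resp <- as.matrix(data[sdef$items])
  if (anyNA(resp)) abort("Item responses contain missing values; filter first.")
  if (length(sdef$reverse_keyed)) {
    max_cat <- sdef$n_categories %||% (max(resp) + 1L)
    rev_cols <- match(sdef$reverse_keyed, sdef$items)
    resp[, rev_cols] <- (max_cat - 1L) - resp[, rev_cols]
  }
  score <- if (sdef$scoring == "sum") rowSums(resp) else rowMeans(resp)
  tibble(score = score, group = data[[group_col]])
}

#' Read and write item-level response data
#'
#' Plain-CSV interchange: one row per respondent, one integer column per
#' item plus a group column.
#'
#' @param path File path.
#' @param data Data frame of item responses and a group column.
#' @return `read_item_data()` returns a tibble; `write_item_data()` returns
#'   `path` invisibly.
#' @export
read_item_data <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_item_data
#' @export
write_item_data <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read a scale definition from YAML or JSON
#'
#' Expects keys `items`, optionally `reverse_keyed`, `scoring`,
#' `n_categories` and `name`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scale_def()].
#' @export
read_scale_def <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$items)) abort("Scale definition must list `items`.")
  scale_def(
    items = unlist(cfg$items),
    reverse_keyed = unlist(cfg$reverse_keyed) %||% character(),
    scoring = cfg$scoring %||% "sum",
    n_categories = cfg$n_categories,
    name = cfg$name
  )
}
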