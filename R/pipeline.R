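#' Keep complete observations and exactly two groups
#'
#' Drops respondents with any missing item response and, when the group
#' column has more than two observed levels, keeps only the two most
#' frequent ones. Counts of dropped rows are reported. A warning is issued
#' when fewer than 20 respondents per item remain.
#'
#' @param data Data frame of item columns plus a group column.
#' @param items Item columns; default: all columns except `group_col`.
#' @param group_col Name of the group column.
#' @param min_ratio Respondent-per-item ratio below which to warn.
#' @return Filtered tibble with a droplevels'ed two-level group factor.
#' @export
filter_complete_cases <- function(data, items = NULL, group_col = "group",
                                  min_ratio = 20) {
  if (!group_col %in% names(data)) abort("`group_col` not found in `data`.")
  items <- items %||% setdiff(names(data), group_col)
  check_item_columns(data, items)
  data <- as_tibble(data)
  grp <- factor(data[[group_col]])
  n0 <- nrow(data)
  if (nlevels(grp) > 2L) {
    keep_levels <- names(sort(table(grp), decreasing = TRUE))[1:2]
    drop_n <- sum(!grp %in% keep_levels)
    data <- data[grp %in% keep_levels, , drop = FALSE]
    inform(paste0("Dropped ", drop_n, " row(s) outside the two largest groups (",
                  paste(sort(keep_levels), collapse = ", "), ")."))
  }
  cc <- complete.cases(data[c(items, group_col)])
  if (any(!cc)) {
    inform(paste0("Dropped ", sum(!cc), " incomplete row(s) of ", n0, "."))
    data <- data[cc, , drop = FALSE]
  }
  data[[group_col]] <- droplevels(factor(data[[group_col]]))
  if (nlevels(data[[group_col]]) < 2L) {
    abort("Fewer than two groups remain after filtering.")
  }
  if (nrow(data) < min_ratio * length(items)) {
    warn(paste0("Fewer than ", min_ratio, " respondents per item (",
                nrow(data), " rows, ", length(items), " items)."))
  }
  data
}

#' Run a multi-scale observed-versus-latent comparison study
#'
#' Orchestrates the full pipeline over a list of scales: obtain each
#' scale's data (from a CSV file or a generator configuration), score and
#' compare observed versus latent standardized mean differences
#' ([compare_groups()]), then meta-analyze the absolute and signed
#' discrepancies across scales ([random_effects_meta()]) using
#' `var_d_tau + var_d_y` as each scale's sampling variance. Scales that
#' fail — most importantly Heywood (improper) solutions — are excluded and
#' recorded, and the run continues.
#'
#' @param scales A list; each element needs a `name`, either `config` (an
#'   [ordinal_config()]) or `path` (a CSV readable by [read_item_data()]),
#'   and for CSV sources a `scale_def`. Generator scales default to the
#'   sum-scored [config_scale_def()].
#' @param estimator Passed to [compare_groups()].
#' @param meta_method Passed to [random_effects_meta()].
#' @param group_col Group column name.
#' @param seed Optional integer seed; scale `i` generated from `config`
#'   draws with `seed + i - 1`.
#' @return Object of class `latentdiff_study`: list with `comparisons`
#'   (one row per successful scale), `meta` (list `absolute`, `signed`),
#'   `excluded` (tibble `scale`, `reason`).
#' @examples
#' \donttest{
#' scales <- lapply(1:3, function(i) {
#'   list(name = paste0("scale", i),
#'        config = ordinal_config(n_items = 4, loadings = 0.7,
#'                                n_per_group = c(400, 400), latent_d = 0.3))
#' })
#' study <- run_study(scales, estimator = "ULS", seed = 1)
#' study$comparisons
#' }
#' @export
run_study <- function(scales, estimator = "DWLS", meta_method = "REML",
                      group_col = "group", seed = NULL) {
  if (!length(scales)) abort("`scales` must name at least one scale.")
  rows <- list(); excluded <- list()
  for (i in seq_along(scales)) {
    sc <- scales[[i]]
    name <- sc$name %||% paste0("scale", i)
    res <- tryCatch({
      if (!is.null(sc$config)) {
        data <- simulate_ordinal(sc$config,
                                 seed = if (!is.null(seed)) seed + i - 1L
                                        else sc$config$seed)
        sdef <- sc$scale_def %||% config_scale_def(sc$config, name = name)
      } else if (!is.null(sc$path)) {
        if (is.null(sc$scale_def)) {
          abort("CSV-sourced scales need a `scale_def`.")
        }
        sdef <- sc$scale_def
        sdef$name <- name
        data <- filter_complete_cases(read_item_data(sc$path),
                                      items = sdef$items,
                                      group_col = group_col)
      } else {
        abort("Each scale needs a `config` or a `path`.")
      }
      compare_groups(data, sdef, group_col = group_col, estimator = estimator)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        tibble(scale = name, reason = conditionMessage(res))
      inform(paste0("Scale `", name, "` excluded: ", conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  comparisons <- bind_rows(rows)
  meta <- if (nrow(comparisons) >= 2L) {
    vi <- comparisons$var_d_tau + comparisons$var_d_y
    list(
      absolute = random_effects_meta(comparisons$delta_d, vi,
                                     method = meta_method),
      signed = random_effects_meta(comparisons$signed_delta_d, vi,
                                   method = meta_method)
    )
  }
  structure(
    list(comparisons = comparisons,
         meta = meta,
         excluded = if (length(excluded)) bind_rows(excluded) else
           tibble(scale = character(), reason = character())),
    class = "latentdiff_study"
  )
}

#' @export
print.latentdiff_study <- function(x, ...) {
  cat("<latentdiff_study> ", nrow(x$comparisons), " scale(s) compared, ",
      nrow(x$excluded), " excluded\n", sep = "")
  print(x$comparisons)
  if (!is.null(x$meta)) {
    m <- x$meta$signed
    cat(sprintf(
      "signed discrepancy: pooled %.3f [%.3f, %.3f], Q(%d) = %.2f, I2 = %.1f%%, tau = %.3f\n",
      m$estimate, m$ci_low, m$ci_high, m$df, m$Q, m$I2, m$tau))
  }
  invisible(x)
}

#' @method tidy latentdiff_study
#' @export
tidy.latentdiff_study <- function(x, ...) x$comparisons

#' @method glance latentdiff_study
#' @export
glance.latentdiff_study <- function(x, ...) {
  if (is.null(x$meta)) {
    abort("Fewer than two scales succeeded; no meta-analysis available.")
  }
  bind_rows(
    mutate(as_tibble(x$meta$absolute), discrepancy = "absolute", .before = 1),
    mutate(as_tibble(x$meta$signed), discrepancy = "signed", .before = 1)
  )
}

#' Read a study configuration from YAML
#'
#' The file may carry `estimator`, `meta_method`, `group_col`, `seed`, and
#' a `scales` list whose entries have `name`, and either a `generator`
#' block (arguments to [ordinal_config()]) or a `path` plus a `scale_def`
#' block (arguments to [scale_def()]).
#'
#' @param path YAML file path.
#' @return A list of arguments suitable for `do.call(run_study, ...)`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scales)) abort("Study configuration must list `scales`.")
  scales <- lapply(cfg$scales, function(sc) {
    out <- list(name = sc$name)
    if (!is.null(sc$generator)) {
      out$config <- do.call(ordinal_config, sc$generator)
    }
    if (!is.null(sc$path)) out$path <- sc$path
    if (!is.null(sc$scale_def)) {
      out$scale_def <- scale_def(
        items = unlist(sc$scale_def$items),
        reverse_keyed = unlist(sc$scale_def$reverse_keyed) %||% character(),
        scoring = sc$scale_def$scoring %||% "sum",
        n_categories = sc$scale_def$n_categories,
        name = sc$name
      )
    }
    out
  })
  list(scales = scales,
       estimator = cfg$estimator %||% "DWLS",
       meta_method = cfg$meta_method %||% "REML",
       group_col = cfg$group_col %||% "group",
       seed = cfg$seed)
}
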