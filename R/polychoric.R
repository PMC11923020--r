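#' Estimate item thresholds from ordinal margins
#'
#' Places the k-th threshold at the standard-normal quantile of the
#' cumulative proportion of responses through category k (the first-stage
#' estimator of two-step ordinal factor analysis).
#'
#' @param x Integer vector of observed categories for one item.
#' @param levels Optional full category set; categories unobserved in `x`
#'   but listed here yield duplicated cumulative proportions and are
#'   dropped. Default: the sorted observed categories.
#' @param item Item label used in error messages.
#' @return Named numeric vector of strictly increasing thresholds; names are
#'   the cut indices (`"1"` = below-vs-above the lowest retained category).
#' @examples
#' estimate_thresholds(c(rep(0, 50), rep(1, 50)))  # 0
#' @export
estimate_thresholds <- function(x, levels = NULL, item = "item") {
  x <- x[!is.na(x)]
  levels <- levels %||% sort(unique(x))
  if (length(unique(x)) < 2L) {
    abort(paste0("Item `", item, "` is constant; thresholds are undefined."),
          class = "latentdiff_degenerate_item")
  }
  counts <- tabulate(match(x, levels), nbins = length(levels))
  cum <- cumsum(counts)[-length(levels)]
  keep <- cum > 0 & cum < length(x)          # cuts identified in this sample
  thr <- qnorm(cum[keep] / length(x))
  names(thr) <- as.character(which(keep))
  thr
}

polychoric_loglik <- function(tab, thresholds_a, thresholds_b, rho) {
  p <- bvn_cell_probs(thresholds_a, thresholds_b, rho)
  sum(tab[tab > 0] * log(pmax(p[tab > 0], 1e-300)))
}

RHO_BOUND <- 0.999

#' Two-step polychoric correlation
#'
#' Maximum-likelihood latent correlation of the bivariate normal assumed to
#' underlie a two-way ordinal contingency table, with the thresholds held
#' fixed (by default at their margin-based estimates). The search is
#' bounded to \[-0.999, 0.999\]; estimates at the bound are clamped and
#' flagged.
#'
#' @param tab Contingency table (matrix) of the two items, or an object
#'   coercible with `as.matrix()`.
#' @param thresholds_a,thresholds_b Optional fixed thresholds; defaults are
#'   estimated from the table margins.
#' @return A list with elements `rho`, `loglik`, `boundary` (logical),
#'   `converged`.
#' @examples
#' tab <- outer(c(30, 70), c(40, 60)) # independence
#' polychoric_corr(tab)$rho           # ~0
#' @export
polychoric_corr <- function(tab, thresholds_a = NULL, thresholds_b = NULL) {
  tab <- as.matrix(tab)
  if (sum(tab) <= 0) abort("Contingency table is empty.")
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("Both items need at least 2 observed categories.",
          class = "latentdiff_degenerate_item")
  }
  n <- sum(tab)
  thresholds_a <- thresholds_a %||% qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n)
  thresholds_b <- thresholds_b %||% qnorm(cumsum(colSums(tab))[-ncol(tab)] / n)
  if (any(!is.finite(thresholds_a)) || any(!is.finite(thresholds_b))) {
    abort("A margin category has zero count; collapse categories first.",
          class = "latentdiff_degenerate_item")
  }
  opt <- optimize(function(r) polychoric_loglik(tab, thresholds_a, thresholds_b, r),
                  interval = c(-RHO_BOUND, RHO_BOUND), maximum = TRUE,
                  tol = 1e-6)
  rho <- opt$maximum
  boundary <- abs(rho) >= RHO_BOUND - 1e-3
  if (boundary) rho <- sign(rho) * RHO_BOUND
  list(rho = rho, loglik = opt$objective, boundary = boundary, converged = TRUE)
}

#' Per-group thresholds and polychoric correlation matrix
#'
#' The input statistics of ordinal least-squares factor analysis: for each
#' item the margin-based thresholds, and for each item pair the two-step
#' polychoric correlation. The returned matrix is not forced to be positive
#' definite; the model fitter works directly on its entries.
#'
#' @param data Data frame of integer item columns plus (optionally) a group
#'   column.
#' @param items Character vector of item columns; default: all columns
#'   except `group_col`.
#' @param group Optional single group level; rows of other groups are
#'   dropped first.
#' @param group_col Name of the group column.
#' @return An object of class `polychoric`: list with `rho` (item x item
#'   matrix), `thresholds` (named list), `boundary` (logical matrix), `n`.
#' @export
polychoric_matrix <- function(data, items = NULL, group = NULL,
                              group_col = "group") {
  if (!is.null(group)) {
    if (!group_col %in% names(data)) abort("`group_col` not found.")
    data <- data[data[[group_col]] == group, , drop = FALSE]
    if (!nrow(data)) abort(paste0("Group `", group, "` has no rows."))
  }
  items <- items %||% setdiff(names(data), group_col)
  check_item_columns(data, items)
  p <- length(items)
  thresholds <- lapply(items, function(it) {
    estimate_thresholds(data[[it]], item = it)
  })
  names(thresholds) <- items
  rho <- diag(1, p); dimnames(rho) <- list(items, items)
  boundary <- matrix(FALSE, p, p, dimnames = list(items, items))
  if (p > 1L) {
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        tab <- table(factor(data[[items[i]]]), factor(data[[items[j]]]))
        est <- polychoric_corr(tab)
        rho[i, j] <- rho[j, i] <- est$rho
        boundary[i, j] <- boundary[j, i] <- est$boundary
      }
    }
  }
  structure(list(rho = rho, thresholds = thresholds, boundary = boundary,
                 n = nrow(data)),
            class = "polychoric")
}

#' @export
print.polychoric <- function(x, ...) {
  cat("<polychoric> ", ncol(x$rho), " items, n = ", x$n, "\n", sep = "")
  print(round(x$rho, 3))
  if (any(x$boundary)) cat("(some estimates clamped at the search bound)\n")
  invisible(x)
}
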