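#' Group-wise input statistics for the two-group ordinal factor model
#'
#' Computes, per group, the margin-based item thresholds (on a category set
#' shared across groups, so cut indices align) and the polychoric
#' correlation matrix. These are the statistics the least-squares fitter
#' matches.
#'
#' @param data Data frame of integer item columns plus a two-level group
#'   column.
#' @param items Item columns; default: all columns except `group_col`.
#' @param group_col Name of the group column.
#' @return Object of class `mgcfa_stats`: `items`, `group_levels`, and
#'   `per_group` (each with `thresholds`, `rho`, `n`).
#' @export
mgcfa_stats <- function(data, items = NULL, group_col = "group") {
  if (!group_col %in% names(data)) abort("`group_col` not found in `data`.")
  items <- items %||% setdiff(names(data), group_col)
  check_item_columns(data, items)
  grp <- factor(data[[group_col]])
  if (nlevels(grp) != 2L) abort("Exactly two group levels are required.")
  global_levels <- lapply(items, function(it) sort(unique(data[[it]])))
  names(global_levels) <- items
  per_group <- lapply(levels(grp), function(g) {
    rows <- grp == g
    thr <- lapply(items, function(it) {
      estimate_thresholds(data[[it]][rows], levels = global_levels[[it]],
                          item = paste0(it, " (group ", g, ")"))
    })
    names(thr) <- items
    pm <- polychoric_matrix(data[rows, items, drop = FALSE], items = items)
    list(thresholds = thr, rho = pm$rho, boundary = pm$boundary, n = sum(rows))
  })
  names(per_group) <- levels(grp)
  structure(list(items = items, group_levels = levels(grp),
                 global_levels = global_levels, per_group = per_group),
            class = "mgcfa_stats")
}

# stack one group's statistics: thresholds (item-major, by cut) then the
# lower triangle of the polychoric matrix (column-major, i < j)
stack_group_stats <- function(g) {
  c(unlist(g$thresholds, use.names = FALSE),
    g$rho[lower.tri(g$rho)])
}

# model-implied counterpart of stack_group_stats under the delta
# parameterization: group 1 latent responses are standardized; group 2's
# scale follows from the shared loadings, psi2 and theta = 1 - lambda^2
implied_group_stats <- function(which_group, params, stats) {
  items <- stats$items
  lam <- params$lambda
  if (which_group == 1L) {
    sdv <- rep(1, length(items))
    shift <- rep(0, length(items))
    psi <- 1
  } else {
    sdv <- sqrt(lam^2 * params$psi2 + (1 - lam^2))
    shift <- lam * params$alpha2
    psi <- params$psi2
  }
  g <- stats$per_group[[which_group]]
  thr <- unlist(lapply(seq_along(items), function(i) {
    cuts <- as.integer(names(g$thresholds[[i]]))
    (params$tau[[i]][cuts] - shift[i]) / sdv[i]
  }), use.names = FALSE)
  R <- (tcrossprod(lam) * psi) / tcrossprod(sdv)
  c(thr, R[lower.tri(R)])
}

mgcfa_discrepancy <- function(params, stats, weights = NULL) {
  total <- 0
  N <- sum(vapply(stats$per_group, `[[`, 0, "n"))
  for (gi in 1:2) {
    resid <- stack_group_stats(stats$per_group[[gi]]) -
      implied_group_stats(gi, params, stats)
    w <- if (is.null(weights)) {
      stats$per_group[[gi]]$n / N
    } else {
      weights[[gi]]
    }
    total <- total + sum(w * resid^2)
  }
  total
}

# number of model cuts per item: union of cuts identified in either group
model_cuts <- function(stats) {
  lapply(seq_along(stats$items), function(i) {
    sort(unique(c(
      as.integer(names(stats$per_group[[1]]$thresholds[[i]])),
      as.integer(names(stats$per_group[[2]]$thresholds[[i]]))
    )))
  })
}

pack_params <- function(params, constraints, cuts) {
  z_lam <- atanh(pmin(pmax(params$lambda, -0.999), 0.999))
  if (constraints$equal_loadings) z_lam <- z_lam[1]
  enc_thr <- function(t) if (length(t) == 1L) t else c(t[1], log(diff(t)))
  tau <- if (constraints$equal_thresholds) {
    enc_thr(params$tau[[1]][cuts[[1]]])
  } else {
    unlist(lapply(seq_along(cuts), function(i) enc_thr(params$tau[[i]][cuts[[i]]])))
  }
  c(z_lam, tau, params$alpha2,
    if (!constraints$fix_psi2) log(params$psi2))
}

unpack_params <- function(par, constraints, cuts, n_items, n_cats) {
  pos <- 1L
  take <- function(k) {
    out <- par[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  lam <- if (constraints$equal_loadings) {
    rep(tanh(take(1L)), n_items)
  } else tanh(take(n_items))
  dec_thr <- function(v) if (length(v) == 1L) v else cumsum(c(v[1], exp(v[-1])))
  tau <- vector("list", n_items)
  if (constraints$equal_thresholds) {
    shared <- dec_thr(take(length(cuts[[1]])))
    for (i in seq_len(n_items)) {
      tau[[i]] <- rep(NA_real_, n_cats[i] - 1L)
      tau[[i]][cuts[[i]]] <- shared
    }
  } else {
    for (i in seq_len(n_items)) {
      tau[[i]] <- rep(NA_real_, n_cats[i] - 1L)
      tau[[i]][cuts[[i]]] <- dec_thr(take(length(cuts[[i]])))
    }
  }
  alpha2 <- take(1L)
  psi2 <- if (constraints$fix_psi2) 1 else exp(take(1L))
  list(lambda = lam, tau = tau, alpha2 = alpha2, psi2 = psi2)
}

start_params <- function(stats) {
  n <- vapply(stats$per_group, `[[`, 0, "n")
  rho_pool <- (stats$per_group[[1]]$rho * n[1] +
               stats$per_group[[2]]$rho * n[2]) / sum(n)
  e <- eigen(rho_pool, symmetric = TRUE)
  lam <- e$vectors[, 1] * sqrt(max(e$values[1], 0.2))
  if (sum(lam) < 0) lam <- -lam
  lam <- pmin(pmax(lam, -0.9), 0.9)
  p <- length(stats$items)
  n_cats <- vapply(stats$global_levels, length, 0L)
  tau <- lapply(seq_len(p), function(i) {
    full <- rep(NA_real_, n_cats[i] - 1L)
    for (gi in 1:2) {
      t_g <- stats$per_group[[gi]]$thresholds[[i]]
      idx <- as.integer(names(t_g))
      full[idx] <- ifelse(is.na(full[idx]), t_g, (full[idx] + t_g) / 2)
    }
    full
  })
  # crude alpha2 start from average group threshold shift scaled by loading
  shifts <- unlist(lapply(seq_len(p), function(i) {
    t1 <- stats$per_group[[1]]$thresholds[[i]]
    t2 <- stats$per_group[[2]]$thresholds[[i]]
    common <- intersect(names(t1), names(t2))
    if (!length(common) || abs(lam[i]) < 0.05) return(NULL)
    (t1[common] - t2[common]) / lam[i]
  }))
  alpha2 <- if (length(shifts)) pmin(pmax(mean(shifts), -2), 2) else 0
  list(lambda = lam, tau = tau, alpha2 = alpha2, psi2 = 1)
}

default_constraints <- function(constraints = list()) {
  utils::modifyList(
    list(equal_loadings = FALSE, equal_thresholds = FALSE, fix_psi2 = FALSE),
    constraints
  )
}

HEYWOOD_THETA <- 2e-3

#' Fit the invariance-constrained two-group ordinal one-factor model
#'
#' Minimizes a (diagonally weighted or unweighted) least-squares discrepancy
#' between each group's estimated thresholds/polychoric correlations and
#' their model-implied values under a one-factor model with loadings and
#' thresholds constrained equal across groups (item intercepts are fixed at
#' zero in both groups: for ordinal items the thresholds carry the location
#' information). Group 1 identifies the scale (latent mean 0, variance 1,
#' standardized latent responses — the delta parameterization); group 2's
#' latent mean `alpha2` and variance `psi2` are free.
#'
#' `fit_mgcfa()` computes the input statistics from raw data;
#' `fit_mgcfa_stats()` fits directly from an [mgcfa_stats()] object (useful
#' for fitting at population values).
#'
#' @param data Data frame of integer item columns plus a two-level group
#'   column.
#' @param items Item columns; default: all columns except `group_col`.
#' @param group_col Name of the group column.
#' @param estimator `"DWLS"` (diagonal weights: inverse jackknife variances
#'   of the input statistics, estimated over `blocks` respondent blocks per
#'   group) or `"ULS"` (identity weights, group terms weighted by group
#'   size). Point estimates are consistent under both.
#' @param constraints Optional list overriding any of `equal_loadings`,
#'   `equal_thresholds`, `fix_psi2` (all `FALSE` by default).
#' @param blocks Number of jackknife blocks per group for DWLS weights.
#' @param control Passed to [stats::optim()] (`maxit` 500 and `reltol`
#'   1e-10 by default).
#' @return Object of class `mgcfa_fit` with elements `lambda`, `theta`,
#'   `tau`, `alpha2`, `psi2`, `n1`, `n2`, `group_levels`, `discrepancy`,
#'   `converged`, `iterations`, `estimator`, `items`, `stats`.
#' @section Improper solutions: a loading whose implied residual variance
#'   `1 - lambda^2` is not positive (a Heywood condition) raises an error of
#'   class `latentdiff_heywood` naming the offending items; callers may
#'   exclude the scale.
#' @export
fit_mgcfa <- function(data, items = NULL, group_col = "group",
                      estimator = c("DWLS", "ULS"), constraints = list(),
                      blocks = 10, control = list()) {
  estimator <- match.arg(estimator)
  stats <- mgcfa_stats(data, items = items, group_col = group_col)
  weights <- if (estimator == "DWLS") {
    jackknife_weights(data, stats, group_col = group_col, blocks = blocks)
  }
  fit_mgcfa_stats(stats, estimator = estimator, weights = weights,
                  constraints = constraints, control = control)
}

#' @rdname fit_mgcfa
#' @param stats An [mgcfa_stats()] object.
#' @param weights For `"DWLS"`, a list of two vectors of per-statistic
#'   weights (one per group), e.g. from the internal jackknife; required
#'   when fitting DWLS from statistics alone.
#' @export
fit_mgcfa_stats <- function(stats, estimator = c("DWLS", "ULS"),
                            weights = NULL, constraints = list(),
                            control = list()) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(stats, "mgcfa_stats"))
  if (length(stats$items) < 3L && !isTRUE(constraints$equal_loadings)) {
    abort("At least 3 items are required to identify the one-factor model.")
  }
  if (estimator == "DWLS" && is.null(weights)) {
    abort("DWLS from statistics alone needs `weights`; use fit_mgcfa() or ULS.")
  }
  constraints <- default_constraints(constraints)
  cuts <- model_cuts(stats)
  n_items <- length(stats$items)
  n_cats <- vapply(stats$global_levels, length, 0L)
  if (constraints$equal_thresholds &&
      length(unique(lapply(cuts, identity))) != 1L) {
    abort("equal_thresholds requires identical cut sets across items.")
  }
  start <- start_params(stats)
  par0 <- pack_params(start, constraints, cuts)
  obj <- function(par) {
    params <- unpack_params(par, constraints, cuts, n_items, n_cats)
    mgcfa_discrepancy(params, stats, weights)
  }
  control <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  opt <- optim(par0, obj, method = "BFGS", control = control)
  params <- unpack_params(opt$par, constraints, cuts, n_items, n_cats)
  theta <- 1 - params$lambda^2
  heywood <- theta < HEYWOOD_THETA
  if (any(heywood)) {
    abort(paste0("Heywood condition: non-positive residual variance for ",
                 paste(stats$items[heywood], collapse = ", ")),
          class = "latentdiff_heywood",
          items = stats$items[heywood])
  }
  structure(
    list(lambda = setNames(params$lambda, stats$items),
         theta = setNames(theta, stats$items),
         tau = setNames(params$tau, stats$items),
         alpha2 = unname(params$alpha2), psi2 = unname(params$psi2),
         n1 = stats$per_group[[1]]$n, n2 = stats$per_group[[2]]$n,
         group_levels = stats$group_levels,
         discrepancy = opt$value, converged = opt$convergence == 0L,
         iterations = unname(opt$counts["function"]),
         estimator = estimator, items = stats$items, stats = stats,
         constraints = constraints),
    class = "mgcfa_fit"
  )
}

# inverse-variance diagonal weights from a deterministic grouped jackknife:
# respondents are assigned to blocks cyclically within group; each block is
# left out once and the statistics recomputed
jackknife_weights <- function(data, stats, group_col = "group", blocks = 10) {
  grp <- factor(data[[group_col]])
  items <- stats$items
  lapply(seq_along(levels(grp)), function(gi) {
    g <- levels(grp)[gi]
    rows <- which(grp == g)
    B <- min(blocks, length(rows))
    block <- (seq_along(rows) - 1L) %% B + 1L
    full <- stack_group_stats(stats$per_group[[gi]])
    reps <- matrix(NA_real_, nrow = B, ncol = length(full))
    for (b in seq_len(B)) {
      sub <- data[rows[block != b], items, drop = FALSE]
      reps[b, ] <- tryCatch(
        group_stat_vector(sub, stats, gi),
        error = function(e) full
      )
    }
    reps[is.na(reps)] <- rep(full, each = B)[is.na(reps)]
    v <- (B - 1) / B * colSums(sweep(reps, 2, colMeans(reps))^2)
    1 / pmax(v, 1e-8)
  })
}

# recompute one group's stacked statistic vector on a data subset, aligned
# to the cut set of the full-sample stats (unidentified entries -> NA)
group_stat_vector <- function(sub, stats, gi) {
  items <- stats$items
  thr <- unlist(lapply(items, function(it) {
    full_cuts <- names(stats$per_group[[gi]]$thresholds[[it]])
    t_sub <- tryCatch(
      estimate_thresholds(sub[[it]], levels = stats$global_levels[[it]],
                          item = it),
      error = function(e) setNames(numeric(0), character(0))
    )
    out <- setNames(rep(NA_real_, length(full_cuts)), full_cuts)
    common <- intersect(full_cuts, names(t_sub))
    out[common] <- t_sub[common]
    out
  }), use.names = FALSE)
  p <- length(items)
  R <- diag(1, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      R[i, j] <- R[j, i] <- tryCatch(
        polychoric_corr(table(factor(sub[[items[i]]]),
                              factor(sub[[items[j]]])))$rho,
        error = function(e) NA_real_
      )
    }
  }
  c(thr, R[lower.tri(R)])
}

#' @export
print.mgcfa_fit <- function(x, ...) {
  cat("<mgcfa_fit> ", length(x$items), " items, groups n = ", x$n1, "/", x$n2,
      " (", x$estimator, ")\n", sep = "")
  cat("  loadings: ", paste(sprintf("%.3f", x$lambda), collapse = " "), "\n",
      sep = "")
  cat(sprintf("  group-2 latent mean %.3f, variance %.3f\n", x$alpha2, x$psi2))
  cat(sprintf("  discrepancy %.3g after %d evaluations (converged: %s)\n",
              x$discrepancy, x$iterations, x$converged))
  invisible(x)
}

#' Standardized latent mean difference from a fitted model
#'
#' Group 1 minus group 2 latent mean, divided by the pooled latent standard
#' deviation `sqrt(((n1-1)*1 + (n2-1)*psi2)/(n1+n2-2))` (the classical
#' Cohen's-d pooling applied to the latent variances). With group 1's mean
#' fixed at 0, this is `-alpha2 / sd_pooled`.
#'
#' @param fit An `mgcfa_fit`.
#' @return A single number (SD units).
#' @export
latent_d <- function(fit) {
  stopifnot(inherits(fit, "mgcfa_fit"))
  if (fit$psi2 <= 0) abort("Group-2 latent variance must be positive.")
  sd_pool <- sqrt(((fit$n1 - 1) + (fit$n2 - 1) * fit$psi2) /
                    (fit$n1 + fit$n2 - 2))
  -fit$alpha2 / sd_pool
}

#' McDonald's omega from a fitted model
#'
#' Composite reliability on the latent-response scale of the constrained
#' model: `(sum(lambda))^2 * psi_bar / ((sum(lambda))^2 * psi_bar +
#' sum(theta))`, with `psi_bar` the sample-size-weighted pooled latent
#' variance.
#'
#' @param fit An `mgcfa_fit`.
#' @return Reliability in (0, 1) for proper solutions.
#' @export
mcdonald_omega <- function(fit) {
  stopifnot(inherits(fit, "mgcfa_fit"))
  psi_bar <- (fit$n1 + fit$n2 * fit$psi2) / (fit$n1 + fit$n2)
  sl2 <- sum(fit$lambda)^2 * psi_bar
  sl2 / (sl2 + sum(fit$theta))
}

#' @method tidy mgcfa_fit
#' @export
tidy.mgcfa_fit <- function(x, ...) {
  bind_rows(
    tibble(term = paste0("lambda[", x$items, "]"), estimate = unname(x$lambda)),
    tibble(term = paste0("theta[", x$items, "]"), estimate = unname(x$theta)),
    bind_rows(lapply(x$items, function(it) {
      t <- x$tau[[it]]
      idx <- which(!is.na(t))
      tibble(term = paste0("tau[", it, ",", idx, "]"), estimate = t[idx])
    })),
    tibble(term = c("alpha2", "psi2"), estimate = c(x$alpha2, x$psi2))
  )
}

#' @method glance mgcfa_fit
#' @export
glance.mgcfa_fit <- function(x, ...) {
  tibble(
    n1 = x$n1, n2 = x$n2, estimator = x$estimator,
    discrepancy = x$discrepancy, iterations = x$iterations,
    converged = x$converged, alpha2 = x$alpha2, psi2 = x$psi2,
    latent_d = latent_d(x), omega = mcdonald_omega(x)
  )
}
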