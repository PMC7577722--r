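# First-level prewhitened GLM, contrasts, fixed-effects and group models,
# conjunction, FDR and permutation cluster correction.

#' AR(1) prewhitened general linear model fit
#'
#' Fits each region's time series by ordinary least squares, estimates a
#' lag-1 autoregressive coefficient from the residuals, then re-estimates
#' the coefficients after exact AR(1) (Prais-Winsten) whitening of both data
#' and design: row 1 is scaled by sqrt(1 - phi^2) and row t becomes
#' `x[t] - phi * x[t-1]`. With the true phi this whitening reproduces the
#' generalized-least-squares solution exactly. An intercept column is added
#' automatically. One residual degree of freedom is charged for the
#' autocorrelation estimate, so `dof = n_scans - rank(design) - 1`.
#'
#' @param signals Numeric matrix `n_scans x n_regions` (a vector is treated
#'   as one region).
#' @param design A `design_matrix` from [build_condition_design()] or
#'   [build_trialwise_design()].
#' @param phi Optional known AR(1) coefficient (scalar or one per region);
#'   when `NULL` it is estimated per region from OLS residuals.
#' @return An object of class `glm_fit` with elements `beta`
#'   (regressors x regions), `sigma2`, `dof`, `phi`, `xtx_inv`
#'   (p x p x regions array of whitened-design inverse cross-products),
#'   `terms` and `design_ref`.
#' @export
fit_glm_prewhitened <- function(signals, design, phi = NULL) {
  Y <- as.matrix(signals)
  X <- cbind(`(Intercept)` = 1, design$X)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n)
    stopf("signals have %d timepoints but the design has %d scans", nrow(Y), n)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stopf("design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  if (n <= p + 2)
    stopf("series too short: %d scans for %d regressors", n, p)
  R <- ncol(Y)
  beta0 <- qr.coef(qx, Y)
  E <- Y - X %*% beta0
  if (is.null(phi)) {
    phi_hat <- colSums(E[-1, , drop = FALSE] * E[-n, , drop = FALSE]) /
      colSums(E * E)
  } else {
    check_ar <- phi
    if (any(abs(check_ar) >= 1)) stopf("'phi' must lie in (-1, 1)")
    phi_hat <- rep_len(phi, R)
  }
  phi_hat <- pmin(pmax(phi_hat, -0.99), 0.99)
  dof <- n - p - 1
  beta <- matrix(NA_real_, p, R, dimnames = list(colnames(X), colnames(Y)))
  sigma2 <- numeric(R)
  xtx_inv <- array(NA_real_, c(p, p, R),
                   dimnames = list(colnames(X), colnames(X), colnames(Y)))
  for (r in seq_len(R)) {
    ph <- phi_hat[r]
    w1 <- sqrt(1 - ph^2)
    Xw <- rbind(X[1, ] * w1, X[-1, , drop = FALSE] - ph * X[-n, , drop = FALSE])
    yw <- c(Y[1, r] * w1, Y[-1, r] - ph * Y[-n, r])
    xtx <- crossprod(Xw)
    xi <- chol2inv(chol(xtx))
    b <- xi %*% crossprod(Xw, yw)
    res <- yw - Xw %*% b
    beta[, r] <- b
    sigma2[r] <- sum(res^2) / dof
    xtx_inv[, , r] <- xi
  }
  structure(list(beta = beta, sigma2 = sigma2, dof = dof, phi = phi_hat,
                 xtx_inv = xtx_inv, terms = colnames(X), n_scans = n,
                 design_ref = design$column_names),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d regressors x %d regions, dof %d, phi in [%.3f, %.3f]\n",
              nrow(x$beta), ncol(x$beta), x$dof, min(x$phi), max(x$phi)))
  invisible(x)
}

stat_map <- function(values, kind = c("contrast", "conjunction", "group"),
                     label = "") {
  kind <- match.arg(kind)
  structure(as.numeric(values), names = names(values), kind = kind,
            label = label, class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map:%s> %s\n", attr(x, "kind"), attr(x, "label")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

resolve_contrast <- function(fit, contrast) {
  if (!is.null(names(contrast))) {
    unknown <- setdiff(names(contrast), fit$terms)
    if (length(unknown))
      stopf("contrast names not in the design: %s",
            paste(unknown, collapse = ", "))
    cv <- stats::setNames(numeric(length(fit$terms)), fit$terms)
    cv[names(contrast)] <- contrast
  } else {
    if (length(contrast) == length(fit$terms) - 1L)
      contrast <- c(0, contrast)  # intercept not addressed
    if (length(contrast) != length(fit$terms))
      stopf("contrast has length %d but the fit has %d regressors",
            length(contrast), length(fit$terms))
    cv <- as.numeric(contrast)
  }
  if (all(cv == 0)) stopf("contrast vector is identically zero")
  cv
}

#' Contrast z-statistic map from a prewhitened fit
#'
#' Computes `t = c'beta / sqrt(sigma2 * c' (Xw'Xw)^-1 c)` on the whitened
#' design per region and converts it to a z-statistic by matched tail
#' probability of the t distribution at the fit's residual dof.
#'
#' @param fit A `glm_fit`.
#' @param contrast Named numeric vector over design columns (missing columns
#'   are 0), or a full-length numeric vector; the intercept can be addressed
#'   as `"(Intercept)"`.
#' @param label Label stored in the returned map.
#' @return A `stat_map` (named numeric z per region) with the contrast
#'   estimates in attribute `"estimate"` and their variances in `"variance"`.
#' @export
contrast_z <- function(fit, contrast, label = NULL) {
  cv <- resolve_contrast(fit, contrast)
  est <- drop(crossprod(cv, fit$beta))
  cvar <- apply(fit$xtx_inv, 3, function(m) drop(crossprod(cv, m %*% cv)))
  v <- fit$sigma2 * cvar
  z <- t_to_z(est / sqrt(v), fit$dof)
  out <- stat_map(stats::setNames(z, colnames(fit$beta)), "contrast",
                  label %||% paste(deparse(substitute(contrast)), collapse = ""))
  attr(out, "estimate") <- stats::setNames(est, colnames(fit$beta))
  attr(out, "variance") <- stats::setNames(v, colnames(fit$beta))
  out
}

#' z-statistics of every of-interest (per-trial) regressor
#'
#' @param fit A `glm_fit` of a trial-wise design.
#' @param columns Regressor names to extract; defaults to the design's
#'   of-interest columns recorded at fit time is not stored, so pass the
#'   design's `of_interest`.
#' @return matrix length(columns) x regions of z values.
#' @noRd
regressor_z <- function(fit, columns) {
  j <- match(columns, fit$terms)
  if (anyNA(j))
    stopf("columns not in the fit: %s",
          paste(columns[is.na(j)], collapse = ", "))
  R <- ncol(fit$beta)
  z <- matrix(NA_real_, length(j), R,
              dimnames = list(columns, colnames(fit$beta)))
  for (r in seq_len(R)) {
    se <- sqrt(fit$sigma2[r] * diag(fit$xtx_inv[, , r])[j])
    z[, r] <- t_to_z(fit$beta[j, r] / se, fit$dof)
  }
  z
}

#' Inverse-variance weighted (fixed effects) average of contrast estimates
#'
#' Combines per-run or per-visit contrast estimates into a single
#' fixed-effects estimate per region. With equal variances this reduces to
#' the arithmetic mean.
#'
#' @param estimates List (or k x regions matrix) of contrast estimates.
#' @param variances Matching list/matrix of estimate variances.
#' @return List with `estimate` and `variance` (named per region) and `z`,
#'   the combined estimate over its standard error under a normal reference.
#' @export
fixed_effects_average <- function(estimates, variances) {
  bind_aligned <- function(x) {
    if (!is.list(x)) return(x)
    nms <- lapply(x, names)
    if (length(unique(nms)) > 1L)
      stopf("maps are aligned to different regions: %s vs %s",
            paste(nms[[1]], collapse = ","),
            paste(nms[[which(!vapply(nms, identical, TRUE, nms[[1]]))[1]]],
                  collapse = ","))
    do.call(rbind, x)
  }
  estimates <- bind_aligned(estimates)
  variances <- bind_aligned(variances)
  estimates <- rbind(estimates); variances <- rbind(variances)
  if (!identical(dim(estimates), dim(variances)))
    stopf("estimates and variances must have matching dimensions")
  if (!is.null(colnames(estimates)) && !is.null(colnames(variances)) &&
      !identical(colnames(estimates), colnames(variances)))
    stopf("estimates and variances are aligned to different regions")
  if (any(variances <= 0)) stopf("variances must be positive")
  w <- 1 / variances
  est <- colSums(w * estimates) / colSums(w)
  v <- 1 / colSums(w)
  list(estimate = est, variance = v, z = est / sqrt(v))
}

#' Group-level model over subject maps
#'
#' One-sample t-test per region (no covariate), or the slope of a
#' mean-centred covariate regression per region, converted to z. Ordinary
#' (unweighted) least squares is used at the group level. Zero-variance
#' degenerate inputs yield a capped z (|z| = 38) flagged in attribute
#' `"degenerate"` rather than infinities.
#'
#' @param maps n_subjects x n_regions matrix of per-subject statistics.
#' @param covariate Optional numeric vector (length n_subjects) whose
#'   mean-centred slope is tested instead of the group mean.
#' @return A `stat_map` of z values per region.
#' @export
group_model <- function(maps, covariate = NULL) {
  maps <- rbind(maps)
  n <- nrow(maps)
  if (n < 3) stopf("group model needs at least 3 subjects, got %d", n)
  if (is.null(covariate)) {
    m <- colMeans(maps)
    s <- apply(maps, 2, stats::sd)
    t <- m / (s / sqrt(n))
    degen <- s == 0 & m != 0
    t[s == 0 & m == 0] <- 0
    z <- t_to_z(t, n - 1)
    z[degen] <- sign(m[degen]) * Z_CAP
    out <- stat_map(stats::setNames(z, colnames(maps)), "group", "one-sample")
  } else {
    if (length(covariate) != n)
      stopf("covariate has length %d but there are %d subjects",
            length(covariate), n)
    if (stats::sd(covariate) == 0)
      stopf("covariate is constant; its slope is not estimable")
    x <- covariate - mean(covariate)
    b <- drop(crossprod(x, maps)) / sum(x^2)
    fitted <- outer(rep(1, n), colMeans(maps)) + outer(x, b)
    rss <- colSums((maps - fitted)^2)
    se <- sqrt(rss / (n - 2) / sum(x^2))
    degen <- se == 0 & b != 0
    t <- ifelse(se == 0, 0, b / se)
    z <- t_to_z(t, n - 2)
    z[degen] <- sign(b[degen]) * Z_CAP
    out <- stat_map(stats::setNames(z, colnames(maps)), "group", "covariate slope")
  }
  attr(out, "degenerate") <- unname(degen)
  out
}

#' Minimum-statistic conjunction of two z maps
#'
#' Element-wise minimum; a region is jointly active only if both maps carry
#' evidence, so the conjunction z is conservative for the joint null.
#'
#' @param map_a,map_b `stat_map`s (or named numeric vectors) over the same
#'   regions.
#' @return A `stat_map` of kind `"conjunction"`.
#' @export
conjunction_min <- function(map_a, map_b) {
  if (length(map_a) != length(map_b))
    stopf("maps have different lengths (%d vs %d)", length(map_a), length(map_b))
  if (!is.null(names(map_a)) && !is.null(names(map_b)) &&
      !identical(names(map_a), names(map_b)))
    stopf("maps are aligned to different regions")
  stat_map(stats::setNames(pmin(as.numeric(map_a), as.numeric(map_b)),
                           names(map_a)),
           "conjunction", "minimum statistic")
}

#' Benjamini-Hochberg FDR rejection set
#'
#' Step-up false discovery rate control at level `alpha`: rejects all
#' hypotheses with BH-adjusted p-value at or below `alpha`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return List with `rejected` (indices), `adjusted` (BH-adjusted
#'   p-values) and `n_rejected`.
#' @export
fdr_threshold <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  rejected <- which(adj <= alpha)
  list(rejected = rejected, adjusted = adj, n_rejected = length(rejected))
}

# maximum extent of supra-threshold connected components
max_cluster_extent <- function(supra, neighbours) {
  cl <- label_clusters(supra, neighbours)
  if (!length(cl)) 0L else max(lengths(cl))
}

# connected components over an adjacency list, restricted to supra nodes
label_clusters <- function(supra, neighbours) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  seen <- logical(length(supra))
  out <- list()
  for (s in idx) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- neighbours[[v]]
      nb <- nb[supra[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

grid_adjacency <- function(grid_dim) {
  nd <- length(grid_dim)
  n <- prod(grid_dim)
  coords <- arrayInd(seq_len(n), .dim = grid_dim)
  lapply(seq_len(n), function(i) {
    nb <- integer(0)
    for (d in seq_len(nd)) {
      for (step in c(-1L, 1L)) {
        cc <- coords[i, ]
        cc[d] <- cc[d] + step
        if (cc[d] >= 1L && cc[d] <= grid_dim[d])
          nb <- c(nb, sum((cc - 1L) * cumprod(c(1L, grid_dim[-nd]))) + 1L)
      }
    }
    nb
  })
}

#' Sign-flip permutation cluster correction for a group map
#'
#' Forms the group one-sample statistic per node, thresholds it at
#' `z_form`, and assesses the spatial extent of the resulting clusters
#' against the permutation null distribution of the maximum cluster extent
#' obtained by randomly sign-flipping subject maps (valid under symmetric
#' subject-level nulls). A cluster is significant when its family-wise
#' p-value `(1 + #{null >= extent}) / (n_perm + 1)` is at or below `alpha`.
#'
#' @param maps n_subjects x n_nodes matrix of subject statistics on a
#'   spatial grid.
#' @param grid_dim Integer vector of grid dimensions (nodes are in
#'   column-major order); alternatively supply `adjacency`.
#' @param adjacency List of integer neighbour vectors, one per node.
#' @param z_form Cluster-forming threshold on the group z map.
#' @param alpha Family-wise error level.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return List with `clusters` (list of node-index vectors), `extent`,
#'   `p_fwe`, `significant`, the observed group `z` map, and
#'   `null_quantile`, the (1-alpha) quantile of the max-extent null.
#' @export
cluster_correct_permutation <- function(maps, grid_dim = NULL,
                                        adjacency = NULL, z_form = 2.3,
                                        alpha = 0.05, n_perm = 1000,
                                        seed = 1) {
  maps <- rbind(maps)
  n <- nrow(maps); m <- ncol(maps)
  if (is.null(grid_dim) && is.null(adjacency))
    stopf(paste("no spatial topology declared (grid_dim or adjacency);",
                "for non-spatial region sets use fdr_threshold()"))
  if (n_perm < 100) stopf("'n_perm' must be at least 100")
  neighbours <- adjacency %||% grid_adjacency(as.integer(grid_dim))
  chain <- is.null(adjacency) && length(grid_dim) == 1L
  df <- n - 1
  t_form <- stats::qt(stats::pnorm(z_form, lower.tail = FALSE), df,
                      lower.tail = FALSE)
  ss <- colSums(maps^2)
  t_of_mean <- function(mn) {
    v <- (ss / n - mn^2) * n / (n - 1)
    ifelse(v <= 0, 0, mn / sqrt(v / n))
  }
  obs_t <- t_of_mean(colMeans(maps))
  obs_supra <- obs_t > t_form
  obs_clusters <- if (chain) {
    r <- rle(obs_supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mapply(function(s, e) s:e, starts[r$values], ends[r$values],
           SIMPLIFY = FALSE)
  } else label_clusters(obs_supra, neighbours)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    mns <- S %*% maps / n
    vapply(seq_len(n_perm), function(b) {
      supra <- t_of_mean(mns[b, ]) > t_form
      if (chain) {
        r <- rle(supra)
        mx <- r$lengths[r$values]
        if (length(mx)) max(mx) else 0L
      } else max_cluster_extent(supra, neighbours)
    }, numeric(1))
  })
  extent <- lengths(obs_clusters)
  p_fwe <- vapply(extent, function(e) (1 + sum(null_max >= e)) / (n_perm + 1),
                  numeric(1))
  keep <- p_fwe <= alpha
  list(clusters = obs_clusters[keep], extent = extent[keep],
       p_fwe = p_fwe[keep], significant = any(keep),
       all_clusters = obs_clusters, all_p_fwe = p_fwe,
       z = t_to_z(obs_t, df),
       null_quantile = unname(stats::quantile(null_max, 1 - alpha, type = 1)))
}

#' Region-of-interest mask
#'
#' @param indices Integer region (or voxel) indices into the shared region
#'   registry.
#' @param label Mask label.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(indices, label = "roi") {
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices)) stopf("an ROI mask cannot be empty")
  structure(list(indices = indices, label = label), class = "roi_mask")
}

#' Intersect a significant region set with an anatomical mask
#'
#' @param significant `roi_mask` (or integer vector) of supra-threshold
#'   regions.
#' @param anatomical `roi_mask` of the a priori structural region.
#' @return A `roi_mask` of the intersection, labelled after the anatomical
#'   mask; an empty intersection is returned with attribute `"empty" = TRUE`
#'   and a warning.
#' @export
intersect_roi <- function(significant, anatomical) {
  si <- if (inherits(significant, "roi_mask")) significant$indices
        else as.integer(significant)
  ai <- if (inherits(anatomical, "roi_mask")) anatomical$indices
        else as.integer(anatomical)
  lab <- if (inherits(anatomical, "roi_mask")) anatomical$label else "roi"
  common <- intersect(si, ai)
  if (!length(common)) {
    warnf("ROI intersection is empty")
    out <- structure(list(indices = integer(0), label = lab),
                     class = "roi_mask")
    attr(out, "empty") <- TRUE
    return(out)
  }
  roi_mask(common, lab)
}
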