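# Effect sizes and multilevel random-effects meta-regression.
#
# The estimator is a GLS meta-regression with known sampling variances,
# random intercepts per grouping factor and an optional continuous-time
# autoregressive (CAR) serial structure within time series; variance
# components are estimated by REML (or ML), and ML log-likelihoods are
# kept for likelihood-ratio moderator tests. Cluster-robust sandwich
# covariances correct for shared-control dependence.

#' Convert a standard error to a standard deviation
#'
#' Source tables often report standard errors of arm means; these are
#' converted to SDs via `SD = SE * sqrt(n)` before pooling. The
#' conversion is explicit so record provenance stays auditable.
#'
#' @param se Standard error(s) of the arm mean.
#' @param n Arm sample size(s).
#' @return Standard deviation(s).
#' @export
se_to_sd <- function(se, n) se * sqrt(n)

#' Hedges g standardized mean difference with unbiased sampling variance
#'
#' Computes `d = (mean_t - mean_c) / s_pooled` with the (n-1)-weighted
#' pooled SD, applies the small-sample correction
#' `J = 1 - 3 / (4 (n_c + n_t - 2) - 1)` to give `g = J d`, and the
#' sampling variance `v = (n_c + n_t)/(n_c n_t) + g^2 / (2 (n_c + n_t))`.
#' Sign convention: a pesticide that reduces pest densities relative to
#' the untreated control gives negative `g`.
#'
#' @param mean_c,sd_c,n_c Control-arm mean, SD and sample size.
#' @param mean_t,sd_t,n_t Treated-arm mean, SD and sample size.
#' @return A data frame with columns `g` and `v` (one row per input).
#' @examples
#' hedges_g(10, 2, 5, 8, 2, 5)  # g about -0.9032, v about 0.4408
#' @export
hedges_g <- function(mean_c, sd_c, n_c, mean_t, sd_t, n_t) {
  if (any(n_c < 2) || any(n_t < 2)) stop("need n >= 2 per arm")
  if (any(sd_c < 0) || any(sd_t < 0)) stop("SDs must be >= 0")
  sp <- sqrt(((n_c - 1) * sd_c^2 + (n_t - 1) * sd_t^2) / (n_c + n_t - 2))
  diff <- mean_t - mean_c
  if (any(sp == 0 & diff != 0))
    stop("undefined effect size: zero pooled SD with unequal means")
  if (any(sp == 0 & diff == 0))
    warning("equal means with zero SD: g = 0, v from the sample-size term only")
  d <- ifelse(sp == 0, 0, diff / sp)
  J <- 1 - 3 / (4 * (n_c + n_t - 2) - 1)
  g <- J * d
  v <- (n_c + n_t) / (n_c * n_t) + g^2 / (2 * (n_c + n_t))
  data.frame(g = g, v = v)
}

#' Append Hedges g effect sizes to a trial-record table
#'
#' @param records Data frame with columns `mean_c`, `sd_c`, `n_c`,
#'   `mean_t`, `sd_t`, `n_t` (the documented trial-record schema).
#' @return `records` with columns `g` and `v` appended.
#' @export
effect_sizes <- function(records) {
  es <- hedges_g(records$mean_c, records$sd_c, records$n_c,
                 records$mean_t, records$sd_t, records$n_t)
  cbind(records, es)
}

## ---- covariance machinery ----------------------------------------------

# 0/1 group-membership indicator matrix (model.matrix chokes on
# single-level factors)
indicator_matrix <- function(x) {
  f <- factor(x)
  m <- matrix(0, length(f), nlevels(f))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# Per-block marginal covariance at variance components vc:
# diag(v) + sum_b tau2_b J + tau2_ar * exp(-rho |dt|) within series.
block_V <- function(v, Zs, times, series, vc) {
  n <- length(v)
  V <- diag(v, n)
  for (b in seq_along(Zs)) V <- V + vc$tau2[b] * tcrossprod(Zs[[b]])
  if (!is.null(times)) {
    C <- exp(-vc$rho * abs(outer(times, times, "-")))
    C[outer(series, series, "!=")] <- 0
    V <- V + vc$tau2_ar * C
  }
  V
}

# Negative twice log-likelihood (ML or REML) with profiled beta.
# Returns list(obj, beta, XtVX_inv, logdet, quad).
gls_objective <- function(y, X, v, blocks, Zs_by_block, times, series, vc,
                          reml = TRUE) {
  p <- ncol(X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  ytVy <- 0; logdet <- 0
  for (g in seq_along(blocks)) {
    i <- blocks[[g]]
    V <- block_V(v[i], Zs_by_block[[g]], times[i], series[i], vc)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(list(obj = 1e10))
    logdet <- logdet + 2 * sum(log(diag(R)))
    Xi <- X[i, , drop = FALSE]; yi <- y[i]
    Lx <- backsolve(R, Xi, transpose = TRUE)
    Ly <- backsolve(R, yi, transpose = TRUE)
    XtVX <- XtVX + crossprod(Lx)
    XtVy <- XtVy + crossprod(Lx, Ly)[, 1]
    ytVy <- ytVy + sum(Ly^2)
  }
  XtVX_chol <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(XtVX_chol)) return(list(obj = 1e10))
  beta <- backsolve(XtVX_chol, backsolve(XtVX_chol, XtVy, transpose = TRUE))
  quad <- ytVy - sum(XtVy * beta)
  obj <- logdet + quad + (length(y) - if (reml) p else 0) * log(2 * pi)
  if (reml) obj <- obj + 2 * sum(log(diag(XtVX_chol)))
  list(obj = obj, beta = beta, XtVX_chol = XtVX_chol, logdet = logdet,
       quad = quad)
}

# Fast path: single random intercept, no AR; vectorized Woodbury.
fast_objective <- function(y, X, v, cluster, tau2, reml = TRUE) {
  p <- ncol(X)
  wi <- 1 / v
  s1 <- rowsum(wi, cluster)[, 1]
  A <- tau2 / (1 + tau2 * s1)          # per-cluster Woodbury factor
  wX <- wi * X
  sX <- rowsum(wX, cluster)            # per-cluster t(X_g) w_g
  sy <- rowsum(wi * y, cluster)[, 1]
  XtVX <- crossprod(X, wX) - crossprod(sX, A * sX)
  XtVy <- crossprod(wX, y)[, 1] - crossprod(sX, A * sy)[, 1]
  ytVy <- sum(wi * y^2) - sum(A * sy^2)
  logdet <- sum(log(v)) + sum(log1p(tau2 * s1))
  XtVX_chol <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(XtVX_chol)) return(list(obj = 1e10))
  beta <- backsolve(XtVX_chol, backsolve(XtVX_chol, XtVy, transpose = TRUE))
  quad <- ytVy - sum(XtVy * beta)
  obj <- logdet + quad + (length(y) - if (reml) p else 0) * log(2 * pi)
  if (reml) obj <- obj + 2 * sum(log(diag(XtVX_chol)))
  list(obj = obj, beta = beta, XtVX_chol = XtVX_chol)
}

#' Fit a multilevel random-effects meta-regression
#'
#' Generalized least squares meta-regression of effect sizes on moderators
#' with known sampling variances, random intercepts for the given grouping
#' factors (variance `tau^2` each, REML- or ML-estimated) and an optional
#' continuous-time AR serial structure `tau2_ar * exp(-rho * dt)` between
#' effects within one time series. For seasonal-average data use a study
#' random intercept; for time-series data use a series intercept plus the
#' serial structure. The ML log-likelihood is always computed (refitting
#' the variance components under ML) so nested fits can be compared with
#' likelihood-ratio tests.
#'
#' @param data Data frame holding effect sizes, variances, moderators and
#'   grouping columns.
#' @param moderators Model formula for the fixed effects (right-hand side
#'   only), e.g. `~ enemy_presence + application + duration`.
#' @param random Character vector of grouping columns given random
#'   intercepts, outermost first (blocks of the marginal covariance are
#'   formed by the first element); `NULL` for a fixed-effect model.
#' @param ar Optional list `list(series = <column>, time = <column>)`
#'   adding the serial structure within levels of `series`.
#' @param method `"REML"` (default) or `"ML"` for the reported fit.
#' @param g_col,v_col Column names of the effect sizes and variances.
#' @return An object of class `"meta_fit"` with elements `beta`, `se`,
#'   `vb` (model-based covariance), `tau2` (named), `tau2_ar`, `rho`,
#'   `phi` (`exp(-rho)`, the correlation at lag 1), `ll`, `ll_ml`, `k`,
#'   `p`, and the design/bookkeeping needed by [robust_inference()],
#'   [lrt_moderator()] and [summarize_by_level()].
#' @export
fit_meta <- function(data, moderators = ~ 1, random = NULL, ar = NULL,
                     method = c("REML", "ML"), g_col = "g", v_col = "v") {
  method <- match.arg(method)
  y <- data[[g_col]]; v <- data[[v_col]]
  if (is.null(y) || is.null(v)) stop("data must contain '", g_col,
                                     "' and '", v_col, "' columns")
  if (any(v <= 0)) stop("sampling variances must be > 0")
  mf <- stats::model.frame(moderators, data, na.action = stats::na.fail)
  X <- stats::model.matrix(moderators, mf)
  if (qr(X)$rank < ncol(X)) {
    stop("moderator design matrix is rank deficient; aliased columns: ",
         paste(colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]],
               collapse = ", "))
  }
  k <- length(y); p <- ncol(X)
  n_tau <- length(random)
  has_ar <- !is.null(ar)
  if (has_ar && (is.null(ar$series) || is.null(ar$time)))
    stop("ar must be list(series =, time =)")

  block_col <- if (n_tau > 0) random[1] else if (has_ar) ar$series else NULL
  blocks <- if (is.null(block_col)) list(seq_len(k))
            else split(seq_len(k), data[[block_col]])
  times <- if (has_ar) as.numeric(data[[ar$time]]) else NULL
  series <- if (has_ar) as.character(data[[ar$series]]) else NULL
  Zs_by_block <- lapply(blocks, function(i) {
    lapply(random, function(rc) indicator_matrix(data[[rc]][i]))
  })

  fast <- n_tau == 1 && !has_ar
  cluster <- if (n_tau > 0) factor(data[[random[1]]]) else NULL

  n_par <- n_tau + if (has_ar) 2 else 0
  make_vc <- function(theta) {
    list(tau2 = if (n_tau > 0) exp(theta[seq_len(n_tau)]) else numeric(0),
         tau2_ar = if (has_ar) exp(theta[n_tau + 1]) else 0,
         rho = if (has_ar) exp(theta[n_tau + 2]) else 0)
  }
  obj_fun <- function(theta, reml) {
    if (fast) fast_objective(y, X, v, cluster, exp(theta[1]), reml)$obj
    else gls_objective(y, X, v, blocks, Zs_by_block, times, series,
                       make_vc(theta), reml)$obj
  }

  optimize_vc <- function(reml) {
    if (n_par == 0) return(list(theta = numeric(0), convergence = 0L))
    start <- c(rep(log(max(stats::var(y) - mean(v), 0.01)), n_tau),
               if (has_ar) c(log(0.05), log(1)) else NULL)
    fit <- stats::nlminb(start, obj_fun, reml = reml,
                         lower = rep(-30, n_par), upper = rep(10, n_par),
                         control = list(rel.tol = 1e-10, iter.max = 500))
    if (fit$convergence != 0 && !fit$message %in%
        c("relative convergence (4)", "both X-convergence and relative convergence (5)",
          "X-convergence (3)"))
      stop("variance-component optimization did not converge: ", fit$message)
    list(theta = fit$par, convergence = fit$convergence)
  }

  opt <- optimize_vc(method == "REML")
  vc <- make_vc(opt$theta)
  # snap vanishing components to the boundary
  vc$tau2[vc$tau2 < 1e-8] <- 0
  if (has_ar && vc$tau2_ar < 1e-8) vc$tau2_ar <- 0
  final <- if (fast)
    fast_objective(y, X, v, cluster, vc$tau2[1], method == "REML")
  else gls_objective(y, X, v, blocks, Zs_by_block, times, series, vc,
                     method == "REML")
  ll <- -final$obj / 2

  if (method == "ML") {
    ll_ml <- ll
  } else {
    opt_ml <- optimize_vc(FALSE)
    vc_ml <- make_vc(opt_ml$theta)
    f_ml <- if (fast) fast_objective(y, X, v, cluster, vc_ml$tau2[1], FALSE)
            else gls_objective(y, X, v, blocks, Zs_by_block, times, series,
                               vc_ml, FALSE)
    ll_ml <- -f_ml$obj / 2
  }

  vb <- chol2inv(final$XtVX_chol)
  beta <- as.numeric(final$beta)
  names(beta) <- colnames(X)
  dimnames(vb) <- list(colnames(X), colnames(X))
  structure(list(
    beta = beta, se = sqrt(diag(vb)), vb = vb,
    tau2 = stats::setNames(vc$tau2, random),
    tau2_ar = if (has_ar) vc$tau2_ar else NULL,
    rho = if (has_ar) vc$rho else NULL,
    phi = if (has_ar) exp(-vc$rho) else NULL,
    ll = ll, ll_ml = ll_ml, k = k, p = p,
    method = method, moderators = moderators,
    X = X, y = y, v = v, data = data, random = random, ar = ar,
    blocks = blocks, Zs_by_block = Zs_by_block,
    times = times, series = series, vc = vc,
    convergence = opt$convergence), class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Multilevel meta-regression (%s), k = %d effects\n",
              x$method, x$k))
  tab <- data.frame(estimate = x$beta, se = x$se,
                    z = x$beta / x$se,
                    p = 2 * stats::pnorm(-abs(x$beta / x$se)))
  print(round(tab, 4))
  if (length(x$tau2))
    cat("tau2:", paste(sprintf("%s = %.4f", names(x$tau2), x$tau2),
                       collapse = ", "), "\n")
  if (!is.null(x$tau2_ar))
    cat(sprintf("serial: tau2 = %.4f, rho = %.4f (phi = %.4f)\n",
                x$tau2_ar, x$rho, x$phi))
  cat(sprintf("log-likelihood (%s): %.4f; ML: %.4f\n", x$method, x$ll,
              x$ll_ml))
  invisible(x)
}

fit_V_inv_blocks <- function(fit, idx_list) {
  # V^{-1} per block of row indices, at the fitted variance components
  lapply(seq_along(idx_list), function(j) {
    i <- idx_list[[j]]
    Zs <- lapply(fit$random, function(rc) indicator_matrix(fit$data[[rc]][i]))
    V <- block_V(fit$v[i], Zs,
                 if (!is.null(fit$ar)) fit$times[i] else NULL,
                 fit$series[i], fit$vc)
    chol2inv(chol(V))
  })
}

#' Cluster-robust (sandwich) inference for a meta-regression fit
#'
#' Computes the cluster-robust covariance of the fixed-effect
#' coefficients with small-sample scaling `G/(G-1)` (`G` = number of
#' clusters) and 95% confidence intervals from a t reference with
#' `G - p` degrees of freedom. Used when several effect sizes share an
#' untreated control or study.
#'
#' @param fit A [fit_meta()] object.
#' @param cluster Column of `fit$data` defining independent clusters;
#'   defaults to the outermost random factor.
#' @param level Confidence level (default 0.95).
#' @return A list with `table` (coefficient, robust SE, t, df, CI, p),
#'   `vb_robust`, `G` and `df`.
#' @export
robust_inference <- function(fit, cluster = NULL, level = 0.95) {
  if (is.null(cluster)) {
    if (is.null(fit$random)) stop("no cluster column given")
    cluster <- fit$random[1]
  }
  cl <- factor(fit$data[[cluster]])
  G <- nlevels(cl)
  if (G < 2) stop("need >= 2 clusters for robust inference")
  idx <- split(seq_len(fit$k), cl)
  Vinv <- fit_V_inv_blocks(fit, idx)
  p <- fit$p
  bread <- matrix(0, p, p); meat <- matrix(0, p, p)
  resid <- fit$y - as.numeric(fit$X %*% fit$beta)
  for (j in seq_along(idx)) {
    i <- idx[[j]]
    Xi <- fit$X[i, , drop = FALSE]
    XiW <- crossprod(Xi, Vinv[[j]])
    bread <- bread + XiW %*% Xi
    u <- XiW %*% resid[i]
    meat <- meat + tcrossprod(u)
  }
  bread_inv <- solve(bread)
  vb_r <- bread_inv %*% meat %*% bread_inv * G / (G - 1)
  vb_r <- (vb_r + t(vb_r)) / 2
  df <- G - p
  if (df < 1) stop("fewer clusters than coefficients: df < 1")
  se <- sqrt(diag(vb_r))
  tval <- fit$beta / se
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  tab <- data.frame(estimate = fit$beta, se_robust = se, t = tval, df = df,
                    ci.lb = fit$beta - tcrit * se,
                    ci.ub = fit$beta + tcrit * se,
                    p = 2 * stats::pt(-abs(tval), df))
  list(table = tab, vb_robust = vb_r, G = G, df = df)
}

#' Likelihood-ratio test for moderators
#'
#' Compares two nested meta-regression fits of the same data by their ML
#' log-likelihoods: `LRT = 2 (ll_full - ll_reduced)` on `df` equal to the
#' difference in fixed-effect parameter counts, with a chi-squared
#' p-value. Deletion tests for a moderator compare the full model with
#' the model dropping it; level contrasts compare the full coding with an
#' aggregated coding.
#'
#' @param full,reduced [fit_meta()] objects fitted to the same effects;
#'   the reduced fixed-effect design must be nested in the full one.
#' @return A list with `statistic`, `df` and `p`.
#' @export
lrt_moderator <- function(full, reduced) {
  if (full$k != reduced$k)
    stop("fits must use the same data (k differs)")
  df <- full$p - reduced$p
  if (df < 0) stop("'full' has fewer parameters than 'reduced'; not nested")
  # nesting check: reduced design must lie in the column span of the full
  qf <- qr(full$X)
  proj <- qr.fitted(qf, reduced$X)
  if (max(abs(proj - reduced$X)) > 1e-8)
    stop("designs are not nested")
  stat <- max(0, 2 * (full$ll_ml - reduced$ll_ml))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Pooled effects per level of a moderator
#'
#' Linear-combination estimates of the cell means for each level of a
#' categorical moderator, evaluated from the fitted coefficients (other
#' factors at their reference level, numeric covariates at their mean),
#' with model-based or cluster-robust covariance. Produces a
#' forest-style table.
#'
#' @param fit A [fit_meta()] object.
#' @param grouping Name of a factor column used in the moderator formula.
#' @param cluster Optional cluster column for robust covariance.
#' @param level Confidence level.
#' @return Data frame with one row per moderator level: `estimate`, `se`,
#'   `ci.lb`, `ci.ub`, `n` (effects in the level). Levels absent from the
#'   data are flagged with `NA` estimates.
#' @export
summarize_by_level <- function(fit, grouping, cluster = NULL, level = 0.95) {
  dat <- fit$data
  if (!grouping %in% names(dat)) stop("no column '", grouping, "'")
  f <- factor(dat[[grouping]])
  levs <- levels(f)
  vars <- all.vars(fit$moderators)
  newdata <- data.frame(.level = levs, stringsAsFactors = FALSE)
  for (vn in vars) {
    col <- dat[[vn]]
    newdata[[vn]] <- if (vn == grouping) {
      if (is.numeric(col)) as.numeric(levs) else levs
    } else if (is.numeric(col)) mean(col) else levels(factor(col))[1]
  }
  for (vn in vars) if (!is.numeric(dat[[vn]]))
    newdata[[vn]] <- factor(newdata[[vn]], levels = levels(factor(dat[[vn]])))
  L <- stats::model.matrix(fit$moderators, newdata)
  if (is.null(cluster)) {
    vb <- fit$vb
    crit <- stats::qnorm(1 - (1 - level) / 2)
  } else {
    ri <- robust_inference(fit, cluster, level)
    vb <- ri$vb_robust
    crit <- stats::qt(1 - (1 - level) / 2, ri$df)
  }
  est <- as.numeric(L %*% fit$beta)
  se <- sqrt(diag(L %*% vb %*% t(L)))
  n <- as.integer(table(f)[levs])
  est[n == 0] <- NA_real_; se[n == 0] <- NA_real_
  data.frame(level = levs, estimate = est, se = se,
             ci.lb = est - crit * se, ci.ub = est + crit * se, n = n)
}
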