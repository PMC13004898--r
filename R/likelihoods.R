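# Maximum-likelihood fitters for the three outcome families used in the
# gene-by-environment analysis: interval-censored Gaussian, binary logit,
# and proportional-odds (ordered) logit. All three share one internal
# parameter vector theta, a per-row log-likelihood closure (used for the
# cluster sandwich), and a quasi-Newton optimizer with analytic gradients
# and a Newton polish to drive the gradient norm below tolerance.

# log(1 - exp(x)) for x <= 0, numerically stable
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# log(pnorm(zu) - pnorm(zl)) for zl < zu, stable in both tails (vectorized)
log_pnorm_diff <- function(zl, zu) {
  out <- numeric(length(zu))
  both_hi <- is.finite(zl) & zl > 0            # use upper tail
  lo <- !both_hi
  if (any(both_hi)) {
    a <- stats::pnorm(zl[both_hi], lower.tail = FALSE, log.p = TRUE)
    b <- stats::pnorm(zu[both_hi], lower.tail = FALSE, log.p = TRUE)
    out[both_hi] <- a + log1mexp(pmin(b - a, 0))
  }
  if (any(lo)) {
    a <- stats::pnorm(zu[lo], log.p = TRUE)
    b <- stats::pnorm(zl[lo], log.p = TRUE)  # -Inf when zl = -Inf
    out[lo] <- a + log1mexp(pmin(b - a, 0))
  }
  out
}

# Minimize nll with BFGS (analytic gradient), then polish with Newton steps
# on a finite-difference Hessian until max |gradient| < gtol.
optimize_mle <- function(theta0, nll, ngr, gtol = 1e-6, maxit = 500L) {
  opt <- stats::optim(theta0, nll, ngr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  theta <- opt$par
  for (i in 1:25) {
    g <- ngr(theta)
    if (max(abs(g)) < gtol) break
    H <- stats::optimHess(theta, nll, ngr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # backtracking to ensure decrease
    f0 <- nll(theta); lam <- 1
    repeat {
      cand <- theta - lam * step
      if (is.finite(nll(cand)) && nll(cand) <= f0 + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- theta; break }
    }
    if (identical(cand, theta)) break
    theta <- cand
  }
  g <- ngr(theta)
  H <- stats::optimHess(theta, nll, ngr)
  list(theta = theta, value = nll(theta), grad = g,
       grad_norm = max(abs(g)), hessian = (H + t(H)) / 2)
}

new_pref_fit <- function(family, coefficients, vcov, logLik, n, theta,
                         vcov_theta, loglik_rows, report_jac, grad_norm,
                         sigma = NULL, thresholds = NULL, X = NULL,
                         extra = list()) {
  structure(c(list(family = family, coefficients = coefficients,
                   vcov = vcov, logLik = logLik, n = n, theta = theta,
                   vcov_theta = vcov_theta, loglik_rows = loglik_rows,
                   report_jac = report_jac, grad_norm = grad_norm,
                   converged = grad_norm < 1e-5, sigma = sigma,
                   thresholds = thresholds, X = X), extra),
            class = "pref_fit")
}

#' @export
print.pref_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, logLik = %.3f%s\n", x$family, x$n, x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  if (!is.null(x$sigma)) cat("sigma:", paste(round(x$sigma, 4), collapse = " "), "\n")
  if (!is.null(x$thresholds))
    cat("thresholds:", paste(round(x$thresholds, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.pref_fit <- function(object, ...) object$coefficients

#' @export
vcov.pref_fit <- function(object, ...) object$vcov

#' @export
logLik.pref_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$theta), class = "logLik")
}

#' Interval-censored Gaussian regression
#'
#' Maximum likelihood for the latent model Y* = X beta + eps,
#' eps ~ N(0, sigma^2), where each observation is seen only as an interval
#' `[lower, upper]`. Point observations (lower = upper) contribute the
#' normal density; half-infinite intervals contribute one-sided censoring
#' probabilities; finite intervals contribute normal-CDF differences.
#' sigma is optimized on the log scale and may differ across the levels of
#' `sigma_group` (used to let the error variance vary across childhood
#' environment groups).
#'
#' @param lower,upper Numeric interval bounds per row (`-Inf`/`Inf`
#'   allowed); `lower <= upper`, at least one finite bound per row.
#' @param X Design matrix including any intercept.
#' @param sigma_group Optional factor/vector: one sigma per level.
#' @param start Optional start for beta (default: OLS on interval
#'   midpoints, finite bounds used for half-infinite rows).
#' @param gtol Gradient-norm convergence tolerance.
#' @return A `"pref_fit"` object; `coefficients` are the betas, `sigma` the
#'   estimated scale(s), `vcov` covers betas then sigma(s) on the original
#'   scale (delta method).
#' @export
fit_interval <- function(lower, upper, X, sigma_group = NULL, start = NULL,
                         gtol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(lower) == n, length(upper) == n)
  if (any(lower > upper)) stop("fit_interval: lower > upper")
  if (any(!is.finite(lower) & !is.finite(upper)))
    stop("fit_interval: rows with both bounds infinite carry no information")
  if (all(!is.finite(upper)) || all(!is.finite(lower)))
    stop("fit_interval: all rows censored on the same side; model degenerate")
  if (is.null(sigma_group)) sigma_group <- rep(1L, n)
  sg <- as.integer(factor(sigma_group))
  ng <- max(sg)
  glabs <- levels(factor(sigma_group))

  mid <- ifelse(is.finite(lower) & is.finite(upper), (lower + upper) / 2,
                ifelse(is.finite(lower), lower, upper))
  if (is.null(start)) start <- stats::lm.fit(X, mid)$coefficients
  start[!is.finite(start)] <- 0
  r0 <- mid - drop(X %*% start)
  ls0 <- log(max(stats::sd(r0), 1e-3))
  theta0 <- c(start, rep(ls0, ng))

  is_pt <- is.finite(lower) & is.finite(upper) & lower == upper
  is_lc <- !is.finite(lower) & is.finite(upper)     # left-censored
  is_rc <- is.finite(lower) & !is.finite(upper)     # right-censored
  is_iv <- is.finite(lower) & is.finite(upper) & lower < upper

  rows_ll <- function(theta) {
    beta <- theta[seq_len(p)]
    sig <- exp(theta[p + sg])
    mu <- drop(X %*% beta)
    ll <- numeric(n)
    if (any(is_pt)) ll[is_pt] <- stats::dnorm(lower[is_pt], mu[is_pt],
                                              sig[is_pt], log = TRUE)
    if (any(is_lc)) ll[is_lc] <- stats::pnorm((upper[is_lc] - mu[is_lc]) /
                                                sig[is_lc], log.p = TRUE)
    if (any(is_rc)) ll[is_rc] <- stats::pnorm((lower[is_rc] - mu[is_rc]) /
                                                sig[is_rc],
                                              lower.tail = FALSE, log.p = TRUE)
    if (any(is_iv)) ll[is_iv] <- log_pnorm_diff((lower[is_iv] - mu[is_iv]) /
                                                  sig[is_iv],
                                                (upper[is_iv] - mu[is_iv]) /
                                                  sig[is_iv])
    ll
  }
  nll <- function(theta) -sum(rows_ll(theta))
  ngr <- function(theta) {
    beta <- theta[seq_len(p)]
    sig <- exp(theta[p + sg])
    mu <- drop(X %*% beta)
    dmu <- numeric(n)      # d ll_i / d mu_i
    dls <- numeric(n)      # d ll_i / d log sigma_{g(i)}
    if (any(is_pt)) {
      z <- (lower[is_pt] - mu[is_pt]) / sig[is_pt]
      dmu[is_pt] <- z / sig[is_pt]
      dls[is_pt] <- z^2 - 1
    }
    idx <- is_lc | is_rc | is_iv
    if (any(idx)) {
      zl <- (lower[idx] - mu[idx]) / sig[idx]   # -Inf allowed
      zu <- (upper[idx] - mu[idx]) / sig[idx]   # +Inf allowed
      logP <- numeric(sum(idx))
      fin_l <- is.finite(zl); fin_u <- is.finite(zu)
      logP[fin_l & fin_u] <- log_pnorm_diff(zl[fin_l & fin_u], zu[fin_l & fin_u])
      logP[!fin_l] <- stats::pnorm(zu[!fin_l], log.p = TRUE)
      logP[!fin_u] <- stats::pnorm(zl[!fin_u], lower.tail = FALSE, log.p = TRUE)
      wl <- ifelse(fin_l, exp(stats::dnorm(zl, log = TRUE) - logP), 0)
      wu <- ifelse(fin_u, exp(stats::dnorm(zu, log = TRUE) - logP), 0)
      dmu[idx] <- (wl - wu) / sig[idx]
      zwl <- ifelse(fin_l, zl, 0) * wl
      zwu <- ifelse(fin_u, zu, 0) * wu
      dls[idx] <- zwl - zwu
    }
    gbeta <- -drop(crossprod(X, dmu))
    gls <- -as.numeric(rowsum(dls, sg, reorder = TRUE))
    c(gbeta, gls)
  }

  res <- optimize_mle(theta0, nll, ngr, gtol = gtol)
  if (res$grad_norm > 1e-4)
    stop(sprintf("fit_interval: did not converge (max |gradient| = %.3g)",
                 res$grad_norm))
  vtheta <- solve(res$hessian)
  vtheta <- (vtheta + t(vtheta)) / 2
  beta <- res$theta[seq_len(p)]
  names(beta) <- colnames(X) %||% paste0("x", seq_len(p))
  sig <- exp(res$theta[p + seq_len(ng)])
  names(sig) <- if (ng > 1) paste0("sigma.", glabs) else "sigma"
  # report scale: (beta, sigma); d sigma / d log sigma = sigma
  jac <- diag(p + ng)
  diag(jac)[p + seq_len(ng)] <- sig
  vrep <- jac %*% vtheta %*% t(jac)
  dimnames(vrep) <- list(c(names(beta), names(sig)),
                         c(names(beta), names(sig)))
  new_pref_fit("interval", beta, vrep, -res$value, n, res$theta, vtheta,
               rows_ll, function(theta) {
                 j <- diag(p + ng)
                 diag(j)[p + seq_len(ng)] <- exp(theta[p + seq_len(ng)])
                 j
               }, res$grad_norm, sigma = sig, X = X,
               extra = list(sigma_group = sg, lower = lower, upper = upper))
}

#' Binary logistic regression by Newton-Raphson
#'
#' MLE for P(y = 1 | x) = logistic(x' beta), with observed-information
#' covariance and explicit perfect-separation detection.
#'
#' @param y 0/1 outcome vector.
#' @param X Design matrix including any intercept.
#' @param gtol Gradient-norm convergence tolerance.
#' @return A `"pref_fit"` object.
#' @export
fit_logit <- function(y, X, gtol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (!all(y %in% c(0, 1))) stop("fit_logit: y must be 0/1")
  if (length(unique(y)) < 2L) stop("fit_logit: outcome is constant")
  beta <- rep(0, p)
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    g <- drop(crossprod(X, y - pr))
    if (max(abs(g)) < gtol && it > 1) break
    w <- pmax(pr * (1 - pr), 1e-12)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g), error = function(e)
      stop("fit_logit: singular information matrix"))
    # step halving on the log-likelihood
    ll0 <- sum(stats::dbinom(y, 1, stats::plogis(eta), log = TRUE))
    lam <- 1
    repeat {
      cand <- beta + lam * step
      llc <- sum(stats::dbinom(y, 1, stats::plogis(drop(X %*% cand)),
                               log = TRUE))
      if (is.finite(llc) && llc >= ll0 - 1e-10) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; break }
    }
    beta <- cand
  }
  eta <- drop(X %*% beta)
  pr <- stats::plogis(eta)
  # perfect separation: fitted probabilities collapse onto the outcome
  extreme <- abs(eta) > 15
  if (any(extreme) && all((pr > 0.5) == (y == 1)) && mean(extreme) > 0.95)
    stop("fit_logit: perfect separation detected (fitted probabilities 0/1)")
  g <- drop(crossprod(X, y - pr))
  if (max(abs(g)) > 1e-4)
    stop(sprintf("fit_logit: did not converge (max |gradient| = %.3g); %s",
                 max(abs(g)), "possible quasi-separation"))
  w <- pr * (1 - pr)
  H <- crossprod(X * w, X)
  v <- solve(H)
  nm <- colnames(X) %||% paste0("x", seq_len(p))
  names(beta) <- nm; dimnames(v) <- list(nm, nm)
  rows_ll <- function(theta)
    stats::dbinom(y, 1, stats::plogis(drop(X %*% theta)), log = TRUE)
  new_pref_fit("logit", beta, v,
               sum(stats::dbinom(y, 1, pr, log = TRUE)), n, beta, v,
               rows_ll, function(theta) diag(p), max(abs(g)), X = X,
               extra = list(y = y, fitted = pr))
}

#' Ordered logistic (proportional odds) regression
#'
#' MLE of the cumulative model P(y <= j | x) = logistic(theta_j - x' beta)
#' with strictly increasing thresholds, enforced by an unconstrained
#' log-difference reparameterization; the reported covariance for
#' (beta, thresholds) is recovered by the delta method.
#'
#' @param y Ordinal outcome: integer codes or an ordered factor. Every
#'   level between the observed min and max must be non-empty unless
#'   `collapse = TRUE`, in which case empty levels are dropped.
#' @param X Design matrix WITHOUT an intercept (absorbed by thresholds).
#' @param collapse Drop empty categories instead of erroring.
#' @param gtol Gradient-norm convergence tolerance.
#' @return A `"pref_fit"` object; `coefficients` are the slopes,
#'   `thresholds` the cutpoints.
#' @export
fit_ologit <- function(y, X, collapse = FALSE, gtol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("fit_ologit: X must not contain a constant column ",
         "(the intercept is absorbed by the thresholds)")
  yf <- factor(y, ordered = TRUE)
  if (any(table(yf) == 0)) {
    if (collapse) yf <- droplevels(yf)
    else stop("fit_ologit: empty outcome category; set collapse = TRUE to drop")
  }
  J <- nlevels(yf)
  if (J < 2L) stop("fit_ologit: need at least two observed levels")
  yi <- as.integer(yf)

  # theta = (beta_1..p, zeta_1, log-diffs_2..J-1); thresholds = cumsum
  to_cuts <- function(theta) {
    z <- theta[p + 1L]
    if (J > 2L) cumsum(c(z, exp(theta[(p + 2L):(p + J - 1L)]))) else z
  }
  cum_p <- stats::qlogis(cumsum(prop.table(table(yi)))[-J])
  theta0 <- c(rep(0, p), cum_p[1L],
              if (J > 2L) log(pmax(diff(cum_p), 1e-3)))

  rows_ll <- function(theta) {
    beta <- theta[seq_len(p)]
    cuts <- c(-Inf, to_cuts(theta), Inf)
    eta <- drop(X %*% beta)
    pu <- stats::plogis(cuts[yi + 1L] - eta)
    pl <- stats::plogis(cuts[yi] - eta)
    log(pmax(pu - pl, 1e-300))
  }
  nll <- function(theta) -sum(rows_ll(theta))
  ngr <- function(theta) {
    beta <- theta[seq_len(p)]
    cuts <- c(-Inf, to_cuts(theta), Inf)
    eta <- drop(X %*% beta)
    au <- cuts[yi + 1L] - eta
    al <- cuts[yi] - eta
    P <- pmax(stats::plogis(au) - stats::plogis(al), 1e-300)
    fu <- ifelse(is.finite(au), stats::dlogis(au), 0)
    fl <- ifelse(is.finite(al), stats::dlogis(al), 0)
    dbeta <- drop(crossprod(X, (fl - fu) / P))       # gradient of ll
    # d ll / d cut_j: + fu/P for rows with y = j, - fl/P for rows with y = j+1
    wu <- fu / P; wl <- fl / P
    dcut <- vapply(seq_len(J - 1L), function(j)
      sum(wu[yi == j]) - sum(wl[yi == j + 1L]), numeric(1))
    # chain rule to (zeta, log-diffs): dcut/dzeta = 1 for all cuts;
    # dcut_m/ddelta_j = exp(delta_j) for m >= j+1
    gz <- sum(dcut)
    gd <- if (J > 2L) {
      ed <- exp(theta[(p + 2L):(p + J - 1L)])
      vapply(seq_len(J - 2L), function(j) ed[j] * sum(dcut[(j + 1L):(J - 1L)]),
             numeric(1))
    } else NULL
    -c(dbeta, gz, gd)
  }

  res <- optimize_mle(theta0, nll, ngr, gtol = gtol)
  if (res$grad_norm > 1e-4)
    stop(sprintf("fit_ologit: did not converge (max |gradient| = %.3g)",
                 res$grad_norm))
  vtheta <- solve(res$hessian)
  vtheta <- (vtheta + t(vtheta)) / 2
  beta <- res$theta[seq_len(p)]
  nm <- colnames(X) %||% paste0("x", seq_len(p))
  names(beta) <- nm
  cuts <- to_cuts(res$theta)
  names(cuts) <- paste0(levels(yf)[-J], "|", levels(yf)[-1L])
  report_jac <- function(theta) {
    jac <- diag(p + J - 1L)
    if (J > 2L) {
      ed <- exp(theta[(p + 2L):(p + J - 1L)])
      for (m in 2L:(J - 1L)) for (j in seq_len(m - 1L))
        jac[p + m, p + 1L + j] <- ed[j]
      for (m in 1L:(J - 1L)) jac[p + m, p + 1L] <- 1
    }
    jac
  }
  jac <- report_jac(res$theta)
  vrep <- jac %*% vtheta %*% t(jac)
  dimnames(vrep) <- list(c(nm, names(cuts)), c(nm, names(cuts)))
  new_pref_fit("ologit", beta, vrep, -res$value, n, res$theta, vtheta,
               rows_ll, report_jac, res$grad_norm, thresholds = cuts, X = X,
               extra = list(y = yi, levels = levels(yf)))
}

#' Likelihood-ratio diagnostic for the proportional-odds assumption
#'
#' Approximate test comparing a common-slope model against category-specific
#' slopes, both fitted on the stacked J-1 cumulative binary splits of the
#' ordinal outcome (split-specific intercepts in both models). The stacked
#' rows reuse each observation, so the chi-square reference is approximate;
#' the returned object records this caveat.
#'
#' @param y Ordinal outcome.
#' @param X Design matrix without intercept.
#' @param min_cell Minimum count in the rarer class of each split; sparser
#'   splits skip the test with a warning.
#' @return List: `stat`, `df` = (J-2)*ncol(X), `p`, `note`.
#' @export
prop_odds_test <- function(y, X, min_cell = 10L) {
  X <- as.matrix(X)
  yf <- droplevels(factor(y, ordered = TRUE))
  J <- nlevels(yf)
  p <- ncol(X)
  if (J == 2L)
    return(list(stat = NA_real_, df = 0L, p = NA_real_,
                note = "two categories: proportional odds is vacuous"))
  yi <- as.integer(yf)
  splits <- seq_len(J - 1L)
  yb <- lapply(splits, function(j) as.integer(yi > j))
  cnt <- vapply(yb, function(v) min(sum(v), sum(1 - v)), numeric(1))
  if (any(cnt < min_cell)) {
    warning("prop_odds_test: sparse cumulative split; test skipped")
    return(list(stat = NA_real_, df = (J - 2L) * p, p = NA_real_,
                note = "skipped: sparse split"))
  }
  ystack <- unlist(yb)
  nrep <- length(yi)
  split_f <- factor(rep(splits, each = nrep))
  D <- stats::model.matrix(~ split_f - 1)            # split intercepts
  Xs <- X[rep(seq_len(nrep), J - 1L), , drop = FALSE]
  Xr <- cbind(D, Xs)                                 # common slopes
  Xu <- cbind(D, stats::model.matrix(~ split_f:Xs - 1))  # per-split slopes
  fr <- fit_logit(ystack, Xr)
  fu <- fit_logit(ystack, Xu)
  stat <- 2 * (fu$logLik - fr$logLik)
  df <- (J - 2L) * p
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE),
       note = paste("approximate LR on stacked cumulative splits;",
                    "rows are reused across splits"))
}

#' Cluster-robust sandwich covariance
#'
#' Sandwich estimator with cluster-summed scores and the small-sample
#' factor G/(G-1): V = A^{-1} (sum_g s_g s_g') A^{-1} * G/(G-1), where A is
#' the observed information of the fitted likelihood and s_g the summed
#' per-observation score of cluster g. Scores are obtained by central
#' finite differences of the per-row log-likelihood at the MLE. With every
#' observation its own cluster this reduces to the heteroskedasticity-
#' robust sandwich up to the finite-G factor.
#'
#' @param fit A `"pref_fit"`.
#' @param clusters Cluster identifier per observation.
#' @return Covariance matrix on the reported-parameter scale, with
#'   attribute `"n_clusters"`. Pass to downstream contrasts in place of the
#'   model covariance.
#' @export
cluster_vcov <- function(fit, clusters) {
  stopifnot(inherits(fit, "pref_fit"))
  cl <- factor(clusters)
  if (length(cl) != fit$n)
    stop("cluster_vcov: need one cluster id per observation")
  G <- nlevels(cl)
  if (G < 2L) stop("cluster_vcov: at least two clusters required")
  theta <- fit$theta
  q <- length(theta)
  S <- matrix(0, fit$n, q)
  for (j in seq_len(q)) {
    h <- 1e-6 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    S[, j] <- (fit$loglik_rows(tp) - fit$loglik_rows(tm)) / (2 * h)
  }
  Sg <- rowsum(S, cl)
  B <- crossprod(Sg) * G / (G - 1)
  Vt <- fit$vcov_theta %*% B %*% fit$vcov_theta
  J <- fit$report_jac(theta)
  V <- J %*% Vt %*% t(J)
  dimnames(V) <- dimnames(fit$vcov)
  attr(V, "n_clusters") <- G
  V
}
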