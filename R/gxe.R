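# Gene-by-environment inference layer: a fully interacted design in which
# every parameter (including, for the interval model, the error SD) may
# differ across childhood-environment groups, with implied group effects
# and prediction profiles derived from a single fit.

#' Build a fully interacted gene-by-environment design matrix
#'
#' Columns are ordered deterministically: intercept, moderator, predictor,
#' predictor x moderator, then each covariate followed by all covariate x
#' moderator products. With this coding the coefficient on the predictor is
#' its association in the moderator-0 ("no disadvantage") group and the
#' interaction is the group difference; the sum is the implied association
#' in the moderator-1 group.
#'
#' @param data Data frame with no missing values in the used columns.
#' @param predictor Name of the predictor of interest (standardized PGS).
#' @param moderator Name of the binary moderator (disadvantage indicator).
#' @param covariates Character vector of covariate column names.
#' @param full_interaction Interact every covariate with the moderator
#'   (default TRUE, the "all parameters differ" specification).
#' @param intercept Include the intercept/moderator main-effect columns
#'   (FALSE for ordinal fits, where thresholds absorb the intercept but the
#'   moderator main effect is retained).
#' @return Numeric design matrix with informative column names.
#' @export
build_gxe_design <- function(data, predictor, moderator, covariates = character(),
                             full_interaction = TRUE, intercept = TRUE) {
  cols <- c(predictor, moderator, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("build_gxe_design: missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(data[cols]))
    stop("build_gxe_design: missing values present; resolve the policy first")
  g <- as.numeric(data[[moderator]])
  if (!all(g %in% c(0, 1))) stop("build_gxe_design: moderator must be binary 0/1")
  if (stats::var(g) == 0)
    stop("build_gxe_design: constant moderator; interaction not identifiable")
  x <- as.numeric(data[[predictor]])
  X <- cbind(x, x * g)
  nm <- c(predictor, paste0(predictor, ":", moderator))
  if (intercept) {
    X <- cbind(1, g, X)
    nm <- c("(Intercept)", moderator, nm)
  } else {
    X <- cbind(g, X)
    nm <- c(moderator, nm)
  }
  for (cv in covariates) {
    v <- as.numeric(data[[cv]])
    X <- cbind(X, v)
    nm <- c(nm, cv)
    if (full_interaction) {
      X <- cbind(X, v * g)
      nm <- c(nm, paste0(cv, ":", moderator))
    }
  }
  colnames(X) <- nm
  X
}

#' Fit a gene-by-environment preference model
#'
#' The central fitting function: regresses a preference outcome on a
#' standardized polygenic score, a binary childhood-disadvantage moderator,
#' their interaction, and fully moderator-interacted covariates, using the
#' likelihood appropriate to the outcome: interval-censored Gaussian for
#' interval-valued preferences (CRRA coefficient, weekly discount rate),
#' logistic for binary codings, proportional-odds logistic for ordinal
#' scales. For the interval family the error SD is, by default, allowed to
#' differ across moderator groups, making the single interacted fit exactly
#' equivalent to two separate group fits.
#'
#' @param outcome For `family = "interval"`, a length-2 character vector of
#'   lower/upper bound columns; otherwise a single column name.
#' @param data Data frame.
#' @param family One of `"interval"`, `"logit"`, `"ologit"`.
#' @param predictor,moderator,covariates Column names; see
#'   [build_gxe_design()].
#' @param cluster Optional cluster-id column name: the reported covariance
#'   becomes the cluster-robust sandwich.
#' @param group_sigma Interval family only: group-specific error SD
#'   (default TRUE).
#' @param full_interaction Interact covariates with the moderator.
#' @return Object of class `"gxe_fit"` with `print`, `summary`, `coef`,
#'   `vcov`, `confint`, `logLik`, `predict` and `plot` methods.
#' @examples
#' sim <- generate(sim_config(n = 300, n_snps = 50), seed = 7)
#' f <- gxe_fit(c("beg_lower", "beg_upper"), sim$data, family = "interval",
#'              covariates = c("age_c", "age_c2", "female"))
#' summary(f)
#' implied_effect(f)
#' @export
gxe_fit <- function(outcome, data, family = c("interval", "logit", "ologit"),
                    predictor = "pgs", moderator = "disadv",
                    covariates = c("age_c", "age_c2", "female"),
                    cluster = NULL, group_sigma = TRUE,
                    full_interaction = TRUE) {
  family <- match.arg(family)
  used <- c(outcome, predictor, moderator, covariates, cluster)
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("gxe_fit: missing columns: ",
                         paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[used])
  data <- data[keep, , drop = FALSE]
  X <- build_gxe_design(data, predictor, moderator, covariates,
                        full_interaction = full_interaction,
                        intercept = family != "ologit")
  fit <- switch(family,
    interval = fit_interval(data[[outcome[1]]], data[[outcome[2]]], X,
                            sigma_group = if (group_sigma)
                              data[[moderator]] else NULL),
    logit = fit_logit(data[[outcome]], X),
    ologit = fit_ologit(data[[outcome]], X))
  robust <- NULL
  if (!is.null(cluster)) robust <- cluster_vcov(fit, data[[cluster]])
  structure(list(fit = fit, family = family, outcome = outcome,
                 predictor = predictor, moderator = moderator,
                 covariates = covariates, robust_vcov = robust,
                 cluster = cluster, n = fit$n,
                 data_means = vapply(covariates, function(cv)
                   mean(as.numeric(data[[cv]])), numeric(1)),
                 pgs_sd = stats::sd(data[[predictor]]),
                 pgs_mean = mean(data[[predictor]])),
            class = "gxe_fit")
}

# covariance actually used for inference (cluster-robust when available)
active_vcov <- function(object) object$robust_vcov %||% object$fit$vcov

#' @export
coef.gxe_fit <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.gxe_fit <- function(object, ...) active_vcov(object)

#' @export
logLik.gxe_fit <- function(object, ...) logLik(object$fit)

#' @export
confint.gxe_fit <- function(object, parm, level = 0.95, ...) {
  ct <- summary(object)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(ct[, "estimate"] - z * ct[, "se"],
              ct[, "estimate"] + z * ct[, "se"])
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.gxe_fit <- function(object, ...) {
  b <- coef(object)
  V <- active_vcov(object)
  se <- sqrt(diag(V))[names(b)]
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(estimate = b, se = se, z = z, p = p,
               ci_lo = b - 1.96 * se, ci_hi = b + 1.96 * se)
  if (object$family %in% c("logit", "ologit"))
    tab <- cbind(tab, or = exp(b))
  out <- list(coefficients = tab, family = object$family, n = object$n,
              logLik = object$fit$logLik,
              robust = !is.null(object$robust_vcov),
              sigma = object$fit$sigma, thresholds = object$fit$thresholds,
              implied = implied_effect(object))
  class(out) <- "summary.gxe_fit"
  out
}

#' @export
print.summary.gxe_fit <- function(x, ...) {
  cat(sprintf("Gene-by-environment %s model (n = %d, logLik = %.2f%s)\n",
              x$family, x$n, x$logLik,
              if (x$robust) ", cluster-robust SEs" else ""))
  stats::printCoefmat(x$coefficients[, c("estimate", "se", "z", "p")],
                      P.values = TRUE, has.Pvalue = TRUE, digits = 4)
  if (!is.null(x$sigma))
    cat("sigma:", paste(sprintf("%.4f", x$sigma), collapse = " "), "\n")
  if (!is.null(x$thresholds))
    cat("thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " "), "\n")
  cat(sprintf("Implied predictor effect, moderator = 1: %.4f (SE %.4f, p = %.3g)\n",
              x$implied$estimate, x$implied$se, x$implied$p))
  invisible(x)
}

#' @export
print.gxe_fit <- function(x, ...) { print(summary(x)); invisible(x) }

#' Implied predictor effect in the moderated group
#'
#' The association of the predictor in the moderator-1 group implied by a
#' fully interacted fit: estimate = beta_main + beta_interaction, with
#' variance V_mm + V_ii + 2 V_mi from the (cluster-robust, if present)
#' covariance; Wald z, two-sided normal p, 95% CI, and the odds-ratio
#' transform for logit-family models.
#'
#' @param fit A `gxe_fit`, or any `pref_fit` if both term names are given.
#' @param main_term,interaction_term Coefficient names; default the fit's
#'   predictor and predictor:moderator terms.
#' @param vcov Optional covariance overriding the fit's.
#' @return List of class `"gxe_contrast"`: `estimate`, `se`, `z`, `p`,
#'   `ci`, and `or`/`or_ci` for logit families.
#' @export
implied_effect <- function(fit, main_term = NULL, interaction_term = NULL,
                           vcov = NULL) {
  if (inherits(fit, "gxe_fit")) {
    main_term <- main_term %||% fit$predictor
    interaction_term <- interaction_term %||%
      paste0(fit$predictor, ":", fit$moderator)
    V <- vcov %||% active_vcov(fit)
    b <- coef(fit)
    family <- fit$family
  } else {
    stopifnot(inherits(fit, "pref_fit"))
    if (is.null(main_term) || is.null(interaction_term))
      stop("implied_effect: give main_term and interaction_term for a raw fit")
    V <- vcov %||% fit$vcov
    b <- coef(fit)
    family <- fit$family
  }
  for (trm in c(main_term, interaction_term))
    if (!trm %in% names(b)) stop("implied_effect: no term named '", trm, "'")
  est <- unname(b[main_term] + b[interaction_term])
  v <- V[main_term, main_term] + V[interaction_term, interaction_term] +
    2 * V[main_term, interaction_term]
  se <- sqrt(v)
  z <- est / se
  out <- list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
              ci = est + c(-1.96, 1.96) * se)
  if (family %in% c("logit", "ologit")) {
    out$or <- exp(est)
    out$or_ci <- exp(out$ci)
  }
  class(out) <- "gxe_contrast"
  out
}

#' @export
print.gxe_contrast <- function(x, ...) {
  cat(sprintf("implied effect: %.4f (SE %.4f), z = %.2f, p = %.3g, 95%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, x$z, x$p, x$ci[1], x$ci[2]))
  if (!is.null(x$or))
    cat(sprintf("  OR = %.3f, 95%% CI [%.3f, %.3f]\n", x$or, x$or_ci[1], x$or_ci[2]))
  invisible(x)
}

#' Prediction profile over the polygenic-score range
#'
#' Model-scale predictions with delta-method 95% CIs over a grid of
#' standardized PGS values (default +/- 2 SD around the estimation-sample
#' mean) for each moderator group, covariates held at estimation-sample
#' means. Interval family: latent mean. Logit: event probability. Ologit:
#' probability of the category given by `category` (default the highest).
#'
#' @param object A `gxe_fit`.
#' @param pgs_grid Numeric grid; default 41 points spanning +/- 2 SD.
#' @param category Ologit only: which outcome category's probability.
#' @param ... Unused.
#' @return Data frame: `pgs`, `group`, `fit`, `se`, `lower`, `upper`.
#' @export
predict.gxe_fit <- function(object, pgs_grid = NULL, category = NULL, ...) {
  if (is.null(pgs_grid))
    pgs_grid <- seq(object$pgs_mean - 2 * object$pgs_sd,
                    object$pgs_mean + 2 * object$pgs_sd, length.out = 41L)
  grid <- expand.grid(pgs = pgs_grid, group = c(0, 1))
  newdata <- data.frame(grid["pgs"], grid["group"])
  names(newdata) <- c(object$predictor, object$moderator)
  for (cv in object$covariates) newdata[[cv]] <- object$data_means[[cv]]
  # rebuild the design rows exactly as in fitting (moderator varies here)
  Xg <- build_gxe_design_rows(newdata, object)
  b <- coef(object)
  V <- active_vcov(object)[names(b), names(b)]
  eta <- drop(Xg %*% b)
  se_eta <- sqrt(rowSums((Xg %*% V) * Xg))
  if (object$family == "interval") {
    fitv <- eta; se <- se_eta
  } else if (object$family == "logit") {
    fitv <- stats::plogis(eta)
    se <- stats::dlogis(eta) * se_eta           # delta method
  } else {
    cuts <- object$fit$thresholds
    J <- length(cuts) + 1L
    k <- category %||% J
    if (k < 1L || k > J) stop("predict.gxe_fit: category out of range")
    # P(y = k) = F(cut_k - eta) - F(cut_{k-1} - eta); delta method in
    # (eta, cuts) using the active covariance of (beta, cuts)
    Vfull <- active_vcov(object)
    up <- if (k == J) Inf else cuts[k]
    lo <- if (k == 1L) -Inf else cuts[k - 1L]
    fitv <- stats::plogis(up - eta) - stats::plogis(lo - eta)
    fu <- if (is.finite(up)) stats::dlogis(up - eta) else rep(0, length(eta))
    fl <- if (is.finite(lo)) stats::dlogis(lo - eta) else rep(0, length(eta))
    se <- numeric(nrow(Xg))
    cut_names <- names(cuts)
    for (i in seq_len(nrow(Xg))) {
      gvec <- c(-(fu[i] - fl[i]) * Xg[i, ],
                stats::setNames(numeric(length(cuts)), cut_names))
      if (is.finite(up)) gvec[cut_names[k]] <- fu[i]
      if (is.finite(lo)) gvec[cut_names[k - 1L]] <- gvec[cut_names[k - 1L]] - fl[i]
      se[i] <- sqrt(drop(t(gvec) %*% Vfull[names(gvec), names(gvec)] %*% gvec))
    }
  }
  data.frame(pgs = grid$pgs, group = grid$group, fit = fitv, se = se,
             lower = fitv - 1.96 * se, upper = fitv + 1.96 * se)
}

# design rows for new data, mirroring the fitted column layout
build_gxe_design_rows <- function(newdata, object) {
  g <- as.numeric(newdata[[object$moderator]])
  x <- as.numeric(newdata[[object$predictor]])
  X <- cbind(x, x * g)
  nm <- c(object$predictor, paste0(object$predictor, ":", object$moderator))
  if (object$family != "ologit") {
    X <- cbind(1, g, X)
    nm <- c("(Intercept)", object$moderator, nm)
  } else {
    X <- cbind(g, X)
    nm <- c(object$moderator, nm)
  }
  for (cv in object$covariates) {
    v <- as.numeric(newdata[[cv]])
    X <- cbind(X, v, v * g)
    nm <- c(nm, cv, paste0(cv, ":", object$moderator))
  }
  colnames(X) <- nm
  X[, names(coef(object)), drop = FALSE]
}

#' Plot prediction profiles by group
#'
#' Base-graphics plot of [predict.gxe_fit()] output: predicted outcome
#' against standardized PGS for both moderator groups with shaded 95% CI
#' bands.
#'
#' @param x A `gxe_fit`.
#' @param ylab,main Plot labels.
#' @param ... Passed to [predict.gxe_fit()].
#' @return Invisibly, the prediction data frame.
#' @export
plot.gxe_fit <- function(x, ylab = "predicted outcome",
                         main = "prediction profile by childhood environment",
                         ...) {
  pr <- predict(x, ...)
  ylim <- range(pr$lower, pr$upper)
  p0 <- pr[pr$group == 0, ]; p1 <- pr[pr$group == 1, ]
  plot(p0$pgs, p0$fit, type = "n", ylim = ylim,
       xlab = "standardized PGS", ylab = ylab, main = main)
  graphics::polygon(c(p0$pgs, rev(p0$pgs)), c(p0$lower, rev(p0$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::polygon(c(p1$pgs, rev(p1$pgs)), c(p1$lower, rev(p1$upper)),
                    col = grDevices::adjustcolor("firebrick", 0.25), border = NA)
  graphics::lines(p0$pgs, p0$fit, col = "steelblue", lwd = 2, lty = 2)
  graphics::lines(p1$pgs, p1$fit, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("no disadvantage", "disadvantage"),
                   col = c("steelblue", "firebrick"), lty = c(2, 1), lwd = 2,
                   bty = "n")
  invisible(pr)
}
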