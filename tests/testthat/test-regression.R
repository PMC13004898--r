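test_that("GxE design matrix has deterministic fully interacted layout", {
  d <- data.frame(pgs = rnorm(20), disadv = rep(c(0, 1), 10),
                  a = rnorm(20), b = rnorm(20))
  X <- build_gxe_design(d, "pgs", "disadv", c("a", "b"))
  expect_equal(colnames(X),
               c("(Intercept)", "disadv", "pgs", "pgs:disadv",
                 "a", "a:disadv", "b", "b:disadv"))
  expect_equal(ncol(X), 8L)
  # interaction columns vanish where the moderator is zero
  expect_true(all(X[d$disadv == 0, c("pgs:disadv", "a:disadv", "b:disadv")] == 0))
  d0 <- d; d0$disadv <- 0
  expect_error(build_gxe_design(d0, "pgs", "disadv", "a"), "constant moderator")
  dna <- d; dna$a[3] <- NA
  expect_error(build_gxe_design(dna, "pgs", "disadv", "a"), "missing values")
})

test_that("interval likelihood with degenerate intervals is OLS MLE", {
  fx <- make_interval_fixture(n = 300, censor = c(0, 0, 0))
  fit <- fit_interval(fx$y, fx$y, fx$X)
  ols <- lm.fit(fx$X, fx$y)
  expect_equal(unname(coef(fit)), unname(ols$coefficients), tolerance = 1e-6)
  expect_equal(unname(fit$sigma)^2, sum(ols$residuals^2) / 300,
               tolerance = 1e-6)
  expect_lt(fit$grad_norm, 1e-5)
})

test_that("per-row interval log-likelihood equals quadrature", {
  fx <- make_interval_fixture(n = 60, seed = 7)
  fit <- fit_interval(fx$lower, fx$upper, fx$X)
  theta <- fit$theta
  mu <- drop(fx$X %*% theta[1:3]); sig <- exp(theta[4])
  ll <- fit$loglik_rows(theta)
  for (i in seq_len(60)) {
    if (fx$lower[i] == fx$upper[i]) {
      expect_equal(ll[i], dnorm(fx$lower[i], mu[i], sig, log = TRUE))
    } else {
      q <- integrate(dnorm, max(fx$lower[i], mu[i] - 40 * sig),
                     min(fx$upper[i], mu[i] + 40 * sig),
                     mean = mu[i], sd = sig, rel.tol = 1e-12)$value
      expect_equal(ll[i], log(q), tolerance = 1e-6)
    }
  }
})

test_that("interval MLE recovers generating parameters from censored data", {
  fx <- make_interval_fixture(n = 2000, seed = 13)
  fit <- fit_interval(fx$lower, fx$upper, fx$X)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - fx$beta) < 3 * se[1:3]))
  expect_lt(abs(fit$sigma - fx$sigma), 3 * se[4])
  # cross-check against survival::survreg on the same data
  skip_if_not_installed("survival")
  sv <- survival::survreg(
    survival::Surv(ifelse(is.finite(fx$lower), fx$lower, NA),
                   ifelse(is.finite(fx$upper), fx$upper, NA),
                   type = "interval2") ~ fx$X[, -1], dist = "gaussian")
  expect_equal(unname(coef(fit)), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(unname(fit$sigma), unname(sv$scale), tolerance = 1e-6)
})

test_that("interval fits reject degenerate censoring layouts", {
  X <- cbind(1, rnorm(20))
  expect_error(fit_interval(rep(-Inf, 20), rnorm(20), X), "same side")
  expect_error(fit_interval(rep(-Inf, 20), rep(Inf, 20), X), "no information")
  expect_error(fit_interval(rnorm(20), rnorm(20) - 10, X), "lower > upper")
})

test_that("fully interacted fit equals two separate group fits", {
  sim <- generate(sim_config(n = 500, n_snps = 60), seed = 77)
  d <- sim$data
  fit <- gxe_fit(c("beg_lower", "beg_upper"), d, family = "interval",
                 covariates = c("age_c", "female"), group_sigma = TRUE)
  fit_by_group <- function(g) {
    sub <- d[d$disadv == g, ]
    X <- cbind(1, sub$pgs, sub$age_c, sub$female)
    fit_interval(sub$beg_lower, sub$beg_upper, X)
  }
  f0 <- fit_by_group(0); f1 <- fit_by_group(1)
  expect_equal(fit$fit$logLik, f0$logLik + f1$logLik, tolerance = 1e-6)
  b <- coef(fit)
  expect_equal(unname(b["pgs"]), unname(coef(f0)[2]), tolerance = 1e-5)
  expect_equal(unname(b["pgs"] + b["pgs:disadv"]), unname(coef(f1)[2]),
               tolerance = 1e-5)
  expect_equal(unname(fit$fit$sigma),
               unname(c(f0$sigma, f1$sigma)), tolerance = 1e-5)
})

test_that("logit MLE matches glm and flags separation", {
  set.seed(55)
  X <- cbind(1, x = rnorm(300), z = rbinom(300, 1, 0.5))
  y <- rbinom(300, 1, plogis(drop(X %*% c(-0.3, 0.9, -0.6))))
  fit <- fit_logit(y, X)
  gl <- glm.fit(X, y, family = binomial())
  expect_equal(unname(coef(fit)), unname(gl$coefficients), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(vcov(fit)))),
               unname(sqrt(diag(chol2inv(gl$qr$qr[1:3, 1:3])))),
               tolerance = 1e-5)
  # intercept-only fit returns the logit of the sample mean
  f0 <- fit_logit(y, matrix(1, 300))
  expect_equal(unname(coef(f0)), qlogis(mean(y)), tolerance = 1e-8)
  # perfect separation errors instead of returning garbage
  xs <- c(rnorm(50, -3), rnorm(50, 3))
  ys <- as.integer(xs > 0)
  expect_error(fit_logit(ys, cbind(1, xs)), "separation|converge")
})

test_that("two-category ordered logit is a binary logit", {
  set.seed(66)
  X <- cbind(x = rnorm(400), g = rbinom(400, 1, 0.4))
  y <- 1L + rbinom(400, 1, plogis(drop(X %*% c(0.7, -0.4))))
  fo <- fit_ologit(y, X)
  fl <- fit_logit(as.integer(y == 2L), cbind(1, X))
  expect_equal(unname(coef(fo)), unname(coef(fl)[-1]), tolerance = 1e-6)
  expect_equal(unname(fo$thresholds), -unname(coef(fl)[1]), tolerance = 1e-6)
  expect_equal(fo$logLik, fl$logLik, tolerance = 1e-8)
})

test_that("proportional-odds MLE matches MASS::polr and recovers slopes", {
  fx <- make_ologit_fixture(n = 800)
  fit <- fit_ologit(fx$y, fx$X)
  expect_lt(fit$grad_norm, 1e-5)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - fx$beta) < 3 * se[1:2]))
  expect_true(all(diff(fit$thresholds) > 0))
  skip_if_not_installed("MASS")
  pf <- MASS::polr(factor(fx$y) ~ fx$X, method = "logistic", Hess = TRUE)
  expect_equal(unname(coef(fit)), unname(coef(pf)), tolerance = 1e-4)
  expect_equal(unname(fit$thresholds), unname(pf$zeta), tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(pf)), tolerance = 1e-6)
  expect_error(fit_ologit(fx$y, cbind(1, fx$X)), "constant column")
})

test_that("ologit category probabilities sum to one on the profile grid", {
  sim <- generate(sim_config(n = 400, n_snps = 50), seed = 5)
  fit <- gxe_fit("la_level", sim$data, family = "ologit",
                 covariates = c("age_c", "female"))
  J <- length(fit$fit$thresholds) + 1L
  grids <- lapply(seq_len(J), function(k)
    predict(fit, pgs_grid = c(-2, 0, 2), category = k))
  tot <- Reduce(`+`, lapply(grids, `[[`, "fit"))
  expect_equal(tot, rep(1, 6), tolerance = 1e-10)
  expect_true(all(vapply(grids, function(g)
    all(g$fit >= 0 & g$fit <= 1), logical(1))))
})

test_that("proportional-odds diagnostic behaves at its edges and under violation", {
  fx <- make_ologit_fixture(n = 700, seed = 19)
  res <- prop_odds_test(fx$y, fx$X)
  expect_equal(res$df, (max(fx$y) - 2L) * 2L)
  expect_true(is.finite(res$stat))
  # two categories: vacuous
  res2 <- prop_odds_test(as.integer(fx$y > 2), fx$X)
  expect_equal(res2$df, 0L)
  expect_true(is.na(res2$stat))
  # strong slope heterogeneity across splits is detected
  set.seed(23)
  n <- 900; x <- rnorm(n)
  y <- ifelse(x > 0.7, 3L, ifelse(x + rlogis(n, scale = 4) > 0, 2L, 1L))
  if (min(table(y)) > 20) {
    r3 <- prop_odds_test(y, cbind(x = x))
    expect_lt(r3$p, 0.01)
  }
  # sparse split skips with a warning
  ys <- c(rep(1L, 300), rep(2L, 300), rep(3L, 4))
  expect_warning(r4 <- prop_odds_test(ys, cbind(x = rnorm(604))), "sparse")
  expect_true(is.na(r4$stat))
})

test_that("cluster sandwich reduces to the HC sandwich for singleton clusters", {
  set.seed(88)
  n <- 250
  X <- cbind(1, x = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.2 + 0.8 * X[, 2]))
  fit <- fit_logit(y, X)
  V <- cluster_vcov(fit, seq_len(n))
  # independent HC construction from the analytic logit scores
  pr <- plogis(drop(X %*% coef(fit)))
  S <- X * (y - pr)
  bread <- solve(crossprod(X * (pr * (1 - pr)), X))
  hc0 <- bread %*% crossprod(S) %*% bread
  expect_equal(unname(V), unname(hc0 * n / (n - 1)), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_error(cluster_vcov(fit, rep(1, n)), "two clusters")
})

test_that("duplicating rows within clusters does not shrink clustered SEs", {
  set.seed(99)
  n <- 200
  X <- cbind(1, x = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 * X[, 2]))
  f1 <- fit_logit(y, X)
  idx <- rep(seq_len(n), 2)
  f2 <- fit_logit(y[idx], X[idx, ])
  V2 <- cluster_vcov(f2, idx)
  # model-based SEs halve in variance under duplication; clustered ones do not
  expect_lt(diag(vcov(f2))[2], 0.6 * diag(vcov(f1))[2])
  expect_gt(diag(V2)[2], 0.8 * diag(vcov(f1))[2])
})

test_that("implied effect equals the recoded-baseline main effect", {
  sim <- generate(sim_config(n = 600, n_snps = 50), seed = 14)
  d <- sim$data
  fit <- gxe_fit("la_bin", d, family = "logit",
                 covariates = c("age_c", "female"))
  ie <- implied_effect(fit)
  # reparameterization oracle: flip the moderator baseline and refit
  d2 <- d; d2$disadv <- 1 - d$disadv
  fit2 <- gxe_fit("la_bin", d2, family = "logit",
                  covariates = c("age_c", "female"))
  expect_equal(ie$estimate, unname(coef(fit2)["pgs"]), tolerance = 1e-5)
  expect_equal(ie$se, unname(sqrt(diag(vcov(fit2)))["pgs"]), tolerance = 1e-5)
  # arithmetic identity and OR transform
  b <- coef(fit)
  expect_equal(ie$estimate, unname(b["pgs"] + b["pgs:disadv"]))
  expect_equal(ie$or, exp(ie$estimate))
  expect_error(implied_effect(fit, main_term = "nope"), "no term")
})

test_that("prediction profiles are linear-algebra identities for the interval model", {
  sim <- generate(sim_config(n = 500, n_snps = 50), seed = 31)
  fit <- gxe_fit(c("beg_lower", "beg_upper"), sim$data, family = "interval",
                 covariates = c("age_c", "age_c2", "female"))
  pr <- predict(fit, pgs_grid = c(-2, 0, 2))
  b <- coef(fit)
  m <- fit$data_means
  for (i in seq_len(nrow(pr))) {
    g <- pr$group[i]; x <- pr$pgs[i]
    eta <- b["(Intercept)"] + b["disadv"] * g + b["pgs"] * x +
      b["pgs:disadv"] * x * g +
      b["age_c"] * m["age_c"] + b["age_c:disadv"] * m["age_c"] * g +
      b["age_c2"] * m["age_c2"] + b["age_c2:disadv"] * m["age_c2"] * g +
      b["female"] * m["female"] + b["female:disadv"] * m["female"] * g
    expect_equal(pr$fit[i], unname(eta), tolerance = 1e-10)
  }
  # opposing generating slopes produce crossing profiles
  p0 <- pr[pr$group == 0, ]; p1 <- pr[pr$group == 1, ]
  expect_true(any(sign(p0$fit - p1$fit) != sign(p0$fit - p1$fit)[1]))
})
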