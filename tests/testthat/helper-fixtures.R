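# Shared fixtures: the printed instrument tables and small simulated
# regression designs, built in code.

# six-lottery risk task: payoffs with printed EV, SD and CRRA bounds
table1 <- data.frame(
  label = LETTERS[1:6],
  low   = c(28, 24, 20, 16, 12, 2),
  high  = c(28, 36, 44, 52, 60, 70),
  ev    = c(28, 30, 32, 34, 36, 36),
  sd    = c(0, 8.5, 17, 25.5, 33.9, 48.1),
  lower = c(3.46, 1.16, 0.71, 0.499, 0, -Inf),
  upper = c(Inf, 3.46, 1.16, 0.71, 0.499, 0))

# loss-aversion variant: payoffs with printed EV and SD
table2 <- data.frame(
  label = LETTERS[1:6],
  low   = c(10, 6, 2, -2, -4, -5),
  high  = c(10, 18, 22, 28, 35, 38),
  ev    = c(10, 12, 12, 13, 15.5, 16.5),
  sd    = c(0, 8.5, 14.1, 21.2, 27.6, 30.4))

# MPL panels: future amounts and printed per-row discount-rate bounds
table3 <- list(
  one_month = list(fv = c(26, 28, 30, 32, 35, 38), t = 2.43,
                   bounds = c(0.0163, 0.0477, 0.0779, 0.1069, 0.1485, 0.1880)),
  two_month = list(fv = c(26, 30, 35, 37, 40, 45), t = 6.71,
                   bounds = c(0.0059, 0.0275, 0.0514, 0.0602, 0.0726, 0.0915)))

# interval-censored regression fixture with known parameters; censoring
# must be non-informative, so detection limits are drawn independently of
# y and unit-bin intervals are a fixed partition of the line
make_interval_fixture <- function(n = 400, beta = c(1, -0.5, 0.8),
                                  sigma = 1.2, seed = 42,
                                  censor = c(0.15, 0.15, 0.4)) {
  set.seed(seed)
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- drop(X %*% beta) + rnorm(n, 0, sigma)
  lower <- y; upper <- y
  if (sum(censor) > 0) {
    llim <- rnorm(n, stats::quantile(y, 0.25), 0.5)  # independent limits
    rlim <- rnorm(n, stats::quantile(y, 0.75), 0.5)
    u <- runif(n)
    lc <- u < censor[1] & y < llim
    rc <- u >= censor[1] & u < censor[1] + censor[2] & y > rlim
    iv <- u >= censor[1] + censor[2] & u < sum(censor) & !lc & !rc
    lower[lc] <- -Inf; upper[lc] <- llim[lc]
    upper[rc] <- Inf;  lower[rc] <- rlim[rc]
    lower[iv] <- floor(y[iv]); upper[iv] <- ceiling(y[iv])
  }
  list(X = X, lower = lower, upper = upper, y = y,
       beta = beta, sigma = sigma)
}

# proportional-odds fixture with known slopes
make_ologit_fixture <- function(n = 500, beta = c(0.8, -0.5),
                                cuts = c(-1.5, -0.5, 0.5, 1.5), seed = 9) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  star <- drop(X %*% beta) + rlogis(n)
  y <- findInterval(star, cuts) + 1L
  list(X = X, y = y, beta = beta, cuts = cuts)
}
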