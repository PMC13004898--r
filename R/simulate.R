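# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes -- a standard-normal polygenic score built from binomial
# allele counts, four weakly PGS-correlated binary disadvantage dimensions
# with missingness, age/sex covariates, and latent risk-aversion /
# discount-rate / planning-horizon outcomes from a group-varying linear
# model -- and renders the latents into instrument responses, keeping the
# ground truth alongside for recovery tests.

#' Simulation configuration
#'
#' Defaults state the emulated world: cohort size 624 (the incentivized
#' experimental sample; the survey preset uses 5881 persons with ~1.96
#' waves each), disadvantage-dimension prevalences 0.498/0.276/0.237/0.152,
#' a PGS-to-disadvantage log-odds slope of -0.10 (calibrated once so the
#' PGS x binary-index correlation is about -0.07), per-dimension
#' missingness 0.09 (about 29% of subjects missing one dimension), ages
#' 50-75 centred near 64, 53.7% female, and group-varying outcome
#' coefficients whose signs and magnitudes mirror the estimated
#' gene-by-environment pattern (negative PGS slope on risk aversion and
#' discounting without disadvantage; sign reversal on risk aversion and
#' attenuation on patience under disadvantage). MPL inconsistency rates
#' default to 0.096 and 0.075 of subjects (one random row flip).
#'
#' @param n Cohort size (experimental preset).
#' @param n_snps Number of simulated SNPs.
#' @param preset `"experimental"` (default) or `"survey"` (person-wave
#'   planning-horizon data with a person random intercept).
#' @param ... Overrides for any default component (see the returned list).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n = 624L, n_snps = 500L,
                       preset = c("experimental", "survey"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n = if (preset == "survey") 5881L else n,
    n_snps = n_snps,
    maf_range = c(0.05, 0.5),
    weight_sd = 0.1,
    dis_prevalence = c(human_capital = 0.498, carer_occupation = 0.276,
                       housing = 0.237, family_instability = 0.152),
    dis_slope = -0.10,
    dis_missing = rep(0.09, 4),
    dis_threshold = 2L,
    age_mean = 64.2, age_sd = 5.6, age_range = c(50, 75),
    female_share = 0.537,
    outcomes = list(
      # per-coefficient vectors are c(no-disadvantage, disadvantage)
      risk = list(intercept = c(2.34, 2.56), pgs = c(-0.368, 0.431),
                  age_c = c(0.10, 0.10), age_c2 = c(0, 0),
                  female = c(0.25, 0.25), sd = c(1.4, 1.4),
                  noise = "normal"),
      d1 = list(intercept = c(0.10, 0.10), pgs = c(-0.021, -0.027),
                age_c = c(0, 0), age_c2 = c(0, 0), female = c(0, 0),
                sd = c(0.05, 0.05), noise = "normal"),
      d2 = list(intercept = c(0.06, 0.06), pgs = c(-0.011, -0.004),
                age_c = c(0, 0), age_c2 = c(0, 0), female = c(0, 0),
                sd = c(0.03, 0.03), noise = "normal"),
      horizon = list(intercept = c(0.2, -0.4), pgs = c(0.199, 0.068),
                     age_c = c(-0.2, -0.2), age_c2 = c(0, 0),
                     female = c(0, 0), sd = c(1, 1), noise = "logistic")),
    horizon_thresholds = c(-2.2, -1.2, -0.4, 0.3, 1.2, 2.6),
    inconsist_rate = c(one_month = 0.096, two_month = 0.075),
    n_persons = 5881L, wave2_prob = 0.959, person_sd = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("sim_config: unknown fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Simulate a genotype panel
#'
#' Per-SNP allele frequencies drawn uniformly from `maf_range`, allele
#' counts Binomial(2, f) independently across SNPs and individuals, and
#' GWAS-style weights Normal(0, weight_sd^2).
#'
#' @param config A `sim_config` (uses n, n_snps, maf_range, weight_sd).
#' @param n Optional override of `config$n`.
#' @return A [genotype_panel()] with attribute `"freqs"`.
#' @export
simulate_genotypes <- function(config = sim_config(), n = NULL) {
  n <- n %||% config$n
  J <- config$n_snps
  f <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  G <- matrix(stats::rbinom(n * J, 2L, rep(f, each = n)), nrow = n)
  W <- stats::rnorm(J, 0, config$weight_sd)
  panel <- genotype_panel(G, W)
  attr(panel, "freqs") <- f
  panel
}

#' Simulate disadvantage dimensions with missingness
#'
#' Each of the four binary dimensions is Bernoulli(logistic(a_k + b * PGS))
#' with the intercept a_k root-found so that the marginal prevalence on the
#' supplied PGS sample matches the configured target at slope b; item
#' missingness is then applied independently per dimension.
#'
#' @param pgs Standardized PGS vector.
#' @param config A `sim_config`.
#' @return List: `complete` (0/1 matrix), `observed` (with NAs),
#'   `intercepts`.
#' @export
simulate_disadvantage <- function(pgs, config = sim_config()) {
  b <- config$dis_slope
  prev <- config$dis_prevalence
  K <- length(prev)
  a <- vapply(prev, function(p)
    stats::uniroot(function(a) mean(stats::plogis(a + b * pgs)) - p,
                   c(-15, 15), tol = 1e-10)$root, numeric(1))
  n <- length(pgs)
  complete <- vapply(seq_len(K), function(k)
    stats::rbinom(n, 1L, stats::plogis(a[k] + b * pgs)), integer(n))
  colnames(complete) <- names(prev)
  observed <- complete
  for (k in seq_len(K))
    observed[stats::runif(n) < config$dis_missing[k], k] <- NA_integer_
  list(complete = complete, observed = observed, intercepts = a)
}

# truncated-normal ages via inverse CDF
sim_ages <- function(n, config) {
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
}

#' Simulate latent preferences from the group-varying linear model
#'
#' Each latent is intercept(g) + slope(g) * PGS + covariate terms(g) plus
#' noise: normal for the CRRA and discount-rate latents (matching the
#' interval-regression likelihood) and logistic for the planning-horizon
#' propensity (matching the ordered/binary logit likelihoods).
#'
#' @param pgs Standardized PGS.
#' @param group Binary disadvantage indicator.
#' @param covariates Data frame with `age_c`, `age_c2`, `female`.
#' @param config A `sim_config`.
#' @return Data frame with `r`, `d1`, `d2`, `horizon_star`.
#' @export
simulate_latents <- function(pgs, group, covariates, config = sim_config()) {
  g <- as.integer(group) + 1L       # 1 = no disadvantage, 2 = disadvantage
  n <- length(pgs)
  one <- function(oc) {
    lp <- oc$intercept[g] + oc$pgs[g] * pgs +
      oc$age_c[g] * covariates$age_c + oc$age_c2[g] * covariates$age_c2 +
      oc$female[g] * covariates$female
    noise <- if (oc$noise == "logistic")
      stats::rlogis(n, 0, oc$sd[g]) else stats::rnorm(n, 0, oc$sd[g])
    lp + noise
  }
  data.frame(r = one(config$outcomes$risk),
             d1 = one(config$outcomes$d1),
             d2 = one(config$outcomes$d2),
             horizon_star = one(config$outcomes$horizon))
}

# expected-utility argmax over a menu for a vector of CRRA coefficients
eu_argmax <- function(menu, r) {
  pow <- function(x, r) ifelse(abs(1 - r) < 1e-9, log(x), x^(1 - r) / (1 - r))
  EU <- vapply(menu$lotteries, function(l)
    0.5 * (pow(l$low, r) + pow(l$high, r)), numeric(length(r)))
  if (is.null(dim(EU))) EU <- matrix(EU, nrow = 1L)
  max.col(EU, ties.method = "first")
}

#' Render latent preferences into instrument responses
#'
#' B-EG choice: brute-force expected-utility argmax over the six-lottery
#' menu at the subject's latent CRRA coefficient. Loss-aversion choice:
#' monotone ordinal map of the CRRA latent through configured thresholds
#' (loss payoffs bar CRRA evaluation, mirroring the ordinal treatment).
#' MPL rows: future option chosen iff FV/(1+d)^t > PV; with the configured
#' probability one random row is then flipped and the subject flagged as a
#' ground-truth inconsistent responder. Planning horizon: the propensity
#' latent thresholded into 7 levels.
#'
#' @param latents Output of [simulate_latents()].
#' @param instruments Output of [load_instruments()].
#' @param config A `sim_config`.
#' @return List: `beg_choice` (1 = A safest), `la_level` (1 = most
#'   risk-seeking .. 6 = most risk-averse), `mpl` (list per panel of choice
#'   matrices plus true inconsistency flags), `horizon` (0..6).
#' @export
render_choices <- function(latents, instruments, config = sim_config()) {
  n <- nrow(latents)
  beg_choice <- eu_argmax(instruments$beg_menu, latents$r)
  la_level <- 1L + findInterval(latents$r, instruments$la_thresholds)
  mpl <- lapply(names(instruments$mpl_panels), function(nm) {
    panel <- instruments$mpl_panels[[nm]]
    b <- mpl_bounds(panel)
    d <- latents[[if (nm == "one_month") "d1" else "d2"]]
    ch <- outer(d, b, function(d, b) b > d)   # TRUE = future option B
    rate <- config$inconsist_rate[[nm]]
    flip <- stats::runif(n) < rate
    rows <- sample.int(ncol(ch), n, replace = TRUE)
    for (i in which(flip)) ch[i, rows[i]] <- !ch[i, rows[i]]
    # a flip can land on an already-matching boundary; the ground-truth
    # flag records the injected perturbation, the coded flag what the
    # first-switch rule sees
    list(choices = ifelse(ch, "B", "A"), injected_flip = flip)
  })
  names(mpl) <- names(instruments$mpl_panels)
  horizon <- findInterval(latents$horizon_star, config$horizon_thresholds)
  list(beg_choice = beg_choice, la_level = la_level, mpl = mpl,
       horizon = horizon)
}

#' Generate a synthetic cohort
#'
#' Full pipeline: genotypes -> PGS -> disadvantage -> covariates -> latents
#' -> instrument responses -> elicited intervals, deterministic given the
#' seed. The experimental preset yields one row per subject with every
#' instrument; the survey preset yields person-wave planning-horizon data
#' with a person random intercept (cluster id `person`).
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (mandatory).
#' @param instruments Instrument set; default the bundled one.
#' @return List of class `"sim_dataset"`: `data` (analysis table), `truth`
#'   (latents and generating flags), `panel`, `config`, `seed`.
#' @export
generate <- function(config = sim_config(), seed, instruments = load_instruments()) {
  if (missing(seed)) stop("generate: a seed is mandatory")
  set.seed(seed)
  n <- if (config$preset == "survey") config$n_persons else config$n
  panel <- simulate_genotypes(config, n = n)
  score <- compute_pgs(panel)
  dis <- simulate_disadvantage(score$pgs, config)
  idx_obs <- disadvantage_index(dis$observed, threshold = config$dis_threshold)
  idx_true <- disadvantage_index(dis$complete, threshold = config$dis_threshold)
  age <- sim_ages(n, config)
  female <- stats::rbinom(n, 1L, config$female_share)
  cov <- data.frame(age = age, age_c = (age - 65) / 10,
                    age_c2 = ((age - 65) / 10)^2, female = female)
  lat <- simulate_latents(score$pgs, idx_obs$binary, cov, config)

  if (config$preset == "survey") {
    u <- stats::rnorm(n, 0, config$person_sd)
    waves <- 1L + stats::rbinom(n, 1L, config$wave2_prob)
    person <- rep(seq_len(n), waves)
    wave <- sequence(waves)
    oc <- config$outcomes$horizon
    g <- idx_obs$binary[person] + 1L
    lp <- oc$intercept[g] + oc$pgs[g] * score$pgs[person] +
      oc$age_c[g] * (cov$age_c[person] + 0.2 * (wave - 1)) +
      oc$female[g] * cov$female[person]
    star <- lp + u[person] + stats::rlogis(length(person), 0, oc$sd[g])
    horizon <- findInterval(star, config$horizon_thresholds)
    data <- data.frame(person = person, wave = wave,
                       pgs = score$pgs[person],
                       disadv = idx_obs$binary[person],
                       disadv_count = idx_obs$count[person],
                       age = cov$age[person] + 2 * (wave - 1),
                       age_c = cov$age_c[person] + 0.2 * (wave - 1),
                       female = cov$female[person],
                       horizon = horizon,
                       horizon_bin = planning_binary(horizon))
    data$age_c2 <- data$age_c^2
    truth <- data.frame(person = seq_len(n), horizon_intercept = u,
                        disadv_true = idx_true$binary)
    return(structure(list(data = data, truth = truth, panel = panel,
                          config = config, seed = seed),
                     class = "sim_dataset"))
  }

  resp <- render_choices(lat, instruments, config)
  crra <- menu_crra_intervals(instruments$beg_menu)
  iv1 <- lapply(seq_len(n), function(i)
    mpl_interval(resp$mpl$one_month$choices[i, ], instruments$mpl_panels$one_month))
  iv2 <- lapply(seq_len(n), function(i)
    mpl_interval(resp$mpl$two_month$choices[i, ], instruments$mpl_panels$two_month))
  gx <- function(l, f) vapply(l, function(e) f(e), numeric(1))
  data <- data.frame(
    id = score$id, pgs = score$pgs,
    disadv = idx_obs$binary, disadv_count = idx_obs$count,
    dis$observed,
    age = cov$age, age_c = cov$age_c, age_c2 = cov$age_c2,
    female = cov$female,
    beg_choice = resp$beg_choice,
    beg_scale = 7L - resp$beg_choice,     # 1 = riskiest (F) .. 6 = safest (A)
    beg_lower = crra$lower[resp$beg_choice],
    beg_upper = crra$upper[resp$beg_choice],
    la_level = resp$la_level,
    la_bin = la_binary(7L - resp$la_level),
    d1_lower = gx(iv1, function(e) e$lower),
    d1_upper = gx(iv1, function(e) e$upper),
    d1_inconsistent = as.integer(!gx(iv1, function(e) e$consistent)),
    d1_scale = gx(iv1, function(e) if (is.na(e$switch_row)) 7 else e$switch_row),
    d2_lower = gx(iv2, function(e) e$lower),
    d2_upper = gx(iv2, function(e) e$upper),
    d2_inconsistent = as.integer(!gx(iv2, function(e) e$consistent)),
    d2_scale = gx(iv2, function(e) if (is.na(e$switch_row)) 7 else e$switch_row),
    horizon = resp$horizon,
    horizon_bin = planning_binary(resp$horizon),
    row.names = NULL)
  truth <- data.frame(id = score$id, r = lat$r, d1 = lat$d1, d2 = lat$d2,
                      horizon_star = lat$horizon_star,
                      disadv_true = idx_true$binary,
                      dis$complete,
                      flip1 = resp$mpl$one_month$injected_flip,
                      flip2 = resp$mpl$two_month$injected_flip)
  structure(list(data = data, truth = truth, panel = panel,
                 config = config, seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic cohort (%s preset): %d rows, seed %d\n",
              x$config$preset, nrow(x$data), x$seed))
  invisible(x)
}
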