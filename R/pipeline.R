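# Orchestration: raw choice tables -> per-subject preference intervals,
# grouped descriptives, the six gene-by-environment fits, prediction
# profiles, a power report, and a machine-readable manifest.

#' Invert a subject-level choice table into preference intervals
#'
#' Applies the instrument inversions row by row: the ordered-lottery choice
#' becomes a CRRA interval, each MPL choice pattern a weekly discount-rate
#' interval with a consistency flag, the loss-aversion choice its ordinal
#' and binary codings, the planning-horizon level its binary collapse, and
#' the four disadvantage dimensions the count/binary index under the chosen
#' missingness policy.
#'
#' Expected columns (all optional; present ones are processed):
#' `beg_choice` (1..6, 1 = safest lottery A); `la_choice` (1..6 on A..F);
#' MPL row choices `one_month_1`..`one_month_6` and `two_month_1`..
#' `two_month_6` ("A"/"B"); `horizon` (0..6); `dis_1`..`dis_4` (0/1/NA).
#'
#' @param choices Data frame, one row per subject.
#' @param instruments Instrument set from [load_instruments()].
#' @param policy Disadvantage missingness policy, see
#'   [disadvantage_index()].
#' @return Tidy data frame of per-subject intervals, flags, and binary
#'   collapses.
#' @export
elicit_preferences <- function(choices, instruments = load_instruments(),
                               policy = "missing_as_zero") {
  n <- nrow(choices)
  out <- data.frame(row = seq_len(n))
  if ("beg_choice" %in% names(choices)) {
    crra <- menu_crra_intervals(instruments$beg_menu)
    ch <- as.integer(choices$beg_choice)
    if (any(ch < 1L | ch > nrow(crra), na.rm = TRUE))
      stop("elicit_preferences: beg_choice out of range")
    out$crra_lower <- crra$lower[ch]
    out$crra_upper <- crra$upper[ch]
    out$beg_scale <- nrow(crra) + 1L - ch
  }
  if ("la_choice" %in% names(choices)) {
    out$la_scale <- 7L - as.integer(choices$la_choice)
    out$la_bin <- la_binary(choices$la_choice)
  }
  for (nm in names(instruments$mpl_panels)) {
    panel <- instruments$mpl_panels[[nm]]
    cols <- paste0(nm, "_", seq_along(panel$future_amounts))
    if (!all(cols %in% names(choices))) next
    ivs <- lapply(seq_len(n), function(i)
      mpl_interval(unlist(choices[i, cols]), panel))
    out[[paste0(nm, "_lower")]] <- vapply(ivs, `[[`, numeric(1), "lower")
    out[[paste0(nm, "_upper")]] <- vapply(ivs, `[[`, numeric(1), "upper")
    out[[paste0(nm, "_inconsistent")]] <-
      as.integer(!vapply(ivs, `[[`, logical(1), "consistent"))
  }
  if ("horizon" %in% names(choices))
    out$horizon_bin <- planning_binary(choices$horizon)
  dcols <- paste0("dis_", 1:4)
  if (all(dcols %in% names(choices))) {
    idx <- disadvantage_index(as.matrix(choices[dcols]), policy = policy)
    out <- cbind(out, idx)
  }
  out
}

# grouped PGS-vs-measure correlations in the two-group descriptive layout
grouped_correlations <- function(data, measures, predictor = "pgs",
                                 moderator = "disadv") {
  rows <- list()
  for (m in measures) for (g in c(1, 0)) {
    sub <- data[data[[moderator]] == g, ]
    pc <- pearson_ci(sub[[predictor]], sub[[m]])
    rows[[length(rows) + 1L]] <- data.frame(
      group = if (g == 1) "disadv" else "no_disadv", variable = m,
      r = pc$r, p = pc$p, ci_lo = pc$ci[1], ci_hi = pc$ci[2], n = pc$n)
  }
  do.call(rbind, rows)
}

fit_summary_table <- function(model, fit) {
  tab <- as.data.frame(summary(fit)$coefficients)
  if (is.null(tab$or)) tab$or <- NA_real_
  data.frame(model = model, term = rownames(tab), tab, row.names = NULL)
}

#' Run the full simulate-then-analyze pipeline
#'
#' Generates a synthetic cohort, elicits preference intervals, computes
#' grouped PGS-preference correlations, fits the gene-by-environment
#' models appropriate to the preset (experimental: interval regressions on
#' the CRRA and two discount-rate intervals, ordered logit on the
#' loss-aversion scale, logit on its binary collapse; survey: ordered and
#' binary logits on the planning horizon with person-clustered errors),
#' extracts implied group effects and +/-2 SD prediction profiles, runs the
#' sensitivity power analysis, and writes every artifact as a delimited
#' table plus a JSON manifest.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed); NULL to skip
#'   writing.
#' @param config A `sim_config`; default chosen by `preset`.
#' @param preset `"experimental"` or `"survey"` (ignored when `config`
#'   given).
#' @param pcs Number of ancestry PCs to include as covariates (0 to skip;
#'   default 10 for the experimental preset).
#' @return Invisibly, a list with `sim`, `correlations`, `fits`,
#'   `implied`, `profiles`, `power`, `manifest`.
#' @export
run_pipeline <- function(seed, out_dir = NULL, config = NULL,
                         preset = c("experimental", "survey"), pcs = 10L) {
  preset <- match.arg(preset)
  t0 <- proc.time()[["elapsed"]]
  if (is.null(config)) config <- sim_config(preset = preset)
  preset <- config$preset
  sim <- generate(config, seed = seed)
  data <- sim$data
  covs <- c("age_c", "age_c2", "female")
  if (pcs > 0L && preset == "experimental") {
    pc <- ancestry_pcs(sim$panel, k = pcs)
    data <- cbind(data, pc$scores)
    covs <- c(covs, colnames(pc$scores))
  }
  t_sim <- proc.time()[["elapsed"]] - t0

  if (preset == "experimental") {
    measures <- c("beg_scale", "la_level", "la_bin", "d1_scale", "d2_scale")
    corr <- grouped_correlations(data, measures)
    fits <- list(
      risk_beg = gxe_fit(c("beg_lower", "beg_upper"), data,
                         family = "interval", covariates = covs),
      risk_la = gxe_fit("la_level", data, family = "ologit",
                        covariates = covs),
      risk_la_bin = gxe_fit("la_bin", data, family = "logit",
                            covariates = covs),
      discount_1m = gxe_fit(c("d1_lower", "d1_upper"), data,
                            family = "interval",
                            covariates = c(covs, "d1_inconsistent")),
      discount_2m = gxe_fit(c("d2_lower", "d2_upper"), data,
                            family = "interval",
                            covariates = c(covs, "d2_inconsistent")))
  } else {
    measures <- c("horizon", "horizon_bin")
    corr <- grouped_correlations(data, measures)
    fits <- list(
      horizon = gxe_fit("horizon", data, family = "ologit",
                        covariates = covs, cluster = "person"),
      horizon_bin = gxe_fit("horizon_bin", data, family = "logit",
                            covariates = covs, cluster = "person"))
  }
  t_fit <- proc.time()[["elapsed"]] - t0 - t_sim

  implied <- do.call(rbind, lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    b <- coef(fit)
    ie <- implied_effect(fit)
    main <- fit$predictor
    int <- paste0(fit$predictor, ":", fit$moderator)
    data.frame(model = nm, main = unname(b[main]),
               interaction = unname(b[int]), implied = ie$estimate,
               se = ie$se, z = ie$z, p = ie$p,
               ci_lo = ie$ci[1], ci_hi = ie$ci[2])
  }))
  profiles <- lapply(fits, predict)
  pw <- sensitivity_f2(nrow(data))
  manifest <- list(seed = seed, preset = preset,
                   n = nrow(data), package = "gxepref",
                   version = as.character(utils::packageVersion("gxepref")),
                   r_version = R.version.string,
                   timing = list(simulate = t_sim, fit = t_fit),
                   config = config[setdiff(names(config), "outcomes")],
                   outcome_config = config$outcomes)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
    wr(data, "subject_data.csv")
    wr(sim$truth, "truth.csv")
    wr(corr, "correlations.csv")
    wr(do.call(rbind, lapply(names(fits), function(nm)
      fit_summary_table(nm, fits[[nm]]))), "fit_summaries.csv")
    wr(implied, "implied_effects.csv")
    for (nm in names(profiles))
      wr(profiles[[nm]], paste0("profile_", nm, ".csv"))
    wr(data.frame(n = pw$n, alpha = pw$alpha, power = pw$power,
                  f2 = pw$f2, partial_r2 = pw$partial_r2,
                  lambda = pw$lambda, f_crit = pw$f_crit), "power.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(sim = sim, correlations = corr, fits = fits,
                 implied = implied, profiles = profiles, power = pw,
                 manifest = manifest))
}
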