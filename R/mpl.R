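# Multiple price list (time preference) instruments, plus the scalar
# codings used downstream (planning horizon, loss-avoidance, disadvantage).

#' Multiple price list panel
#'
#' A column of sooner-vs-later choices: a fixed sooner amount against an
#' increasing schedule of future amounts paid after a common delay. The row
#' at which a respondent first switches from the sooner option (A) to the
#' future option (B) brackets their exponential weekly discount rate.
#'
#' @param sooner_amount Sooner payment, GBP (> 0).
#' @param future_amounts Strictly increasing future payments, all greater
#'   than `sooner_amount`.
#' @param delay_weeks Delay between the sooner and future payment dates, in
#'   weeks (> 0). Stored as instrument configuration, not a code constant.
#' @param name Optional panel name.
#' @return Object of class `"mpl_panel"`.
#' @examples
#' mpl_panel(25, c(26, 28, 30, 32, 35, 38), delay_weeks = 2.43)
#' @export
mpl_panel <- function(sooner_amount, future_amounts, delay_weeks,
                      name = NULL) {
  stopifnot(is.numeric(sooner_amount), length(sooner_amount) == 1L,
            sooner_amount > 0, is.numeric(future_amounts),
            length(future_amounts) >= 1L, is.numeric(delay_weeks),
            length(delay_weeks) == 1L, delay_weeks > 0)
  if (is.unsorted(future_amounts, strictly = TRUE))
    stop("mpl_panel: future amounts must be strictly increasing")
  if (any(future_amounts <= sooner_amount))
    stop("mpl_panel: all future amounts must exceed the sooner amount")
  structure(list(sooner_amount = sooner_amount,
                 future_amounts = future_amounts,
                 delay_weeks = delay_weeks, name = name),
            class = "mpl_panel")
}

#' @export
print.mpl_panel <- function(x, ...) {
  cat(sprintf("MPL panel%s: GBP %g now vs %s in %g weeks\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$sooner_amount,
              paste0(x$future_amounts, collapse = "/"), x$delay_weeks))
  invisible(x)
}

#' Weekly discount rate at indifference
#'
#' Under exponential discounting PV = FV / (1 + d)^t, the rate that makes a
#' respondent exactly indifferent between `pv` now and `fv` after `t` weeks
#' is d = (fv/pv)^(1/t) - 1.
#'
#' @param pv Present (sooner) amount, > 0. Vectorized with `fv`.
#' @param fv Future amount, > 0.
#' @param t Delay in weeks, > 0.
#' @return Weekly discount rate(s) (proportion per week).
#' @examples
#' weekly_discount_bound(25, 28, 2.43)  # 0.0477
#' @export
weekly_discount_bound <- function(pv, fv, t) {
  stopifnot(is.numeric(pv), is.numeric(fv), is.numeric(t), all(t > 0))
  if (any(pv <= 0) || any(fv <= 0))
    stop("weekly_discount_bound: amounts must be positive")
  (fv / pv)^(1 / t) - 1
}

#' Discount-rate bounds for every row of an MPL panel
#'
#' @param panel An `mpl_panel`.
#' @return Numeric vector of per-row indifference rates (increasing).
#' @export
mpl_bounds <- function(panel) {
  stopifnot(inherits(panel, "mpl_panel"))
  weekly_discount_bound(panel$sooner_amount, panel$future_amounts,
                        panel$delay_weeks)
}

#' Discount-rate interval implied by an MPL choice pattern
#'
#' Codes the first switching point from the sooner option ("A") to the
#' future option ("B") as the respondent's implied weekly discount-rate
#' interval. Monotone A..A,B..B patterns give the interval between the
#' bound at the last A row and the bound at the first B row; all-A gives
#' `[top bound, Inf)` (never tempted to wait); all-B gives `(-Inf, first
#' bound]`. Non-monotone patterns (switching back) are coded by the same
#' first-switch rule and flagged `consistent = FALSE`; the flag must enter
#' downstream fits as a control covariate.
#'
#' @param choices Character vector of "A"/"B" (or 0/1 with 1 = B), one per
#'   panel row.
#' @param panel An `mpl_panel`.
#' @return List of class `"discount_interval"`: `lower`, `upper` (weekly
#'   rates, possibly infinite), `consistent`, `switch_row` (first B row, or
#'   NA if none).
#' @examples
#' p <- mpl_panel(25, c(26, 28, 30, 32, 35, 38), 2.43)
#' mpl_interval(c("A", "A", "A", "A", "B", "B"), p)  # [0.1069, 0.1485]
#' @export
mpl_interval <- function(choices, panel) {
  stopifnot(inherits(panel, "mpl_panel"))
  if (length(choices) == 0L) stop("mpl_interval: empty choice vector")
  if (is.numeric(choices)) choices <- ifelse(choices == 1, "B", "A")
  choices <- toupper(as.character(choices))
  k <- length(panel$future_amounts)
  if (length(choices) != k)
    stop("mpl_interval: expected ", k, " choices, got ", length(choices))
  if (!all(choices %in% c("A", "B")))
    stop("mpl_interval: choices must be 'A' or 'B'")
  b <- mpl_bounds(panel)
  is_b <- choices == "B"
  first_b <- if (any(is_b)) which(is_b)[1L] else NA_integer_
  consistent <- !any(is_b) ||
    identical(is_b, c(rep(FALSE, first_b - 1L), rep(TRUE, k - first_b + 1L)))
  if (is.na(first_b)) {              # always sooner: very impatient
    lower <- b[k]; upper <- Inf
  } else if (first_b == 1L) {        # always future: very patient
    lower <- -Inf; upper <- b[1L]
  } else {
    lower <- b[first_b - 1L]; upper <- b[first_b]
  }
  structure(list(lower = lower, upper = upper, consistent = consistent,
                 switch_row = first_b), class = "discount_interval")
}

#' @export
print.discount_interval <- function(x, ...) {
  cat(sprintf("weekly discount rate in [%s, %s]%s\n",
              format(x$lower, digits = 4), format(x$upper, digits = 4),
              if (x$consistent) "" else "  (inconsistent pattern, first-switch rule)"))
  invisible(x)
}

#' Binary long-horizon coding of the planning-horizon item
#'
#' The 7-level financial planning-horizon item (0 = "does not plan / plans
#' day to day" ... 6 = "longer than 10 years") collapsed to 1 when the
#' reported horizon extends beyond the next year (levels 4-6) and 0
#' otherwise.
#'
#' @param level Integer ordinal level(s) in 0..6.
#' @return 0/1 vector.
#' @export
planning_binary <- function(level) {
  lv <- as.integer(level)
  if (anyNA(lv) || any(lv < 0L | lv > 6L))
    stop("planning_binary: level must be in 0..6")
  as.integer(lv >= 4L)
}

#' Childhood disadvantage index
#'
#' Combines four binary disadvantage dimensions (parental human capital,
#' carer occupation, housing amenities, family instability) into a count
#' and a binary indicator for experiencing at least `threshold` dimensions.
#' Missing dimensions are resolved by policy: `"missing_as_zero"` (the
#' default, preserving sample size), `"missing_indicator"` (as zero, plus a
#' missingness flag to include as a control), or `"complete_case"` (flag
#' rows with any missing dimension for exclusion).
#'
#' @param dims Matrix or data frame with 4 columns of 0/1/NA (one row per
#'   subject), or a length-4 vector for a single subject.
#' @param policy Missingness policy (see above).
#' @param threshold Count at or above which `binary` is 1; default 2.
#' @return Data frame with `count`, `binary`, `n_missing`, and (policy
#'   dependent) `any_missing` / `exclude`.
#' @examples
#' disadvantage_index(c(1, 1, 0, 0))            # count 2, binary 1
#' disadvantage_index(c(0, NA, 0, 0))           # missing-as-zero: count 0
#' @export
disadvantage_index <- function(dims,
                               policy = c("missing_as_zero",
                                          "missing_indicator",
                                          "complete_case"),
                               threshold = 2L) {
  policy <- match.arg(policy)
  if (is.null(dim(dims))) dims <- matrix(dims, nrow = 1L)
  dims <- as.matrix(dims)
  if (ncol(dims) != 4L)
    stop("disadvantage_index: expected four dimension columns")
  if (!all(dims %in% c(0, 1, NA)))
    stop("disadvantage_index: dimensions must be 0, 1 or missing")
  n_missing <- rowSums(is.na(dims))
  imputed <- dims; imputed[is.na(imputed)] <- 0
  count <- as.integer(rowSums(imputed))
  out <- data.frame(count = count,
                    binary = as.integer(count >= threshold),
                    n_missing = as.integer(n_missing))
  if (policy == "missing_indicator") out$any_missing <- as.integer(n_missing > 0)
  if (policy == "complete_case") {
    out$exclude <- as.integer(n_missing > 0)
    out$count[out$exclude == 1L] <- NA_integer_
    out$binary[out$exclude == 1L] <- NA_integer_
  }
  out
}
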