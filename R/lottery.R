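#' Two-outcome lottery
#'
#' A lottery paying `low` or `high` (GBP) with probability 1/2 each, the
#' building block of the ordered-lottery (Binswanger/Eckel-Grossman style)
#' risk elicitation task.
#'
#' @param low,high Numeric payoffs in GBP; `low <= high`, both finite.
#' @param label Optional single-letter label ("A" safest by convention).
#' @return An object of class `"lottery"`.
#' @examples
#' lottery(24, 36, "B")
#' @export
lottery <- function(low, high, label = NULL) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, is.finite(low), is.finite(high))
  if (low > high) stop("lottery: 'low' must not exceed 'high'")
  structure(list(low = low, high = high, label = label), class = "lottery")
}

#' @export
print.lottery <- function(x, ...) {
  m <- lottery_moments(x)
  cat(sprintf("Lottery %s: (%g, %g) 50/50  EV = %g, SD = %.3g\n",
              if (is.null(x$label)) "" else x$label, x$low, x$high,
              m$expected_value, m$std_dev))
  invisible(x)
}

#' Ordered lottery menu
#'
#' An ordered collection of 50/50 lotteries, conventionally labelled A..F
#' with A the safe option; expected value and spread increase down the menu.
#'
#' @param ... `lottery` objects, or a single list of them, ordered safest
#'   first.
#' @param labels Optional character labels; defaults to LETTERS.
#' @return An object of class `"lottery_menu"`.
#' @examples
#' beg_menu()
#' @export
lottery_menu <- function(..., labels = NULL) {
  lots <- list(...)
  if (length(lots) == 1L && is.list(lots[[1L]]) &&
      !inherits(lots[[1L]], "lottery")) lots <- lots[[1L]]
  if (length(lots) < 2L) stop("lottery_menu: need at least two lotteries")
  if (!all(vapply(lots, inherits, logical(1), "lottery")))
    stop("lottery_menu: all elements must be 'lottery' objects")
  if (is.null(labels)) {
    labels <- vapply(lots, function(l)
      if (is.null(l$label)) NA_character_ else l$label, character(1))
    if (anyNA(labels)) labels <- LETTERS[seq_along(lots)]
  }
  for (i in seq_along(lots)) lots[[i]]$label <- labels[i]
  structure(list(lotteries = lots, labels = labels), class = "lottery_menu")
}

#' @export
print.lottery_menu <- function(x, ...) {
  cat("Lottery menu (", length(x$lotteries), " options, safest first)\n",
      sep = "")
  for (l in x$lotteries) print(l)
  invisible(x)
}

#' @export
length.lottery_menu <- function(x) length(x$lotteries)

#' CRRA utility
#'
#' Constant-relative-risk-aversion utility \eqn{u(x) = x^{1-r}/(1-r)} with
#' the log-utility limit \eqn{u(x) = \log x} at \eqn{r = 1}. Payoffs are
#' taken as integrated into a background income of zero, so `x` must be
#' strictly positive (add an offset first for loss lotteries, or treat them
#' ordinally).
#'
#' @param x Positive payoff(s), GBP.
#' @param r CRRA coefficient; `r = 0` is risk-neutral, `r > 0` risk-averse.
#' @return Utility value(s), same length as `x`.
#' @examples
#' crra_value(10, 0)   # 10
#' crra_value(exp(1), 1)  # 1
#' @export
crra_value <- function(x, r) {
  stopifnot(is.numeric(x), is.numeric(r), length(r) == 1L, is.finite(r))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("crra_value: payoffs must be positive and finite ",
         "(background income is zero; offset loss lotteries or treat them ordinally)")
  if (abs(r - 1) < 1e-10) log(x) else x^(1 - r) / (1 - r)
}

#' Expected CRRA utility of a lottery
#'
#' @param lot A `lottery`.
#' @param r CRRA coefficient.
#' @return Mean of the two outcome utilities (probability 1/2 each).
#' @examples
#' lottery_eu(lottery(24, 36), 0)  # 30, the expected value
#' @export
lottery_eu <- function(lot, r) {
  stopifnot(inherits(lot, "lottery"))
  tryCatch(
    0.5 * (crra_value(lot$low, r) + crra_value(lot$high, r)),
    error = function(e) stop("lottery_eu [", lot$label %||% "?", "]: ",
                             conditionMessage(e), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Indifference CRRA coefficient between two lotteries
#'
#' Root of the expected-utility difference between two lotteries, found by
#' bracketed root solving on the continuous-in-r EU function (the log case
#' at r = 1 is handled by the limit). For r > 1 both utilities are negative
#' and the comparison is made on the signed utilities, so the same root
#' applies throughout the bracket.
#'
#' @param lotA,lotB Two distinct `lottery` objects.
#' @param bracket Length-2 numeric search interval for r.
#' @param tol Absolute tolerance on r.
#' @return The indifference coefficient r*.
#' @examples
#' indifference_r(lottery(28, 28), lottery(24, 36))  # ~3.46
#' @export
indifference_r <- function(lotA, lotB, bracket = c(-10, 10), tol = 1e-9) {
  stopifnot(inherits(lotA, "lottery"), inherits(lotB, "lottery"),
            length(bracket) == 2L, bracket[1] < bracket[2])
  if (isTRUE(lotA$low == lotB$low) && isTRUE(lotA$high == lotB$high))
    stop("indifference_r: lotteries are identical")
  f <- function(r) lottery_eu(lotA, r) - lottery_eu(lotB, r)
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("indifference_r: EU difference does not change sign on the bracket [",
         bracket[1], ", ", bracket[2], "]")
  stats::uniroot(f, bracket, tol = tol)$root
}

#' CRRA interval implied by each menu choice
#'
#' Inverts an ordered lottery menu into the partition of the real line by
#' adjacent-lottery indifference points: choosing lottery k implies a CRRA
#' coefficient between the (k, k+1) and (k-1, k) indifference points, with
#' the safest choice unbounded above and the riskiest unbounded below.
#' Intervals are closed on the left (ties at an indifference point assigned
#' to the safer option's interval).
#'
#' @param menu A `lottery_menu`, safest first.
#' @param bracket,tol Passed to [indifference_r()].
#' @return A data frame with one row per menu option: `label`, `lower`,
#'   `upper` (CRRA bounds, `-Inf`/`Inf` at the extremes).
#' @examples
#' menu_crra_intervals(beg_menu())
#' @export
menu_crra_intervals <- function(menu, bracket = c(-10, 10), tol = 1e-9) {
  stopifnot(inherits(menu, "lottery_menu"))
  k <- length(menu)
  roots <- vapply(seq_len(k - 1L), function(i)
    indifference_r(menu$lotteries[[i]], menu$lotteries[[i + 1L]],
                   bracket = bracket, tol = tol), numeric(1))
  if (is.unsorted(rev(roots), strictly = TRUE))
    stop("menu_crra_intervals: adjacent indifference points are not strictly ",
         "decreasing from the safe end; menu is not a valid ordered instrument")
  lower <- c(roots, -Inf)
  upper <- c(Inf, roots)
  data.frame(label = menu$labels, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' Expected value and standard deviation of a lottery
#'
#' Two-point moments under the n-1 sample convention over the two equally
#' likely payoffs: EV = (low+high)/2, SD = |high-low|/sqrt(2). This is the
#' convention under which every printed instrument cell reproduces; the
#' population (divide-by-n) convention does not.
#'
#' @param lot A `lottery`.
#' @return List with `expected_value` and `std_dev`.
#' @examples
#' lottery_moments(lottery(24, 36))  # EV 30, SD 8.49
#' @export
lottery_moments <- function(lot) {
  stopifnot(inherits(lot, "lottery"))
  list(expected_value = (lot$low + lot$high) / 2,
       std_dev = abs(lot$high - lot$low) / sqrt(2))
}

#' Binary loss-avoidance coding of an ordered-menu choice
#'
#' For the loss-aversion variant of the six-lottery task, codes 1 if the
#' chosen lottery is loss-free (options A-C) and 0 if it contains a possible
#' loss (options D-F).
#'
#' @param choice_index Integer 1..6, 1 = A (safest).
#' @return 0 or 1 (vectorized).
#' @export
la_binary <- function(choice_index) {
  ci <- as.integer(choice_index)
  if (anyNA(ci) || any(ci < 1L | ci > 6L))
    stop("la_binary: choice index must be in 1..6")
  as.integer(ci <= 3L)
}

#' Default instrument set
#'
#' Reads the bundled instrument definitions (lottery menus and MPL panels,
#' including the calibrated week delays) from the package's config file, or
#' from a user-supplied JSON file with the same schema.
#'
#' @param path Path to an instrument JSON file; default the bundled set.
#' @return List with elements `beg_menu`, `la_menu` (lottery_menu),
#'   `mpl_panels` (list of `mpl_panel`), `la_thresholds`, `horizon_levels`.
#' @export
load_instruments <- function(path = system.file("extdata", "instruments.json",
                                                package = "gxepref")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  mk_menu <- function(m) {
    lots <- lapply(seq_len(nrow(m$payoffs)), function(i)
      lottery(m$payoffs[i, 1], m$payoffs[i, 2], m$labels[i]))
    lottery_menu(lots, labels = m$labels)
  }
  panels <- lapply(cfg$mpl_panels, function(p)
    mpl_panel(sooner_amount = p$sooner_amount,
              future_amounts = p$future_amounts,
              delay_weeks = p$delay_weeks, name = p$name))
  names(panels) <- vapply(cfg$mpl_panels, `[[`, character(1), "name")
  list(beg_menu = mk_menu(cfg$beg_menu), la_menu = mk_menu(cfg$la_menu),
       mpl_panels = panels,
       la_thresholds = cfg$la_thresholds,
       horizon_levels = cfg$horizon_levels)
}

#' @rdname load_instruments
#' @export
beg_menu <- function() load_instruments()$beg_menu

#' @rdname load_instruments
#' @export
la_menu <- function() load_instruments()$la_menu
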