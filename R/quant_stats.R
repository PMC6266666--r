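# Bioassay and abundance statistics: quantal dose-response (PD50) fitting,
# per-gram dose conversion, venom composition fractions, and the correlation
# between transcript expression and proteomic precursor-count intensity.

#' Fit a PD50 from quantal paralysis counts
#'
#' Maximum-likelihood fit of a binomial GLM in log10(dose) (logit link by
#' default, probit optional). The PD50 is the dose at 50% response,
#' `10^(-intercept/slope)`; its confidence interval comes from delta-method
#' standard-error propagation on the log10 scale. When the data show complete
#' separation (every dose group all-paralysed or none-paralysed) the
#' likelihood has no interior maximum: the fit is flagged unstable and only
#' the bracketing dose interval is reported.
#'
#' @param observations Data frame with columns `dose` (ug per animal, > 0),
#'   `n_injected`, `n_paralysed`, for a single observation time point. At
#'   least 3 distinct positive doses are required.
#' @param link `"logit"` or `"probit"`.
#' @param conf_level Confidence level for the PD50 interval.
#' @return Object of class `pd50_fit`: list with `pd50`, `slope`, `ci_low`,
#'   `ci_high` (dose units), `link`, `unstable`, `timepoint` (if the input
#'   carries a `timepoint` column), and the underlying `glm` fit (`model`,
#'   `NULL` when unstable).
#' @examples
#' obs <- data.frame(dose = c(0.5, 1, 2, 4, 8, 16), n_injected = 20,
#'                   n_paralysed = c(1, 4, 9, 15, 19, 20))
#' fit_pd50(obs)
#' @export
fit_pd50 <- function(observations, link = c("logit", "probit"),
                     conf_level = 0.95) {
  link <- match.arg(link)
  stopifnot(all(c("dose", "n_injected", "n_paralysed") %in%
                  names(observations)))
  obs <- observations[observations$n_injected > 0, , drop = FALSE]
  stopifnot(all(obs$dose > 0), all(obs$n_paralysed >= 0),
            all(obs$n_paralysed <= obs$n_injected))
  if (length(unique(obs$dose)) < 3L) {
    stop("need at least 3 distinct positive doses to fit a PD50")
  }
  timepoint <- if ("timepoint" %in% names(obs)) unique(obs$timepoint)[1] else NA_character_

  extreme <- obs$n_paralysed == 0L | obs$n_paralysed == obs$n_injected
  if (all(extreme)) {
    # complete separation: report only the bracketing interval
    prop <- obs$n_paralysed / obs$n_injected
    lo <- suppressWarnings(max(obs$dose[prop == 0]))
    hi <- suppressWarnings(min(obs$dose[prop == 1]))
    out <- list(pd50 = NA_real_, slope = NA_real_,
                ci_low = if (is.finite(lo)) lo else min(obs$dose),
                ci_high = if (is.finite(hi)) hi else max(obs$dose),
                link = link, unstable = TRUE, timepoint = timepoint,
                model = NULL, conf_level = conf_level)
    class(out) <- "pd50_fit"
    return(out)
  }

  fit <- suppressWarnings(glm(
    cbind(n_paralysed, n_injected - n_paralysed) ~ log10(dose),
    family = binomial(link = link), data = obs))
  b <- coef(fit)
  logpd50 <- -b[1] / b[2]
  V <- vcov(fit)
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- list(
    pd50 = unname(10^logpd50), slope = unname(b[2]),
    ci_low = unname(10^(logpd50 - z * se)),
    ci_high = unname(10^(logpd50 + z * se)),
    link = link, unstable = FALSE, timepoint = timepoint, model = fit,
    conf_level = conf_level)
  class(out) <- "pd50_fit"
  out
}

#' @export
print.pd50_fit <- function(x, ...) {
  if (x$unstable) {
    cat(sprintf(
      "PD50 fit (%s link): complete separation; PD50 bracketed in (%.4g, %.4g)\n",
      x$link, x$ci_low, x$ci_high))
  } else {
    cat(sprintf(
      "PD50 = %.4g (%.0f%% CI %.4g-%.4g), slope %.3g on log10(dose), %s link%s\n",
      x$pd50, 100 * x$conf_level, x$ci_low, x$ci_high, x$slope, x$link,
      if (!is.na(x$timepoint)) paste0(", timepoint ", x$timepoint) else ""))
  }
  invisible(x)
}

#' Convert a per-animal dose to a per-gram dose
#'
#' @param pd50_per_fly Dose in ug per animal.
#' @param fly_mass Body mass in g (> 0).
#' @return Dose in ug per g.
#' @examples
#' per_gram(1.16, 0.025)
#' @export
per_gram <- function(pd50_per_fly, fly_mass) {
  if (any(fly_mass <= 0)) stop("fly_mass must be positive")
  pd50_per_fly / fly_mass
}

#' Per-animal dose from an injected concentration
#'
#' @param concentration ug/uL of the injected solution.
#' @param volume_ul Injected volume in uL (default 2.1, a hand
#'   microapplicator injection).
#' @return Dose in ug per animal.
#' @export
dose_from_concentration <- function(concentration, volume_ul = 2.1) {
  stopifnot(volume_ul > 0, all(concentration >= 0))
  concentration * volume_ul
}

#' Paralytic doses contained in one venom harvest
#'
#' @param yield_ug Venom yield per harvest in ug.
#' @param pd50_ug PD50 in ug per animal.
#' @return Number of PD50-equivalent doses in the harvest.
#' @export
doses_per_harvest <- function(yield_ug, pd50_ug) {
  stopifnot(yield_ug >= 0, pd50_ug > 0)
  yield_ug / pd50_ug
}

#' Composition fractions of a venom by group
#'
#' Expresses each group's share of the proteomic precursor-count intensity
#' and of the transcriptomic expression as a percentage of the respective
#' grand total.
#'
#' @param records Data frame with columns `precursor_count_intensity` and
#'   `expression` (non-negative) plus the grouping column.
#' @param group_by Name of the grouping column (default `"family_label"`).
#' @return Data frame: group, `intensity_pct`, `expression_pct`; each column
#'   sums to 100.
#' @export
composition_fractions <- function(records, group_by = "family_label") {
  stopifnot(group_by %in% names(records),
            all(c("precursor_count_intensity", "expression") %in%
                  names(records)))
  stopifnot(all(records$precursor_count_intensity >= 0),
            all(records$expression >= 0))
  tot_i <- sum(records$precursor_count_intensity)
  tot_e <- sum(records$expression)
  if (tot_i <= 0 || tot_e <= 0) {
    stop("grand total of intensity and expression must both be positive")
  }
  g <- records[[group_by]]
  agg <- aggregate(records[, c("precursor_count_intensity", "expression")],
                   by = setNames(list(g), group_by), FUN = sum)
  out <- data.frame(
    agg[[group_by]],
    intensity_pct = 100 * agg$precursor_count_intensity / tot_i,
    expression_pct = 100 * agg$expression / tot_e,
    stringsAsFactors = FALSE)
  names(out)[1] <- group_by
  out
}

#' Correlation between transcript expression and proteomic intensity
#'
#' Pearson correlation (with the standard t-based two-sided p-value on n - 2
#' degrees of freedom) between per-entity expression and precursor-count
#' intensity, optionally after log transformation of both quantities.
#'
#' @param records Data frame with columns `precursor_count_intensity` and
#'   `expression`.
#' @param log Log-transform both quantities first (requires all values > 0).
#' @return List with `r`, `p`, `n`, and the underlying `htest`.
#' @export
expression_intensity_correlation <- function(records, log = FALSE) {
  x <- records$precursor_count_intensity
  y <- records$expression
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 records")
  if (log) {
    if (any(x <= 0) || any(y <= 0)) {
      stop("log transform requires strictly positive values")
    }
    x <- base::log(x); y <- base::log(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the quantities")
  }
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x), test = ht)
}
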