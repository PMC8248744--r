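#' Probit dose-response fit and LC50
#'
#' Maximum-likelihood binomial regression of mortality on log10
#' concentration with a probit link.  The median lethal concentration is
#' `LC50 = 10^(-alpha/beta)` and its 95% confidence interval is obtained by
#' the delta method on `-alpha/beta`.  An optional Abbott correction for
#' control (dose 0) mortality is available but off by default.
#'
#' @param data data.frame with `dose` (mg/L, positive for fitted points),
#'   `n` exposed and `dead`.
#' @param abbott Apply Abbott's correction using the dose-0 row, if present
#'   (default FALSE).
#' @return A `probit_fit`: coefficients `alpha` (intercept) and `beta`
#'   (slope on log10 dose), their covariance, `lc50`, `lc50_ci`, and the
#'   fitted model.
#' @export
probit_fit <- function(data, abbott = FALSE) {
  ctrl <- data[data$dose == 0, , drop = FALSE]
  data <- data[data$dose > 0, , drop = FALSE]
  stopifnot(all(data$dead >= 0), all(data$dead <= data$n))
  dead <- data$dead
  n <- data$n
  if (abbott && nrow(ctrl)) {
    c0 <- sum(ctrl$dead) / sum(ctrl$n)
    p <- pmax(0, (dead / n - c0) / (1 - c0))
    dead <- round(p * n)
  }
  partial <- dead > 0 & dead < n
  if (!any(partial)) stop("no partial kill: cannot fit a probit model")
  if (length(unique(data$dose[partial])) < 2 && length(unique(data$dose)) < 3) {
    stop("need responses at several doses to fit a probit model")
  }
  fit <- glm(cbind(dead, n - dead) ~ log10(data$dose),
             family = binomial(link = "probit"))
  alpha <- unname(coef(fit)[1])
  beta <- unname(coef(fit)[2])
  if (is.na(beta) || beta <= 0) stop("invalid probit fit: non-positive slope")
  V <- vcov(fit)
  log_lc50 <- -alpha / beta
  # delta method on g(alpha, beta) = -alpha/beta
  grad <- c(-1 / beta, alpha / beta^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  ci <- 10^(log_lc50 + c(-1, 1) * qnorm(0.975) * se)
  structure(list(alpha = alpha, beta = beta, vcov = V,
                 lc50 = 10^log_lc50, lc50_ci = ci, model = fit),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> slope %.3f; LC50 %.3g mg/L (95%% CI %.3g-%.3g)\n",
              x$beta, x$lc50, x$lc50_ci[1], x$lc50_ci[2]))
  invisible(x)
}

#' Predicted mortality from a probit fit
#'
#' @param fit A [probit_fit()].
#' @param dose Positive concentrations.
#' @return Predicted mortality proportions.
#' @export
predict_mortality <- function(fit, dose) {
  pnorm(fit$alpha + fit$beta * log10(dose))
}

#' Stone's degree of dominance
#'
#' `D = (2 log LC50_F1 - log LC50_R - log LC50_S) /
#'      (log LC50_R - log LC50_S)` with base-10 logs: D = 1 means fully
#' dominant resistance, D = -1 fully recessive, and intermediate negative
#' values incompletely recessive resistance.
#'
#' @param lc50_R,lc50_S,lc50_F1 Positive LC50s of the resistant parent, the
#'   susceptible parent and the F1.
#' @return List with `D` and a `clipped` flag when D falls outside
#'   `[-1, 1]`.
#' @export
degree_of_dominance <- function(lc50_R, lc50_S, lc50_F1) {
  stopifnot(lc50_R > 0, lc50_S > 0, lc50_F1 > 0)
  if (lc50_R == lc50_S) stop("parental LC50s are equal: D is undefined")
  D <- (2 * log10(lc50_F1) - log10(lc50_R) - log10(lc50_S)) /
    (log10(lc50_R) - log10(lc50_S))
  list(D = D, clipped = D < -1 || D > 1)
}

#' Goodness-of-fit test of a monogenic recessive expectation
#'
#' Under one-locus recessive resistance, the expected backcross mortality
#' at each dose is `c = 0.5 W(F1) + 0.5 W(R)`, the average of the observed
#' F1 and resistant-parent mortalities at that dose.  The chi-square
#' statistic sums `(observed - expected)^2 / expected` over the dead and
#' alive cells of every dose, with degrees of freedom equal to the number
#' of doses used.
#'
#' @param w_f1,w_r Named numeric vectors of observed mortality proportions
#'   of the F1 and the resistant strain, named by dose.
#' @param backcross data.frame with `dose`, `n`, `dead` for the backcross
#'   progeny.
#' @return A `monogenic_test` list: per-dose expectations, `chisq`, `df`,
#'   `p_value`.
#' @export
monogenic_test <- function(w_f1, w_r, backcross) {
  doses <- as.character(backcross$dose)
  miss <- doses[!(doses %in% names(w_f1)) | !(doses %in% names(w_r))]
  if (length(miss)) {
    stop("dose missing from a parent mortality table: ",
         paste(unique(miss), collapse = ", "))
  }
  c_d <- 0.5 * w_f1[doses] + 0.5 * w_r[doses]
  usable <- c_d > 0 & c_d < 1
  if (any(!usable)) {
    warning("excluding ", sum(!usable),
            " dose(s) with degenerate expected mortality (0 or 1)")
  }
  bc <- backcross[usable, , drop = FALSE]
  cc <- c_d[usable]
  exp_dead <- bc$n * cc
  exp_alive <- bc$n * (1 - cc)
  chisq <- sum((bc$dead - exp_dead)^2 / exp_dead +
                 ((bc$n - bc$dead) - exp_alive)^2 / exp_alive)
  df <- nrow(bc)
  structure(list(
    expected = data.frame(dose = bc$dose, n = bc$n, dead = bc$dead,
                          expected_mortality = as.numeric(cc)),
    chisq = chisq, df = df,
    p_value = pchisq(chisq, df, lower.tail = FALSE)
  ), class = "monogenic_test")
}

#' @export
print.monogenic_test <- function(x, ...) {
  cat(sprintf("<monogenic_test> chi-square %.3f on %d df, p = %.3g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Classify the mode of inheritance from reciprocal-cross fits
#'
#' A maternal effect is flagged when the LC50 confidence intervals of the
#' two reciprocal F1s are disjoint.  Stone's D is computed from the pooled
#' F1 LC50 (geometric mean of the reciprocal estimates) and labelled:
#' incompletely recessive for -1 < D < 0, incompletely dominant for
#' 0 < D < 1, and fully recessive/dominant at the boundaries.
#'
#' @param fit_R,fit_S,fit_F1a,fit_F1b [probit_fit()]s of the resistant
#'   parent, susceptible parent, and the two reciprocal F1s.
#' @return List with `maternal_effect`, `D`, `label`, and the pooled F1
#'   LC50.
#' @export
classify_inheritance <- function(fit_R, fit_S, fit_F1a, fit_F1b) {
  disjoint <- fit_F1a$lc50_ci[2] < fit_F1b$lc50_ci[1] ||
    fit_F1b$lc50_ci[2] < fit_F1a$lc50_ci[1]
  lc50_f1 <- sqrt(fit_F1a$lc50 * fit_F1b$lc50)
  dom <- degree_of_dominance(fit_R$lc50, fit_S$lc50, lc50_f1)
  label <- if (dom$D <= -1) "fully recessive"
  else if (dom$D < 0) "incompletely recessive"
  else if (dom$D == 0) "semi-dominant"
  else if (dom$D < 1) "incompletely dominant"
  else "fully dominant"
  list(maternal_effect = disjoint, D = dom$D, label = label,
       lc50_f1_pooled = lc50_f1)
}
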