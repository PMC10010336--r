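# Survival analysis: Kaplan-Meier estimation, log-rank testing and Cox
# proportional hazards, thin surfaces over the survival package.

check_survival <- function(os_months, os_event) {
  if (length(os_months) != length(os_event))
    stop_input("os_months and os_event must have equal length")
  if (any(os_months < 0)) stop_input("negative survival times")
  if (!all(os_event %in% c(0, 1))) stop_input("os_event must be 0 (censored) or 1 (death)")
  invisible(NULL)
}

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimate of the survival function; the median is the
#' smallest time at which the estimate drops to 0.5 or below, and is
#' \code{NA} when the curve never reaches 0.5.
#'
#' @param os_months follow-up time (months, >= 0).
#' @param os_event event indicator: 1 death observed, 0 censored.
#' @return object of class \code{km_curve}: list with \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv} and
#'   \code{median}.
#' @export
km_estimate <- function(os_months, os_event) {
  check_survival(os_months, os_event)
  if (!length(os_months)) stop_input("at least one subject is required")
  fit <- survival::survfit(survival::Surv(os_months, os_event) ~ 1)
  s <- summary(fit, censored = TRUE)
  med <- if (any(s$surv <= 0.5)) min(s$time[s$surv <= 0.5]) else NA_real_
  structure(list(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                 n_censor = s$n.censor, surv = s$surv, median = med,
                 n = length(os_months), n_events = sum(os_event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, median %s months\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Overall survival", ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), main = "", ...)
  invisible(x)
}

#' Log-rank test of survival differences between groups
#'
#' @param os_months,os_event survival outcome per sample.
#' @param groups group label per sample (2 or more groups).
#' @return \code{htest}-style list with the chi-square statistic,
#'   \code{parameter} (df = groups - 1) and \code{p.value}.
#' @export
logrank_test <- function(os_months, os_event, groups) {
  check_survival(os_months, os_event)
  groups <- as.factor(groups)
  if (length(groups) != length(os_months)) stop_input("one group per sample is required")
  if (nlevels(groups) < 2L) stop_input("at least 2 groups are required")
  if (sum(os_event) == 0) {
    warning("no events observed; log-rank statistic is 0")
    stat <- 0; df <- nlevels(groups) - 1L; p <- 1
  } else {
    fit <- survival::survdiff(survival::Surv(os_months, os_event) ~ groups)
    stat <- unname(fit$chisq)
    df <- nlevels(groups) - 1L
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  structure(list(statistic = c(chisq = stat), parameter = c(df = df),
                 p.value = p, method = "Log-rank test",
                 data.name = "survival by group"),
            class = "htest")
}

#' Cox proportional hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron tie handling and returns
#' per-covariate log hazard ratios with Wald inference.
#'
#' @param os_months,os_event survival outcome per sample.
#' @param covariates numeric matrix or data.frame of covariates (samples in
#'   rows); factors are expanded by the usual treatment contrasts.
#' @return object of class \code{cox_fit}: data.frame \code{coefficients}
#'   with columns \code{coef} (log HR), \code{hr}, \code{se}, \code{z},
#'   \code{p_value}, plus \code{converged} and the underlying
#'   \code{\link[survival]{coxph}} fit.
#' @export
cox_fit <- function(os_months, os_event, covariates) {
  check_survival(os_months, os_event)
  if (is.vector(covariates)) covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(os_months))
    stop_input("covariates must have one row per sample")
  constant <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1L))
  if (any(constant))
    stop_input("constant covariate(s): %s",
               paste(names(covariates)[constant], collapse = ", "))
  dat <- cbind(data.frame(.time = os_months, .event = os_event), covariates)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  if (!converged)
    warning("Cox partial likelihood did not converge cleanly (possible monotone likelihood); coefficients reported anyway")
  sm <- summary(fit)$coefficients
  coefs <- data.frame(coef = sm[, "coef"], hr = sm[, "exp(coef)"],
                      se = sm[, "se(coef)"], z = sm[, "z"],
                      p_value = sm[, "Pr(>|z|)"],
                      row.names = rownames(sm))
  structure(list(coefficients = coefs, converged = converged,
                 n = length(os_months), n_events = sum(os_event), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (Efron ties): %d subjects, %d events%s\n",
              x$n, x$n_events, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$coefficients$coef, rownames(object$coefficients))
}

#' Univariate screen followed by multivariate Cox
#'
#' Fits one univariate Cox model per covariate, keeps those with
#' univariate Wald p below \code{screen_p}, and fits the multivariate model
#' on the retained set — the conventional two-step prognostic-factor
#' analysis.
#'
#' @param os_months,os_event survival outcome per sample.
#' @param covariates data.frame of candidate covariates.
#' @param screen_p univariate inclusion threshold (default 0.1).
#' @return list with \code{univariate} (one \code{cox_fit} per covariate),
#'   \code{selected} (names) and \code{multivariate} (a \code{cox_fit}, or
#'   NULL when fewer than one covariate passes the screen).
#' @export
cox_screen <- function(os_months, os_event, covariates, screen_p = 0.1) {
  covariates <- as.data.frame(covariates)
  uni <- lapply(names(covariates), function(nm) {
    cox_fit(os_months, os_event, covariates[, nm, drop = FALSE])
  })
  names(uni) <- names(covariates)
  pmin_of <- vapply(uni, function(f) min(f$coefficients$p_value), numeric(1L))
  selected <- names(covariates)[pmin_of < screen_p]
  multi <- if (length(selected) >= 1L)
    cox_fit(os_months, os_event, covariates[, selected, drop = FALSE]) else NULL
  list(univariate = uni, selected = selected, multivariate = multi)
}
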