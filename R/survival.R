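# Survival stratification: Kaplan-Meier, log-rank, restricted mean survival
# time, Cox proportional hazards, and the maximally selected log-rank
# cutpoint search. The product-limit estimator, log-rank test and Cox fit
# are delegated to the survival package; RMST and the cutpoint scan are
# computed here from the fitted curves.

.check_survival_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("at least one survival record is required")
  }
  if (!all(c("time", "event") %in% names(records))) {
    stop("records must carry 'time' and 'event' columns")
  }
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("survival times must be positive")
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (cancer-related death)")
  }
  invisible(TRUE)
}

#' Censor non-cancer deaths
#'
#' Overall survival counts only cancer-related deaths as events; patients
#' who died of other causes are censored at their last known time. Records
#' with `event == 1` and a `death_cause` other than `"cancer"` are converted
#' to censored.
#'
#' @param records Clinical data frame with `time`, `event` and (optionally)
#'   `death_cause` columns.
#' @return The records with non-cancer deaths censored.
#' @export
censor_noncancer_deaths <- function(records) {
  if ("death_cause" %in% names(records)) {
    flip <- records$event == 1 & !is.na(records$death_cause) &
      records$death_cause != "cancer"
    records$event[flip] <- 0
  }
  records
}

#' Kaplan-Meier estimate of the survivor function
#'
#' Product-limit estimator; censorings tied with event times are handled by
#' the standard convention that events precede censorings at the same time.
#'
#' @param records Data frame with `time` (months) and `event` (1 = death,
#'   0 = censored) columns.
#' @return Object of class `km_curve`: data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` at each observed time.
#' @export
km_estimate <- function(records) {
  .check_survival_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, final S(t) = %.3f\n",
              nrow(x), if (nrow(x) > 0) x$surv[nrow(x)] else 1))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival distributions
#' over the pooled risk sets; p-value from the chi-square distribution with
#' one degree of freedom.
#'
#' @param group_a,group_b Data frames of survival records (see
#'   [km_estimate()]).
#' @return List with `chisq`, `p_value`, `n` (per-group sizes), `obs` and
#'   `exp` (observed and expected event counts per group).
#' @export
logrank_test <- function(group_a, group_b) {
  .check_survival_records(group_a)
  .check_survival_records(group_b)
  d <- rbind(data.frame(time = group_a$time, event = group_a$event, g = "a"),
             data.frame(time = group_b$time, event = group_b$event, g = "b"))
  if (sum(d$event) == 0) stop("log-rank test undefined with zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.vector(sd$n), obs = as.vector(sd$obs), exp = as.vector(sd$exp))
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier step function on `[0, tau]`. When the last
#' observed time precedes `tau` the curve is extended flat at its last
#' value.
#'
#' @param records Survival records (see [km_estimate()]).
#' @param tau Horizon in months (e.g. 24 and 36 for 2- and 3-year RMST).
#' @return RMST in months.
#' @examples
#' rmst(data.frame(time = c(1, 2), event = c(1, 0)), tau = 2)  # 1.5
#' @export
rmst <- function(records, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop("tau must be a positive horizon")
  }
  km <- km_estimate(records)
  times <- c(0, km$time[km$time <= tau], tau)
  surv <- c(1, km$surv[km$time <= tau])
  sum(diff(times) * surv)
}

#' @rdname rmst
#' @param group_a,group_b Survival records for the two groups.
#' @return `rmst_difference()` returns RMST(a) - RMST(b) in months.
#' @export
rmst_difference <- function(group_a, group_b, tau) {
  rmst(group_a, tau) - rmst(group_b, tau)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with the Efron correction for tied
#' event times by Newton iteration (convergence when the log-likelihood
#' changes by less than 1e-9, at most 100 iterations). Hazard ratios, Wald
#' 95% confidence intervals and p-values are reported per covariate.
#'
#' @param records Survival records including the covariate columns.
#' @param covariates Character vector of covariate column names (factors or
#'   numeric).
#' @return Object of class `cox_fit`: data frame `table` (term, hr, lower,
#'   upper, p_value, log_hr, se), `loglik` (log partial likelihood at the
#'   solution), `converged`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(records, covariates) {
  .check_survival_records(records)
  if (length(covariates) == 0 || !all(covariates %in% names(records))) {
    stop("covariates must name columns of the records")
  }
  for (cv in covariates) {
    if (length(unique(records[[cv]])) < 2) {
      stop("covariate '", cv, "' is constant")
    }
  }
  if (sum(records$event) == 0) stop("at least one event is required")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  tab <- data.frame(term = names(beta),
                    hr = exp(beta),
                    lower = exp(beta - z * se),
                    upper = exp(beta + z * se),
                    p_value = 2 * stats::pnorm(-abs(beta / se)),
                    log_hr = beta, se = se,
                    row.names = NULL, stringsAsFactors = FALSE)
  converged <- !warned && all(is.finite(beta)) && all(is.finite(se))
  structure(list(table = tab, loglik = fit$loglik[2], converged = converged,
                 n = fit$n, n_event = fit$nevent, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Efron ties): n = %d, events = %d\n",
              x$n, x$n_event))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-24s HR %.2f (%.2f-%.2f)  p = %.3g\n", tab$term[i],
                tab$hr[i], tab$lower[i], tab$upper[i], tab$p_value[i]))
  }
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$table$log_hr, object$table$term)
}

#' Maximally selected log-rank cutpoint search
#'
#' Exhaustive scan over admissible dichotomizations of a continuous (or
#' count-valued) biomarker: candidate cutoffs are the midpoints between
#' consecutive distinct observed values whose induced High/Low split leaves
#' both groups at least `min_group_fraction` of the cohort; for each
#' candidate the two-group log-rank statistic is computed, and the candidate
#' maximizing it is returned (ties broken toward the smaller cutoff). The
#' full scan table is returned so multiplicity corrections can be applied
#' downstream.
#'
#' @param values Numeric biomarker per patient (e.g. TNB in
#'   neoantigens/Mb), aligned with `records` rows.
#' @param records Survival records (see [km_estimate()]).
#' @param min_group_fraction Minimum fraction of patients per group
#'   (default 0.10).
#' @return Object of class `cutpoint_result`: `cutoff`, `statistic`
#'   (log-rank chi-square at the cutoff), `p_value` (unadjusted), `n_high`,
#'   `n_low`, and `scan` (data frame over all candidates).
#' @export
search_survival_cutpoint <- function(values, records,
                                     min_group_fraction = 0.10) {
  .check_survival_records(records)
  if (length(values) != nrow(records)) {
    stop("values must align with the survival records")
  }
  if (any(!is.finite(values))) stop("biomarker values must be finite")
  if (sum(records$event) == 0) stop("at least one event is required")
  v <- sort(unique(values))
  if (length(v) < 2) stop("constant biomarker: no admissible split")
  n <- length(values)
  min_size <- ceiling(min_group_fraction * n)
  cand <- (v[-length(v)] + v[-1]) / 2
  scan <- lapply(cand, function(cut) {
    high <- values >= cut
    if (sum(high) < min_size || sum(!high) < min_size) return(NULL)
    lr <- tryCatch(logrank_test(records[high, , drop = FALSE],
                                records[!high, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(lr)) return(NULL)
    data.frame(cutoff = cut, statistic = lr$chisq,
               n_high = sum(high), n_low = sum(!high))
  })
  scan <- do.call(rbind, scan)
  if (is.null(scan) || nrow(scan) == 0) {
    stop("no admissible split at min_group_fraction = ", min_group_fraction)
  }
  best <- which.max(scan$statistic)  # which.max takes the first = smaller cutoff
  structure(list(cutoff = scan$cutoff[best], statistic = scan$statistic[best],
                 p_value = stats::pchisq(scan$statistic[best], df = 1,
                                         lower.tail = FALSE),
                 n_high = scan$n_high[best], n_low = scan$n_low[best],
                 scan = scan),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(paste0("Maximally selected log-rank cutpoint: %.4g ",
                     "(chi-square %.3f, unadjusted p = %.3g)\n"),
              x$cutoff, x$statistic, x$p_value))
  cat(sprintf("  groups: %d High / %d Low; %d candidates scanned\n",
              x$n_high, x$n_low, nrow(x$scan)))
  invisible(x)
}

#' Read a clinical/survival table
#'
#' TSV with header columns `sample_id`, `time_months`, `event`,
#' `death_cause`, `age_group`, `sex`, `stage`, `n_status`,
#' `differentiation`, `chemotherapy`. Non-cancer deaths are converted to
#' censored observations (see [censor_noncancer_deaths()]).
#'
#' @param path File path.
#' @param censor_noncancer Convert non-cancer deaths to censored
#'   (default TRUE).
#' @return Data frame with a `time` column (months) and 0/1 `event`.
#' @export
read_clinical <- function(path, censor_noncancer = TRUE) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% names(d))) {
    stop("clinical table must carry columns: ", paste(need, collapse = ", "))
  }
  d$time <- d$time_months
  if (censor_noncancer) d <- censor_noncancer_deaths(d)
  d
}
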