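srec <- function(time, event) data.frame(time = time, event = event)

test_that("Kaplan-Meier estimator matches hand product-limit values", {
  # all censored: survival stays at 1
  km0 <- km_estimate(srec(c(3, 5, 9), c(0, 0, 0)))
  expect_true(all(km0$surv == 1))

  # {1 event, 2 censored}: S = 1 before t=1, 0.5 from t=1 on
  km1 <- km_estimate(srec(c(1, 2), c(1, 0)))
  expect_equal(km1$surv[km1$time == 1], 0.5)

  # duplicating every record leaves the curve unchanged
  set.seed(21)
  d <- srec(rexp(30, 0.1), rbinom(30, 1, 0.7))
  expect_equal(km_estimate(d)$surv, km_estimate(rbind(d, d))$surv)

  # with no censoring the KM curve is the empirical survivor function
  dd <- srec(c(2, 4, 4, 7, 10), c(1, 1, 1, 1, 1))
  km <- km_estimate(dd)
  expect_equal(km$surv, c(4 / 5, 2 / 5, 1 / 5, 0))
  expect_true(all(diff(km$surv) <= 0) && all(km$surv >= 0 & km$surv <= 1))

  expect_error(km_estimate(srec(c(1, -2), c(1, 0))), "positive")
})

test_that("log-rank statistic matches direct risk-set tabulation", {
  a <- srec(c(2, 4, 6), c(1, 1, 0))
  b <- srec(c(1, 3, 5), c(1, 0, 1))
  lr <- logrank_test(a, b)
  expect_equal(lr$chisq,
               logrank_oracle(a$time, a$event, b$time, b$event),
               tolerance = 1e-10)

  # symmetry under label swap
  lr_swap <- logrank_test(b, a)
  expect_equal(lr$chisq, lr_swap$chisq, tolerance = 1e-12)

  # identical groups: statistic 0, p = 1
  lr_same <- logrank_test(a, a)
  expect_equal(lr_same$chisq, 0, tolerance = 1e-12)
  expect_equal(lr_same$p_value, 1, tolerance = 1e-9)

  # larger instances against the oracle
  set.seed(31)
  for (rep in 1:5) {
    ga <- srec(round(rexp(8, 0.2), 2) + 0.1, rbinom(8, 1, 0.8))
    gb <- srec(round(rexp(9, 0.4), 2) + 0.1, rbinom(9, 1, 0.8))
    if (sum(ga$event) + sum(gb$event) == 0) next
    expect_equal(logrank_test(ga, gb)$chisq,
                 logrank_oracle(ga$time, ga$event, gb$time, gb$event),
                 tolerance = 1e-8)
  }

  expect_error(logrank_test(srec(1, 0), srec(2, 0)), "zero events")
})

test_that("RMST is the area under the KM step function", {
  # no events before tau: RMST = tau
  expect_equal(rmst(srec(c(30, 40), c(0, 0)), tau = 24), 24)
  # hand integral: 1 x 1 + 0.5 x 1 = 1.5 months at tau = 2
  expect_equal(rmst(srec(c(1, 2), c(1, 0)), tau = 2), 1.5)
  # identical groups: difference 0
  d <- srec(c(1, 3, 5, 7), c(1, 0, 1, 0))
  expect_equal(rmst_difference(d, d, tau = 6), 0)
  # RMST <= tau and monotone non-decreasing in tau
  set.seed(41)
  dd <- srec(rexp(40, 0.05), rbinom(40, 1, 0.6))
  taus <- c(6, 12, 24, 36)
  vals <- vapply(taus, function(t) rmst(dd, t), numeric(1))
  expect_true(all(vals <= taus))
  expect_true(all(diff(vals) >= 0))
  expect_error(rmst(d, tau = -1), "tau")
})

test_that("Cox log-HR matches a grid search of the Efron partial likelihood", {
  # 8-patient toy with tied event times
  d <- data.frame(time = c(2, 2, 3, 5, 6, 8, 9, 12),
                  event = c(1, 1, 0, 1, 1, 0, 1, 1),
                  x = c(1, 1, 0, 1, 0, 1, 0, 0))
  fit <- cox_fit(d, "x")
  grid <- seq(-3, 3, by = 5e-4)
  ll <- vapply(grid, function(b) efron_loglik(b, d$time, d$event, d$x),
               numeric(1))
  expect_equal(unname(coef(fit)["x"]), grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("a null covariate yields HR ~ 1 and constant covariates are rejected", {
  set.seed(51)
  d <- data.frame(time = rep(round(rexp(30, 0.1), 2) + 0.1, 2),
                  event = rep(rbinom(30, 1, 0.8), 2),
                  g = rep(c(0, 1), each = 30))
  fit <- cox_fit(d, "g")
  expect_equal(unname(fit$table$hr), 1, tolerance = 1e-6)
  d$g <- 1
  expect_error(cox_fit(d, "g"), "constant")
})

test_that("Cox recovers generator effects on a synthetic cohort", {
  cfg <- cohort_config(n_patients = 300, seed = 71,
                       tmb_lognormal_mu = log(1), variants_per_patient = 30,
                       immunogenic_fraction = 0.15,
                       log_hr_map = c(age_gt65 = log(4.5), female = log(2.68),
                                      n3 = log(4.32), tnb_high = log(3)))
  gt <- generate_cohort(cfg, withr::local_tempdir())
  clin <- read_clinical(gt$paths$clinical)
  clin$age65 <- as.integer(clin$age_group == ">65")
  clin$tnbh <- as.integer(clin$tnb_true_group == "High")
  fit <- cox_fit(clin, c("age65", "tnbh"))
  tab <- fit$table
  # the fitted log hazard ratios recover the truth within 2 standard errors
  expect_lt(abs(tab$log_hr[tab$term == "age65"] - log(4.5)),
            2 * tab$se[tab$term == "age65"])
  expect_lt(abs(tab$log_hr[tab$term == "tnbh"] - log(3.0)),
            2 * tab$se[tab$term == "tnbh"])
})

test_that("cutpoint search equals an exhaustive independent re-scan", {
  set.seed(61)
  n <- 60
  bio <- sample(0:8, n, replace = TRUE)
  rec <- srec(round(rexp(n, 0.05 * ifelse(bio > 4, 2, 1)), 2) + 0.1,
              rbinom(n, 1, 0.8))
  res <- search_survival_cutpoint(bio, rec, min_group_fraction = 0.10)
  # independent re-scan over every admissible midpoint
  v <- sort(unique(bio))
  cands <- (v[-length(v)] + v[-1]) / 2
  stats <- vapply(cands, function(cut) {
    hi <- bio >= cut
    if (min(sum(hi), sum(!hi)) < ceiling(0.10 * n)) return(NA_real_)
    logrank_oracle(rec$time[hi], rec$event[hi],
                   rec$time[!hi], rec$event[!hi])
  }, numeric(1))
  expect_equal(res$statistic, max(stats, na.rm = TRUE), tolerance = 1e-8)
  expect_equal(res$cutoff, cands[which.max(stats)])
  expect_equal(nrow(res$scan), sum(!is.na(stats)))
  # ties break toward the smaller cutoff by construction (first maximum)
  expect_true(res$cutoff %in% cands)
})

test_that("cutpoint search handles forced and degenerate candidate sets", {
  rec <- srec(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 1, 0))
  res <- search_survival_cutpoint(c(0, 0, 0, 1, 1, 1), rec,
                                  min_group_fraction = 0.1)
  expect_equal(res$cutoff, 0.5)  # single admissible midpoint
  expect_error(search_survival_cutpoint(rep(2, 6), rec), "constant")
  expect_error(search_survival_cutpoint(c(0, 0, 0, 1, 1, 1),
                                        srec(1:6, rep(0, 6))), "event")
})

test_that("cutpoint search recovers a known threshold effect", {
  set.seed(81)
  n <- 200
  bio <- rpois(n, 4)
  hazard <- 0.03 * ifelse(bio > 5, 2, 1)  # hazard doubles above 5
  rec <- srec(pmin(round(rexp(n, hazard), 2) + 0.01, 44), rep(1, n))
  rec$event[rec$time >= 44] <- 0
  res <- search_survival_cutpoint(bio, rec)
  # chosen cutoff within one candidate step of the true threshold (5.5)
  cands <- sort(res$scan$cutoff)
  truth_idx <- which.min(abs(cands - 5.5))
  chosen_idx <- which(cands == res$cutoff)
  expect_lte(abs(chosen_idx - truth_idx), 1)
})

test_that("non-cancer deaths are censored when reading clinical tables", {
  d <- data.frame(sample_id = c("A", "B", "C"), time_months = c(5, 8, 11),
                  event = c(1, 1, 0),
                  death_cause = c("cancer", "noncancer", NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- read_clinical(path)
  expect_equal(clin$event, c(1, 0, 0))
  expect_equal(read_clinical(path, censor_noncancer = FALSE)$event,
               c(1, 1, 0))
})
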