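test_that("learning/test split partitions employees, never episodes", {
  x <- toy_cohort()
  sp <- split_learning_test(x, 2 / 3, seed = 1)
  ids_l <- unique(sp$learning$subject_id)
  ids_t <- unique(sp$test$subject_id)
  expect_equal(length(ids_l), 2L)  # 3 employees at 2/3 -> 2 learning, 1 test
  expect_equal(length(ids_t), 1L)
  expect_length(intersect(ids_l, ids_t), 0)
  expect_setequal(c(ids_l, ids_t), unique(x$subject_id))
  # an employee's episodes never straddle the split
  for (id in ids_l)
    expect_equal(sum(sp$learning$subject_id == id), sum(x$subject_id == id))
  expect_equal(nrow(sp$learning) + nrow(sp$test), nrow(x))
  # deterministic given seed
  sp2 <- split_learning_test(x, 2 / 3, seed = 1)
  expect_identical(as.data.frame(sp$learning), as.data.frame(sp2$learning))
})

test_that("LRT handles identity, nesting and refusal correctly", {
  sim <- simulate_cohort(simulation_design(n_subjects = 400, seed = 17))
  x <- sim$cohort
  cv <- c("male", "age_c")
  fe <- fit_model(hazard_spec("exponential", covariates = cv), x)
  fw <- fit_model(hazard_spec("weibull", covariates = cv), x)
  f12 <- fit_model(hazard_spec("pem", piece_grid(12), covariates = cv), x)
  f19 <- fit_model(hazard_spec("pem", piece_grid(19), covariates = cv), x)

  same <- lrt(fe, fe)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  r <- lrt(fe, fw)
  expect_equal(r$df, fw$n_params - fe$n_params)  # one extra shape parameter
  expect_equal(r$df, 1)
  expect_gte(r$statistic, 0)
  expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE))

  expect_error(lrt(fw, f12), "not nested")
  expect_error(lrt(f12, f19), "not nested")
  # reversed arguments (alt worse than null) signal a fitting failure
  expect_error(lrt(fw, fe), "not nested|below")
})

test_that("BIC and Bayes factors do the textbook arithmetic", {
  fake <- function(ll, k) structure(list(loglik = ll, n_params = k,
                                         n_events = 50, n_subjects = 50,
                                         spec = hazard_spec("exponential")),
                                    class = "hazard_fit")
  expect_equal(BIC(fake(-100, 2), n = 50), 200 + 2 * log(50))
  expect_gt(BIC(fake(-105, 2), n = 50), BIC(fake(-100, 2), n = 50))
  a <- fake(-100, 2); b <- fake(-101, 2)
  expect_equal(bayes_factor(a, a), 1)
  expect_equal(bayes_factor(a, b) * bayes_factor(b, a), 1)
  # delta BIC of -2 in favour of a -> BF = e
  expect_equal(bayes_factor(a, b, n = 50), exp(1))
})

test_that("Kaplan-Meier product-limit matches hand computation", {
  co <- cohort(data.frame(subject_id = c("a", "b", "c"), job_id = "j", entry = 0,
                          exit = c(1, 2, 3), event = 1L, censor_reason = "event"))
  km <- km_curve(co)
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))

  allc <- cohort(data.frame(subject_id = c("a", "b"), job_id = "j", entry = 0,
                            exit = c(5, 7), event = 0L, censor_reason = "admin_end"))
  expect_true(all(km_curve(allc)$curve$surv == 1))

  # mixed censoring, by hand: events at 1 (4 at risk) and 3 (2 at risk)
  mx <- cohort(data.frame(subject_id = letters[1:4], job_id = "j", entry = 0,
                          exit = c(1, 2, 3, 4), event = c(1L, 0L, 1L, 0L),
                          censor_reason = c("event", "job_change", "event", "admin_end")))
  kmx <- km_curve(mx)
  s <- kmx$curve$surv[match(c(1, 3), kmx$curve$time)]
  expect_equal(s, c(3 / 4, 3 / 4 * 1 / 2))
})

test_that("comparison tables refuse the two two-piece models and flag nesting", {
  sim <- simulate_cohort(simulation_design(n_subjects = 500, seed = 23))
  x <- sim$cohort
  fits <- list(
    exponential = fit_model(hazard_spec("exponential", covariates = "male"), x),
    weibull = fit_model(hazard_spec("weibull", covariates = "male"), x),
    pem12 = fit_model(hazard_spec("pem", piece_grid(12), covariates = "male"), x),
    pem19 = fit_model(hazard_spec("pem", piece_grid(19), covariates = "male"), x))
  ct <- compare_models(fits)
  pr <- ct$pairs
  two_piece <- pr[pr$model_a == "pem12" & pr$model_b == "pem19", ]
  expect_equal(two_piece$relation, "not_compared")
  expect_true(is.na(two_piece$lrt_statistic) && is.na(two_piece$bayes_factor_ab))
  wb <- pr[pr$model_a == "weibull" & pr$model_b == "pem12", ]
  expect_equal(wb$relation, "non_nested")
  expect_true(is.na(wb$lrt_statistic))
  expect_false(is.na(wb$bayes_factor_ab))
  nested <- pr[pr$model_a == "exponential", ]
  expect_true(all(nested$relation == "nested"))
  expect_true(all(nested$lrt_statistic >= 0))
})

test_that("the 5-step pipeline runs end to end, deterministically", {
  des <- simulation_design(n_subjects = 900, seed = 31,
                           missingness = mar_spec(target_fraction = 0.4))
  x <- simulate_cohort(des)$cohort
  cfg <- pipeline_config(covariates = c("male", "phys_demand", "union", "smelter"),
                         candidates = seq(4, 32, by = 4), bootstrap_B = 4,
                         bootstrap_size = 400, mi_m = 2, mi_iterations = 3, seed = 5)
  res <- run_selection_pipeline(x, cfg)
  expect_s3_class(res$comparison, "comparison_table")
  expect_equal(sort(res$comparison$models$model),
               sort(c("exponential", "weibull", "pem_fixed", "pem_data_driven")))
  expect_s3_class(res$final$cc$fixed, "hazard_fit")
  expect_true(res$final$cc$fixed$spec$frailty)
  expect_s3_class(res$final$mi$fixed, "pooled_fit")
  # the data-driven cut used on the test set comes from the learning set only
  expect_equal(res$changepoint$tau_hat,
               profile_changepoint(
                 pemfrail:::subset_subjects(
                   cohort(as.data.frame(x)[!is.na(x$phys_demand), ],
                          covariates = covariate_names(x), validate = FALSE),
                   unique(res$split$learning$subject_id)),
                 candidates = seq(4, 32, by = 4),
                 covariates = cfg$covariates)$tau_hat)
  # determinism
  res2 <- run_selection_pipeline(x, cfg)
  expect_identical(res$changepoint$tau_hat, res2$changepoint$tau_hat)
  expect_identical(res$bootstrap$replicates, res2$bootstrap$replicates)
  expect_identical(coef(res$final$cc$fixed), coef(res2$final$cc$fixed))
  expect_identical(res$final$mi$fixed$table$estimate, res2$final$mi$fixed$table$estimate)

  # without missingness the MI path is skipped and CC is the full-data fit
  des0 <- simulation_design(n_subjects = 400, seed = 32)
  x0 <- simulate_cohort(des0)$cohort
  cfg0 <- pipeline_config(covariates = "male", candidates = seq(4, 32, by = 4),
                          bootstrap_B = 2, bootstrap_size = 200, seed = 5)
  res0 <- run_selection_pipeline(x0, cfg0)
  expect_null(res0$final$mi)
  full_fit <- fit_model(hazard_spec("pem", piece_grid(cfg0$fixed_cut),
                                    covariates = "male", frailty = TRUE), x0)
  expect_equal(coef(res0$final$cc$fixed), coef(full_fit))
})
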