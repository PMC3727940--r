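test_that("exponential MLE is the closed form events / person-time", {
  x <- toy_cohort()
  f <- fit_model(hazard_spec("exponential"), x)
  d <- sum(x$event); E <- sum(x$exit - x$entry)
  expect_equal(exp(unname(coef(f)[1])), d / E, tolerance = 1e-12)
  expect_equal(f$loglik, d * log(d / E) - d, tolerance = 1e-12)
  # score at the MLE is exactly zero: d - lambda_hat * E
  expect_equal(d - exp(coef(f)[[1]]) * E, 0)
})

test_that("single-episode log-likelihood matches the hand-computed closed form", {
  co <- cohort(data.frame(subject_id = "s", job_id = "j", entry = 0, exit = 10,
                          event = 1, censor_reason = "event"))
  expect_equal(loglik_independence(hazard_spec("exponential"), log(0.1), co),
               log(0.1) - 1.0)
})

test_that("nesting identities hold exactly on random fixtures", {
  for (seed in 1:5) {
    x <- rand_int_cohort(n_subjects = 30, seed = seed)
    lam <- runif(1, 0.005, 0.05)
    b <- rnorm(1, 0, 0.3)
    spec_e <- hazard_spec("exponential", covariates = "x1")
    ll_e <- loglik_independence(spec_e, c(log(lam), b), x)
    # Weibull at shape 1 is the exponential
    ll_w <- loglik_independence(hazard_spec("weibull", covariates = "x1"),
                                c(log(lam), 0, b), x)
    expect_equal(ll_w, ll_e, tolerance = 1e-12)
    # pem with equal piece rates is the exponential
    ll_p <- loglik_independence(hazard_spec("pem", piece_grid(c(6, 24)), covariates = "x1"),
                                c(log(lam), 0, 0, b), x)
    expect_equal(ll_p, ll_e, tolerance = 1e-12)
  }
})

test_that("Poisson-equivalence and direct maximization agree", {
  des <- simulation_design(n_subjects = 600, seed = 15)
  x <- simulate_cohort(des)$cohort
  spec <- hazard_spec("pem", piece_grid(12), covariates = c("male", "age_c"))
  fp <- fit_model(spec, x, method = "poisson")
  fd <- fit_model(spec, x, method = "direct")
  expect_lt(max(abs(coef(fp) - coef(fd))), 1e-6)
  expect_equal(fp$loglik, fd$loglik, tolerance = 1e-8)
  # no-covariate closed form: exp(intercepts) reproduce d_k / E_k
  rows <- split_at_cuts(x, piece_grid(12))
  f0 <- fit_pem_poisson(rows, covariates = character(0))
  dk <- tapply(rows$events, rows$piece, sum)
  Ek <- tapply(rows$exposure, rows$piece, sum)
  expect_equal(exp(coef(f0)[["log_lambda"]]), dk[[2]] / Ek[[2]], tolerance = 1e-12)
  expect_equal(exp(coef(f0)[["log_lambda"]] + coef(f0)[["piece_0_12"]]),
               dk[[1]] / Ek[[1]], tolerance = 1e-12)
})

test_that("exponential and Weibull fits agree with an independent implementation", {
  skip_if_not_installed("flexsurv")
  # single-episode cohort so the reference implementation sees the same data
  set.seed(21)
  n <- 800
  tt <- rweibull(n, shape = 1.4, scale = 30)
  cens <- runif(n, 5, 60)
  df <- data.frame(subject_id = paste0("s", 1:n), job_id = "j1", entry = 0,
                   exit = pmin(tt, cens), event = as.integer(tt <= cens),
                   censor_reason = ifelse(tt <= cens, "event", "admin_end"),
                   male = rbinom(n, 1, 0.5))
  x <- cohort(df)
  fw <- fit_model(hazard_spec("weibull", covariates = "male"), x)
  ref <- flexsurv::flexsurvreg(survival::Surv(exit, event) ~ male, data = df,
                               dist = "weibullPH")
  # flexsurv weibullPH: h(t) = shape * scale * t^(shape-1); ours: lambda p t^(p-1)
  expect_equal(exp(coef(fw)[["log_shape"]]), ref$res["shape", "est"], tolerance = 1e-4)
  expect_equal(exp(coef(fw)[["log_lambda"]]), ref$res["scale", "est"], tolerance = 1e-4)
  expect_equal(coef(fw)[["male"]], ref$res["male", "est"], tolerance = 1e-4)
  expect_equal(fw$loglik, ref$loglik, tolerance = 1e-6)

  fe <- fit_model(hazard_spec("exponential", covariates = "male"), x)
  refe <- flexsurv::flexsurvreg(survival::Surv(exit, event) ~ male, data = df,
                                dist = "exp")
  expect_equal(fe$loglik, refe$loglik, tolerance = 1e-6)
})

test_that("gamma-frailty likelihood has the right closed form and limit", {
  # single censored subject: ll = -(1/theta) log(1 + theta * Lambda)
  co <- cohort(data.frame(subject_id = "a", job_id = "j", entry = 0, exit = 10,
                          event = 0, censor_reason = "admin_end"))
  th <- 0.7
  expect_equal(loglik_frailty(hazard_spec("exponential", frailty = TRUE),
                              c(log(0.1), th), co),
               -(1 / th) * log1p(th * 1.0))
  # theta -> 0 recovers independence on a 100-subject fixture
  x <- rand_int_cohort(n_subjects = 100, seed = 9)
  ll_ind <- loglik_independence(hazard_spec("exponential"), log(0.02), x)
  ll_fr <- loglik_frailty(hazard_spec("exponential", frailty = TRUE),
                          c(log(0.02), 1e-8), x)
  expect_lt(abs(ll_fr - ll_ind), 1e-4)
  expect_error(loglik_frailty(hazard_spec("exponential", frailty = TRUE),
                              c(log(0.02), 0), x), "theta")
})

test_that("analytic gradients match finite differences", {
  x <- rand_int_cohort(n_subjects = 40, seed = 12)
  for (case in list(
    list(spec = hazard_spec("pem", piece_grid(c(10, 25)), covariates = "x1", frailty = TRUE),
         par = c(log(0.02), 0.2, -0.1, 0.15, log(0.4))),
    list(spec = hazard_spec("weibull", covariates = "x1", frailty = TRUE),
         par = c(log(0.02), 0.1, 0.15, log(0.4))),
    list(spec = hazard_spec("weibull", covariates = "x1", frailty = FALSE),
         par = c(log(0.02), 0.1, 0.15)))) {
    dat <- pemfrail:::prep_loglik_data(case$spec, x)
    g <- pemfrail:::loglik_kernel(case$par, dat, case$spec$frailty)$grad
    fd <- vapply(seq_along(case$par), function(j) {
      h <- 1e-6
      pp <- pm <- case$par
      pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
      (pemfrail:::loglik_kernel(pp, dat, case$spec$frailty, want_grad = FALSE)$value -
         pemfrail:::loglik_kernel(pm, dat, case$spec$frailty, want_grad = FALSE)$value) / (2 * h)
    }, 0)
    expect_equal(unname(g), fd, tolerance = 1e-5)
  }
})

test_that("frailty fits recover theta on simulated data", {
  sim <- simulate_cohort(plain_design(3000, rates = 0.02, theta = 0.5,
                                      admin = 48, seed = 33))
  f <- fit_model(hazard_spec("exponential", frailty = TRUE), sim$cohort)
  expect_true(f$converged)
  th <- frailty_variance(f)
  se_log <- f$se[["log_theta"]]
  expect_lt(abs(log(th) - log(0.5)), 2.5 * se_log)
})

test_that("predicted survival curves have the right form", {
  x <- toy_cohort()
  f <- fit_model(hazard_spec("exponential"), x)
  s <- predict_survival(f, times = c(0, 5, 10))
  expect_equal(s$surv[1], 1)
  # hand-set exponential: S(10) at lambda 0.1 is e^-1
  f2 <- f; f2$par["log_lambda"] <- log(0.1)
  expect_equal(predict_survival(f2, times = 10)$surv, exp(-1))

  # pem curve: continuous, piecewise log-linear with kinks exactly at the cuts
  sim <- simulate_cohort(plain_design(500, rates = c(0.03, 0.01), cuts = 12,
                                      admin = 40, seed = 3))
  fp <- fit_model(hazard_spec("pem", piece_grid(12)), sim$cohort)
  tt <- c(0, 6, 12, 18, 24)
  s2 <- predict_survival(fp, times = tt)
  ls <- log(s2$surv)
  slope1 <- (ls[3] - ls[2]) / 6; slope0 <- (ls[2] - ls[1]) / 6
  slope2 <- (ls[4] - ls[3]) / 6; slope3 <- (ls[5] - ls[4]) / 6
  expect_equal(slope0, slope1, tolerance = 1e-10)
  expect_equal(slope2, slope3, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(slope1, slope2)))

  # population-averaged frailty curve follows (1 + theta Lam)^(-1/theta)
  ff <- fit_model(hazard_spec("exponential", frailty = TRUE), sim$cohort)
  th <- frailty_variance(ff); lam <- exp(coef(ff)[["log_lambda"]])
  expect_equal(predict_survival(ff, times = 10, type = "population")$surv,
               (1 + th * lam * 10)^(-1 / th))
  expect_error(predict_survival(fp, times = 1, covariates = c(bogus = 1)), "not in fit")
})

test_that("hazard-ratio tables do the Wald arithmetic", {
  x <- toy_cohort()
  f <- fit_model(hazard_spec("pem", piece_grid(12), covariates = "male"), x)
  # forge a coefficient with known se to check the arithmetic exactly
  f$par["male"] <- 0; f$se["male"] <- 1
  tab <- hazard_ratio_table(f)
  row <- tab[tab$term == "male", ]
  expect_equal(row$hr, 1)
  expect_equal(row$conf_low, exp(-1.96), tolerance = 1e-12)
  expect_equal(row$conf_high, exp(1.96), tolerance = 1e-12)
  expect_equal(row$p_value, 1)
  # CI width is monotone in the SE
  f$se["male"] <- 2
  tab2 <- hazard_ratio_table(f)
  expect_gt(tab2$conf_high[tab2$term == "male"], row$conf_high)
})

test_that("degenerate fits are flagged, not silent", {
  co <- cohort(data.frame(subject_id = "s", job_id = "j", entry = 0, exit = 10,
                          event = 0, censor_reason = "admin_end"))
  expect_warning(f <- fit_model(hazard_spec("exponential"), co), "zero events")
  expect_true(f$boundary)
  x <- toy_cohort()
  x$male[2] <- NA
  expect_error(fit_model(hazard_spec("exponential", covariates = "male"), x),
               "impute")
})
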