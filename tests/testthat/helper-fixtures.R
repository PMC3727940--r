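# in-code fixtures; nothing is read from disk

toy_cohort <- function() {
  cohort(data.frame(
    subject_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    job_id = c("j1", "j1", "j2", "j1", "j1", "j1"),
    entry = c(0, 8, 0, 0, 14, 0),
    exit = c(8, 20, 30, 14, 25, 40),
    event = c(1L, 0L, 0L, 1L, 1L, 0L),
    censor_reason = c("event", "job_change", "admin_end", "event", "event", "termination"),
    male = c(1, 1, 1, 0, 0, 1),
    age_c = c(-4, -4, -3, 6, 6, 0),
    stringsAsFactors = FALSE))
}

# random integer-month cohort for exact-arithmetic property tests
rand_int_cohort <- function(n_subjects = 20, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    n_ep <- sample(1:3, 1)
    bounds <- sort(sample(0:60, n_ep + 1))
    ev <- rbinom(n_ep, 1, 0.4)
    data.frame(subject_id = paste0("s", i), job_id = "j1",
               entry = bounds[-length(bounds)], exit = bounds[-1],
               event = ev,
               censor_reason = ifelse(ev == 1, "event", "admin_end"),
               x1 = rnorm(n_ep), stringsAsFactors = FALSE)
  })
  cohort(do.call(rbind, rows), covariates = "x1", validate = FALSE)
}

# simple no-covariate design used across tests
plain_design <- function(n, rates, cuts = numeric(0), theta = 0,
                         admin = 60, jc = 0, term = 0, seed = NULL) {
  simulation_design(
    n_subjects = n,
    jobs_per_subject = list(dist = "shifted_poisson", mean = 1),
    true_grid = piece_grid(cuts), true_piece_rates = rates,
    true_beta = c(), frailty_variance = theta,
    covariate_generators = list(),
    censoring = list(job_change_rate = jc, termination_rate = term,
                     death_rate = 0, admin_horizon = admin),
    seed = seed)
}
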