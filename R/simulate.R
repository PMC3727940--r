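#' Default covariate generators for the synthetic cohort
#'
#' Returns the generator specification used by [simulation_design()]:
#' a mostly-male workforce (78%), age centred at the cohort mean and spread
#' like an industrial workforce, plant flags (smelter, union, original
#' founding plant), and a continuous physical-demand score that is higher at
#' union and smelter plants (which is what later makes a complete-case
#' analysis differ from multiple imputation when physical demand goes
#' missing).
#'
#' Each entry is a list with a `type` (`"bernoulli"`, `"normal"`, or
#' `"normal_link"`, the latter a linear combination of previously generated
#' covariates plus Gaussian noise), its parameters, and a `level`
#' (`"subject"` or `"job"`).
#'
#' @return Named list of generator specs.
#' @export
default_covariate_generators <- function() {
  list(
    male = list(type = "bernoulli", p = 0.78, level = "subject"),
    age_c = list(type = "normal", mean = 0, sd = 11.3, level = "subject"),
    smelter = list(type = "bernoulli", p = 0.30, level = "job"),
    union = list(type = "bernoulli", p = 0.45, level = "job"),
    original_plant = list(type = "bernoulli", p = 0.10, level = "job"),
    phys_demand = list(type = "normal_link", sd = 1,
                       depends = c(smelter = 0.5, union = 0.3), level = "job")
  )
}

#' Specify a missing-at-random mechanism for one covariate
#'
#' Missingness is modelled at the job level with a logistic model on fully
#' observed quantities: covariates and/or the reserved outcome summaries
#' `.has_event` (any injury on the job), `.n_events`, and `.log_person_time`.
#' The intercept is calibrated so the expected missing fraction equals
#' `target_fraction`. Because the mechanism depends only on observed data it
#' is MAR; letting it depend on the observed outcome mirrors cohorts in which
#' jobs with injuries are over-represented among those with the covariate
#' measured, which is exactly the situation in which a complete-case analysis
#' is biased while multiple imputation is not.
#'
#' @param variable Name of the covariate to make missing.
#' @param coefficients Named numeric vector of log-odds coefficients on the
#'   conditioning variables (covariate names or reserved outcome summaries).
#' @param target_fraction Target overall missing fraction in `[0, 1)`.
#' @return An object of class `mar_spec`.
#' @export
mar_spec <- function(variable = "phys_demand",
                     coefficients = c(union = -1.5, smelter = -1.5, .has_event = -1),
                     target_fraction = 0.84) {
  stopifnot(is.character(variable), length(variable) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)),
            target_fraction >= 0, target_fraction < 1)
  structure(list(variable = variable, coefficients = coefficients,
                 target_fraction = target_fraction), class = "mar_spec")
}

#' Specify a synthetic occupational-injury cohort
#'
#' Bundles everything the generator needs: cohort size, the jobs-per-worker
#' distribution, the true piecewise-constant baseline hazard, true covariate
#' log-hazard-ratios, the gamma-frailty variance, covariate generators,
#' censoring clocks and an optional MAR missingness mechanism. The defaults
#' emulate a large industrial workforce: ~2.4 jobs per worker, 78% male, a
#' baseline injury hazard that drops by the factor 1.32 after 12 months on
#' the job, hazard ratios of the magnitude typically reported for gender,
#' age, physical demand and plant attributes, and censoring by job change,
#' termination, or an administrative horizon.
#'
#' @param n_subjects Number of workers.
#' @param jobs_per_subject List with `dist = "shifted_poisson"` and `mean`;
#'   the job count is `1 + Poisson(mean - 1)`.
#' @param true_grid A [piece_grid()] for the true baseline hazard.
#' @param true_piece_rates Events per person-month in each piece
#'   (length `true_grid$K`).
#' @param true_beta Named log-hazard-ratios; names must be generated
#'   covariates.
#' @param frailty_variance Gamma frailty variance \eqn{\theta \ge 0} (mean 1).
#' @param covariate_generators See [default_covariate_generators()].
#' @param censoring List with `job_change_rate`, `termination_rate`,
#'   `death_rate` (per month, may be 0) and `admin_horizon` (months).
#' @param missingness Optional [mar_spec()] applied after generation.
#' @param seed Optional integer seed stored in the design.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_subjects = 5000,
                              jobs_per_subject = list(dist = "shifted_poisson", mean = 2.36),
                              true_grid = piece_grid(12),
                              true_piece_rates = c(0.00528, 0.0040),
                              true_beta = c(male = log(0.71), age_c = log(0.99),
                                            phys_demand = log(1.26), smelter = log(1.30),
                                            union = log(1.30), original_plant = log(1.58)),
                              frailty_variance = 0.5,
                              covariate_generators = default_covariate_generators(),
                              censoring = list(job_change_rate = 0.012,
                                               termination_rate = 0.008,
                                               death_rate = 0.0002,
                                               admin_horizon = 144),
                              missingness = NULL,
                              seed = NULL) {
  stopifnot(inherits(true_grid, "piece_grid"),
            length(true_piece_rates) == true_grid$K)
  if (any(!is.finite(true_piece_rates)) || any(true_piece_rates <= 0))
    stop("true_piece_rates must be finite and positive")
  if (!is.finite(frailty_variance) || frailty_variance < 0)
    stop("frailty_variance must be finite and >= 0")
  if (length(true_beta) && !all(names(true_beta) %in% names(covariate_generators)))
    stop("every true_beta name must have a covariate generator")
  for (nm in c("job_change_rate", "termination_rate", "admin_horizon")) {
    if (is.null(censoring[[nm]]) || !is.finite(censoring[[nm]]) || censoring[[nm]] < 0)
      stop("censoring$", nm, " must be finite and >= 0")
  }
  if (is.null(censoring$death_rate)) censoring$death_rate <- 0
  if (!is.null(missingness) && !inherits(missingness, "mar_spec"))
    stop("missingness must be a mar_spec or NULL")
  structure(list(n_subjects = as.integer(n_subjects),
                 jobs_per_subject = jobs_per_subject,
                 true_grid = true_grid, true_piece_rates = true_piece_rates,
                 true_beta = true_beta, frailty_variance = frailty_variance,
                 covariate_generators = covariate_generators,
                 censoring = censoring, missingness = missingness, seed = seed),
            class = "simulation_design")
}

draw_covariate <- function(gen, n, existing) {
  switch(gen$type,
    bernoulli = stats::rbinom(n, 1L, gen$p),
    normal = stats::rnorm(n, if (is.null(gen$mean)) 0 else gen$mean, gen$sd),
    normal_link = {
      mu <- if (is.null(gen$mean)) 0 else gen$mean
      eta <- rep(mu, n)
      for (v in names(gen$depends)) {
        if (is.null(existing[[v]])) stop("normal_link depends on ungenerated covariate ", v)
        eta <- eta + gen$depends[[v]] * existing[[v]]
      }
      eta + stats::rnorm(n, 0, gen$sd)
    },
    stop("unknown covariate generator type: ", gen$type))
}

#' Simulate a recurrent-injury cohort
#'
#' Draws a cohort from a [simulation_design()]: a shared gamma frailty per
#' worker (mean 1, variance \eqn{\theta}), covariates at subject or job
#' level, a censoring time per job as the earliest of independent exponential
#' job-change/termination/death clocks and the administrative horizon, and
#' recurrent injury times from an inhomogeneous Poisson process with
#' intensity \eqn{u \exp(x'\beta)\,\lambda_0(t)} on the job clock (inversion
#' of the piecewise-linear cumulative hazard). Episodes are emitted in
#' counting-process form; a worker re-enters risk immediately after each
#' injury.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed (defaults to `design$seed`). The run is
#'   deterministic given the seed.
#' @return List with `cohort` (a [cohort()]) and `truth` (a `truth_record`:
#'   the design echoed plus per-subject frailty draws).
#' @examples
#' sim <- simulate_cohort(simulation_design(n_subjects = 200, seed = 1))
#' sim$cohort
#' @export
simulate_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  theta <- design$frailty_variance
  cuts <- design$true_grid$cuts
  rates <- design$true_piece_rates

  u <- if (theta > 0) stats::rgamma(n, shape = 1 / theta, scale = theta) else rep(1, n)
  names(u) <- paste0("s", seq_len(n))

  n_jobs <- 1L + stats::rpois(n, max(design$jobs_per_subject$mean - 1, 0))
  subj <- rep(seq_len(n), n_jobs)
  J <- length(subj)
  job_seq <- sequence(n_jobs)

  # covariates: subject-level generators drawn once per subject, job-level per job
  covs <- list()
  for (nm in names(design$covariate_generators)) {
    gen <- design$covariate_generators[[nm]]
    if (identical(gen$level, "subject")) {
      val <- draw_covariate(gen, n, lapply(covs, function(v) v[match(seq_len(n), subj)]))
      covs[[nm]] <- val[subj]
    } else {
      covs[[nm]] <- draw_covariate(gen, J, covs)
    }
  }

  # censoring: competing exponential clocks truncated at the admin horizon
  cens <- design$censoring
  rclock <- function(rate) if (rate > 0) stats::rexp(J, rate) else rep(Inf, J)
  clocks <- cbind(job_change = rclock(cens$job_change_rate),
                  termination = rclock(cens$termination_rate),
                  death = rclock(cens$death_rate),
                  admin_end = cens$admin_horizon)
  cwhich <- max.col(-clocks, ties.method = "first")
  ctime <- clocks[cbind(seq_len(J), cwhich)]
  creason <- colnames(clocks)[cwhich]
  if (any(!is.finite(ctime))) stop("censoring produced non-finite follow-up; set admin_horizon")

  # covariate-and-frailty multiplier, then event counts and times by inversion
  eta <- rep(0, J)
  for (nm in names(design$true_beta)) eta <- eta + design$true_beta[[nm]] * covs[[nm]]
  mult <- u[subj] * exp(eta)
  lam_tot <- mult * cumhaz_pem(ctime, rates, cuts)
  nev <- stats::rpois(J, lam_tot)

  ev_job <- rep(seq_len(J), nev)
  v <- stats::runif(length(ev_job)) * lam_tot[ev_job]
  o <- order(ev_job, v)
  ev_job <- ev_job[o]
  tev <- invcumhaz_pem(v[o] / mult[ev_job], rates, cuts)
  # guard against floating-point collisions with the censoring time
  tev <- pmin(tev, ctime[ev_job] * (1 - 1e-12))

  first_in_job <- !duplicated(ev_job)
  ev_entry <- ifelse(first_in_job, 0, c(0, tev[-length(tev)]))
  last_ev <- numeric(J)
  if (length(ev_job)) {
    last_flag <- !duplicated(ev_job, fromLast = TRUE)
    last_ev[ev_job[last_flag]] <- tev[last_flag]
  }

  sid <- paste0("s", subj)
  jid <- paste0("j", job_seq)
  ep <- data.frame(
    subject_id = c(sid[ev_job], sid),
    job_id = c(jid[ev_job], jid),
    entry = c(ev_entry, last_ev),
    exit = c(tev, ctime),
    event = c(rep(1L, length(ev_job)), rep(0L, J)),
    censor_reason = c(rep("event", length(ev_job)), creason),
    stringsAsFactors = FALSE)
  for (nm in names(covs)) ep[[nm]] <- c(covs[[nm]][ev_job], covs[[nm]])
  ep <- ep[ep$exit > ep$entry, , drop = FALSE]
  ep <- ep[order(match(ep$subject_id, paste0("s", seq_len(n))),
                 as.integer(sub("^j", "", ep$job_id)), ep$entry), , drop = FALSE]
  rownames(ep) <- NULL
  co <- cohort(ep, covariates = names(covs), validate = FALSE)

  if (!is.null(design$missingness)) {
    miss_seed <- if (is.null(seed)) NULL else (seed %% 1000003L) + 17L
    co <- inject_missingness(co, design$missingness, seed = miss_seed)
  }
  truth <- structure(list(design = design, frailty = u, seed = seed),
                     class = "truth_record")
  list(cohort = co, truth = truth)
}

# job-level covariate + outcome-summary table used by missingness and imputation
job_table <- function(x) {
  key <- paste(x$subject_id, x$job_id, sep = "\r")
  first <- !duplicated(key)
  jt <- as.data.frame(x)[first, c("subject_id", "job_id", covariate_names(x)), drop = FALSE]
  f <- factor(key, levels = key[first])
  jt$.n_events <- as.numeric(tapply(x$event, f, sum))
  jt$.has_event <- as.numeric(jt$.n_events > 0)
  jt$.log_person_time <- log(as.numeric(tapply(x$exit - x$entry, f, sum)))
  jt$.key <- key[first]
  rownames(jt) <- NULL
  jt
}

#' Inject missing-at-random covariate cells into a cohort
#'
#' Applies a [mar_spec()]: one missingness draw per job (the covariate is a
#' job attribute, so every episode of a missing job loses the value). The
#' logistic intercept is calibrated on the cohort at hand so the expected
#' missing fraction equals the spec's target.
#'
#' @param x A [cohort()].
#' @param spec A [mar_spec()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return The cohort with `NA` injected into the target covariate.
#' @export
inject_missingness <- function(x, spec, seed = NULL) {
  stopifnot(inherits(spec, "mar_spec"))
  if (!spec$variable %in% covariate_names(x))
    stop("covariate not present: ", spec$variable)
  if (spec$target_fraction == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  jt <- job_table(x)
  eta <- rep(0, nrow(jt))
  for (nm in names(spec$coefficients)) {
    if (is.null(jt[[nm]])) stop("conditioning variable not available: ", nm)
    if (anyNA(jt[[nm]])) stop("conditioning variable has missing values: ", nm)
    eta <- eta + spec$coefficients[[nm]] * jt[[nm]]
  }
  a <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - spec$target_fraction,
                      interval = c(-50, 50), tol = 1e-10)$root
  miss <- stats::rbinom(nrow(jt), 1L, stats::plogis(a + eta)) == 1L
  key <- paste(x$subject_id, x$job_id, sep = "\r")
  x[[spec$variable]][key %in% jt$.key[miss]] <- NA_real_
  x
}

#' @export
print.truth_record <- function(x, ...) {
  d <- x$design
  cat("<truth_record>", d$n_subjects, "subjects; theta =", d$frailty_variance, "\n")
  cat("  true piece rates:", paste(signif(d$true_piece_rates, 4), collapse = ", "),
      "with cuts", paste(d$true_grid$cuts, collapse = ", "), "\n")
  if (length(d$true_beta))
    cat("  true HRs:", paste(sprintf("%s=%.3f", names(d$true_beta), exp(d$true_beta)),
                             collapse = ", "), "\n")
  cat("  mean frailty draw:", round(mean(x$frailty), 4), "\n")
  invisible(x)
}
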