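#' Partition a cohort into learning and test sets by employee
#'
#' The split unit is the employee: all of a worker's jobs and episodes land
#' on the same side, so model development on the learning set never sees any
#' test-set information.
#'
#' @param x A [cohort()].
#' @param learn_fraction Fraction of employees in the learning set
#'   (default 2/3).
#' @param seed Integer seed; the partition is deterministic given it.
#' @return List with `learning` and `test` cohorts.
#' @export
split_learning_test <- function(x, learn_fraction = 2 / 3, seed = NULL) {
  stopifnot(learn_fraction > 0, learn_fraction < 1)
  ids <- unique(x$subject_id)
  if (length(ids) < 2L) stop("need at least 2 employees to split")
  if (!is.null(seed)) set.seed(seed)
  n_learn <- min(max(round(learn_fraction * length(ids)), 1L), length(ids) - 1L)
  learn_ids <- sample(ids, n_learn)
  list(learning = subset_subjects(x, learn_ids),
       test = subset_subjects(x, setdiff(ids, learn_ids)))
}

spec_signature <- function(spec) {
  list(family = spec$family, cuts = spec$grid$cuts,
       covariates = sort(spec$covariates), frailty = spec$frailty)
}

# nesting relation between two specs on the same covariates and frailty flag
nesting_relation <- function(null_spec, alt_spec) {
  if (!identical(sort(null_spec$covariates), sort(alt_spec$covariates)) ||
      !identical(null_spec$frailty, alt_spec$frailty)) return("incomparable")
  nf <- null_spec$family; af <- alt_spec$family
  if (nf == af && identical(null_spec$grid$cuts, alt_spec$grid$cuts)) return("identical")
  if (nf == "exponential" && af %in% c("weibull", "pem")) return("nested")
  if (nf == "pem" && af == "pem" &&
      all(null_spec$grid$cuts %in% alt_spec$grid$cuts)) return("nested")
  if (nf == "pem" && af == "pem") return("two_piece_pair")
  "non_nested"
}

#' Likelihood ratio test for nested hazard models
#'
#' Computes \eqn{2(\ell_{alt} - \ell_{null})} with degrees of freedom equal
#' to the difference in parameter counts and a chi-square p-value. The pair
#' must be declared nested (exponential within Weibull, exponential within
#' any piecewise model, or a piecewise model within one whose cuts contain
#' its own); anything else is refused, as the LRT's null distribution is
#' unknown for non-nested pairs.
#'
#' @param null_fit,alt_fit Converged `hazard_fit`s on the same data.
#' @param tol Tolerance for a negative statistic before it is treated as a
#'   fitting failure.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(null_fit, alt_fit, tol = 1e-6) {
  rel <- nesting_relation(null_fit$spec, alt_fit$spec)
  if (!rel %in% c("nested", "identical"))
    stop("models are not nested (", rel, "); use BIC / Bayes factors instead")
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (stat < -tol)
    stop("alternative log-likelihood below the null's (", format(stat / 2),
         "); a fit failed to converge")
  stat <- max(stat, 0)
  df <- alt_fit$n_params - null_fit$n_params
  p <- if (df == 0) {
    if (stat <= tol) 1 else stop("equal parameter counts with unequal likelihoods")
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p)
}

effective_n <- function(fit, which = c("events", "subjects", "rows")) {
  if (is.numeric(which)) return(which)
  switch(match.arg(which),
         events = fit$n_events, subjects = fit$n_subjects, rows = NA_real_)
}

#' Bayesian information criterion of a hazard fit
#'
#' \eqn{BIC = -2\ell + k \log n}. The effective sample size `n` for survival
#' models is taken as the number of events by default (the common
#' convention), with the number of subjects or an explicit numeric value as
#' alternatives.
#'
#' @param object A `hazard_fit`.
#' @param ... Unused.
#' @param n `"events"` (default), `"subjects"`, or a number.
#' @return The BIC value (smaller is better).
#' @export
BIC.hazard_fit <- function(object, ..., n = "events") {
  nn <- if (is.numeric(n)) n else effective_n(object, n)
  -2 * object$loglik + object$n_params * log(nn)
}

#' Schwarz-approximate Bayes factor between two fits
#'
#' \eqn{BF_{ab} = \exp(-(BIC_a - BIC_b)/2)}: values above 1 favour model
#' `a`. Used for non-nested comparisons (e.g. Weibull versus two-piece
#' exponential) where the LRT does not apply.
#'
#' @param fit_a,fit_b `hazard_fit`s on the same data.
#' @param n Effective sample size passed to [BIC.hazard_fit()].
#' @return The Bayes factor in favour of `fit_a`.
#' @export
bayes_factor <- function(fit_a, fit_b, n = "events") {
  exp(-(BIC(fit_a, n = n) - BIC(fit_b, n = n)) / 2)
}

#' Kaplan-Meier injury-free curve with log-log diagnostic
#'
#' Product-limit estimate of the injury-free probability on the job clock,
#' computed from the counting-process episodes (left truncation at each
#' episode's entry). Also emits the \eqn{(\log t, \log(-\log S(t)))} pairs
#' used to gauge a Weibull baseline: under a Weibull hazard they fall on a
#' straight line with slope equal to the shape.
#'
#' @param x A [cohort()].
#' @return Object of class `km_curve`: `curve` (time, n_risk, n_event,
#'   surv), `loglog` (log_time, cloglog).
#' @export
km_curve <- function(x) {
  sf <- survival::survfit(survival::Surv(entry, exit, event) ~ 1,
                          data = as.data.frame(x), id = seq_len(nrow(x)))
  cur <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv)
  keep <- cur$surv > 0 & cur$surv < 1 & cur$time > 0
  structure(list(curve = cur,
                 loglog = data.frame(log_time = log(cur$time[keep]),
                                     cloglog = log(-log(cur$surv[keep])))),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>", nrow(x$curve), "time points;",
      sum(x$curve$n_event), "events\n")
  invisible(x)
}

#' Compare competing baseline-hazard fits
#'
#' Builds the comparison table for a set of fits on the same data: per-model
#' log-likelihood, parameter count and BIC, then pairwise comparisons — LRT
#' for declared-nested pairs, \eqn{\Delta}BIC and Schwarz Bayes factors for
#' non-nested pairs. A pair of two-piece models with different cut points is
#' never compared: the hypothesis-driven and data-driven models address
#' different questions.
#'
#' @param fits Named list of `hazard_fit`s.
#' @param n Effective sample size rule for BIC (see [BIC.hazard_fit()]).
#' @return Object of class `comparison_table` with `models` and `pairs`
#'   data frames.
#' @export
compare_models <- function(fits, n = "events") {
  stopifnot(is.list(fits), length(fits) >= 2L, !is.null(names(fits)))
  models <- data.frame(model = names(fits),
                       family = vapply(fits, function(f) f$spec$family, ""),
                       loglik = vapply(fits, function(f) f$loglik, 0),
                       n_params = vapply(fits, function(f) f$n_params, 0),
                       bic = vapply(fits, BIC, 0, n = n),
                       row.names = NULL, stringsAsFactors = FALSE)
  pairs <- list()
  nmv <- names(fits)
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i >= j) next
    a <- fits[[i]]; b <- fits[[j]]
    rel <- nesting_relation(a$spec, b$spec)
    rel2 <- nesting_relation(b$spec, a$spec)
    row <- data.frame(model_a = nmv[i], model_b = nmv[j],
                      relation = NA_character_, lrt_statistic = NA_real_,
                      df = NA_real_, p_value = NA_real_,
                      delta_bic = NA_real_, bayes_factor_ab = NA_real_,
                      stringsAsFactors = FALSE)
    if (rel == "two_piece_pair" || rel2 == "two_piece_pair") {
      row$relation <- "not_compared"
    } else if (rel == "nested" || rel2 == "nested") {
      row$relation <- "nested"
      lr <- if (rel == "nested") lrt(a, b) else lrt(b, a)
      row$lrt_statistic <- lr$statistic
      row$df <- lr$df
      row$p_value <- lr$p_value
      row$delta_bic <- BIC(a, n = n) - BIC(b, n = n)
      row$bayes_factor_ab <- bayes_factor(a, b, n = n)
    } else if (rel %in% c("non_nested")) {
      row$relation <- "non_nested"
      row$delta_bic <- BIC(a, n = n) - BIC(b, n = n)
      row$bayes_factor_ab <- bayes_factor(a, b, n = n)
    } else {
      row$relation <- rel
    }
    pairs[[length(pairs) + 1L]] <- row
  }
  structure(list(models = models, pairs = do.call(rbind, pairs), n_rule = n),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table> fit statistics:\n")
  print(transform(x$models, loglik = round(loglik, 1), bic = round(bic, 1)),
        row.names = FALSE)
  cat("pairwise comparisons:\n")
  p <- x$pairs
  p$lrt_statistic <- round(p$lrt_statistic, 2)
  p$delta_bic <- round(p$delta_bic, 1)
  p$bayes_factor_ab <- signif(p$bayes_factor_ab, 3)
  print(p, row.names = FALSE)
  invisible(x)
}

#' Configuration for the model-selection pipeline
#'
#' @param covariates Covariates adjusted for in all models.
#' @param learn_fraction Learning-set fraction of employees.
#' @param fixed_cut Hypothesis-driven cut point in months (default 12).
#' @param candidates Candidate grid for the data-driven cut (default: built
#'   from the learning set).
#' @param min_events Feasibility floor per side for the profile.
#' @param bootstrap_B,bootstrap_size Bootstrap replicates and employees per
#'   replicate (Appendix defaults 400 and 10000).
#' @param frailty Fit the final full-cohort models with gamma frailty.
#' @param mi_m,mi_iterations Multiple-imputation settings used when the
#'   cohort has missing covariates.
#' @param effective_n BIC effective-sample-size rule.
#' @param seed Master seed; stage seeds are derived from it and logged.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(covariates = character(0), learn_fraction = 2 / 3,
                            fixed_cut = 12, candidates = NULL, min_events = 5,
                            bootstrap_B = 400, bootstrap_size = 10000,
                            frailty = TRUE, mi_m = 4, mi_iterations = 10,
                            effective_n = "events", seed = 1L) {
  structure(list(covariates = covariates, learn_fraction = learn_fraction,
                 fixed_cut = fixed_cut, candidates = candidates,
                 min_events = min_events, bootstrap_B = bootstrap_B,
                 bootstrap_size = bootstrap_size, frailty = frailty,
                 mi_m = mi_m, mi_iterations = mi_iterations,
                 effective_n = effective_n, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the five-step model-selection pipeline
#'
#' Orchestrates the full protocol: (1) split employees into learning and
#' test sets; (2) estimate the data-driven cut point on the learning set by
#' profile likelihood; (3) bootstrap its variability from the learning set;
#' (4) compare exponential, Weibull and both two-piece models on the
#' held-out test set by LRT (nested pairs) and BIC/Bayes factors
#' (non-nested) — the estimated cut never touches test data before this
#' comparison, which is what keeps the LRT for the data-driven model
#' honest; (5) fit both two-piece models with gamma frailty on the full
#' cohort, as a complete-case analysis and, when covariates are missing, a
#' multiple-imputation analysis pooled by Rubin's rules.
#'
#' When covariates have missing values, the selection-phase fits (steps
#' 2-4) use complete-case episodes; step 5 provides both CC and MI results.
#'
#' @param x A [cohort()].
#' @param config A [pipeline_config()].
#' @return Object of class `selection_pipeline` with elements `split`,
#'   `changepoint`, `bootstrap`, `comparison`, `final` (lists `cc` and
#'   optionally `mi` with `fixed` and `data_driven` fits), `seeds` and
#'   `config`. Stage failures are captured as `error` entries so partial
#'   results survive.
#' @export
run_selection_pipeline <- function(x, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(split = config$seed, bootstrap = config$seed + 1L,
                mi = config$seed + 2L)
  cv <- config$covariates
  has_missing <- length(cv) && anyNA(as.data.frame(x)[, cv])
  cc_of <- function(co) {
    if (!has_missing) return(co)
    ok <- stats::complete.cases(as.data.frame(co)[, cv, drop = FALSE])
    out <- as.data.frame(co)[ok, , drop = FALSE]
    cohort(out, covariates = covariate_names(co), validate = FALSE)
  }
  stage <- function(expr) tryCatch(expr, error = function(e) structure(
    list(error = conditionMessage(e)), class = "pipeline_error"))
  failed <- function(z) inherits(z, "pipeline_error")

  sp <- stage(split_learning_test(x, config$learn_fraction, seed = seeds$split))
  if (failed(sp)) return(structure(list(split = sp, config = config, seeds = seeds),
                                   class = "selection_pipeline"))
  learn_cc <- cc_of(sp$learning)
  test_cc <- cc_of(sp$test)
  candidates <- config$candidates
  if (is.null(candidates)) candidates <- default_candidates(learn_cc)

  cp <- stage(profile_changepoint(learn_cc, candidates = candidates,
                                  covariates = cv, min_events = config$min_events))
  bs <- stage(bootstrap_changepoint(learn_cc, candidates = candidates,
                                    covariates = cv, B = config$bootstrap_B,
                                    sample_size = config$bootstrap_size,
                                    min_events = config$min_events,
                                    seed = seeds$bootstrap))
  cmp <- stage({
    if (failed(cp)) stop("changepoint stage failed: ", cp$error)
    fits <- list(
      exponential = fit_model(hazard_spec("exponential", covariates = cv), test_cc),
      weibull = fit_model(hazard_spec("weibull", covariates = cv), test_cc),
      pem_fixed = fit_model(hazard_spec("pem", piece_grid(config$fixed_cut),
                                        covariates = cv), test_cc),
      pem_data_driven = fit_model(hazard_spec("pem", piece_grid(cp$tau_hat),
                                              covariates = cv), test_cc))
    compare_models(fits, n = config$effective_n)
  })
  final <- stage({
    if (failed(cp)) stop("changepoint stage failed: ", cp$error)
    grids <- list(fixed = piece_grid(config$fixed_cut),
                  data_driven = piece_grid(cp$tau_hat))
    cc <- lapply(grids, function(g)
      fit_model(hazard_spec("pem", g, covariates = cv, frailty = config$frailty),
                cc_of(x)))
    out <- list(cc = cc)
    if (has_missing) {
      imp <- fcs_impute(x, m = config$mi_m, iterations = config$mi_iterations,
                        seed = seeds$mi)
      out$mi <- lapply(grids, function(g) {
        spec <- hazard_spec("pem", g, covariates = cv, frailty = config$frailty)
        pool_rubin(lapply(imp$cohorts, function(co) fit_model(spec, co)))
      })
      out$imputations <- imp
    }
    out
  })
  structure(list(split = sp, changepoint = cp, bootstrap = bs, comparison = cmp,
                 final = final, seeds = seeds, config = config),
            class = "selection_pipeline")
}

#' @export
print.selection_pipeline <- function(x, ...) {
  cat("<selection_pipeline>\n")
  if (!inherits(x$changepoint, "pipeline_error"))
    cat("  data-driven cut point:", x$changepoint$tau_hat, "months\n")
  if (!inherits(x$bootstrap, "pipeline_error"))
    cat(sprintf("  bootstrap: mean %.2f, SD %.2f over %d replicates\n",
                x$bootstrap$mean, x$bootstrap$sd, x$bootstrap$B))
  if (!inherits(x$comparison, "pipeline_error")) print(x$comparison)
  for (nm in names(x)[vapply(x, inherits, TRUE, what = "pipeline_error")])
    cat("  stage", nm, "FAILED:", x[[nm]]$error, "\n")
  invisible(x)
}
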