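draw_norm_imputation <- function(y_obs, X_obs, X_mis, pmm_k = 0) {
  qrX <- qr(X_obs)
  n <- length(y_obs)
  k <- qrX$rank
  bhat <- qr.coef(qrX, y_obs)
  bhat[is.na(bhat)] <- 0
  res <- y_obs - X_obs %*% bhat
  df <- max(n - k, 1)
  sig2 <- sum(res^2) / df
  sig2_star <- sig2 * df / stats::rchisq(1, df)
  XtXinv <- chol2inv(qr.R(qrX)[seq_len(ncol(X_obs)), , drop = FALSE])
  bstar <- bhat + drop(chol(sig2_star * XtXinv) %*% stats::rnorm(ncol(X_obs)))
  mu_mis <- drop(X_mis %*% bstar)
  if (pmm_k > 0) {
    mu_obs <- drop(X_obs %*% bstar)
    vapply(mu_mis, function(m) {
      donors <- order(abs(mu_obs - m))[seq_len(min(pmm_k, n))]
      y_obs[sample(donors, 1L)]
    }, 0)
  } else {
    mu_mis + stats::rnorm(length(mu_mis), 0, sqrt(sig2_star))
  }
}

draw_logistic_imputation <- function(y_obs, X_obs, X_mis) {
  gf <- suppressWarnings(stats::glm.fit(X_obs, y_obs, family = stats::binomial()))
  bhat <- gf$coefficients
  bhat[is.na(bhat)] <- 0
  w <- gf$weights
  XtWX <- crossprod(X_obs * sqrt(w))
  vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) diag(1e-4, ncol(X_obs)))
  bstar <- bhat + drop(chol(vc) %*% stats::rnorm(ncol(X_obs)))
  p <- stats::plogis(drop(X_mis %*% bstar))
  stats::rbinom(length(p), 1L, p)
}

#' Fully-conditional-specification multiple imputation
#'
#' Chained-equations imputation of incomplete covariates at the job level
#' (a job attribute is constant across that job's episodes). Each incomplete
#' variable is regressed on the other covariates plus outcome summaries —
#' the job's event count and log person-time — which is standard practice
#' for imputation with survival outcomes: leaving the outcome out would
#' bias covariate-outcome associations toward the null. Draws are proper
#' (parameters drawn from their posterior, then residual noise), continuous
#' variables via a normal linear model (optionally predictive-mean
#' matching), binary variables via logistic regression. The `m` imputed
#' cohorts share every observed value; only missing cells differ.
#'
#' @param x A [cohort()] with missing cells in one or more covariates.
#' @param variables Variables to impute (default: every covariate with
#'   missing cells). A cohort with nothing missing returns `m` identical
#'   copies.
#' @param predictors Covariates used as predictors (default: all other
#'   covariates; outcome summaries are always added).
#' @param m Number of imputations (default 4).
#' @param iterations FCS cycles per imputation (default 10).
#' @param pmm_k Predictive-mean-matching donors for continuous variables;
#'   0 (default) draws from the normal model instead.
#' @param seed Integer seed; results are deterministic given it.
#' @return Object of class `imputation_set`: `cohorts` (list of `m`
#'   completed cohorts), `m`, `iterations`, `variables`, `seed`.
#' @export
fcs_impute <- function(x, variables = NULL, predictors = NULL, m = 4,
                       iterations = 10, pmm_k = 0, seed = NULL) {
  if (m < 1) stop("m must be >= 1")
  cv <- covariate_names(x)
  n_missing <- vapply(cv, function(v) sum(is.na(x[[v]])), 0L)
  if (is.null(variables)) variables <- cv[n_missing > 0]
  if (!length(variables)) {
    return(structure(list(cohorts = replicate(m, x, simplify = FALSE), m = m,
                          iterations = 0L, variables = character(0), seed = seed),
                     class = "imputation_set"))
  }
  for (v in variables) {
    if (!v %in% cv) stop("not a covariate: ", v)
    if (all(is.na(x[[v]]))) stop("all values of ", v, " are missing; cannot impute")
  }
  if (!is.null(seed)) set.seed(seed)
  jt <- job_table(x)
  out_summ <- c(".n_events", ".log_person_time")
  completed <- vector("list", m)
  key <- paste(x$subject_id, x$job_id, sep = "\r")
  for (imp in seq_len(m)) {
    work <- jt
    # initial fill: random draws from the observed values
    for (v in variables) {
      mis <- is.na(work[[v]])
      work[[v]][mis] <- sample(work[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (it in seq_len(max(iterations, 1L))) {
      for (v in variables) {
        preds <- if (is.null(predictors)) setdiff(cv, v) else setdiff(predictors, v)
        Xall <- cbind(`(Intercept)` = 1,
                      as.matrix(work[, c(preds, out_summ), drop = FALSE]))
        mis <- is.na(jt[[v]])
        y_obs <- work[[v]][!mis]
        binary <- all(jt[[v]][!is.na(jt[[v]])] %in% c(0, 1))
        work[[v]][mis] <- if (binary) {
          draw_logistic_imputation(y_obs, Xall[!mis, , drop = FALSE],
                                   Xall[mis, , drop = FALSE])
        } else {
          draw_norm_imputation(y_obs, Xall[!mis, , drop = FALSE],
                               Xall[mis, , drop = FALSE], pmm_k = pmm_k)
        }
      }
    }
    co <- x
    for (v in variables) co[[v]] <- work[[v]][match(key, work$.key)]
    completed[[imp]] <- co
  }
  structure(list(cohorts = completed, m = m, iterations = iterations,
                 variables = variables, seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set>", x$m, "completed cohorts;",
      if (length(x$variables)) paste("imputed:", paste(x$variables, collapse = ", "))
      else "nothing was missing", "\n")
  invisible(x)
}

#' Pool fits across imputations by Rubin's rules
#'
#' For each coefficient, the pooled estimate is the mean across the `m`
#' imputed-data fits; the total variance is
#' \eqn{T = W + (1 + 1/m)B} with within-imputation variance \eqn{W} (mean
#' squared SE) and between-imputation variance \eqn{B}; degrees of freedom
#' use Rubin's small-sample formula. Pooling happens on the estimation
#' (log) scale.
#'
#' @param fits List of `m` converged `hazard_fit`s sharing one spec, fitted
#'   to the completed cohorts of an [fcs_impute()] run.
#' @return Object of class `pooled_fit` with a per-coefficient `table`
#'   (`estimate`, `W`, `B`, `T`, `df`, `conf_low`, `conf_high`, `p_value`
#'   on the estimation scale), `m`, and the shared `spec`.
#' @export
pool_rubin <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  m <- length(fits)
  sig <- spec_signature(fits[[1]]$spec)
  for (f in fits) {
    if (!identical(spec_signature(f$spec), sig))
      stop("all fits must share the same hazard_spec")
  }
  est <- vapply(fits, function(f) f$par, fits[[1]]$par)
  ses <- vapply(fits, function(f) f$se, fits[[1]]$se)
  if (m == 1L) est <- matrix(est, ncol = 1, dimnames = list(names(fits[[1]]$par)))
  if (m == 1L) ses <- matrix(ses, ncol = 1, dimnames = list(names(fits[[1]]$par)))
  qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- if (m > 1) apply(est, 1, stats::var) else rep(NA_real_, length(qbar))
  Tv <- if (m > 1) W + (1 + 1 / m) * B else W
  df <- if (m > 1) {
    r <- (1 + 1 / m) * B / W
    ifelse(B > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  } else rep(Inf, length(qbar))
  tq <- stats::qt(0.975, pmin(df, 1e8))
  tab <- data.frame(term = names(qbar), estimate = unname(qbar),
                    W = unname(W), B = unname(B), T = unname(Tv),
                    df = unname(df),
                    conf_low = unname(qbar - tq * sqrt(Tv)),
                    conf_high = unname(qbar + tq * sqrt(Tv)),
                    p_value = unname(2 * stats::pt(-abs(qbar / sqrt(Tv)),
                                                   pmin(df, 1e8))),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, m = m, spec = fits[[1]]$spec,
                 loglik_mean = mean(vapply(fits, function(f) f$loglik, 0))),
            class = "pooled_fit")
}

#' @export
hazard_ratio_table.pooled_fit <- function(fit, ...) {
  tab <- fit$table
  keep <- !tab$term %in% c("log_lambda", "log_shape", "log_theta")
  tab <- tab[keep, , drop = FALSE]
  data.frame(term = tab$term, hr = exp(tab$estimate),
             conf_low = exp(tab$conf_low), conf_high = exp(tab$conf_high),
             p_value = tab$p_value, log_est = tab$estimate,
             se = sqrt(tab$T), row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("<pooled_fit> Rubin's rules over m =", x$m, "imputations;",
      x$spec$family, if (x$spec$frailty) "+ gamma frailty" else "", "\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(z) signif(z, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
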