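new_hazard_fit <- function(spec, par, vcov, loglik, converged, x,
                           method, boundary = FALSE) {
  nm <- param_names(spec)
  names(par) <- nm
  se <- rep(NA_real_, length(par))
  if (!is.null(vcov)) {
    dimnames(vcov) <- list(nm, nm)
    se <- sqrt(pmax(diag(vcov), 0))
  }
  names(se) <- nm
  structure(list(spec = spec, par = par, vcov = vcov, se = se,
                 loglik = loglik, n_params = length(par),
                 converged = converged, boundary = boundary,
                 n_events = sum(x$event), n_subjects = length(unique(x$subject_id)),
                 person_time = sum(x$exit - x$entry), method = method),
            class = "hazard_fit")
}

#' @export
coef.hazard_fit <- function(object, ...) object$par

#' @export
vcov.hazard_fit <- function(object, ...) object$vcov

#' @export
logLik.hazard_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_events,
            class = "logLik")
}

#' Frailty variance estimate from a fit
#' @param fit A `hazard_fit`.
#' @return Estimated theta (natural scale), or `NA` when the fit has no
#'   frailty term.
#' @export
frailty_variance <- function(fit) {
  if (!fit$spec$frailty) return(NA_real_)
  unname(exp(fit$par["log_theta"]))
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("<hazard_fit>", x$spec$family,
      if (x$spec$family == "pem") paste0("(cuts: ", paste(x$spec$grid$cuts, collapse = ", "), ")") else "",
      if (x$spec$frailty) "+ gamma frailty" else "", "\n")
  cat(sprintf("  loglik %.4f on %d parameters; %d events / %d subjects / %.1f person-months\n",
              x$loglik, x$n_params, x$n_events, x$n_subjects, x$person_time))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  tab <- cbind(estimate = x$par, se = x$se)
  print(round(tab, 5))
  if (x$spec$frailty) cat("  theta =", round(frailty_variance(x), 4), "\n")
  invisible(x)
}

# quasi-Newton maximization with Newton polishing for tight convergence
maximize_loglik <- function(start, dat, frailty, control = list()) {
  fn <- function(p) -loglik_kernel(p, dat, frailty, want_grad = FALSE)$value
  gr <- function(p) -loglik_kernel(p, dat, frailty)$grad
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = utils::modifyList(list(maxit = 500, reltol = 1e-12), control))
  par <- opt$par
  f <- opt$value
  for (i in 1:25) {
    g <- gr(par)
    if (max(abs(g)) < 1e-8 * (1 + abs(f))) break
    H <- stats::optimHess(par, fn, gr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- par - lam * step
      fc <- fn(cand)
      if (is.finite(fc) && fc <= f + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-6) { cand <- par; fc <- f; break }
    }
    if (max(abs(cand - par)) < 1e-12) { par <- cand; f <- fc; break }
    par <- cand; f <- fc
  }
  g <- gr(par)
  H <- stats::optimHess(par, fn, gr)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  list(par = par, loglik = -f,
       converged = opt$convergence == 0 && max(abs(g)) < 1e-4 * (1 + abs(f)),
       vcov = vc)
}

default_start <- function(spec, x) {
  d <- sum(x$event)
  E <- sum(x$exit - x$entry)
  lr <- log(max(d, 0.5) / E)
  start <- switch(spec$family,
    exponential = lr,
    weibull = c(lr, 0),
    pem = c(lr, rep(0, spec$grid$K - 1L)))
  c(start, rep(0, length(spec$covariates)), if (spec$frailty) log(0.2))
}

#' Fit a parametric proportional-hazards model
#'
#' Maximizes the independence likelihood, or the gamma-frailty marginal
#' likelihood when `spec$frailty` is `TRUE`. Piecewise-exponential (and
#' exponential) models without frailty are fitted by default through the
#' Poisson-regression equivalence ([fit_pem_poisson()]); `method = "direct"`
#' forces quasi-Newton maximization of the survival likelihood instead, and
#' the two routes agree to numerical precision. Weibull and all frailty
#' models are always maximized directly (analytic gradients, numeric
#' Hessian for standard errors).
#'
#' @param spec A [hazard_spec()].
#' @param x A [cohort()]; covariates named in the spec must be complete.
#' @param method `"auto"` (Poisson route where available), `"poisson"`, or
#'   `"direct"`.
#' @param start Optional starting parameter vector (estimation scale).
#' @return A `hazard_fit`.
#' @examples
#' sim <- simulate_cohort(simulation_design(n_subjects = 300, seed = 7))
#' fit_model(hazard_spec("exponential"), sim$cohort)
#' @export
fit_model <- function(spec, x, method = c("auto", "poisson", "direct"), start = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "hazard_spec"))
  X <- covariate_matrix(spec, x)
  if (anyNA(X))
    stop("missing values in model covariates; restrict to complete cases or impute first (see fcs_impute)")
  d <- sum(x$event)
  if (d == 0) {
    warning("cohort has zero events: baseline rate estimate is on the boundary (lambda -> 0)")
    spec0 <- spec
    par <- default_start(spec0, x)
    par[1] <- -Inf
    fit <- new_hazard_fit(spec0, par, NULL, 0, converged = FALSE, x,
                          method = "boundary", boundary = TRUE)
    return(fit)
  }
  if (!spec$frailty && spec$family %in% c("exponential", "pem") && method != "direct") {
    rows <- split_at_cuts(x, spec$grid)
    fit <- fit_pem_poisson(rows, covariates = spec$covariates)
    fit$n_subjects <- length(unique(x$subject_id))
    return(fit)
  }
  if (spec$frailty) {
    base_spec <- spec
    base_spec$frailty <- FALSE
    base <- fit_model(base_spec, x,
                      method = if (spec$family == "weibull") "direct" else "auto")
    start0 <- c(base$par, log_theta = log(0.2))
  } else {
    start0 <- default_start(spec, x)
  }
  if (!is.null(start)) start0 <- start
  dat <- prep_loglik_data(spec, x)
  res <- maximize_loglik(start0, dat, frailty = spec$frailty)
  if (!res$converged) warning("model fit did not converge; inspect the returned fit")
  new_hazard_fit(spec, res$par, res$vcov, res$loglik, res$converged, x,
                 method = "direct")
}

#' Fit a piecewise exponential model through its Poisson equivalence
#'
#' A piecewise exponential proportional-hazards model, after splitting the
#' at-risk episodes at the cut points, has the same kernel as a Poisson
#' regression of the per-row event indicator on piece dummies and covariates
#' with a log-exposure offset. The reference piece is the last (most
#' experienced) one, so each piece dummy is directly the log hazard ratio of
#' that piece versus the experienced period. The returned log-likelihood is
#' converted back to the survival scale (the two differ by
#' \eqn{\sum_{rows} d \log(\mathrm{exposure})}, a parameter-free constant).
#'
#' @param rows Expanded rows from [split_at_cuts()].
#' @param covariates Character vector of covariate names (default: the
#'   rows' recorded covariates).
#' @return A `hazard_fit` (family `"exponential"` when the grid has one
#'   piece, `"pem"` otherwise, `frailty = FALSE`).
#' @export
fit_pem_poisson <- function(rows, covariates = attr(rows, "covariates")) {
  grid <- attr(rows, "grid")
  if (is.null(grid)) stop("rows must come from split_at_cuts")
  if (is.null(covariates)) covariates <- character(0)
  if (any(rows$exposure <= 0)) {
    warning("dropping rows with non-positive exposure")
    rows <- rows[rows$exposure > 0, , drop = FALSE]
  }
  K <- grid$K
  present <- sort(unique(rows$piece))
  if (length(present) < K)
    warning("piece(s) with zero exposure dropped: ",
            paste(setdiff(seq_len(K), present), collapse = ", "))
  spec <- hazard_spec(if (K == 1L) "exponential" else "pem", grid = grid,
                      covariates = covariates, frailty = FALSE)
  nm <- param_names(spec)
  fake <- list(subject_id = rows$subject_id, event = rows$events,
               exit = rows$tstop, entry = rows$tstart)

  if (!length(covariates)) {
    # closed form: lambda_k = d_k / E_k
    dk <- vapply(seq_len(K), function(k) sum(rows$events[rows$piece == k]), 0)
    Ek <- vapply(seq_len(K), function(k) sum(rows$exposure[rows$piece == k]), 0)
    loglam <- ifelse(dk > 0, log(dk / Ek), -Inf)
    par <- c(loglam[K], if (K > 1) loglam[-K] - loglam[K])
    ll <- sum(ifelse(dk > 0, dk * (loglam) - dk, 0))
    vc <- matrix(NA_real_, K, K)
    vc[1, 1] <- 1 / dk[K]
    if (K > 1) {
      for (j in 2:K) {
        vc[1, j] <- vc[j, 1] <- -1 / dk[K]
        for (k in 2:K) vc[j, k] <- 1 / dk[K] + if (j == k) 1 / dk[j - 1] else 0
      }
    }
    fit <- new_hazard_fit(spec, par, vc, ll, converged = TRUE, fake,
                          method = "poisson_closed_form")
    fit$person_time <- sum(rows$exposure)
    return(fit)
  }

  df <- as.data.frame(rows)
  df$piece_f <- stats::relevel(factor(df$piece, levels = present), ref = as.character(K))
  rhs <- paste(c(if (K > 1) "piece_f", covariates), collapse = " + ")
  if (rhs == "") rhs <- "1"
  fml <- stats::as.formula(paste("events ~", rhs, "+ offset(log(exposure))"))
  gfit <- stats::glm(fml, family = stats::poisson(), data = df)
  cf <- stats::coef(gfit)
  # map glm names onto the package's parameter layout
  glm_names <- c("(Intercept)",
                 if (K > 1) paste0("piece_f", setdiff(present, K)),
                 covariates)
  pem_names <- c("log_lambda",
                 if (K > 1) sprintf("piece_%g_%g", c(0, grid$cuts)[setdiff(present, K)],
                                    grid$cuts[setdiff(present, K)]),
                 covariates)
  par <- rep(NA_real_, length(nm)); names(par) <- nm
  vc <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  par[pem_names] <- cf[glm_names]
  vc[pem_names, pem_names] <- stats::vcov(gfit)[glm_names, glm_names]
  ll <- as.numeric(stats::logLik(gfit)) - sum(df$events * log(df$exposure))
  fit <- new_hazard_fit(spec, par, vc, ll, converged = gfit$converged, fake,
                        method = "poisson_glm")
  fit$person_time <- sum(rows$exposure)
  fit
}

baseline_cumhaz <- function(fit, times) {
  spec <- fit$spec
  if (spec$family == "weibull") {
    exp(fit$par["log_lambda"]) * times^exp(fit$par["log_shape"])
  } else {
    K <- spec$grid$K
    gamma <- if (K > 1) fit$par[1 + seq_len(K - 1L)] else numeric(0)
    rates <- exp(fit$par["log_lambda"] + c(gamma, 0))
    cumhaz_pem(times, rates, spec$grid$cuts)
  }
}

#' Model-implied injury-free (survival) curve
#'
#' Computes \eqn{S(t\mid x)} at the fitted parameters: the conditional
#' (frailty = 1) curve \eqn{\exp(-\Lambda_0(t)e^{x'\beta})}, or the
#' population-averaged curve \eqn{(1+\theta\Lambda_0(t)e^{x'\beta})^{-1/\theta}}
#' obtained by integrating the gamma frailty out (frailty fits only).
#'
#' @param fit A `hazard_fit`.
#' @param covariates Named numeric vector of covariate values; must cover
#'   exactly the spec's covariates.
#' @param times Non-decreasing vector of non-negative times (months).
#' @param type `"conditional"` or `"population"`.
#' @return Data frame with columns `time` and `surv`.
#' @export
predict_survival <- function(fit, covariates = NULL, times,
                             type = c("conditional", "population")) {
  type <- match.arg(type)
  stopifnot(is.numeric(times), all(times >= 0), !is.unsorted(times))
  spec <- fit$spec
  if (is.null(covariates)) covariates <- numeric(0)
  extra <- setdiff(names(covariates), spec$covariates)
  if (length(extra)) stop("covariate not in fit: ", paste(extra, collapse = ", "))
  missing_cov <- setdiff(spec$covariates, names(covariates))
  if (length(missing_cov)) stop("covariate value required: ", paste(missing_cov, collapse = ", "))
  eta <- if (length(spec$covariates))
    sum(fit$par[spec$covariates] * covariates[spec$covariates]) else 0
  Lam <- baseline_cumhaz(fit, times) * exp(eta)
  surv <- if (type == "conditional") {
    exp(-Lam)
  } else {
    if (!spec$frailty) stop("population-averaged curve requires a frailty fit")
    th <- frailty_variance(fit)
    (1 + th * Lam)^(-1 / th)
  }
  data.frame(time = times, surv = surv)
}

#' Hazard-ratio table of a fitted model
#'
#' Exponentiates each log-hazard-ratio coefficient (piece dummies and
#' covariate effects) with Wald 95% confidence intervals and p-values, the
#' standard reporting layout `HR (95% CI)`.
#'
#' @param fit A `hazard_fit` or `pooled_fit`.
#' @param ... Unused.
#' @return Data frame with columns `term`, `hr`, `conf_low`, `conf_high`,
#'   `p_value` (plus `log_est` and `se` on the estimation scale).
#' @export
hazard_ratio_table <- function(fit, ...) UseMethod("hazard_ratio_table")

#' @export
hazard_ratio_table.hazard_fit <- function(fit, ...) {
  keep <- setdiff(names(fit$par), c("log_lambda", "log_shape", "log_theta"))
  est <- fit$par[keep]
  se <- fit$se[keep]
  z <- est / se
  data.frame(term = keep, hr = exp(est),
             conf_low = exp(est - 1.96 * se), conf_high = exp(est + 1.96 * se),
             p_value = 2 * stats::pnorm(-abs(z)),
             log_est = unname(est), se = unname(se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize a fit to a flat key-value text file
#'
#' @param fit A `hazard_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  flat <- c(list(family = fit$spec$family,
                 cuts = as.numeric(fit$spec$grid$cuts),
                 frailty = fit$spec$frailty,
                 covariates = fit$spec$covariates,
                 loglik = fit$loglik, n_params = fit$n_params,
                 converged = fit$converged, n_events = fit$n_events,
                 n_subjects = fit$n_subjects, person_time = fit$person_time),
            as.list(stats::setNames(unname(fit$par), paste0("par.", names(fit$par)))),
            as.list(stats::setNames(unname(fit$se), paste0("se.", names(fit$se)))))
  yaml::write_yaml(flat, path)
  invisible(path)
}
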