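#' Specify a baseline-hazard model
#'
#' Three proportional-hazards families for the baseline hazard on the job
#' clock: `exponential` (constant \eqn{\lambda_0}), `weibull`
#' (\eqn{\lambda_0(t) = \lambda p t^{p-1}}, reducing to the exponential at
#' shape \eqn{p = 1}), and `pem`, the K-piece exponential whose hazard is
#' constant within the pieces of a [piece_grid()] and free to jump at the
#' cuts. Setting `frailty = TRUE` adds a gamma-distributed worker-specific
#' multiplier on the hazard (mean 1, variance \eqn{\theta}) to absorb
#' within-worker correlation of recurrent injuries.
#'
#' Parameter layout (estimation scale) for a fitted model:
#' `log_lambda` (reference rate: the constant rate, the Weibull rate, or the
#' last piece's rate), `log_shape` (Weibull only), one `piece_<lo>_<hi>`
#' log-hazard-ratio per non-reference piece (pem only, so the
#' "inexperienced-period" effect is a single coefficient), one coefficient
#' per covariate, and `log_theta` when frailty is on.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"pem"`.
#' @param grid A [piece_grid()]; required with at least one cut for `pem`,
#'   must be empty otherwise.
#' @param covariates Character vector of covariate names entering
#'   \eqn{x'\beta}.
#' @param frailty Logical; include a gamma frailty term.
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(family = c("exponential", "weibull", "pem"),
                        grid = piece_grid(), covariates = character(0),
                        frailty = FALSE) {
  family <- match.arg(family)
  stopifnot(inherits(grid, "piece_grid"))
  if (family == "pem" && grid$K < 2L)
    stop("a pem spec needs a grid with at least one cut")
  if (family != "pem" && grid$K != 1L)
    stop("only the pem family takes a non-empty grid")
  structure(list(family = family, grid = grid,
                 covariates = as.character(covariates),
                 frailty = isTRUE(frailty)),
            class = "hazard_spec")
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat("<hazard_spec>", x$family,
      if (x$family == "pem") paste0("(cuts: ", paste(x$grid$cuts, collapse = ", "), ")") else "",
      if (x$frailty) "+ gamma frailty" else "", "\n")
  if (length(x$covariates)) cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

param_names <- function(spec) {
  base <- "log_lambda"
  if (spec$family == "weibull") base <- c(base, "log_shape")
  if (spec$family == "pem") {
    cuts <- spec$grid$cuts
    lower <- c(0, cuts)
    base <- c(base, sprintf("piece_%g_%g", lower[seq_along(cuts)], cuts))
  }
  c(base, spec$covariates, if (spec$frailty) "log_theta")
}

covariate_matrix <- function(spec, x) {
  if (!length(spec$covariates)) return(matrix(0, nrow(x), 0))
  miss <- setdiff(spec$covariates, names(x))
  if (length(miss)) stop("covariates absent from cohort: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(x)[, spec$covariates, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

# prepared data for the likelihood kernels
prep_loglik_data <- function(spec, x) {
  X <- covariate_matrix(spec, x)
  if (anyNA(X)) stop("missing covariate values; complete cases or multiple imputation required (see fcs_impute)")
  subj <- match(x$subject_id, unique(x$subject_id))
  if (spec$family %in% c("exponential", "pem")) {
    rows <- split_at_cuts(x, spec$grid)
    Xr <- covariate_matrix(spec, rows)
    list(kind = "pem", K = spec$grid$K, piece = rows$piece,
         exposure = rows$exposure, events = rows$events, X = Xr,
         subj = match(rows$subject_id, unique(x$subject_id)), n_subj = max(subj))
  } else {
    list(kind = "weibull", entry = x$entry, exit = x$exit,
         event = as.numeric(x$event), X = X, subj = subj, n_subj = max(subj))
  }
}

# log-likelihood and gradient kernels -------------------------------------
# Independence likelihood per episode: d*log lambda(t_exit; x) - (Lam0(exit)
# - Lam0(entry)) * exp(x'beta). The gamma-frailty marginal likelihood per
# subject i with d_i events and covariate-adjusted cumulative hazard H_i:
#   sum_events log lambda(t; x) + lgamma(1/th + d_i) - lgamma(1/th)
#   + d_i log th - (1/th + d_i) log(1 + th H_i)

loglik_kernel <- function(par, dat, frailty, want_grad = TRUE) {
  np <- ncol(dat$X)
  if (dat$kind == "pem") {
    K <- dat$K
    nb <- K  # log_lambda + K-1 piece dummies
    gamma <- if (K > 1) par[2:K] else numeric(0)
    beta <- if (np) par[nb + seq_len(np)] else numeric(0)
    loglam <- par[1] + c(gamma, 0)[dat$piece]
    eta <- if (np) drop(dat$X %*% beta) else 0
    lograte <- loglam + eta
    mu <- exp(lograte) * dat$exposure
    d <- dat$events
    S <- sum(d * lograte)
    dS <- NULL
  } else {
    nb <- 2L
    beta <- if (np) par[2 + seq_len(np)] else numeric(0)
    p <- exp(par[2])
    a <- dat$entry; b <- dat$exit
    eta <- if (np) drop(dat$X %*% beta) else 0
    loghaz <- par[1] + par[2] + (p - 1) * log(b)
    bp <- b^p
    ap <- ifelse(a > 0, a^p, 0)
    mu <- exp(par[1] + eta) * (bp - ap)
    d <- dat$event
    S <- sum(d * (loghaz + eta))
  }
  if (!frailty) {
    ll <- S - sum(mu)
    w <- 1
  } else {
    th <- exp(par[length(par)])
    H <- drop(rowsum(mu, dat$subj))
    Dn <- drop(rowsum(d, dat$subj))
    ll <- S + sum(lgamma(1 / th + Dn) - lgamma(1 / th) + Dn * log(th) -
                    (1 / th + Dn) * log1p(th * H))
    wi <- (1 + th * Dn) / (1 + th * H)
    w <- wi[dat$subj]
  }
  if (!want_grad) return(list(value = ll))
  r <- d - w * mu
  if (dat$kind == "pem") {
    g_base <- sum(r)
    g_gamma <- if (dat$K > 1)
      vapply(seq_len(dat$K - 1L), function(k) sum(r[dat$piece == k]), 0) else numeric(0)
    g_beta <- if (np) drop(crossprod(dat$X, r)) else numeric(0)
    grad <- c(g_base, g_gamma, g_beta)
  } else {
    g_lam <- sum(r)
    lb <- log(b)
    la <- ifelse(a > 0, log(a), 0)
    dmu_dlogp <- exp(par[1] + eta) * p * (bp * lb - ap * la)
    g_p <- sum(d * (1 + p * lb)) - sum(w * dmu_dlogp)
    g_beta <- if (np) drop(crossprod(dat$X, r)) else numeric(0)
    grad <- c(g_lam, g_p, g_beta)
  }
  if (frailty) {
    g_th <- sum((digamma(1 / th) - digamma(1 / th + Dn) + log1p(th * H)) / th +
                  Dn - (1 + th * Dn) * H / (1 + th * H))
    grad <- c(grad, g_th)
  }
  list(value = ll, grad = grad)
}

#' Independence log-likelihood of a hazard model
#'
#' Evaluates \eqn{\sum_e [d_e \log\lambda(t_e; x_e) -
#' (\Lambda_0(t_e)-\Lambda_0(a_e)) e^{x_e'\beta}]} over the cohort's
#' episodes, treating episodes as independent (no frailty).
#'
#' @param spec A [hazard_spec()] (its `frailty` flag is ignored here).
#' @param params Numeric parameter vector on the estimation scale, laid out
#'   as documented in [hazard_spec()] (without `log_theta`).
#' @param x A [cohort()].
#' @return The log-likelihood (a scalar).
#' @export
loglik_independence <- function(spec, params, x) {
  spec$frailty <- FALSE
  expected <- length(param_names(spec))
  if (length(params) != expected)
    stop("expected ", expected, " parameters, got ", length(params))
  if (any(!is.finite(params))) stop("non-finite parameters")
  dat <- prep_loglik_data(spec, x)
  loglik_kernel(params, dat, frailty = FALSE, want_grad = FALSE)$value
}

#' Gamma-frailty marginal log-likelihood
#'
#' Integrates the worker-specific gamma frailty out of the likelihood: each
#' subject contributes
#' \deqn{\sum_{events} \log\lambda(t;x) + \log\Gamma(1/\theta + d_i) -
#'   \log\Gamma(1/\theta) + d_i\log\theta -
#'   (1/\theta + d_i)\log(1 + \theta H_i)}
#' where \eqn{d_i} is the subject's total event count and \eqn{H_i} the
#' covariate-adjusted cumulative hazard summed over all their episodes.
#' As \eqn{\theta \to 0} this tends to the independence log-likelihood.
#'
#' @param spec A [hazard_spec()].
#' @param params Parameter vector as in [loglik_independence()] followed by
#'   the frailty variance `theta` on its natural scale (must be > 0).
#' @param x A [cohort()].
#' @return The marginal log-likelihood (a scalar).
#' @export
loglik_frailty <- function(spec, params, x) {
  spec$frailty <- TRUE
  expected <- length(param_names(spec))
  if (length(params) != expected)
    stop("expected ", expected, " parameters (theta last), got ", length(params))
  theta <- params[length(params)]
  if (!is.finite(theta) || theta <= 0)
    stop("theta must be > 0; use loglik_independence for theta = 0")
  if (any(!is.finite(params))) stop("non-finite parameters")
  dat <- prep_loglik_data(spec, x)
  par <- c(params[-length(params)], log(theta))
  loglik_kernel(par, dat, frailty = TRUE, want_grad = FALSE)$value
}
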