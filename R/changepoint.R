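default_candidates <- function(x) {
  hi <- floor(stats::quantile(x$exit, 0.95, names = FALSE))
  if (hi < 1) stop("follow-up too short for a candidate grid")
  seq_len(hi)
}

#' Profile-likelihood estimation of the two-piece changepoint
#'
#' Fits the two-piece exponential model at every candidate cut point and
#' takes the candidate with the largest maximized (independence)
#' log-likelihood as the changepoint estimate \eqn{\hat\tau_1}. Ties are
#' broken toward the smaller candidate. Candidates leaving fewer than
#' `min_events` events on either side of the cut are infeasible and skipped.
#'
#' @param x A [cohort()].
#' @param candidates Numeric vector of candidate cut points in months;
#'   default: integer months from 1 to the 95th percentile of observed exit
#'   times.
#' @param covariates Covariates adjusted for in the profile fits (default
#'   none).
#' @param min_events Minimum events required on each side of a feasible
#'   candidate (default 5).
#' @return An object of class `changepoint_estimate`: `tau_hat`, the
#'   `profile` data frame (`candidate`, `loglik`, `feasible`), and the fit at
#'   `tau_hat`.
#' @export
profile_changepoint <- function(x, candidates = NULL, covariates = character(0),
                                min_events = 5) {
  if (is.null(candidates)) candidates <- default_candidates(x)
  if (!length(candidates)) stop("no candidates supplied")
  candidates <- sort(unique(as.numeric(candidates)))
  ev_times <- x$exit[x$event == 1L]
  n_before <- vapply(candidates, function(ct) sum(ev_times <= ct), 0)
  feasible <- n_before >= min_events & (length(ev_times) - n_before) >= min_events
  if (!any(feasible))
    stop("no feasible candidate: need >= ", min_events, " events on both sides of a cut")
  ll <- rep(NA_real_, length(candidates))
  fits <- vector("list", length(candidates))
  for (i in which(feasible)) {
    rows <- split_at_cuts(x, piece_grid(candidates[i]))
    fits[[i]] <- fit_pem_poisson(rows, covariates = covariates)
    ll[i] <- fits[[i]]$loglik
  }
  best <- which(ll == max(ll, na.rm = TRUE))[1]
  structure(list(tau_hat = candidates[best],
                 profile = data.frame(candidate = candidates, loglik = ll,
                                      feasible = feasible),
                 candidates = candidates,
                 fit = fits[[best]],
                 covariates = covariates, min_events = min_events),
            class = "changepoint_estimate")
}

#' @export
print.changepoint_estimate <- function(x, ...) {
  cat(sprintf("<changepoint_estimate> tau_hat = %g months (profile over %d candidates, %d feasible)\n",
              x$tau_hat, nrow(x$profile), sum(x$profile$feasible)))
  cat(sprintf("  loglik at tau_hat: %.4f\n", x$fit$loglik))
  invisible(x)
}

#' Employee-level bootstrap of the changepoint estimate
#'
#' Re-samples employees with replacement (all of a worker's jobs and
#' episodes travel together, preserving the clustering) and re-estimates the
#' changepoint on each replicate with the same candidate grid, giving a
#' bootstrap distribution for \eqn{\hat\tau_1}.
#'
#' @param x A [cohort()].
#' @param candidates Candidate grid (see [profile_changepoint()]).
#' @param covariates Covariates for the profile fits.
#' @param B Number of bootstrap replicates (default 400; must be >= 2).
#' @param sample_size Employees drawn per replicate (default 10000, capped
#'   informatively if the cohort is smaller only by explicit choice of the
#'   caller).
#' @param min_events Feasibility floor per side.
#' @param seed Integer seed; the replicate vector is deterministic given it.
#' @return Object of class `bootstrap_changepoint`: `replicates` (tau-hat
#'   values), `mean`, `sd`, `B`, `sample_size`, `seed`.
#' @export
bootstrap_changepoint <- function(x, candidates = NULL, covariates = character(0),
                                  B = 400, sample_size = 10000, min_events = 5,
                                  seed = NULL) {
  if (B < 2) stop("B must be >= 2 (bootstrap SD undefined otherwise)")
  if (sample_size < 1) stop("sample_size must be >= 1")
  if (is.null(candidates)) candidates <- default_candidates(x)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(x$subject_id)
  idx_by_subject <- split(seq_len(nrow(x)), factor(x$subject_id, levels = ids))
  cv <- covariate_names(x)
  taus <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    draw <- sample.int(length(ids), sample_size, replace = TRUE)
    rows <- idx_by_subject[draw]
    n_per <- lengths(rows)
    rows <- unlist(rows, use.names = FALSE)
    rep_df <- as.data.frame(x)[rows, , drop = FALSE]
    rep_df$subject_id <- rep(paste0("b", seq_len(sample_size)), n_per)
    rep_co <- cohort(rep_df, covariates = cv, validate = FALSE)
    taus[b] <- tryCatch(
      profile_changepoint(rep_co, candidates = candidates,
                          covariates = covariates, min_events = min_events)$tau_hat,
      error = function(e) NA_real_)
  }
  structure(list(replicates = taus, mean = mean(taus, na.rm = TRUE),
                 sd = stats::sd(taus[!is.na(taus)]), B = B,
                 sample_size = sample_size, seed = seed,
                 candidates = sort(unique(as.numeric(candidates)))),
            class = "bootstrap_changepoint")
}

#' @export
print.bootstrap_changepoint <- function(x, ...) {
  cat(sprintf("<bootstrap_changepoint> B = %d replicates of %d employees (mean %.2f, SD %.2f)\n",
              x$B, x$sample_size, x$mean, x$sd))
  if (anyNA(x$replicates))
    cat("  ", sum(is.na(x$replicates)), "replicate(s) had no feasible candidate\n")
  invisible(x)
}
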