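.censor_levels <- c("job_change", "termination", "death", "admin_end", "event", "none")

#' Construct a piecewise-hazard cut-point grid
#'
#' A `piece_grid` holds the ordered cut points \eqn{\tau_1 < \ldots < \tau_{K-1}}
#' (in months on the job clock) that partition time into `K` hazard pieces.
#' An empty grid corresponds to a single piece, i.e. a constant (exponential)
#' baseline hazard. Pieces are half-open on the left, \eqn{(\tau_{k-1}, \tau_k]},
#' so an event falling exactly on a cut belongs to the earlier piece.
#'
#' @param cuts Numeric vector of strictly increasing positive cut points in
#'   months; may be empty.
#' @return An object of class `piece_grid` with elements `cuts` and `K`.
#' @examples
#' piece_grid(12)      # two pieces: (0,12] and (12, Inf)
#' piece_grid()        # one piece: exponential
#' @export
piece_grid <- function(cuts = numeric(0)) {
  cuts <- as.numeric(cuts)
  if (length(cuts)) {
    if (anyNA(cuts) || any(!is.finite(cuts))) stop("cut points must be finite")
    if (any(cuts <= 0)) stop("cut points must be strictly positive")
    if (is.unsorted(cuts, strictly = TRUE)) stop("cut points must be strictly increasing")
  }
  structure(list(cuts = cuts, K = length(cuts) + 1L), class = "piece_grid")
}

#' @export
print.piece_grid <- function(x, ...) {
  if (x$K == 1L) {
    cat("<piece_grid> single piece (exponential baseline)\n")
  } else {
    cat("<piece_grid>", x$K, "pieces with cuts at", paste(x$cuts, collapse = ", "), "months\n")
  }
  invisible(x)
}

# piece index of time t under half-open (tau_{k-1}, tau_k] pieces
piece_of <- function(t, cuts) {
  if (!length(cuts)) return(rep(1L, length(t)))
  findInterval(t, cuts, left.open = TRUE) + 1L
}

#' Construct a counting-process cohort
#'
#' A cohort is a data frame of at-risk episodes, one row per interval on the
#' job clock during which a worker was under observation on a given job.
#' Recurrent injuries are represented Andersen-Gill style: after an event at
#' time \eqn{t} the worker re-enters risk at \eqn{t} on the same job clock, so
#' a job with events at \eqn{t_1 < t_2} and censoring at \eqn{c} contributes
#' episodes \eqn{(0,t_1], (t_1,t_2], (t_2,c]}.
#'
#' @param data Data frame with columns `subject_id`, `job_id`, `entry`, `exit`
#'   (months on the job), `event` (0/1) and `censor_reason` (one of
#'   `"job_change"`, `"termination"`, `"death"`, `"admin_end"`, `"event"`,
#'   `"none"`), followed by covariate columns.
#' @param covariates Character vector naming the covariate columns. Defaults to
#'   every column after the six structural ones.
#' @param validate If `TRUE` (default), stop when [validate_cohort()] reports
#'   violations.
#' @return An object of class `cohort` (a data frame).
#' @seealso [read_cohort()], [validate_cohort()], [split_at_cuts()]
#' @export
cohort <- function(data, covariates = NULL, validate = TRUE) {
  required <- c("subject_id", "job_id", "entry", "exit", "event", "censor_reason")
  miss <- setdiff(required, names(data))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$subject_id <- as.character(data$subject_id)
  data$job_id <- as.character(data$job_id)
  data$entry <- as.numeric(data$entry)
  data$exit <- as.numeric(data$exit)
  data$event <- as.integer(data$event)
  data$censor_reason <- as.character(data$censor_reason)
  if (is.null(covariates)) covariates <- setdiff(names(data), required)
  covariates <- as.character(covariates)
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("covariate columns not present: ", paste(miss, collapse = ", "))
  data <- data[, c(required, covariates)]
  attr(data, "covariates") <- covariates
  class(data) <- c("cohort", "data.frame")
  if (validate) {
    v <- validate_cohort(data)
    if (nrow(v)) {
      stop("invalid cohort (", nrow(v), " violation(s)); first: ", v$detail[1],
           " [subject ", v$subject_id[1], ", job ", v$job_id[1], "]")
    }
  }
  data
}

#' Covariate column names of a cohort
#' @param x A `cohort`.
#' @return Character vector of covariate names.
#' @export
covariate_names <- function(x) {
  cv <- attr(x, "covariates")
  if (is.null(cv)) character(0) else cv
}

#' @export
print.cohort <- function(x, ...) {
  ns <- length(unique(x$subject_id))
  nj <- nrow(unique(as.data.frame(x)[, c("subject_id", "job_id")]))
  cat(sprintf("<cohort> %d episodes, %d jobs, %d subjects; %d events over %.1f person-months\n",
              nrow(x), nj, ns, sum(x$event), sum(x$exit - x$entry)))
  cv <- covariate_names(x)
  if (length(cv)) {
    nm <- vapply(cv, function(v) sum(is.na(x[[v]])), 0L)
    cat("  covariates:", paste(cv, collapse = ", "), "\n")
    if (any(nm > 0))
      cat("  missing cells:", paste(sprintf("%s=%d", cv[nm > 0], nm[nm > 0]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a cohort against its structural invariants
#'
#' Checks every episode-level and cohort-level invariant (non-negative entry,
#' `entry < exit`, binary event flag, event/censor-reason agreement, legal
#' censor reasons, and disjoint ordered intervals within each job) and reports
#' violations rather than raising errors.
#'
#' @param x A `cohort` (or plain data frame with the cohort columns).
#' @return Data frame with columns `rule`, `subject_id`, `job_id`, `detail`;
#'   zero rows when the cohort is valid.
#' @export
validate_cohort <- function(x) {
  out <- list()
  add <- function(rule, sid, jid, detail) {
    out[[length(out) + 1L]] <<- data.frame(rule = rule, subject_id = as.character(sid),
                                           job_id = as.character(jid), detail = detail,
                                           stringsAsFactors = FALSE)
  }
  bad <- which(!is.finite(x$entry) | x$entry < 0)
  for (i in bad) add("entry_nonnegative", x$subject_id[i], x$job_id[i],
                     sprintf("entry=%s must be finite and >= 0", format(x$entry[i])))
  bad <- which(!is.finite(x$exit) | x$exit <= x$entry)
  for (i in bad) add("entry_before_exit", x$subject_id[i], x$job_id[i],
                     sprintf("requires 0 <= entry < exit, got entry=%s exit=%s",
                             format(x$entry[i]), format(x$exit[i])))
  bad <- which(!(x$event %in% c(0L, 1L)))
  for (i in bad) add("event_binary", x$subject_id[i], x$job_id[i],
                     sprintf("event=%s not in {0,1}", format(x$event[i])))
  bad <- which(x$event == 1L & x$censor_reason != "event")
  for (i in bad) add("event_reason_agreement", x$subject_id[i], x$job_id[i],
                     sprintf("event=1 requires censor_reason='event', got '%s'", x$censor_reason[i]))
  bad <- which(!(x$censor_reason %in% .censor_levels))
  for (i in bad) add("censor_reason_known", x$subject_id[i], x$job_id[i],
                     sprintf("unknown censor_reason '%s'", x$censor_reason[i]))
  # disjoint, ordered intervals within each (subject, job)
  key <- paste(x$subject_id, x$job_id, sep = "\r")
  for (g in split(seq_len(nrow(x)), key)) {
    if (length(g) < 2L) next
    en <- x$entry[g]; ex <- x$exit[g]
    if (is.unsorted(en)) {
      add("intervals_ordered", x$subject_id[g[1]], x$job_id[g[1]],
          "episodes not ordered by entry time within job")
      o <- order(en); en <- en[o]; ex <- ex[o]
    }
    if (any(en[-1] < ex[-length(ex)] - 1e-12))
      add("intervals_disjoint", x$subject_id[g[1]], x$job_id[g[1]],
          "overlapping at-risk intervals within job")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(rule = character(0), subject_id = character(0),
               job_id = character(0), detail = character(0), stringsAsFactors = FALSE)
}

#' Read a cohort from its CSV representation
#'
#' The package's cohort CSV dialect has a fixed header
#' `subject_id, job_id, entry_months, exit_months, event, censor_reason`
#' followed by one column per covariate; the missing-value marker is an empty
#' cell. [write_cohort()] emits the same dialect, and the pair round-trips.
#'
#' @param path Path to a CSV file.
#' @param covariates Optional character vector restricting/naming the covariate
#'   columns; defaults to every column after `censor_reason`.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(path, covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         check.names = FALSE, colClasses = "character")
  header <- c("subject_id", "job_id", "entry_months", "exit_months", "event", "censor_reason")
  if (ncol(raw) < 6L || !identical(names(raw)[1:6], header))
    stop("malformed cohort file: header must start with ", paste(header, collapse = ", "))
  num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) stop(sprintf("parse error at line %d: non-numeric %s '%s'",
                                  bad[1] + 1L, nm, raw[[col]][bad[1]]))
    if (anyNA(v)) stop(sprintf("parse error at line %d: empty %s",
                               which(is.na(v))[1] + 1L, nm))
    v
  }
  df <- data.frame(subject_id = raw$subject_id, job_id = raw$job_id,
                   entry = num("entry_months", "entry_months"),
                   exit = num("exit_months", "exit_months"),
                   event = num("event", "event"),
                   censor_reason = raw$censor_reason,
                   stringsAsFactors = FALSE)
  cov_cols <- names(raw)[-(1:6)]
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, cov_cols)
    if (length(miss)) stop("covariates absent from file: ", paste(miss, collapse = ", "))
    cov_cols <- covariates
  }
  for (v in cov_cols) df[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  cohort(df, covariates = cov_cols)
}

#' Write a cohort to the package's CSV dialect
#'
#' @param x A `cohort`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_cohort()] for the dialect.
#' @export
write_cohort <- function(x, path) {
  out <- as.data.frame(x)
  names(out)[names(out) == "entry"] <- "entry_months"
  names(out)[names(out) == "exit"] <- "exit_months"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Split episodes at hazard cut points
#'
#' Expands each at-risk episode into one row per hazard piece it overlaps,
#' the long format in which a piecewise exponential model is a Poisson
#' regression with a log-exposure offset. Pieces are half-open
#' \eqn{(\tau_{k-1},\tau_k]}; an episode's event (which occurs at its exit
#' time) is assigned to the piece containing the exit. Person-time and event
#' counts are conserved exactly.
#'
#' @param x A `cohort`.
#' @param grid A [piece_grid()]. An empty grid returns one row per episode.
#' @return Data frame of class `expanded_rows` with columns `subject_id`,
#'   `job_id`, `piece`, `tstart`, `tstop`, `exposure`, `events` and the
#'   cohort's covariates. Attribute `grid` carries the grid.
#' @examples
#' co <- cohort(data.frame(subject_id = "s1", job_id = "j1", entry = 0, exit = 15,
#'                         event = 1, censor_reason = "event"))
#' split_at_cuts(co, piece_grid(12))  # 12 months exposure in piece 1, 3 in piece 2
#' @export
split_at_cuts <- function(x, grid = piece_grid()) {
  stopifnot(inherits(grid, "piece_grid"))
  cuts <- grid$cuts
  K <- grid$K
  lower <- c(0, cuts)
  upper <- c(cuts, Inf)
  ev_piece <- piece_of(x$exit, cuts)
  cv <- covariate_names(x)
  pieces <- vector("list", K)
  for (k in seq_len(K)) {
    lo <- pmax(x$entry, lower[k])
    hi <- pmin(x$exit, upper[k])
    keep <- which(hi > lo)
    if (!length(keep)) next
    d <- data.frame(subject_id = x$subject_id[keep], job_id = x$job_id[keep],
                    piece = k, tstart = lo[keep], tstop = hi[keep],
                    exposure = hi[keep] - lo[keep],
                    events = as.integer(x$event[keep] == 1L & ev_piece[keep] == k),
                    stringsAsFactors = FALSE)
    for (v in cv) d[[v]] <- x[[v]][keep]
    d$.episode <- keep
    pieces[[k]] <- d
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$.episode, out$piece), , drop = FALSE]
  out$.episode <- NULL
  rownames(out) <- NULL
  attr(out, "covariates") <- cv
  attr(out, "grid") <- grid
  class(out) <- c("expanded_rows", "data.frame")
  out
}

#' Crude injury rates by time-on-job bin
#'
#' Aggregates events and person-time into bins of the job clock and reports
#' the crude rate per person-month, optionally rescaled to events per 200,000
#' person-hours given an hours-per-month conversion (the conventional
#' occupational-injury denominator).
#'
#' @param x A `cohort`.
#' @param bin_width Bin width in months (> 0).
#' @param hours_per_month Optional hours worked per person-month; when given,
#'   a `rate_per_200k_hours` column is added.
#' @return Data frame with one row per bin: `bin_start`, `bin_end`, `events`,
#'   `person_months`, `rate` (events per person-month; `NA` and flagged
#'   `undefined` when the bin has zero person-time), and optionally
#'   `rate_per_200k_hours`.
#' @export
crude_rates <- function(x, bin_width, hours_per_month = NULL) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a positive number")
  tmax <- max(x$exit)
  edges <- seq(bin_width, by = bin_width, length.out = ceiling(tmax / bin_width))
  interior <- edges[edges < tmax]
  rows <- split_at_cuts(x, piece_grid(interior))
  nb <- length(interior) + 1L
  ev <- tapply(rows$events, factor(rows$piece, levels = seq_len(nb)), sum)
  pt <- tapply(rows$exposure, factor(rows$piece, levels = seq_len(nb)), sum)
  ev[is.na(ev)] <- 0
  pt[is.na(pt)] <- 0
  out <- data.frame(bin_start = c(0, interior),
                    bin_end = c(interior, nb * bin_width),
                    events = as.numeric(ev), person_months = as.numeric(pt))
  out$undefined <- out$person_months <= 0
  out$rate <- ifelse(out$undefined, NA_real_, out$events / out$person_months)
  if (!is.null(hours_per_month)) {
    out$rate_per_200k_hours <- ifelse(out$undefined, NA_real_,
                                      out$events / (out$person_months * hours_per_month) * 2e5)
  }
  out
}

# subset a cohort to a set of subjects, preserving class/attributes;
# `new_ids` optionally relabels (for with-replacement resampling)
subset_subjects <- function(x, ids, new_ids = NULL) {
  idx_by_subject <- split(seq_len(nrow(x)), x$subject_id)
  rows <- idx_by_subject[ids]
  n_per <- lengths(rows)
  rows <- unlist(rows, use.names = FALSE)
  out <- as.data.frame(x)[rows, , drop = FALSE]
  if (!is.null(new_ids)) out$subject_id <- rep(new_ids, n_per)
  rownames(out) <- NULL
  cohort(out, covariates = covariate_names(x), validate = FALSE)
}
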