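#' Arrival rate at a simulation time
#'
#' The arrival process is a piecewise-constant non-homogeneous Poisson
#' process with a weekly cycle: the rate at time `t` (minutes since Monday
#' 00:00) is the table entry for day `floor(t/1440) mod 7` and hour
#' `floor((t mod 1440)/60)`, times the scenario's scale factor.
#'
#' @param schedule a 7 x 24 rate matrix (day x hour) or an `ed_scenario`.
#' @param t time in minutes, `t >= 0` (vectorized).
#' @param scale multiplicative factor on the rates.
#' @return arrival rate(s) in patients/hour.
#' @export
rate_at <- function(schedule, t, scale = 1) {
  if (inherits(schedule, "ed_scenario")) schedule <- schedule$arrivals
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  d <- (t %/% 1440) %% 7
  h <- (t %% 1440) %/% 60
  scale * schedule[cbind(d + 1, h + 1)]
}

#' Generate one week (or more) of patient arrivals
#'
#' For each hour block the arrival count is Poisson with mean
#' `scale * rate`, and the arrival instants are placed uniformly at random
#' within the block -- the conditional distribution of a homogeneous
#' Poisson process given its count, so the piecewise-constant process is
#' sampled exactly. Events are then sorted globally and ids assigned in
#' time order (ties keep generation order).
#'
#' @inheritParams rate_at
#' @param horizon simulation horizon in minutes, a multiple of 60.
#' @return a data frame with columns `time_min` (nondecreasing, in
#'   `[0, horizon)`) and `patient_id`.
#' @export
generate_arrivals <- function(schedule, horizon, scale = 1) {
  if (inherits(schedule, "ed_scenario")) schedule <- schedule$arrivals
  stopifnot(horizon %% 60 == 0)
  blocks <- horizon / 60
  b <- seq_len(blocks) - 1
  lambda <- scale * schedule[cbind((b %/% 24) %% 7 + 1, b %% 24 + 1)]
  counts <- rpois(blocks, lambda)
  n <- sum(counts)
  if (n == 0)
    return(data.frame(time_min = numeric(0), patient_id = integer(0)))
  t0 <- rep(b * 60, counts)
  times <- t0 + runif(n) * 60
  times <- times[order(times)]
  data.frame(time_min = times, patient_id = seq_len(n))
}

#' Assign triage levels
#'
#' Each patient is Level III with probability `level_probs["3"]`, else
#' Level IV.
#'
#' @param n number of patients.
#' @param triage a triage configuration (`$level_probs`, `$target_wait`)
#'   or an `ed_scenario`.
#' @return integer vector of levels in `{3, 4}`.
#' @export
assign_levels <- function(n, triage) {
  if (inherits(triage, "ed_scenario")) triage <- triage$triage
  p3 <- triage$level_probs[["3"]]
  ifelse(runif(n) < p3, 3L, 4L)
}

#' Write / read an arrival event list
#'
#' CSV replay files (`time_min`, `patient_id`, `level`) allow scripted
#' deterministic arrivals for debugging and tests.
#'
#' @param arrivals a data frame with `time_min`, `patient_id`, `level`.
#' @param path CSV path.
#' @export
write_arrivals_csv <- function(arrivals, path) {
  write.csv(arrivals[, c("time_min", "patient_id", "level")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_arrivals_csv
#' @export
read_arrivals_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_min", "patient_id", "level") %in% names(d)))
    stop("arrival replay CSV needs columns time_min, patient_id, level",
         call. = FALSE)
  if (is.unsorted(d$time_min)) stop("replay arrival times must be sorted",
                                    call. = FALSE)
  if (!all(d$level %in% c(3L, 4L))) stop("replay levels must be 3 or 4",
                                         call. = FALSE)
  d
}
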