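#' Waiting-time records of a replication
#'
#' Two families of waiting-time statistics are computed.
#'
#' *Stage waits* (components): the initial wait is
#' `init_start - arrival` for patients whose initial consultation
#' completed within the horizon; the follow-up wait is
#' `fu_start - t_exam` for patients whose follow-up consultation
#' completed. `w_pooled` pools all stage-wait records (a patient who
#' underwent exams contributes two records) over the total record count.
#'
#' *Journey waits* (the headline KPIs): one record per patient who
#' completed their full care path -- the sum of their initial wait and,
#' if they underwent examinations, their follow-up wait. `w_total` is
#' the mean journey wait over all completed patients and is the quantity
#' the policy comparison and the slack-tolerance optimization minimize;
#' `w_journey3` / `w_journey4` are the per-level means. Time spent in
#' consultation or in the examination subsystem is service, not waiting,
#' and is excluded throughout.
#'
#' A class with zero completions has an undefined (`NA`) mean and drops
#' out of pooled denominators.
#'
#' @param rep an `ed_replication`.
#' @return a list with the stage-wait vectors (`w3`, `w4`, `wf`), the
#'   journey-wait vectors (`j3`, `j4`) and the means `w_init3`,
#'   `w_init4`, `w_follow`, `w_pooled`, `w_journey3`, `w_journey4`,
#'   `w_total`.
#' @export
waiting_times <- function(rep) {
  p <- rep$patients
  done_init <- !is.na(p$init_end)
  w_init <- p$init_start - p$arrival
  w3 <- w_init[done_init & p$level == 3]
  w4 <- w_init[done_init & p$level == 4]
  done_fu <- !is.na(p$fu_end)
  w_fu <- p$fu_start - p$t_exam
  wf <- w_fu[done_fu]
  completed <- done_init & (p$n_exams == 0 | done_fu)
  journey <- w_init + ifelse(is.na(w_fu), 0, w_fu)
  j3 <- journey[completed & p$level == 3]
  j4 <- journey[completed & p$level == 4]
  nz_mean <- function(x) if (length(x)) mean(x) else NA_real_
  nrec <- length(w3) + length(w4) + length(wf)
  list(w3 = w3, w4 = w4, wf = wf, j3 = j3, j4 = j4,
       w_init3 = nz_mean(w3), w_init4 = nz_mean(w4), w_follow = nz_mean(wf),
       w_pooled = if (nrec) (sum(w3) + sum(w4) + sum(wf)) / nrec else NA_real_,
       w_journey3 = nz_mean(j3), w_journey4 = nz_mean(j4),
       w_total = nz_mean(c(j3, j4)))
}

#' Delay rates and service levels
#'
#' The delay rate of level `l` is the share of completed level-`l`
#' *initial* waits strictly exceeding the clinical target `T_l`; the
#' service level is its complement. A wait exactly equal to the target
#' counts as on time. `delay_init` pools both levels (each patient
#' compared against their own target).
#'
#' @param rep an `ed_replication`.
#' @param triage triage configuration (or an `ed_scenario`).
#' @return a list with `delay3`, `delay4`, `sl3`, `sl4`, `delay_init`
#'   (proportions; `NA` when a class has no completions).
#' @export
delay_service <- function(rep, triage) {
  if (inherits(triage, "ed_scenario")) triage <- triage$triage
  w <- waiting_times(rep)
  T3 <- triage$target_wait[["3"]]; T4 <- triage$target_wait[["4"]]
  rate <- function(x, T) if (length(x)) mean(x > T) else NA_real_
  d3 <- rate(w$w3, T3)
  d4 <- rate(w$w4, T4)
  pooled <- rate(c(w$w3 - T3, w$w4 - T4), 0)
  list(delay3 = d3, delay4 = d4, sl3 = 1 - d3, sl4 = 1 - d4,
       delay_init = pooled)
}

#' Physician and device utilization
#'
#' Physician utilization is total consultation busy-minutes over total
#' scheduled physician-minutes for the horizon; device utilization is
#' busy processing minutes (report delays do not occupy the device) over
#' `capacity * horizon`. Busy time accrued before the horizon by censored
#' patients is included.
#'
#' @param rep an `ed_replication`.
#' @param sc the `ed_scenario` the replication was run under.
#' @return a list with `u_doc` and the per-modality vector `u_dev`.
#' @export
utilization <- function(rep, sc) {
  sched <- scheduled_minutes(sc$staffing, rep$horizon)
  if (sched <= 0) stop("zero scheduled physician-minutes", call. = FALSE)
  list(u_doc = rep$doc_busy / sched,
       u_dev = rep$dev_busy / (sc$exams$modalities$capacity * rep$horizon))
}

#' All KPIs of one replication
#'
#' @param rep an `ed_replication`.
#' @param sc the `ed_scenario` it was run under.
#' @return a one-row data frame: journey waits (overall and by level),
#'   stage waits, delay rates and service levels, physician and device
#'   utilizations, and counts (arrivals, completions per class, censored
#'   patients).
#' @export
replication_metrics <- function(rep, sc) {
  w <- waiting_times(rep)
  ds <- delay_service(rep, sc)
  u <- utilization(rep, sc)
  p <- rep$patients
  completed <- !is.na(p$init_end) & (p$n_exams == 0 | !is.na(p$fu_end))
  data.frame(
    w_total = w$w_total, w_journey3 = w$w_journey3, w_journey4 = w$w_journey4,
    w_init3 = w$w_init3, w_init4 = w$w_init4, w_follow = w$w_follow,
    w_pooled = w$w_pooled,
    delay3 = ds$delay3, delay4 = ds$delay4, sl3 = ds$sl3, sl4 = ds$sl4,
    delay_init = ds$delay_init,
    u_doc = u$u_doc,
    u_lab = u$u_dev[["laboratory"]], u_us = u$u_dev[["ultrasound"]],
    u_xray = u$u_dev[["xray"]], u_ct = u$u_dev[["ct"]],
    n_arrivals = nrow(p),
    n_init3 = length(w$w3), n_init4 = length(w$w4), n_follow = length(w$wf),
    n_censored = nrow(p) - sum(completed)
  )
}

#' Aggregate per-replication KPIs
#'
#' For every KPI column: mean, sample standard deviation (n - 1), min,
#' max, median, and the normal-approximation 95% confidence interval
#' `mean +/- 1.96 * SD / sqrt(n)`.
#'
#' @param kpis a data frame of per-replication KPI rows (at least 2).
#' @return a data frame with one row per KPI.
#' @export
aggregate_metrics <- function(kpis) {
  n <- nrow(kpis)
  if (n < 2) stop("need at least 2 replications to aggregate", call. = FALSE)
  num <- kpis[vapply(kpis, is.numeric, logical(1))]
  rows <- lapply(names(num), function(k) {
    x <- num[[k]]
    m <- mean(x); s <- sd(x)
    data.frame(kpi = k, mean = m, sd = s, min = min(x), max = max(x),
               median = median(x),
               ci_lo = m - 1.96 * s / sqrt(n), ci_hi = m + 1.96 * s / sqrt(n),
               n = n)
  })
  do.call(rbind, rows)
}

#' KPI summary of a full experiment
#'
#' Runs (or accepts) a batch of replications and returns the
#' per-replication KPI table together with its aggregate.
#'
#' @param sc an `ed_scenario`.
#' @param reps a list of `ed_replication` (from [run_experiment()]).
#' @return list with `per_rep` and `aggregate` data frames.
#' @export
summarize_experiment <- function(sc, reps) {
  per_rep <- do.call(rbind, lapply(reps, replication_metrics, sc = sc))
  list(per_rep = per_rep, aggregate = aggregate_metrics(per_rep))
}
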