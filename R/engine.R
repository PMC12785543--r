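#' Pre-sample the stochastic inputs of one replication
#'
#' All randomness in a replication is per-patient and policy-independent:
#' arrival times, triage levels, both consultation durations, and the exam
#' requirement vector. They are drawn here, before the (deterministic)
#' event engine runs, from five named substreams seeded from `seed`, so
#' that the same seed yields identical patient populations under every
#' policy (exact common random numbers) and a change in one sampling
#' component (e.g. the lognormal variant's rejection draws) does not
#' perturb the others.
#'
#' @param sc an `ed_scenario`.
#' @param seed integer replication seed.
#' @return a list with `time` (sorted arrival minutes), `level`,
#'   `dur_initial`, `dur_followup`, and `exam` (n x 4 indicator matrix).
#' @export
patient_streams <- function(sc, seed) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 5)
  set.seed(sub[1])
  a <- generate_arrivals(sc$arrivals, sc$horizon, sc$arrival_scale)
  n <- nrow(a)
  set.seed(sub[2])
  lvl <- assign_levels(n, sc$triage)
  set.seed(sub[3])
  di <- sample_consult_duration(sc$consult_initial, n)
  set.seed(sub[4])
  df <- sample_consult_duration(sc$consult_followup, n)
  set.seed(sub[5])
  ex <- sample_exam_requirements(sc$exams, n)
  list(time = a$time_min, level = lvl, dur_initial = di, dur_followup = df,
       exam = ex)
}

#' Run one simulated week
#'
#' Simulates the interval `[0, horizon)` for one replication: patients
#' arrive, queue for an initial consultation, possibly traverse the
#' examination subsystem (devices are FIFO with finite capacity; report
#' delays overlap with subsequent exams), join the follow-up queue once
#' every report is available, and exit after the follow-up consultation.
#' The allocation rule is invoked at every decision epoch (a consult
#' completion, a shift change, or an arrival/report completion that
#' meets idle physicians). Each shift is staffed by its own crew: at a
#' boundary the incoming physicians are all available, while outgoing
#' physicians still mid-consultation finish their patient and then
#' withdraw; consultations are never preempted. The week starts empty,
#' and patients still in the system at the horizon are censored.
#'
#' @param sc an `ed_scenario`.
#' @param policy an [ed_policy()]; defaults to the scenario's.
#' @param seed integer seed (ignored when `streams` is supplied).
#' @param streams optional pre-sampled [patient_streams()] (used for
#'   common random numbers and for scripted/replayed inputs).
#' @return an object of class `ed_replication`: `patients` (one row per
#'   patient with the full timestamp trail), `exam_start` (n x 4 exam
#'   start times), `doc_busy` / `dev_busy` (busy minutes), queue lengths
#'   at the horizon, the policy and seed.
#' @export
run_replication <- function(sc, policy = NULL, seed = 1L, streams = NULL) {
  policy <- policy %||% sc$policy
  if (!inherits(policy, "ed_policy")) policy <- ed_policy(policy)
  if (is.null(streams)) streams <- patient_streams(sc, seed)
  n <- length(streams$time)
  ord <- modality_priority(sc$exams)
  se <- staffing_events(sc$staffing, sc$horizon)
  pol_code <- match(policy$name, c("IFP", "ALT", "SBP")) - 1L
  res <- .engine_run(
    as.numeric(streams$time), as.integer(streams$level),
    as.numeric(streams$dur_initial), as.numeric(streams$dur_followup),
    matrix(as.integer(streams$exam), ncol = 4), as.integer(ord),
    as.numeric(sc$exams$modalities$tau), as.numeric(sc$exams$modalities$delta),
    as.integer(sc$exams$modalities$capacity),
    as.numeric(se$time), as.integer(se$count),
    as.numeric(sc$horizon), pol_code,
    sc$triage$target_wait[["3"]], sc$triage$target_wait[["4"]],
    policy$k1 %||% 0, policy$k2 %||% 0)
  patients <- data.frame(
    id = seq_len(n),
    level = streams$level,
    arrival = streams$time,
    init_start = res$init_start[seq_len(n)],
    init_end = res$init_end[seq_len(n)],
    t_exam = res$t_exam[seq_len(n)],
    fu_start = res$fu_start[seq_len(n)],
    fu_end = res$fu_end[seq_len(n)],
    n_exams = if (n) rowSums(streams$exam) else integer(0)
  )
  exam_start <- res$exam_start[seq_len(max(n, 1)), , drop = FALSE][seq_len(n), , drop = FALSE]
  colnames(exam_start) <- MODALITIES
  structure(list(
    patients = patients,
    exam_start = exam_start,
    exam_req = streams$exam,
    doc_busy = res$doc_busy,
    dev_busy = stats::setNames(res$dev_busy, MODALITIES),
    queue_end = c(init3 = res$q3_end, init4 = res$q4_end, follow = res$qf_end),
    policy = policy,
    seed = seed,
    scenario_hash = rlang::hash(sc[setdiff(names(sc), "policy")]),
    horizon = sc$horizon
  ), class = "ed_replication")
}

#' Run a batch of independent replications
#'
#' Replication `r` uses seed `base_seed + r`. With the same `base_seed`,
#' two policies see identical patient populations (common random
#' numbers), because all sampling happens before the deterministic
#' engine.
#'
#' @inheritParams run_replication
#' @param n_reps number of replications.
#' @param base_seed integer base seed.
#' @return a list of `ed_replication` objects.
#' @export
run_experiment <- function(sc, policy = NULL, n_reps = sc$n_reps,
                           base_seed = sc$base_seed) {
  lapply(seq_len(n_reps), function(r)
    run_replication(sc, policy = policy, seed = base_seed + r))
}

#' Examination timetable for one patient
#'
#' Deterministically schedules one patient's required exams: modalities
#' are taken in [exam_order()]; the patient is ready for exam `k` when the
#' *processing* of exam `k - 1` ends (report delays run concurrently with
#' later exams); each exam starts at the later of the patient's ready time
#' and the device's free time; and the exam stage completes at
#' `t_exam = max(start + tau + delta)` over the required exams.
#'
#' This mirrors the engine's examination logic for a contention-free (or
#' single known device-free-time) setting and is used to cross-check it.
#'
#' @param ready time the patient finishes the initial consult (minutes).
#' @param req required modality names (or indicator vector).
#' @param exams exam configuration or `ed_scenario`.
#' @param device_free named vector of device free times (default all 0).
#' @return a data frame (`modality`, `start`, `proc_end`, `report`) with
#'   attribute `t_exam`.
#' @export
exam_timeline <- function(ready, req, exams, device_free = NULL) {
  if (inherits(exams, "ed_scenario")) exams <- exams$exams
  seqn <- exam_order(req, exams)
  m <- exams$modalities
  free <- stats::setNames(rep(0, 4), m$name)
  if (!is.null(device_free)) free[names(device_free)] <- device_free
  out <- data.frame(modality = seqn, start = NA_real_, proc_end = NA_real_,
                    report = NA_real_)
  for (i in seq_along(seqn)) {
    j <- seqn[i]
    row <- match(j, m$name)
    st <- max(ready, free[[j]])
    out$start[i] <- st
    out$proc_end[i] <- st + m$tau[row]
    out$report[i] <- st + m$tau[row] + m$delta[row]
    ready <- out$proc_end[i]
  }
  attr(out, "t_exam") <- max(out$report)
  out
}

#' @export
print.ed_replication <- function(x, ...) {
  n <- nrow(x$patients)
  cat(sprintf("ED replication (policy %s, seed %d): %d arrivals, %d completed, %d censored\n",
              x$policy$name, x$seed, n, sum(!is.na(x$patients$init_end) &
                (x$patients$n_exams == 0 | !is.na(x$patients$fu_end))),
              n - sum(!is.na(x$patients$init_end) &
                (x$patients$n_exams == 0 | !is.na(x$patients$fu_end)))))
  invisible(x)
}

#' Export a replication's patient trail
#'
#' One row per patient with every recorded timestamp (NA where the stage
#' was not reached before the horizon).
#'
#' @param rep an `ed_replication`.
#' @param path CSV path.
#' @export
write_patient_trail <- function(rep, path) {
  d <- cbind(rep$patients, rep$exam_start)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
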