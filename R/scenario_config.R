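#' @useDynLib edflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median pexp plnorm pt qexp rbinom rlnorm rpois runif sd
#' @importFrom utils read.csv write.csv
NULL

DAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
MODALITIES <- c("laboratory", "ultrasound", "xray", "ct")

#' Baseline emergency-department scenario
#'
#' Returns the default parameterization of the simulated emergency
#' department: a 7 x 24 table of hourly arrival rates with a weekly cycle,
#' a 25/75 triage mix over Levels III and IV with clinical waiting-time
#' targets of 30 and 120 minutes, truncated-exponential consultation times
#' (initial: mean 9 min on [5, 15]; follow-up: mean 15 min on [5, 25]),
#' four diagnostic modalities (laboratory, B-ultrasound, X-ray, CT) with a
#' 60% probability that an initial patient needs at least one exam, three
#' daily physician shifts (07:00-15:00 and 15:00-22:00 with 5 physicians,
#' 22:00-07:00 with 3), a one-week horizon (10,080 min) and 100
#' replications.
#'
#' All times are minutes; arrival rates are patients per hour. The
#' simulation clock starts Monday 00:00 and day index 1 is Monday.
#'
#' @param policy policy name, one of `"IFP"`, `"ALT"`, `"SBP"`.
#' @param k1,k2 slack tolerances in minutes (required when `policy = "SBP"`).
#' @return an object of class `ed_scenario`.
#' @examples
#' sc <- baseline_scenario()
#' sc$arrivals["Mon", 1]        # Monday, hour 0-1
#' @export
baseline_scenario <- function(policy = "IFP", k1 = NULL, k2 = NULL) {
  rates <- matrix(c(
    # Mon   Tue   Wed   Thu   Fri   Sat   Sun       (hour block)
    7.84,  7.50,  7.51,  7.49,  7.49,  7.13,  7.12,  # 0-1
    5.79,  5.37,  5.38,  5.35,  5.36,  5.07,  5.06,  # 1-2
    4.94,  4.50,  4.51,  4.50,  4.49,  4.31,  4.32,  # 2-3
    3.70,  3.33,  3.34,  3.30,  3.34,  3.11,  3.12,  # 3-4
    2.19,  1.83,  1.81,  1.80,  1.82,  1.68,  1.68,  # 4-5
    4.33,  3.58,  3.59,  3.54,  3.55,  3.21,  3.19,  # 5-6
    6.78,  6.39,  6.40,  6.37,  6.36,  6.08,  6.07,  # 6-7
    8.83,  8.23,  8.17,  8.18,  8.25,  7.98,  7.97,  # 7-8
    15.23, 14.95, 14.93, 14.90, 14.90, 14.49, 14.48, # 8-9
    21.59, 21.26, 21.24, 21.23, 21.27, 20.64, 20.61, # 9-10
    21.71, 21.44, 21.43, 21.45, 21.43, 20.65, 20.64, # 10-11
    17.53, 17.11, 17.12, 17.11, 17.10, 16.59, 16.51, # 11-12
    15.55, 15.18, 15.17, 15.18, 15.17, 14.73, 14.72, # 12-13
    18.26, 17.93, 17.94, 17.92, 17.92, 17.43, 17.41, # 13-14
    20.87, 20.76, 20.77, 20.75, 20.77, 19.97, 19.96, # 14-15
    18.28, 18.14, 18.15, 18.13, 18.13, 17.33, 17.35, # 15-16
    17.31, 17.14, 17.15, 17.13, 17.14, 16.47, 16.45, # 16-17
    16.28, 16.10, 16.11, 16.08, 16.10, 15.38, 15.39, # 17-18
    16.87, 16.46, 16.44, 16.43, 16.44, 15.97, 15.98, # 18-19
    22.61, 22.47, 22.46, 22.43, 22.44, 21.64, 21.63, # 19-20
    23.05, 22.81, 22.80, 22.79, 22.79, 22.44, 22.43, # 20-21
    17.53, 17.23, 17.24, 17.21, 17.22, 16.75, 16.74, # 21-22
    12.49, 12.31, 12.30, 12.29, 12.29, 11.83, 11.82, # 22-23
    7.52,  7.23,  7.21,  7.22,  7.24,  7.03,  7.02   # 23-24
  ), nrow = 7, ncol = 24,
  dimnames = list(DAY_NAMES, sprintf("h%02d", 0:23)))
  # column-major fill: each source line above is one hour block across Mon..Sun
  sc <- structure(list(
    arrivals = rates,
    triage = list(
      level_probs = c(`3` = 0.25, `4` = 0.75),
      target_wait = c(`3` = 30, `4` = 120)
    ),
    consult_initial = list(kind = "initial", family = "truncexp",
                           mean = 9, bounds = c(5, 15), sigma = NULL),
    consult_followup = list(kind = "follow-up", family = "truncexp",
                            mean = 15, bounds = c(5, 25), sigma = NULL),
    exams = list(
      p_exam = 0.6,
      modalities = data.frame(
        name = MODALITIES,
        prob = c(0.92, 0.22, 0.29, 0.55),
        tau = c(1.19, 6.58, 3.99, 2.45),
        delta = c(20, 0, 30, 30),
        capacity = c(1L, 1L, 1L, 1L),
        stringsAsFactors = FALSE
      )
    ),
    staffing = data.frame(
      start = c(7 * 60, 15 * 60, 22 * 60),
      end = c(15 * 60, 22 * 60, 7 * 60),
      count = c(5L, 5L, 3L)
    ),
    policy = ed_policy(policy, k1 = k1, k2 = k2),
    horizon = 10080,
    n_reps = 100L,
    base_seed = 1L,
    arrival_scale = 1
  ), class = "ed_scenario")
  validate_scenario(sc)
}

#' Policy specification
#'
#' @param name `"IFP"` (Initial-First), `"ALT"` (Alternating 1:1) or
#'   `"SBP"` (Slack-Based).
#' @param k1,k2 slack tolerances (minutes) for Level III and Level IV;
#'   required for SBP, ignored otherwise.
#' @return a list of class `ed_policy`.
#' @export
ed_policy <- function(name, k1 = NULL, k2 = NULL) {
  name <- match.arg(name, c("IFP", "ALT", "SBP"))
  if (name == "SBP") {
    if (is.null(k1) || is.null(k2))
      stop("policy 'SBP' requires slack tolerances k1 and k2", call. = FALSE)
    if (k1 < 0 || k2 < 0) stop("k1 and k2 must be >= 0", call. = FALSE)
  } else {
    k1 <- NULL; k2 <- NULL
  }
  structure(list(name = name, k1 = k1, k2 = k2), class = "ed_policy")
}

#' Validate a scenario
#'
#' Checks every structural invariant of an `ed_scenario`: nonnegative
#' 7 x 24 arrival table, triage probabilities summing to one, positive
#' waiting-time targets, consultation bounds `0 <= a < b`, exam
#' probabilities in `[0, 1]` with positive processing times and integer
#' capacities, a staffing schedule that partitions the 24-hour day, and a
#' horizon that is a positive multiple of 1440 minutes.
#'
#' @param sc an `ed_scenario`.
#' @return `sc`, invisibly unchanged, or an error naming the offending field.
#' @export
validate_scenario <- function(sc) {
  fail <- function(field, msg)
    stop(sprintf("invalid scenario: %s %s", field, msg), call. = FALSE)
  a <- sc$arrivals
  if (!is.matrix(a) || !all(dim(a) == c(7, 24)))
    fail("arrivals", "must be a 7 x 24 matrix (day x hour)")
  if (anyNA(a) || any(a < 0)) fail("arrivals", "must be nonnegative")
  tp <- sc$triage$level_probs
  if (!identical(names(tp), c("3", "4"))) fail("triage$level_probs", "must cover levels 3 and 4")
  if (any(tp < 0) || abs(sum(tp) - 1) > 1e-12)
    fail("triage$level_probs", "must be a probability mass summing to 1")
  if (any(sc$triage$target_wait <= 0)) fail("triage$target_wait", "must be > 0")
  for (nm in c("consult_initial", "consult_followup")) {
    cc <- sc[[nm]]
    if (!cc$family %in% c("truncexp", "trunclognormal"))
      fail(nm, "family must be 'truncexp' or 'trunclognormal'")
    if (cc$mean <= 0) fail(nm, "mean must be > 0")
    b <- cc$bounds
    if (length(b) != 2 || b[1] < 0 || b[1] >= b[2])
      fail(nm, "bounds must satisfy 0 <= a < b")
    if (cc$family == "trunclognormal" && (is.null(cc$sigma) || cc$sigma <= 0))
      fail(nm, "sigma must be > 0 for the lognormal family")
  }
  ex <- sc$exams
  if (ex$p_exam < 0 || ex$p_exam > 1) fail("exams$p_exam", "must lie in [0, 1]")
  m <- ex$modalities
  if (!identical(m$name, MODALITIES)) fail("exams$modalities", "must list laboratory, ultrasound, xray, ct")
  if (any(m$prob < 0 | m$prob > 1)) fail("exams$modalities$prob", "must lie in [0, 1]")
  if (any(m$tau <= 0)) fail("exams$modalities$tau", "must be > 0")
  if (any(m$delta < 0)) fail("exams$modalities$delta", "must be >= 0")
  if (any(m$capacity < 1) || any(m$capacity != as.integer(m$capacity)))
    fail("exams$modalities$capacity", "must be integers >= 1")
  if (ex$p_exam > 0 && all(m$prob == 0))
    fail("exams", "p_exam > 0 with all modality probabilities 0 cannot terminate")
  st <- sc$staffing
  if (any(st$count < 0) || any(st$count != as.integer(st$count)))
    fail("staffing$count", "must be integers >= 0")
  dur <- ifelse(st$end > st$start, st$end - st$start, 1440 - st$start + st$end)
  if (sum(dur) != 1440) fail("staffing", "shifts must partition the 24-hour day")
  o <- order(st$start)
  nxt <- c(o[-1], o[1])
  if (any(st$end[o] %% 1440 != st$start[nxt]))
    fail("staffing", "shifts must be contiguous (no gaps or overlaps)")
  if (sc$horizon <= 0 || sc$horizon %% 1440 != 0)
    fail("horizon", "must be a positive multiple of 1440 minutes")
  if (sc$n_reps < 1) fail("n_reps", "must be >= 1")
  if (sc$arrival_scale < 0) fail("arrival_scale", "must be >= 0")
  if (!inherits(sc$policy, "ed_policy")) fail("policy", "must be an ed_policy")
  invisible(sc)
}

#' Modify a scenario
#'
#' Convenience helpers returning a validated copy of a scenario with one
#' component replaced.
#'
#' @param sc an `ed_scenario`.
#' @param policy an `ed_policy` or a policy name.
#' @param k1,k2 SBP slack tolerances (minutes).
#' @param scale multiplicative factor on all arrival rates.
#' @param counts integer vector of physician counts, one per staffing shift
#'   (in the order the shifts are stored, morning/afternoon/night for the
#'   baseline).
#' @param family consultation-time family for both consult stages.
#' @param sigma lognormal shape parameter.
#' @return the modified `ed_scenario`.
#' @name scenario-modifiers
NULL

#' @rdname scenario-modifiers
#' @export
set_policy <- function(sc, policy, k1 = NULL, k2 = NULL) {
  sc$policy <- if (inherits(policy, "ed_policy")) policy else ed_policy(policy, k1, k2)
  validate_scenario(sc)
}

#' @rdname scenario-modifiers
#' @export
set_arrival_scale <- function(sc, scale) {
  sc$arrival_scale <- scale
  validate_scenario(sc)
}

#' @rdname scenario-modifiers
#' @export
set_staffing_counts <- function(sc, counts) {
  stopifnot(length(counts) == nrow(sc$staffing))
  sc$staffing$count <- as.integer(counts)
  validate_scenario(sc)
}

#' @rdname scenario-modifiers
#' @export
set_consult_family <- function(sc, family, sigma = 0.3) {
  family <- match.arg(family, c("truncexp", "trunclognormal"))
  for (nm in c("consult_initial", "consult_followup")) {
    sc[[nm]]$family <- family
    sc[[nm]]$sigma <- if (family == "trunclognormal") sigma else NULL
  }
  validate_scenario(sc)
}

minutes_to_hm <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)
hm_to_minutes <- function(s) {
  p <- strsplit(s, ":", fixed = TRUE)
  vapply(p, function(x) as.integer(x[1]) * 60L + as.integer(x[2]), integer(1))
}

#' Physicians on duty at a clock time
#'
#' @param staffing a staffing data frame (`start`, `end`, `count`, minutes
#'   of day; a shift with `end < start` wraps midnight).
#' @param t simulation time in minutes (any nonnegative value; only the
#'   minute-of-day matters).
#' @return integer physician count.
#' @export
staffing_at <- function(staffing, t) {
  stopifnot(t >= 0)
  m <- t %% 1440
  for (i in seq_len(nrow(staffing))) {
    s <- staffing$start[i]; e <- staffing$end[i]
    hit <- if (s < e) (m >= s && m < e) else (m >= s || m < e)
    if (hit) return(staffing$count[i])
  }
  stop("staffing schedule does not cover minute ", m)
}

# Capacity-change event list for the engine: (time, count) at every shift
# start within [0, horizon), with an event at t = 0.
staffing_events <- function(staffing, horizon) {
  days <- seq_len(horizon / 1440) - 1
  tt <- as.vector(outer(staffing$start, days * 1440, `+`))
  cc <- rep(staffing$count, times = length(days))
  o <- order(tt)
  tt <- tt[o]; cc <- cc[o]
  if (tt[1] != 0) {
    tt <- c(0, tt)
    cc <- c(staffing_at(staffing, 0), cc)
  }
  keep <- tt < horizon
  list(time = tt[keep], count = as.integer(cc[keep]))
}

# Total scheduled physician-minutes over the horizon.
scheduled_minutes <- function(staffing, horizon) {
  dur <- ifelse(staffing$end > staffing$start,
                staffing$end - staffing$start,
                1440 - staffing$start + staffing$end)
  sum(dur * staffing$count) * horizon / 1440
}

#' Save / load a scenario file
#'
#' Scenarios are stored as human-editable YAML. All durations are minutes,
#' arrival rates are patients per hour, and shift boundaries are `"HH:MM"`
#' clock strings. `load_scenario()` checks the schema (a missing or
#' malformed field raises an error naming it) and then every scenario
#' invariant via [validate_scenario()].
#'
#' @param sc an `ed_scenario`.
#' @param path file path.
#' @return `load_scenario()` returns the validated `ed_scenario`;
#'   `save_scenario()` returns `path` invisibly.
#' @export
save_scenario <- function(sc, path) {
  x <- list(
    arrivals = stats::setNames(lapply(seq_len(7), function(d) as.numeric(sc$arrivals[d, ])),
                               DAY_NAMES),
    triage = list(level_probs = as.list(sc$triage$level_probs),
                  target_wait = as.list(sc$triage$target_wait)),
    consult = list(
      initial = consult_to_list(sc$consult_initial),
      followup = consult_to_list(sc$consult_followup)
    ),
    exams = list(p_exam = sc$exams$p_exam,
                 modalities = stats::setNames(lapply(seq_len(4), function(i) {
                   m <- sc$exams$modalities[i, ]
                   list(prob = m$prob, tau = m$tau, delta = m$delta,
                        capacity = m$capacity)
                 }), sc$exams$modalities$name)),
    staffing = lapply(seq_len(nrow(sc$staffing)), function(i) {
      list(start = minutes_to_hm(sc$staffing$start[i]),
           end = minutes_to_hm(sc$staffing$end[i]),
           count = sc$staffing$count[i])
    }),
    policy = list(name = sc$policy$name, k1 = sc$policy$k1, k2 = sc$policy$k2),
    horizon = sc$horizon, n_reps = sc$n_reps, base_seed = sc$base_seed,
    arrival_scale = sc$arrival_scale
  )
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

consult_to_list <- function(cc) {
  out <- list(family = cc$family, mean = cc$mean,
              bounds = as.numeric(cc$bounds))
  if (!is.null(cc$sigma)) out$sigma <- cc$sigma
  out
}

#' @rdname save_scenario
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  need <- function(obj, field, where) {
    if (is.null(obj[[field]]))
      stop(sprintf("scenario schema error: missing field '%s' in %s", field, where),
           call. = FALSE)
    obj[[field]]
  }
  for (f in c("arrivals", "triage", "consult", "exams", "staffing", "policy", "horizon"))
    need(x, f, "scenario")
  arr <- x$arrivals
  if (!all(DAY_NAMES %in% names(arr)))
    stop("scenario schema error: arrivals must have entries Mon..Sun", call. = FALSE)
  rates <- t(vapply(DAY_NAMES, function(d) {
    v <- as.numeric(arr[[d]])
    if (length(v) != 24)
      stop("scenario schema error: arrivals$", d, " must have 24 hourly rates",
           call. = FALSE)
    v
  }, numeric(24)))
  dimnames(rates) <- list(DAY_NAMES, sprintf("h%02d", 0:23))
  consult_from_list <- function(cl, kind, where) {
    list(kind = kind,
         family = need(cl, "family", where),
         mean = need(cl, "mean", where),
         bounds = as.numeric(need(cl, "bounds", where)),
         sigma = cl$sigma)
  }
  pol <- x$policy
  pname <- need(pol, "name", "policy")
  if (identical(pname, "SBP") && (is.null(pol$k1) || is.null(pol$k2)))
    stop("scenario schema error: policy 'SBP' requires fields k1 and k2",
         call. = FALSE)
  mods <- need(x$exams, "modalities", "exams")
  md <- do.call(rbind, lapply(MODALITIES, function(nm) {
    m <- need(mods, nm, "exams$modalities")
    data.frame(name = nm, prob = need(m, "prob", nm), tau = need(m, "tau", nm),
               delta = need(m, "delta", nm),
               capacity = as.integer(need(m, "capacity", nm)),
               stringsAsFactors = FALSE)
  }))
  st <- do.call(rbind, lapply(x$staffing, function(s) {
    data.frame(start = hm_to_minutes(need(s, "start", "staffing")),
               end = hm_to_minutes(need(s, "end", "staffing")),
               count = as.integer(need(s, "count", "staffing")))
  }))
  sc <- structure(list(
    arrivals = rates,
    triage = list(
      level_probs = c(`3` = as.numeric(need(x$triage$level_probs, "3", "triage$level_probs")),
                      `4` = as.numeric(need(x$triage$level_probs, "4", "triage$level_probs"))),
      target_wait = c(`3` = as.numeric(need(x$triage$target_wait, "3", "triage$target_wait")),
                      `4` = as.numeric(need(x$triage$target_wait, "4", "triage$target_wait")))
    ),
    consult_initial = consult_from_list(need(x$consult, "initial", "consult"),
                                        "initial", "consult$initial"),
    consult_followup = consult_from_list(need(x$consult, "followup", "consult"),
                                         "follow-up", "consult$followup"),
    exams = list(p_exam = need(x$exams, "p_exam", "exams"), modalities = md),
    staffing = st,
    policy = ed_policy(pname, k1 = pol$k1, k2 = pol$k2),
    horizon = need(x, "horizon", "scenario"),
    n_reps = as.integer(x$n_reps %||% 100L),
    base_seed = as.integer(x$base_seed %||% 1L),
    arrival_scale = as.numeric(x$arrival_scale %||% 1)
  ), class = "ed_scenario")
  validate_scenario(sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import/export the arrival-rate table as CSV
#'
#' The CSV mirrors the scenario's printed layout: a header row
#' `Mon..Sun` and 24 rows of hourly rates (patients/hour), hour 0 first.
#'
#' @param sc an `ed_scenario` (export) .
#' @param path CSV file path.
#' @return `read_arrival_csv()` returns a 7 x 24 rate matrix (day x hour).
#' @export
write_arrival_csv <- function(sc, path) {
  write.csv(as.data.frame(t(sc$arrivals)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arrival_csv
#' @export
read_arrival_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (!identical(names(d), DAY_NAMES) || nrow(d) != 24)
    stop("arrival CSV must have columns Mon..Sun and 24 hour rows", call. = FALSE)
  m <- t(as.matrix(d))
  dimnames(m) <- list(DAY_NAMES, sprintf("h%02d", 0:23))
  m
}

#' @export
print.ed_scenario <- function(x, ...) {
  cat("Emergency-department scenario\n")
  cat(sprintf("  horizon: %d min (%d days), %d replications, base seed %d\n",
              x$horizon, x$horizon %/% 1440, x$n_reps, x$base_seed))
  cat(sprintf("  arrivals: weekly NHPP, mean %.0f patients/week (scale %.2f)\n",
              sum(x$arrivals) * x$arrival_scale, x$arrival_scale))
  cat(sprintf("  triage: P(L3) = %.2f, targets %g/%g min\n",
              x$triage$level_probs[["3"]],
              x$triage$target_wait[["3"]], x$triage$target_wait[["4"]]))
  cat(sprintf("  policy: %s%s\n", x$policy$name,
              if (x$policy$name == "SBP")
                sprintf(" (k1 = %g, k2 = %g)", x$policy$k1, x$policy$k2) else ""))
  invisible(x)
}
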