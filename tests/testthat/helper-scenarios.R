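# Shared fixtures: all built in code at test time.

# Scenario with a constant arrival rate, a single 24 h shift of `c`
# physicians, one patient class and no exams: an M/M/c system when the
# consultation bounds are effectively unbounded.
mmc_scenario <- function(rate_per_hour, mean_service, c_servers,
                         bounds = c(0, 1e6), p3 = 0) {
  sc <- baseline_scenario()
  sc$arrivals[] <- rate_per_hour
  sc$triage$level_probs <- c(`3` = p3, `4` = 1 - p3)
  sc$consult_initial$mean <- mean_service
  sc$consult_initial$bounds <- bounds
  sc$exams$p_exam <- 0
  sc$staffing <- data.frame(start = 0, end = 1440, count = as.integer(c_servers))
  validate_scenario(sc)
}

# Steady-state mean queue wait (minutes) of an M/M/c queue, Erlang-C.
erlang_c_wait <- function(rate_per_hour, mean_service, c_servers) {
  lam <- rate_per_hour / 60            # per minute
  mu <- 1 / mean_service
  a <- lam / mu
  stopifnot(a < c_servers)
  k <- 0:(c_servers - 1)
  p0_inv <- sum(a^k / factorial(k)) +
    a^c_servers / factorial(c_servers) * c_servers / (c_servers - a)
  C <- a^c_servers / factorial(c_servers) * c_servers / (c_servers - a) / p0_inv
  C / (c_servers * mu - lam)
}

# Tiny deterministic scenario: one physician on duty around the clock,
# optionally no exams; patient attributes are supplied explicitly.
micro_scenario <- function(p_exam = 0) {
  sc <- baseline_scenario()
  sc$arrivals[] <- 0
  sc$exams$p_exam <- p_exam
  sc$staffing <- data.frame(start = 0, end = 1440, count = 1L)
  validate_scenario(sc)
}

# Hand-built patient streams for scripted engine runs.
micro_streams <- function(time, level, dur_init = 10, dur_follow = 10,
                          exam = NULL) {
  n <- length(time)
  if (is.null(exam)) exam <- matrix(0L, n, 4, dimnames = list(NULL, c(
    "laboratory", "ultrasound", "xray", "ct")))
  list(time = time, level = as.integer(level),
       dur_initial = base::rep(dur_init, length.out = n),
       dur_followup = base::rep(dur_follow, length.out = n),
       exam = exam)
}

# Random queue states for policy property tests.
random_state <- function(t = 200, max_q = 6, max_free = 6) {
  mk <- function(n) {
    if (n == 0) return(empty_queue())
    data.frame(id = sample.int(10000, n), join = sort(runif(n, 0, t)))
  }
  queue_state(mk(sample(0:max_q, 1)), mk(sample(0:max_q, 1)),
              mk(sample(0:max_q, 1)), t = t, free = sample(0:max_free, 1))
}

# Brute-force reference: explicit priority-ordered patient list, take the
# first `free`.
brute_force_select <- function(state, order_blocks) {
  ids <- unlist(lapply(order_blocks, function(q) q$id), use.names = FALSE)
  utils::head(ids, state$free)
}

brute_force_ifp <- function(state) {
  brute_force_select(state, list(state$init3, state$init4, state$follow))
}

brute_force_sbp <- function(state, cfg) {
  u3 <- state$t - state$init3$join >= cfg$T3 - cfg$k1
  u4 <- state$t - state$init4$join >= cfg$T4 - cfg$k2
  brute_force_select(state, list(
    state$init3[u3, ], state$init4[u4, ], state$follow,
    state$init3[!u3, ], state$init4[!u4, ]))
}

# Independent re-derivation of the ALT quota arithmetic.
alt_counts_reference <- function(D3, D4, Df, R) {
  quota <- R %/% 2
  n3 <- min(D3, quota); n4 <- min(D4, quota - n3)
  nf <- min(Df, R - n3 - n4)
  spare <- R - n3 - n4 - nf
  add3 <- min(D3 - n3, spare)
  add4 <- min(D4 - n4, spare - add3)
  c(n3 = n3 + add3, n4 = n4 + add4, nf = nf)
}

selected_ids <- function(alloc) c(alloc$init3, alloc$init4, alloc$follow)
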