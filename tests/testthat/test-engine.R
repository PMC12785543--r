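test_that("a scripted two-patient day is traced exactly", {
  sc <- micro_scenario()
  st <- micro_streams(time = c(0, 1), level = c(3, 4), dur_init = 10)
  for (pol in list(ed_policy("IFP"), ed_policy("ALT"),
                   ed_policy("SBP", 13.1, 2.1))) {
    r <- run_replication(sc, pol, streams = st)
    p <- r$patients
    expect_equal(p$init_start, c(0, 10))
    expect_equal(p$init_end, c(10, 20))
    expect_equal(p$init_start - p$arrival, c(0, 9))   # waits
    expect_true(all(is.na(p$fu_start)))               # no exams configured
  }
})

test_that("an empty week produces no patients and no busy time", {
  sc <- micro_scenario()
  r <- run_replication(sc, "IFP", seed = 1)
  expect_equal(nrow(r$patients), 0)
  expect_equal(r$doc_busy, 0)
  expect_true(all(r$dev_busy == 0))
  m <- replication_metrics(r, sc)
  expect_true(is.na(m$w_total))
  expect_equal(m$u_doc, 0)
})

test_that("SBP serves a ready follow-up before a non-urgent Level IV", {
  # one physician; B (L3, one zero-delay exam) then C and A (L4, no exams)
  sc <- micro_scenario()
  ex <- matrix(0L, 3, 4, dimnames = list(NULL, c("laboratory", "ultrasound",
                                                 "xray", "ct")))
  ex[1, "ultrasound"] <- 1L
  st <- micro_streams(time = c(0, 12, 13), level = c(3, 4, 4), dur_init = 10,
                      dur_follow = 10, exam = ex)
  r <- run_replication(sc, ed_policy("SBP", 13.1, 2), streams = st)
  p <- r$patients
  # B: consult 0-10, ultrasound 10-16.58, report immediate -> t_exam 16.58
  expect_equal(p$t_exam[1], 16.58)
  # C arrives 12 and meets the idle physician; epoch t = 22: A waited 9 min
  # (not urgent, 9 < 118) so B's follow-up outranks A
  expect_equal(p$init_start[2], 12)
  expect_equal(p$fu_start[1], 22)
  expect_equal(p$init_start[3], 32)
  # under Initial-First, A outranks B's follow-up at the same epoch
  r2 <- run_replication(sc, "IFP", streams = st)
  expect_equal(r2$patients$init_start[3], 22)
  expect_equal(r2$patients$fu_start[1], 32)
})

test_that("examinations chain by processing time with overlapping reports", {
  sc <- micro_scenario(p_exam = 1)
  # single CT after a consult ending at 100
  ex <- matrix(0L, 1, 4, dimnames = list(NULL, c("laboratory", "ultrasound",
                                                 "xray", "ct")))
  ex[1, "ct"] <- 1L
  st <- micro_streams(time = 90, level = 4, dur_init = 10, exam = ex)
  r <- run_replication(sc, "IFP", streams = st)
  expect_equal(r$patients$init_end, 100)
  expect_equal(unname(r$exam_start[1, "ct"]), 100)
  expect_equal(r$patients$t_exam, 100 + 2.45 + 30)   # 132.45

  # xray + lab from a free start: xray 0-3.99 (report 33.99),
  # lab 3.99-5.18 (report 25.18), exams done at 33.99
  tl <- exam_timeline(0, c("laboratory", "xray"), sc)
  expect_equal(tl$modality, c("xray", "laboratory"))
  expect_equal(tl$start, c(0, 3.99))
  expect_equal(tl$proc_end, c(3.99, 5.18))
  expect_equal(tl$report, c(33.99, 25.18))
  expect_equal(attr(tl, "t_exam"), 33.99)

  # engine agrees with the single-patient timetable
  ex2 <- ex; ex2[1, ] <- c(1L, 0L, 1L, 0L)
  st2 <- micro_streams(time = 90, level = 4, dur_init = 10, exam = ex2)
  r2 <- run_replication(sc, "IFP", streams = st2)
  expect_equal(unname(r2$exam_start[1, "xray"]), 100)
  expect_equal(unname(r2$exam_start[1, "laboratory"]), 103.99)
  expect_equal(r2$patients$t_exam, 133.99)
})

test_that("a busy device queues the patient FIFO and delays the start", {
  sc <- micro_scenario(p_exam = 1)
  sc$staffing$count <- 2L
  sc <- validate_scenario(sc)
  ex <- matrix(0L, 2, 4, dimnames = list(NULL, c("laboratory", "ultrasound",
                                                 "xray", "ct")))
  ex[, "ct"] <- 1L
  st <- micro_streams(time = c(30, 31), level = c(4, 4), dur_init = 10, exam = ex)
  r <- run_replication(sc, "IFP", streams = st)
  # A: ct 40-42.45; B ready at 41 while the device is busy -> starts 42.45
  expect_equal(unname(r$exam_start[1, "ct"]), 40)
  expect_equal(unname(r$exam_start[2, "ct"]), 42.45)
})

test_that("mean queue waits match the Erlang-C closed form in the M/M/c limit", {
  cases <- list(c(18, 10, 4), c(10, 9, 2), c(30, 6, 4))
  for (cs in cases) {
    sc <- mmc_scenario(cs[1], cs[2], cs[3])
    w_ref <- erlang_c_wait(cs[1], cs[2], cs[3])
    waits <- vapply(1:40, function(r) {
      rep_ <- run_replication(sc, "IFP", seed = 1000 + r)
      p <- rep_$patients
      keep <- p$arrival > 1440 & !is.na(p$init_end)   # discard warm-up day
      mean(p$init_start[keep] - p$arrival[keep])
    }, numeric(1))
    se <- sd(waits) / sqrt(length(waits))
    expect_lt(abs(mean(waits) - w_ref), 3 * se)
  }
})

test_that("flow conservation, non-preemption and capacity hold on a baseline week", {
  sc <- baseline_scenario()
  for (pol in list(ed_policy("IFP"), ed_policy("SBP", 13.1, 2.1))) {
    r <- run_replication(sc, pol, seed = 31)
    p <- r$patients
    streams <- patient_streams(sc, 31)
    # flow conservation: every arrival is completed, mid-path, or queued
    completed <- !is.na(p$init_end) & (p$n_exams == 0 | !is.na(p$fu_end))
    in_exams <- !is.na(p$init_end) & p$n_exams > 0 & is.na(p$t_exam)
    in_follow_q <- !is.na(p$t_exam) & is.na(p$fu_start)
    in_fu_service <- !is.na(p$fu_start) & is.na(p$fu_end)
    in_init_q <- is.na(p$init_start)
    in_init_service <- !is.na(p$init_start) & is.na(p$init_end)
    expect_equal(sum(completed) + sum(in_exams) + sum(in_follow_q) +
                   sum(in_fu_service) + sum(in_init_q) + sum(in_init_service),
                 nrow(p))
    expect_equal(unname(r$queue_end["follow"]), sum(in_follow_q))
    # non-preemption: realized consult length equals the sampled duration
    done <- !is.na(p$init_end)
    expect_equal(p$init_end[done] - p$init_start[done],
                 streams$dur_initial[done])
    # timestamps weakly increasing along the care path
    expect_true(all(p$init_start >= p$arrival, na.rm = TRUE))
    expect_true(all(p$t_exam >= p$init_end, na.rm = TRUE))
    expect_true(all(p$fu_start >= p$t_exam, na.rm = TRUE))
    expect_true(all(p$fu_end >= p$fu_start, na.rm = TRUE))
    # queue conservation between epochs: joins up to t minus starts up to t
    # is the queue length, hence never negative
    for (t in seq(60, 10020, by = 60)) {
      expect_gte(sum(p$arrival <= t) - sum(p$init_start <= t, na.rm = TRUE), 0)
      expect_gte(sum(p$t_exam <= t, na.rm = TRUE) -
                   sum(p$fu_start <= t, na.rm = TRUE), 0)
    }
    # physician capacity: consults started within the current shift never
    # exceed the on-duty count (carryover consults are handover lame ducks)
    starts <- c(p$init_start, p$fu_start)
    ends <- c(p$init_end, p$fu_end)
    ok <- !is.na(starts) & !is.na(ends)
    starts <- starts[ok]; ends <- ends[ok]
    bounds <- sort(unique(c(0, staffing_events(sc$staffing, sc$horizon)$time)))
    for (t in seq(30, 10050, by = 90)) {
      shift_start <- max(bounds[bounds <= t])
      active_this_shift <- sum(starts >= shift_start & starts <= t & ends > t)
      expect_lte(active_this_shift, staffing_at(sc$staffing, t))
    }
    # device capacity: one concurrent exam per modality
    for (j in colnames(r$exam_start)) {
      s <- r$exam_start[!is.na(r$exam_start[, j]), j]
      if (length(s) > 1) {
        tau <- sc$exams$modalities$tau[sc$exams$modalities$name == j]
        expect_true(all(diff(sort(s)) >= tau - 1e-9))
      }
    }
  }
})

test_that("under Initial-First a follow-up starts only when initial queues are empty", {
  sc <- baseline_scenario()
  r <- run_replication(sc, "IFP", seed = 17)
  p <- r$patients
  fu_epochs <- p$fu_start[!is.na(p$fu_start)]
  waiting_over <- function(t) sum(p$arrival < t & (is.na(p$init_start) |
                                                     p$init_start > t))
  for (t in sample(fu_epochs, 200)) expect_equal(waiting_over(t), 0)
})

test_that("replications are deterministic and share streams across policies", {
  sc <- baseline_scenario()
  r1 <- run_replication(sc, "IFP", seed = 5)
  r2 <- run_replication(sc, "IFP", seed = 5)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$doc_busy, r2$doc_busy)
  # common random numbers: identical arrivals, levels, durations under SBP
  r3 <- run_replication(sc, ed_policy("SBP", 13.1, 2.1), seed = 5)
  expect_identical(r3$patients$arrival, r1$patients$arrival)
  expect_identical(r3$patients$level, r1$patients$level)
  reps <- run_experiment(sc, "IFP", n_reps = 3, base_seed = 4)
  expect_length(reps, 3)
  expect_identical(reps[[1]]$patients, r2$patients)   # seed = base + r = 5
})
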