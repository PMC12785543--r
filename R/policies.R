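#' Queue state at a decision epoch
#'
#' A snapshot of the three consultation queues handed to an allocation
#' rule: the Level III and Level IV initial queues and the follow-up
#' queue, each a FIFO data frame with columns `id` and `join` (the time
#' the patient joined that queue -- arrival time for initial queues, the
#' exam-completion time for the follow-up queue), plus the epoch time and
#' the number of free physicians.
#'
#' @param init3,init4,follow data frames with columns `id`, `join`
#'   (FIFO order; rows are sorted by `join` if not already).
#' @param t epoch time in minutes.
#' @param free number of free physicians (`>= 0`).
#' @return a list of class `ed_queue_state`.
#' @export
queue_state <- function(init3 = empty_queue(), init4 = empty_queue(),
                        follow = empty_queue(), t = 0, free = 0) {
  fix <- function(q) {
    q <- as.data.frame(q)[, c("id", "join")]
    q[order(q$join), , drop = FALSE]
  }
  structure(list(init3 = fix(init3), init4 = fix(init4), follow = fix(follow),
                 t = t, free = as.integer(free)),
            class = "ed_queue_state")
}

#' @rdname queue_state
#' @export
empty_queue <- function() data.frame(id = integer(0), join = numeric(0))

allocation <- function(sel3, sel4, self, n3, n4, nf, nr) {
  structure(list(n3 = n3, n4 = n4, nf = nf, nr = nr,
                 init3 = sel3, init4 = sel4, follow = self),
            class = "ed_allocation")
}

take <- function(q, k) if (k > 0) q$id[seq_len(k)] else integer(0)

#' Initial-First allocation
#'
#' Initial consultations always take precedence: Level III demand is
#' served first, then Level IV, and follow-up patients only receive the
#' physicians left over (`N3 = min(D3, R)`, `N4 = min(D4, R - N3)`,
#' `Nf = min(Df, R - N3 - N4)`), FIFO within each queue.
#'
#' @param state an [queue_state()].
#' @return an `ed_allocation` with per-class counts (`n3`, `n4`, `nf`,
#'   `nr`) and the selected patient ids per queue.
#' @export
ifp_allocate <- function(state) {
  R <- state$free
  n3 <- min(nrow(state$init3), R)
  n4 <- min(nrow(state$init4), R - n3)
  nf <- min(nrow(state$follow), R - n3 - n4)
  allocation(take(state$init3, n3), take(state$init4, n4),
             take(state$follow, nf), n3, n4, nf, 0L)
}

#' Alternating 1:1 allocation
#'
#' Physician capacity is split between initial and follow-up
#' consultations: at most `floor(R/2)` of the free physicians go to
#' initial patients (Level III before Level IV), the remainder to
#' follow-up, and any quota a category cannot use is reassigned to the
#' other, so no physician idles while demand exists. At a single-free-
#' physician epoch the initial quota is `floor(1/2) = 0`: the physician
#' takes a follow-up patient when one is waiting, otherwise an initial
#' patient. Averaged over completions this realizes the 1:1 split, since
#' every follow-up consultation is preceded by exactly one initial
#' consultation of the same patient.
#'
#' @inheritParams ifp_allocate
#' @return an `ed_allocation`.
#' @export
alt_allocate <- function(state) {
  R <- state$free
  D3 <- nrow(state$init3); D4 <- nrow(state$init4); Df <- nrow(state$follow)
  if (R < 1 || D3 + D4 + Df == 0)
    return(allocation(integer(0), integer(0), integer(0), 0L, 0L, 0L, 0L))
  q <- R %/% 2
  n3 <- min(D3, q)
  n4 <- min(D4, q - n3)
  nf <- min(Df, R - n3 - n4)
  rem <- R - n3 - n4 - nf
  e3 <- min(D3 - n3, rem); n3 <- n3 + e3; rem <- rem - e3
  e4 <- min(D4 - n4, rem); n4 <- n4 + e4
  allocation(take(state$init3, n3), take(state$init4, n4),
             take(state$follow, nf),
             as.integer(n3), as.integer(n4), as.integer(nf), 0L)
}

#' Slack-Based allocation
#'
#' A waiting initial patient is *urgent* at time `t` when the remaining
#' slack before their clinical target is at most the tolerance:
#' `w_i(t) >= T_l - k_l` (inclusive). The allocation order is
#' urgent Level III, then urgent Level IV, then follow-up, then
#' non-urgent initial patients (Level III before Level IV), FIFO within
#' each set. Counts `n3`/`n4` are the urgent selections and `nr` the
#' non-urgent initial selections.
#'
#' @inheritParams ifp_allocate
#' @param cfg a list with thresholds `T3`, `T4` and slack tolerances
#'   `k1`, `k2` (minutes).
#' @return an `ed_allocation`.
#' @export
sbp_allocate <- function(state, cfg) {
  u3 <- state$t - state$init3$join >= cfg$T3 - cfg$k1
  u4 <- state$t - state$init4$join >= cfg$T4 - cfg$k2
  R <- state$free
  m3 <- min(sum(u3), R)
  m4 <- min(sum(u4), R - m3)
  nf <- min(nrow(state$follow), R - m3 - m4)
  rem <- R - m3 - m4 - nf
  h3 <- min(sum(!u3), rem); rem <- rem - h3
  h4 <- min(sum(!u4), rem)
  # urgent members are a FIFO prefix of each queue, so urgent + non-urgent
  # selections from one queue are its first m + h members
  allocation(take(state$init3, m3 + h3), take(state$init4, m4 + h4),
             take(state$follow, nf),
             as.integer(m3), as.integer(m4), as.integer(nf),
             as.integer(h3 + h4))
}

#' Dispatch an allocation rule by policy
#'
#' @param state an [queue_state()].
#' @param policy an [ed_policy()].
#' @param triage triage configuration supplying `T3`/`T4` for SBP.
#' @return an `ed_allocation`.
#' @export
allocate <- function(state, policy, triage = NULL) {
  switch(policy$name,
    IFP = ifp_allocate(state),
    ALT = alt_allocate(state),
    SBP = sbp_allocate(state, list(
      T3 = triage$target_wait[["3"]], T4 = triage$target_wait[["4"]],
      k1 = policy$k1, k2 = policy$k2))
  )
}
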