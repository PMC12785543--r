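#' Sample consultation durations
#'
#' Draws service times from the configured family conditioned to lie in
#' the truncation interval `[a, b]`:
#'
#' * `truncexp` -- an exponential with mean `mean` (the mean of the
#'   untruncated base distribution, i.e. rate `1/mean`), sampled by
#'   inverse-CDF on the truncated distribution;
#' * `trunclognormal` -- a lognormal with `meanlog = log(mean) - sigma^2/2`
#'   (so the untruncated mean is exactly `mean`) and `sdlog = sigma`,
#'   sampled by rejection.
#'
#' @param cfg a consultation-time configuration (`$family`, `$mean`,
#'   `$bounds`, `$sigma`).
#' @param n number of draws.
#' @return `n` durations in minutes, all strictly inside `[a, b]`.
#' @export
sample_consult_duration <- function(cfg, n) {
  a <- cfg$bounds[1]; b <- cfg$bounds[2]
  if (cfg$family == "truncexp") {
    rate <- 1 / cfg$mean
    Fa <- pexp(a, rate); Fb <- pexp(b, rate)
    if (Fb - Fa < 1e-12)
      stop("truncation interval [", a, ", ", b,
           "] has negligible base mass", call. = FALSE)
    qexp(Fa + runif(n) * (Fb - Fa), rate)
  } else if (cfg$family == "trunclognormal") {
    mu <- log(cfg$mean) - cfg$sigma^2 / 2
    if (plnorm(b, mu, cfg$sigma) - plnorm(a, mu, cfg$sigma) < 1e-12)
      stop("truncation interval [", a, ", ", b,
           "] has negligible base mass", call. = FALSE)
    out <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      x <- rlnorm(length(todo), mu, cfg$sigma)
      ok <- x > a & x < b
      out[todo[ok]] <- x[ok]
      todo <- todo[!ok]
    }
    out
  } else stop("unknown consultation-time family: ", cfg$family, call. = FALSE)
}

#' Analytic mean of a truncated consultation-time distribution
#'
#' For the truncated exponential the closed form
#' `a + m - (b - a) * exp(-(b-a)/m) / (1 - exp(-(b-a)/m))` is used
#' (with `m` the untruncated mean); for the truncated lognormal the mean
#' is computed by numerical integration.
#'
#' @inheritParams sample_consult_duration
#' @return the expected duration in minutes after truncation.
#' @export
truncated_mean <- function(cfg) {
  a <- cfg$bounds[1]; b <- cfg$bounds[2]
  if (cfg$family == "truncexp") {
    m <- cfg$mean; w <- b - a
    a + m - w * exp(-w / m) / (1 - exp(-w / m))
  } else {
    mu <- log(cfg$mean) - cfg$sigma^2 / 2
    mass <- plnorm(b, mu, cfg$sigma) - plnorm(a, mu, cfg$sigma)
    stats::integrate(function(x) x * stats::dlnorm(x, mu, cfg$sigma),
                     a, b, rel.tol = 1e-10)$value / mass
  }
}

#' Sample examination requirement vectors
#'
#' With probability `1 - p_exam` a patient needs no examination; otherwise
#' independent Bernoulli(`p_j`) indicators are drawn per modality and the
#' vector is resampled until at least one indicator is 1, so every patient
#' passing the gate has at least one exam.
#'
#' @param exams an exam configuration (`$p_exam`, `$modalities`) or an
#'   `ed_scenario`.
#' @param n number of patients.
#' @return an `n x 4` 0/1 integer matrix with columns
#'   `laboratory, ultrasound, xray, ct`.
#' @export
sample_exam_requirements <- function(exams, n) {
  if (inherits(exams, "ed_scenario")) exams <- exams$exams
  p <- exams$modalities$prob
  if (exams$p_exam > 0 && all(p == 0))
    stop("p_exam > 0 with all modality probabilities 0: resampling cannot terminate",
         call. = FALSE)
  req <- matrix(0L, n, 4, dimnames = list(NULL, MODALITIES))
  if (n == 0) return(req)
  gated <- which(runif(n) < exams$p_exam)
  todo <- gated
  while (length(todo)) {
    draw <- matrix(rbinom(length(todo) * 4L, 1L, rep(p, each = length(todo))),
                   ncol = 4)
    ok <- rowSums(draw) > 0
    req[todo[ok], ] <- draw[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  req
}

#' Order a patient's examinations
#'
#' Required modalities are scheduled in descending order of report delay
#' `delta`, so the exams whose results take longest are started first and
#' their reporting overlaps with later exams. Ties in `delta` are broken
#' by processing time `tau` descending, then by modality name, giving a
#' deterministic total order.
#'
#' @param req modality names, a logical/0-1 vector over the four
#'   modalities, or one row of [sample_exam_requirements()].
#' @param exams an exam configuration or an `ed_scenario`.
#' @return character vector of modality names in scheduling order.
#' @export
exam_order <- function(req, exams) {
  if (inherits(exams, "ed_scenario")) exams <- exams$exams
  m <- exams$modalities
  if (is.character(req)) {
    sel <- m$name %in% req
    if (!all(req %in% m$name)) stop("unknown modality in requirement", call. = FALSE)
  } else {
    sel <- as.logical(req)
  }
  if (!any(sel)) stop("empty examination requirement", call. = FALSE)
  mm <- m[sel, ]
  mm$name[order(-mm$delta, -mm$tau, mm$name)]
}

# Global modality scheduling priority for the engine (0-based indices into
# the canonical modality order, sorted by the exam_order rule applied to
# all four modalities).
modality_priority <- function(exams) {
  full <- exam_order(MODALITIES, exams)
  match(full, exams$modalities$name) - 1L
}
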