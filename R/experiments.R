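# Shared runner: per replication r, one set of patient streams is sampled
# (seed base_seed + r) and every policy is simulated on it, so policy
# comparisons use exact common random numbers.
run_policy_set <- function(sc, policies, n_reps, base_seed,
                           streams_list = NULL) {
  if (is.null(streams_list))
    streams_list <- lapply(seq_len(n_reps), function(r)
      patient_streams(sc, base_seed + r))
  out <- lapply(policies, function(pol) {
    rows <- lapply(seq_len(n_reps), function(r) {
      rep_ <- run_replication(sc, policy = pol, seed = base_seed + r,
                              streams = streams_list[[r]])
      replication_metrics(rep_, sc)
    })
    do.call(rbind, rows)
  })
  names(out) <- vapply(policies, policy_label, character(1))
  out
}

policy_label <- function(pol) {
  if (!inherits(pol, "ed_policy")) pol <- ed_policy(pol)
  if (pol$name == "SBP") sprintf("SBP(%g,%g)", pol$k1, pol$k2) else pol$name
}

#' Grid search over the slack tolerances
#'
#' Evaluates the Slack-Based policy on every `(k1, k2)` cell of a grid:
#' each cell is simulated with `n_reps` replications under common random
#' numbers (identical patient streams for every cell, keyed only by the
#' replication index, so the ranking is invariant to evaluation order).
#' Cells are ranked by mean overall waiting time; the reported optimum is
#' the best cell whose mean Level III and Level IV service levels meet the
#' constraints. If no cell is feasible the unconstrained ranking is
#' returned with a feasibility warning.
#'
#' @param sc an `ed_scenario` (its policy field is ignored).
#' @param k1_values,k2_values numeric grids of slack tolerances (minutes).
#' @param n_reps replications per cell (`>= 2`).
#' @param sl_min3,sl_min4 minimum mean service levels for Level III/IV.
#' @param base_seed integer seed.
#' @return an object of class `ed_grid_search`: `table` (one row per cell,
#'   ranked ascending by mean wait, with SD, 95% CI and service levels),
#'   `best` (the constrained argmin row), and `feasible` (logical).
#' @export
grid_search <- function(sc, k1_values, k2_values, n_reps = 50,
                        sl_min3 = 0.95, sl_min4 = 0.95,
                        base_seed = sc$base_seed) {
  stopifnot(length(k1_values) > 0, length(k2_values) > 0, n_reps >= 2)
  streams_list <- lapply(seq_len(n_reps), function(r)
    patient_streams(sc, base_seed + r))
  cells <- expand.grid(k1 = k1_values, k2 = k2_values)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pol <- ed_policy("SBP", cells$k1[i], cells$k2[i])
    kpis <- run_policy_set(sc, list(pol), n_reps, base_seed,
                           streams_list = streams_list)[[1]]
    m <- mean(kpis$w_total); s <- sd(kpis$w_total)
    data.frame(k1 = cells$k1[i], k2 = cells$k2[i],
               mean_wait = m, sd_wait = s,
               ci_lo = m - 1.96 * s / sqrt(n_reps),
               ci_hi = m + 1.96 * s / sqrt(n_reps),
               sl3 = mean(kpis$sl3, na.rm = TRUE),
               sl4 = mean(kpis$sl4, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(ifelse(is.na(tab$mean_wait), Inf, tab$mean_wait),
                   tab$k1, tab$k2), ]
  rownames(tab) <- NULL
  # a level with no completions (NA service level) cannot violate its bound
  feas <- (is.na(tab$sl3) | tab$sl3 >= sl_min3) &
    (is.na(tab$sl4) | tab$sl4 >= sl_min4)
  feasible <- any(feas)
  if (!feasible)
    warning("no grid cell satisfies the service-level constraints; ",
            "returning the unconstrained optimum", call. = FALSE)
  best <- if (feasible) tab[which(feas)[1], ] else tab[1, ]
  structure(list(table = tab, best = best, feasible = feasible,
                 n_reps = n_reps, sl_min3 = sl_min3, sl_min4 = sl_min4),
            class = "ed_grid_search")
}

#' @export
print.ed_grid_search <- function(x, ...) {
  cat(sprintf("Slack-tolerance grid search (%d cells, %d reps/cell)\n",
              nrow(x$table), x$n_reps))
  cat(sprintf("  best%s: k1 = %g, k2 = %g, mean wait %.2f min [%.2f, %.2f]\n",
              if (x$feasible) "" else " (service-level constraints infeasible)",
              x$best$k1, x$best$k2, x$best$mean_wait, x$best$ci_lo, x$best$ci_hi))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' Two-stage slack-tolerance optimization
#'
#' Stage 1 scans a coarse grid (default step 1 over `[0, 40]^2`, 50
#' replications per cell); stage 2 refines with step `fine_step` (default
#' 0.1) over a `+/- fine_halfwidth` neighborhood of the stage-1 optimum
#' (100 replications per cell) and returns the stage-2 constrained
#' argmin.
#'
#' @inheritParams grid_search
#' @param coarse_range numeric length-2 range for both tolerances.
#' @param coarse_step,fine_step grid steps (minutes).
#' @param coarse_reps,fine_reps replications per cell in each stage.
#' @param fine_halfwidth half-width of the stage-2 neighborhood.
#' @return list with `coarse`, `fine` (both `ed_grid_search`) and `best`
#'   (named vector `k1`, `k2`).
#' @export
two_stage_optimize <- function(sc, coarse_range = c(0, 40), coarse_step = 1,
                               coarse_reps = 50, fine_step = 0.1,
                               fine_reps = 100, fine_halfwidth = 1,
                               sl_min3 = 0.95, sl_min4 = 0.95,
                               base_seed = sc$base_seed) {
  grid1 <- seq(coarse_range[1], coarse_range[2], by = coarse_step)
  coarse <- grid_search(sc, grid1, grid1, n_reps = coarse_reps,
                        sl_min3 = sl_min3, sl_min4 = sl_min4,
                        base_seed = base_seed)
  ctr <- c(coarse$best$k1, coarse$best$k2)
  fgrid <- function(c0) seq(max(coarse_range[1], c0 - fine_halfwidth),
                            c0 + fine_halfwidth, by = fine_step)
  fine <- grid_search(sc, fgrid(ctr[1]), fgrid(ctr[2]), n_reps = fine_reps,
                      sl_min3 = sl_min3, sl_min4 = sl_min4,
                      base_seed = base_seed)
  list(coarse = coarse, fine = fine,
       best = c(k1 = fine$best$k1, k2 = fine$best$k2))
}

#' Compare scheduling policies with paired statistics
#'
#' Runs every policy on identical patient streams (common random
#' numbers), aggregates each policy's KPIs, and performs a paired t-test
#' on the per-replication overall mean waits for every policy pair, with
#' Bonferroni-adjusted significance at `alpha / n_pairs` and the paired
#' Cohen's d `mean(diff) / sd(diff)` (which equals `t / sqrt(n)`).
#'
#' @param sc an `ed_scenario`.
#' @param policies a list of [ed_policy()] objects (or names), length
#'   `>= 2`.
#' @param n_reps paired replications.
#' @param base_seed integer seed.
#' @param alpha family-wise significance level before correction.
#' @return an object of class `ed_comparison`: `per_rep` (list of KPI
#'   data frames per policy), `aggregate` (list of aggregate tables),
#'   `pairwise` (mean difference, t, p, Bonferroni flag, Cohen's d).
#' @export
compare_policies <- function(sc, policies, n_reps = sc$n_reps,
                             base_seed = sc$base_seed, alpha = 0.05) {
  if (length(policies) < 2)
    stop("need at least two policies to compare", call. = FALSE)
  policies <- lapply(policies, function(p)
    if (inherits(p, "ed_policy")) p else ed_policy(p))
  per_rep <- run_policy_set(sc, policies, n_reps, base_seed)
  labs <- names(per_rep)
  pairs <- utils::combn(seq_along(policies), 2, simplify = FALSE)
  alpha_adj <- alpha / length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(ij) {
    d <- per_rep[[ij[1]]]$w_total - per_rep[[ij[2]]]$w_total
    n <- length(d)
    if (sd(d) == 0) {
      tstat <- NA_real_; pval <- NA_real_; coh <- if (all(d == 0)) 0 else NA_real_
    } else {
      tstat <- mean(d) / (sd(d) / sqrt(n))
      pval <- 2 * pt(-abs(tstat), df = n - 1)
      coh <- mean(d) / sd(d)
    }
    data.frame(a = labs[ij[1]], b = labs[ij[2]], mean_diff = mean(d),
               t = tstat, p = pval,
               significant = !is.na(pval) & pval < alpha_adj,
               cohens_d = coh)
  }))
  structure(list(per_rep = per_rep,
                 aggregate = lapply(per_rep, aggregate_metrics),
                 pairwise = pw, alpha_adj = alpha_adj, n_reps = n_reps),
            class = "ed_comparison")
}

#' @export
print.ed_comparison <- function(x, ...) {
  cat(sprintf("Policy comparison (%d CRN replications, alpha_adj = %.4f)\n",
              x$n_reps, x$alpha_adj))
  for (lab in names(x$per_rep))
    cat(sprintf("  %-12s overall wait %6.2f min  (L3 %6.2f, L4 %6.2f)\n", lab,
                mean(x$per_rep[[lab]]$w_total),
                mean(x$per_rep[[lab]]$w_journey3),
                mean(x$per_rep[[lab]]$w_journey4)))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Arrival-rate sensitivity analysis
#'
#' Re-runs the policy comparison with all arrival rates scaled by each
#' factor (default `0.85` to `1.15` in steps of `0.03`, 11 scenarios).
#'
#' @inheritParams compare_policies
#' @param scales multiplicative factors on the arrival-rate table.
#' @return list with `scales`, `mean_wait` (scale x policy matrix of mean
#'   overall waits) and `results` (one `ed_comparison` per scale).
#' @export
arrival_sensitivity <- function(sc, policies, scales = arrival_sensitivity_scales(),
                                n_reps = sc$n_reps, base_seed = sc$base_seed) {
  results <- lapply(scales, function(s)
    compare_policies(set_arrival_scale(sc, s), policies, n_reps, base_seed))
  mw <- t(vapply(results, function(cmp)
    vapply(cmp$per_rep, function(k) mean(k$w_total), numeric(1)),
    numeric(length(results[[1]]$per_rep))))
  rownames(mw) <- sprintf("%.2f", scales)
  list(scales = scales, mean_wait = mw, results = results)
}

#' @rdname arrival_sensitivity
#' @export
arrival_sensitivity_scales <- function() seq(0.85, 1.15, by = 0.03)

#' Staffing scenarios for the sensitivity analysis
#'
#' Seven shift configurations S0-S6 (morning, afternoon, night physician
#' counts) from the baseline (5, 5, 3) up to (7, 7, 5).
#'
#' @return a data frame with columns `scenario`, `morning`, `afternoon`,
#'   `night`.
#' @export
staffing_scenarios <- function() {
  data.frame(
    scenario = paste0("S", 0:6),
    morning = c(5L, 5L, 5L, 5L, 5L, 6L, 7L),
    afternoon = c(5L, 5L, 5L, 6L, 7L, 7L, 7L),
    night = c(3L, 4L, 5L, 5L, 5L, 5L, 5L)
  )
}

#' Physician-staffing sensitivity analysis
#'
#' Re-runs the policy comparison under each staffing configuration of
#' [staffing_scenarios()] (or a user-supplied table with the same
#' columns).
#'
#' @inheritParams compare_policies
#' @param scenarios a staffing-scenario data frame.
#' @return list with `scenarios`, `mean_wait` (scenario x policy matrix)
#'   and `results`.
#' @export
staffing_sensitivity <- function(sc, policies, scenarios = staffing_scenarios(),
                                 n_reps = sc$n_reps, base_seed = sc$base_seed) {
  results <- lapply(seq_len(nrow(scenarios)), function(i)
    compare_policies(
      set_staffing_counts(sc, c(scenarios$morning[i], scenarios$afternoon[i],
                                scenarios$night[i])),
      policies, n_reps, base_seed))
  mw <- t(vapply(results, function(cmp)
    vapply(cmp$per_rep, function(k) mean(k$w_total), numeric(1)),
    numeric(length(results[[1]]$per_rep))))
  rownames(mw) <- scenarios$scenario
  list(scenarios = scenarios, mean_wait = mw, results = results)
}

#' Service-time distribution robustness
#'
#' Swaps both consultation-time families to the truncated lognormal
#' (`sigma = 0.3`, `meanlog = log(mean) - sigma^2/2`, same truncation
#' bounds) and re-runs the policy comparison.
#'
#' @inheritParams compare_policies
#' @param sigma lognormal shape parameter.
#' @return an `ed_comparison` with an added `mean_wait` named vector.
#' @export
distribution_robustness <- function(sc, policies, sigma = 0.3,
                                    n_reps = sc$n_reps,
                                    base_seed = sc$base_seed) {
  sc_ln <- set_consult_family(sc, "trunclognormal", sigma = sigma)
  cmp <- compare_policies(sc_ln, policies, n_reps, base_seed)
  cmp$mean_wait <- vapply(cmp$per_rep, function(k) mean(k$w_total), numeric(1))
  cmp
}
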