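#' Summarise a simulation into time/cost metrics
#'
#' Computes the headline metrics of a simulated execution: time-to-solution
#' (TTS — wall-clock makespan from the moment launches are issued, so VM
#' launch time is included), cost-to-solution (CTS — the summed billed cost
#' of every VM's uptime under the billing policy), pooled core utilization
#' (busy core-minutes over core-minutes of uptime) and idle core-minutes
#' after readiness.  The configured policy, threshold, noise level, seed and
#' billing mode are echoed into the row for provenance.
#'
#' @param sim An `ethread_sim` object from [run_simulation()].
#' @param billing A [billing_policy()]; defaults to the one the simulation
#'   was run with.
#' @return A one-row tibble.
#' @export
compute_metrics <- function(sim, billing = NULL) {
  billing <- billing %||% sim$config$billing
  per_vm <- vm_metrics(sim, billing)
  done <- sim$schedule$end_min
  tts <- max(c(done[!is.na(done)], sim$vms$ready_min))
  serve_core_min <- sum(per_vm$cores * (per_vm$shutdown_min - per_vm$ready_min))
  busy <- sum(per_vm$busy_core_min)
  denom <- sum(per_vm$cores * per_vm$uptime_min)
  tibble::tibble(
    tts_min = tts,
    cts_usd = sum(per_vm$cost_usd),
    busy_core_min = busy,
    utilization = if (denom > 0) busy / denom else NA_real_,
    idle_core_min = serve_core_min - busy,
    n_tasks = sim$config$n_tasks,
    n_vms = nrow(per_vm),
    policy = sim$config$policy,
    reschedule_threshold = sim$config$reschedule_threshold,
    noise_sigma = sim$config$noise_sigma,
    seed = sim$config$seed,
    billing_mode = billing$mode,
    base_unit_usd = billing$base_unit_usd
  )
}

#' Per-VM uptime, cost and utilization
#'
#' @inheritParams compute_metrics
#' @return A tibble with one row per VM: readiness, shutdown, uptime, busy
#'   core-minutes, hourly rate, billed cost and utilization.
#' @export
vm_metrics <- function(sim, billing = NULL) {
  billing <- billing %||% sim$config$billing
  vms <- sim$vms
  rate <- vms$relative_cost * billing$base_unit_usd + billing$surcharge_usd_hr
  dplyr::mutate(vms,
                rate_usd_hr = rate,
                cost_usd = billed_cost(.data$uptime_min, rate,
                                       mode = billing$mode),
                utilization = ifelse(.data$uptime_min > 0,
                                     .data$busy_core_min /
                                       (.data$cores * .data$uptime_min),
                                     NA_real_))
}

#' @method tidy ethread_sim
#' @export
tidy.ethread_sim <- function(x, ...) {
  x$schedule
}

#' @method glance ethread_sim
#' @export
glance.ethread_sim <- function(x, ...) {
  x$metrics
}

#' Pareto front of time/cost scenarios
#'
#' Filters a table of scenarios to its non-dominated subset: a scenario stays
#' when no other scenario is at least as good in both time and cost and
#' strictly better in one.  Time-optimal and cost-optimal executions are
#' generally different instance choices, so the front is the menu a planner
#' chooses from.
#'
#' @param scenarios A data frame of scenarios.
#' @param tts,cts Column names (strings) holding time and cost; defaults
#'   `"tts_min"`, `"cts_usd"`.
#' @return The non-dominated rows of `scenarios`, in the original order.
#' @examples
#' pts <- tibble::tibble(tts_min = c(10, 8, 12), cts_usd = c(5, 7, 4))
#' pareto_front(pts)
#' @export
pareto_front <- function(scenarios, tts = "tts_min", cts = "cts_usd") {
  if (nrow(scenarios) == 0) {
    abort("Need at least one scenario.", class = "ethreadsim_validation")
  }
  x <- scenarios[[tts]]
  y <- scenarios[[cts]]
  keep <- vapply(seq_along(x), function(i) {
    dominated <- x <= x[i] & y <= y[i] & (x < x[i] | y < y[i])
    !any(dominated)
  }, logical(1))
  scenarios[keep, , drop = FALSE]
}
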