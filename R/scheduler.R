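#' Order tasks longest-first (LPT)
#'
#' Sorts a workload by descending predicted duration — the longest-processing-
#' time list order that the greedy schedulers consume.  Ties are broken
#' lexicographically by tool name, then sequence id, then task id, so the
#' order is total and deterministic.
#'
#' @param tasks A workload tibble; predictions come from its `predicted_min`
#'   column or from `model` + `instance`.
#' @param model A fitted [fit_runtime_model()] (optional when
#'   `predicted_min` exists).
#' @param instance Instance name used for prediction.
#' @return `tasks` reordered, with a `predicted_min` column attached.
#' @export
order_tasks_lpt <- function(tasks, model = NULL, instance = NULL) {
  if (nrow(tasks) == 0) return(tasks)
  tasks$predicted_min <- predict_duration(tasks, instance, model)
  tasks[order(-tasks$predicted_min, tasks$tool, tasks$seq_id, tasks$task_id,
              method = "radix"), , drop = FALSE]
}

#' Reorder remaining tasks after a runtime deviation
#'
#' The dynamic scheduling rule: when a finished task's actual duration
#' deviates from its prediction by more than `threshold` (relative), the
#' completed task's actual/predicted ratio is applied as a correction to
#' every not-yet-started task of the same tool, and the ready queue is
#' re-sorted longest-first under the corrected predictions.  Below the
#' threshold nothing changes.
#'
#' @param ready Tibble of not-yet-started tasks with `predicted_min` (and the
#'   usual workload columns).
#' @param actual_min,predicted_min Actual and predicted duration of the task
#'   that just completed.
#' @param tool Tool of the completed task (`NA` applies the correction to no
#'   one).
#' @param threshold Relative deviation that triggers rescheduling.
#' @return A list with `ready` (possibly reordered/corrected) and `triggered`
#'   (logical).
#' @examples
#' rdy <- tibble::tibble(task_id = c("a", "b"), tool = c("X", "Y"),
#'                       seq_id = "s", predicted_min = c(10, 8))
#' reschedule_on_deviation(rdy, actual_min = 30, predicted_min = 10, tool = "X")
#' @export
reschedule_on_deviation <- function(ready, actual_min, predicted_min, tool,
                                    threshold = 0.10) {
  if (threshold <= 0) {
    abort("threshold must be positive.", class = "ethreadsim_validation")
  }
  deviation <- abs(actual_min - predicted_min) / predicted_min
  if (!is.finite(deviation) || deviation <= threshold || is.na(tool)) {
    return(list(ready = ready, triggered = FALSE))
  }
  ratio <- actual_min / predicted_min
  same <- !is.na(ready$tool) & ready$tool == tool
  ready$predicted_min[same] <- ready$predicted_min[same] * ratio
  ready <- ready[order(-ready$predicted_min, ready$tool, ready$seq_id,
                       ready$task_id, method = "radix"), , drop = FALSE]
  list(ready = ready, triggered = TRUE)
}

#' Exact minimum makespan for small independent-task instances
#'
#' A brute-force oracle: the exact minimum makespan of independent tasks on a
#' small set of machines, minimized over every assignment of tasks to cores
#' (machine grouping adds nothing beyond its pooled cores, since cores within
#' a machine are identical).  Implemented as branch-and-bound with
#' identical-load symmetry pruning; refuses instances beyond 10 tasks or 3
#' machines, where exhaustive search stops being honest.
#'
#' @param durations Task durations in minutes.
#' @param machines Integer vector of per-machine core counts (length <= 3).
#' @return The optimal makespan in minutes.
#' @examples
#' brute_force_optimal(c(5, 4, 3, 3, 3), machines = c(1, 1))  # 9
#' @export
brute_force_optimal <- function(durations, machines) {
  if (length(durations) > 10 || length(machines) > 3) {
    abort("brute_force_optimal is limited to <= 10 tasks and <= 3 machines.",
          class = "ethreadsim_validation")
  }
  if (length(machines) < 1 || any(machines < 1)) {
    abort("Need at least one machine with >= 1 core.",
          class = "ethreadsim_validation")
  }
  if (length(durations) == 0) return(0)
  if (any(durations < 0)) {
    abort("Durations must be nonnegative.", class = "ethreadsim_validation")
  }
  d <- sort(as.numeric(durations), decreasing = TRUE)
  cores <- sum(machines)
  lower <- max(d[1], sum(d) / cores)
  loads <- numeric(cores)
  best <- Inf
  rec <- function(i) {
    if (best <= lower) return()
    if (i > length(d)) {
      best <<- min(best, max(loads))
      return()
    }
    tried <- c()
    for (k in seq_len(cores)) {
      lk <- loads[k]
      if (any(abs(tried - lk) < 1e-12)) next
      tried <- c(tried, lk)
      if (lk + d[i] >= best) next
      loads[k] <<- lk + d[i]
      rec(i + 1)
      loads[k] <<- lk
    }
  }
  rec(1)
  best
}
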