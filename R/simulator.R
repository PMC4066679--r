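#' Assemble a virtual-machine pool
#'
#' Expands instance-type counts into one row per VM, carrying everything the
#' simulator needs (cores, memory, launch statistics, nonsupport list,
#' relative cost).
#'
#' @param spec Either a character vector of instance-type names (one VM
#'   each) or a named integer vector of counts, e.g. `c(m1.large = 2)`.
#' @param instances Instance catalog, as from [load_instance_catalog()].
#' @return A tibble with one row per VM (`vm`, plus the catalog columns).
#' @examples
#' vm_pool(c(`m1.large` = 2, `c1.xlarge` = 1))
#' @export
vm_pool <- function(spec, instances = load_instance_catalog()) {
  if (is.null(names(spec))) {
    names_vec <- as.character(spec)
  } else {
    names_vec <- rep(names(spec), times = as.integer(spec))
  }
  missing <- setdiff(unique(names_vec), instances$name)
  if (length(missing) > 0) {
    abort(paste0("Unknown instance types: ", paste(missing, collapse = ", ")),
          class = "ethreadsim_validation")
  }
  pool <- instances[match(names_vec, instances$name), , drop = FALSE]
  pool <- dplyr::mutate(pool, vm = sprintf("vm%03d", dplyr::row_number()),
                        .before = 1)
  pool
}

# Memory footprint (GB) a task occupies while running: the owning tool's
# memory class for main/post tasks, BLAST/PSIPRED's own class for separable
# prerequisites, Low for meta-analysis.  Tools absent from the catalog
# (synthetic workloads) are treated as unconstrained.
task_mem_need <- function(workload, tools) {
  key <- dplyr::case_when(
    workload$kind == "prereq_blast" ~ "BLAST",
    workload$kind == "prereq_psipred" ~ "PSIPRED",
    TRUE ~ workload$tool
  )
  hit <- match(key, tools$name)
  need <- ifelse(is.na(hit), 0, MEM_CLASS_GB[tools$mem_class[ifelse(is.na(hit), 1L, hit)]])
  need[workload$kind == "meta_analysis"] <- MEM_CLASS_GB[["Low"]]
  list(group = ifelse(workload$kind == "meta_analysis", ".meta", key),
       need_gb = as.numeric(need))
}

#' Simulate a workload on a VM pool
#'
#' Runs the discrete-event execution of a workload under a scheduling policy:
#' all VMs are launched at time zero and become ready after a sampled launch
#' time; tasks whose dependencies are complete queue in policy order and are
#' placed on idle feasible cores (respecting each instance's nonsupport list
#' and a per-tool concurrent-memory cap); actual durations are the
#' instance-specific predictions perturbed by multiplicative lognormal noise
#' (or taken verbatim from an `actual_min` column).  Policies:
#'
#' * `"greedy_lpt"` — longest-predicted-first list scheduling over the whole
#'   pool (the default).
#' * `"greedy_lpt_dynamic"` — greedy LPT plus deviation-triggered
#'   rescheduling: when a finished task deviates from its prediction by more
#'   than `reschedule_threshold`, its tool's predictions on that instance are
#'   corrected by the observed ratio and the queue is re-sorted.
#' * `"serial"` — one core of the first VM, tasks in dependency order; the
#'   single-machine baseline.
#' * `"per_tool_static"` — each tool's tasks pinned to one VM, tools dealt
#'   round-robin over the VMs feasible for them; the one-VM-per-tool static
#'   plan.
#'
#' @param workload A workload tibble ([build_workload()]); may carry
#'   `predicted_min` / `actual_min` override columns.
#' @param pool A VM pool ([vm_pool()]), or instance-catalog rows (one VM per
#'   row).
#' @param model A fitted [fit_runtime_model()] (optional when
#'   `predicted_min` is present).
#' @param policy Scheduling policy, see above.
#' @param reschedule_threshold Relative deviation triggering a dynamic
#'   re-sort.
#' @param noise_sigma Lognormal sigma of the actual/predicted ratio; 0 makes
#'   actual durations equal predictions.
#' @param seed Integer seed governing launch times and duration noise; equal
#'   seeds give byte-identical event logs.
#' @param billing A [billing_policy()] used for the cost metrics.
#' @param tools Tool catalog used for memory classes.
#' @param ordering_instance Instance name whose predictions order the queue;
#'   defaults to the first VM's type.
#' @return An object of class `ethread_sim`: a list with `events` (the event
#'   log), `schedule` (per-task placement and timing), `vms` (per-VM ready,
#'   shutdown and uptime), `metrics` (see [compute_metrics()]) and `config`.
#' @export
run_simulation <- function(workload, pool, model = NULL,
                           policy = c("greedy_lpt", "greedy_lpt_dynamic",
                                      "serial", "per_tool_static"),
                           reschedule_threshold = 0.10,
                           noise_sigma = 0.1, seed = 1L,
                           billing = billing_policy(),
                           tools = load_tool_catalog(),
                           ordering_instance = NULL) {
  policy <- match.arg(policy)
  if (is.null(pool) || nrow(pool) == 0) {
    abort("no virtual machines configured", class = "ethreadsim_validation")
  }
  validate_workload(workload)
  if (policy == "serial") {
    pool <- pool[1, , drop = FALSE]
    pool$cores <- 1L
  }
  if (!"vm" %in% names(pool)) {
    pool <- dplyr::mutate(pool, vm = sprintf("vm%03d", dplyr::row_number()),
                          .before = 1)
  }
  nvm <- nrow(pool)
  n <- nrow(workload)

  set.seed(seed)
  launch_min <- vapply(seq_len(nvm),
                       function(k) sample_launch_time(pool[k, ], 1), numeric(1))
  ready_vm <- launch_min  # launches are all issued at t = 0
  noise <- if (noise_sigma > 0) rlnorm(n, 0, noise_sigma) else rep(1, n)

  mem <- task_mem_need(workload, tools)

  # task x vm feasibility (nonsupport lists); prereq and meta tasks run
  # anywhere.  Checked before any prediction so an unschedulable workload
  # fails fast even without a calibrated model.
  feas <- matrix(TRUE, nrow = max(n, 1), ncol = nvm)
  if (n > 0) {
    constrained <- workload$kind %in% c("chain_main", "domain_main",
                                        "chain_post", "domain_post")
    for (k in seq_len(nvm)) {
      ns <- pool$nonsupport_tools[[k]]
      feas[, k] <- !(constrained & workload$tool %in% ns)
    }
    infeasible <- which(rowSums(feas) == 0)
    if (length(infeasible) > 0) {
      abort(paste0("Task '", workload$task_id[infeasible[1]],
                   "' (tool ", workload$tool[infeasible[1]],
                   ") is feasible on no VM in the pool."),
            class = "ethreadsim_unschedulable")
    }
  }

  inst_names <- unique(pool$name)
  predm <- matrix(0, nrow = max(n, 1), ncol = length(inst_names),
                  dimnames = list(NULL, inst_names))
  if (n > 0) {
    for (inst in inst_names) {
      predm[, inst] <- predict_duration(workload, inst, model)
    }
    if (any(!is.finite(predm)) || any(predm[workload$kind != "meta_analysis", , drop = FALSE] < 0)) {
      abort("Predicted durations must be finite and nonnegative.",
            class = "ethreadsim_validation")
    }
  }
  actual_override <- if ("actual_min" %in% names(workload)) {
    as.numeric(workload$actual_min)
  } else rep(NA_real_, n)

  # per_tool_static: pin every tool (and the meta group) to one VM chosen
  # round-robin among the VMs feasible for it
  allowed_vm <- NULL
  if (policy == "per_tool_static" && n > 0) {
    groups <- sort(unique(mem$group))
    allowed_vm <- integer(n)
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      rows <- which(mem$group == g)
      ok <- which(colSums(!feas[rows, , drop = FALSE]) == 0)
      if (length(ok) == 0) {
        abort(paste0("Tool group '", g, "' is feasible on no single VM ",
                     "under the per-tool static policy."),
              class = "ethreadsim_unschedulable")
      }
      allowed_vm[rows] <- ok[((gi - 1) %% length(ok)) + 1]
    }
  }

  ord_inst <- ordering_instance %||% pool$name[1]
  if (!ord_inst %in% inst_names) {
    abort("ordering_instance must be an instance type present in the pool.",
          class = "ethreadsim_validation")
  }
  topo_pos <- integer(n)
  if (n > 0) topo_pos[topological_order(workload)] <- seq_len(n)

  sort_ready <- function(idx) {
    if (length(idx) <= 1) return(idx)
    if (policy == "serial") {
      idx[order(topo_pos[idx])]
    } else {
      idx[order(-predm[idx, ord_inst], workload$tool[idx],
                workload$seq_id[idx], workload$task_id[idx],
                method = "radix")]
    }
  }

  # dependency bookkeeping
  indeg <- if (n > 0) lengths(workload$deps) else integer(0)
  dependents <- vector("list", n)
  if (n > 0) {
    idx_of <- setNames(seq_len(n), workload$task_id)
    for (i in seq_len(n)) {
      for (d in workload$deps[[i]]) {
        j <- idx_of[[d]]
        dependents[[j]] <- c(dependents[[j]], i)
      }
    }
  }

  core_task <- lapply(seq_len(nvm), function(k) rep(NA_integer_, pool$cores[k]))
  grp_count <- lapply(seq_len(nvm), function(k) new.env(parent = emptyenv()))
  grp_cap <- function(k, need) {
    if (need <= 0) return(Inf)
    max(1, floor(pool$mem_gb[k] / need))
  }

  start <- end <- pred_assigned <- rep(NA_real_, n)
  vm_of <- core_of <- rep(NA_integer_, n)
  completed <- rep(FALSE, n)
  ev_time <- ev_kind <- ev_task <- ev_vm <- ev_core <- list()
  push_event <- function(time, kind, task = NA_character_,
                         vm = NA_character_, core = NA_integer_) {
    m <- length(ev_time) + 1
    ev_time[[m]] <<- time; ev_kind[[m]] <<- kind; ev_task[[m]] <<- task
    ev_vm[[m]] <<- vm; ev_core[[m]] <<- core
  }
  for (k in seq_len(nvm)) push_event(ready_vm[k], "vm_launched", vm = pool$vm[k])

  ready <- sort_ready(which(indeg == 0))
  t <- 0
  while (any(!completed)) {
    # place as many ready tasks as possible at the current time
    if (length(ready) > 0) {
      placed <- integer(0)
      for (i in ready) {
        cand <- if (is.null(allowed_vm)) seq_len(nvm) else allowed_vm[i]
        hit_vm <- hit_core <- NA_integer_
        for (k in cand) {
          if (!feas[i, k] || ready_vm[k] > t) next
          free <- which(is.na(core_task[[k]]))
          if (length(free) == 0) next
          g <- mem$group[i]
          cnt <- if (exists(g, envir = grp_count[[k]], inherits = FALSE)) {
            get(g, envir = grp_count[[k]])
          } else 0
          if (cnt >= grp_cap(k, mem$need_gb[i])) next
          hit_vm <- k; hit_core <- free[1]
          break
        }
        if (is.na(hit_vm)) next
        k <- hit_vm
        core_task[[k]][hit_core] <- i
        g <- mem$group[i]
        cnt <- if (exists(g, envir = grp_count[[k]], inherits = FALSE)) {
          get(g, envir = grp_count[[k]])
        } else 0
        assign(g, cnt + 1, envir = grp_count[[k]])
        start[i] <- t
        pred_assigned[i] <- predm[i, pool$name[k]]
        act <- if (!is.na(actual_override[i])) actual_override[i] else {
          pred_assigned[i] * noise[i]
        }
        end[i] <- t + act
        vm_of[i] <- k; core_of[i] <- hit_core
        push_event(t, "task_started", workload$task_id[i], pool$vm[k], hit_core)
        placed <- c(placed, i)
      }
      if (length(placed) > 0) ready <- setdiff(ready, placed)
    }

    running <- which(!completed & !is.na(end))
    future_vm <- ready_vm[ready_vm > t + 1e-12]
    if (length(running) == 0) {
      if (length(ready) > 0 && length(future_vm) > 0) {
        t <- min(future_vm)
        next
      }
      if (any(!completed)) {
        abort("Scheduler deadlock: tasks remain but none can be placed.",
              class = "ethreadsim_unschedulable")
      }
      break
    }
    t_next <- min(end[running])
    if (length(ready) > 0 && length(future_vm) > 0) {
      t_next <- min(t_next, min(future_vm))
    }
    t <- t_next
    done_now <- running[end[running] <= t + 1e-12]
    for (i in done_now[order(workload$task_id[done_now])]) {
      completed[i] <- TRUE
      k <- vm_of[i]
      core_task[[k]][core_of[i]] <- NA_integer_
      g <- mem$group[i]
      assign(g, get(g, envir = grp_count[[k]]) - 1, envir = grp_count[[k]])
      push_event(end[i], "task_finished", workload$task_id[i], pool$vm[k],
                 core_of[i])
      if (policy == "greedy_lpt_dynamic" && !is.na(workload$tool[i])) {
        act_i <- end[i] - start[i]
        dev <- abs(act_i - pred_assigned[i]) / pred_assigned[i]
        if (is.finite(dev) && dev > reschedule_threshold) {
          ratio <- act_i / pred_assigned[i]
          unstarted <- which(is.na(start) &
                               !is.na(workload$tool) &
                               workload$tool == workload$tool[i])
          if (length(unstarted) > 0) {
            predm[unstarted, pool$name[k]] <-
              predm[unstarted, pool$name[k]] * ratio
          }
          push_event(end[i], "reschedule", workload$task_id[i], pool$vm[k])
        }
      }
      for (j in dependents[[i]]) {
        indeg[j] <- indeg[j] - 1
        if (indeg[j] == 0) ready <- c(ready, j)
      }
    }
    ready <- sort_ready(ready)
  }

  shutdown <- vapply(seq_len(nvm), function(k) {
    mine <- which(vm_of == k & !is.na(end))
    if (length(mine) > 0) max(end[mine]) else ready_vm[k]
  }, numeric(1))
  for (k in seq_len(nvm)) push_event(shutdown[k], "vm_shutdown", vm = pool$vm[k])

  events <- tibble::tibble(
    time_min = unlist(ev_time),
    kind = unlist(ev_kind),
    task_id = unlist(ev_task),
    vm = unlist(ev_vm),
    core = unlist(ev_core)
  )
  kind_rank <- match(events$kind, c("vm_launched", "task_started",
                                    "task_finished", "reschedule",
                                    "vm_shutdown"))
  events <- events[order(events$time_min, kind_rank, events$task_id,
                         events$vm, method = "radix"), , drop = FALSE]

  schedule <- tibble::tibble(
    task_id = workload$task_id, kind = workload$kind, tool = workload$tool,
    seq_id = workload$seq_id,
    vm = pool$vm[vm_of], instance = pool$name[vm_of], core = core_of,
    start_min = start, end_min = end,
    predicted_min = pred_assigned, actual_min = end - start
  )
  vms <- tibble::tibble(
    vm = pool$vm, instance = pool$name, cores = pool$cores,
    relative_cost = pool$relative_cost,
    launch_start_min = 0, ready_min = ready_vm, shutdown_min = shutdown,
    uptime_min = shutdown,
    busy_core_min = vapply(seq_len(nvm), function(k) {
      mine <- which(vm_of == k)
      sum(end[mine] - start[mine])
    }, numeric(1))
  )

  sim <- structure(list(
    events = events, schedule = schedule, vms = vms,
    config = list(policy = policy, reschedule_threshold = reschedule_threshold,
                  noise_sigma = noise_sigma, seed = seed, billing = billing,
                  ordering_instance = ord_inst, n_tasks = n)
  ), class = "ethread_sim")
  sim$metrics <- compute_metrics(sim, billing)
  sim
}

#' @export
print.ethread_sim <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<ethread_sim> %d tasks on %d VM(s), policy %s\n",
                     "  TTS %.2f min, CTS $%.2f (%s billing), ",
                     "utilization %.1f%%\n"),
              x$config$n_tasks, nrow(x$vms), x$config$policy,
              m$tts_min, m$cts_usd, x$config$billing$mode,
              100 * m$utilization))
  invisible(x)
}

#' Write a simulation event log to CSV
#'
#' @param sim An `ethread_sim` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sim, path) {
  readr::write_csv(sim$events, path)
  invisible(path)
}
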