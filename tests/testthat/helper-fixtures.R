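# Shared in-code fixtures: synthetic instances, pools and workloads.

TOOL_CATALOG <- load_tool_catalog()
INSTANCE_CATALOG <- load_instance_catalog()

toy_instance <- function(name = "box", cores = 1L, mem_gb = 8,
                         relative_cost = 1, launch_mean = 0, launch_sd = 0,
                         nonsupport = character(0)) {
  tibble::tibble(name = name, category = "G", cores = as.integer(cores),
                 mem_gb = mem_gb, relative_cost = relative_cost,
                 launch_mean_min = launch_mean, launch_sd_min = launch_sd,
                 nonsupport_tools = list(nonsupport))
}

# n identical single-type VMs with deterministic (default zero) launch
toy_pool <- function(n = 1, cores = 1L, ...) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) toy_instance(cores = cores, ...)))
}

# Independent tasks with fixed durations (predicted == actual at zero noise)
independent_tasks <- function(durations, tool = "X", prefix = "t") {
  n <- length(durations)
  tibble::tibble(
    task_id = sprintf("%s%03d", prefix, seq_len(n)),
    kind = "chain_main", tool = tool,
    seq_id = sprintf("s%03d", seq_len(n)), length_aa = 100L,
    deps = replicate(n, character(0), simplify = FALSE),
    predicted_min = as.numeric(durations)
  )
}

# A random small pipeline workload (real task-graph structure) with random
# per-task predictions attached, plus a random pool; used by property tests.
random_workload_case <- function(seed) {
  set.seed(seed)
  n_seq <- sample(1:3, 1)
  seqs <- tibble::tibble(id = sprintf("q%02d", seq_len(n_seq)),
                         length_aa = sample(51:600, n_seq, replace = TRUE))
  tool_names <- sample(TOOL_CATALOG$name[!TOOL_CATALOG$prereq_only],
                       sample(1:3, 1))
  tools <- dplyr::filter(TOOL_CATALOG, prereq_only | name %in% tool_names)
  wl <- build_workload(seqs, tools)
  wl$predicted_min <- stats::runif(nrow(wl), 0.5, 10)
  pool <- toy_pool(n = sample(1:3, 1), cores = sample(1:4, 1),
                   launch_mean = stats::runif(1, 0, 2))
  list(workload = wl, pool = pool,
       policy = sample(c("greedy_lpt", "greedy_lpt_dynamic"), 1),
       noise_sigma = sample(c(0, 0.2), 1),
       seed = sample.int(1e6, 1))
}

# Structural validity of a finished schedule: every task runs exactly once,
# cores never overlap, and starts respect VM readiness and dependencies.
expect_valid_schedule <- function(sim, workload) {
  sched <- sim$schedule
  expect_false(anyNA(sched$start_min))
  expect_false(anyDuplicated(sched$task_id) > 0)
  eps <- 1e-9
  by_core <- split(sched, paste(sched$vm, sched$core))
  for (g in by_core) {
    g <- g[order(g$start_min), , drop = FALSE]
    if (nrow(g) > 1) {
      expect_true(all(g$start_min[-1] >= g$end_min[-nrow(g)] - eps))
    }
  }
  ready <- setNames(sim$vms$ready_min, sim$vms$vm)
  expect_true(all(sched$start_min >= ready[sched$vm] - eps))
  end_of <- setNames(sched$end_min, sched$task_id)
  for (i in seq_len(nrow(workload))) {
    deps <- workload$deps[[i]]
    if (length(deps) > 0) {
      row <- sched[sched$task_id == workload$task_id[i], ]
      expect_true(all(row$start_min >= max(end_of[deps]) - eps))
    }
  }
  invisible(TRUE)
}

# Independent exhaustive makespan oracle for two single-core machines:
# enumerate every subset assignment.
two_machine_optimum <- function(durations) {
  n <- length(durations)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    a <- sum(durations[bitwAnd(bitwShiftR(mask, seq_len(n) - 1), 1) == 1])
    best <- min(best, max(a, sum(durations) - a))
  }
  best
}
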