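test_that("one task on one core finishes at launch plus duration", {
  wl <- independent_tasks(7)
  pool <- toy_pool(launch_mean = 1.5)
  sim <- run_simulation(wl, pool, noise_sigma = 0, seed = 1)
  expect_equal(sim$metrics$tts_min, 1.5 + 7)
  expect_equal(sim$schedule$start_min, 1.5)
})

test_that("a hand-simulated five-task fixture is reproduced exactly", {
  # LPT order 5,4,3,3,3 on two idle single-core VMs:
  # vm1: 5 (0-5), 3 (5-8); vm2: 4 (0-4), 3 (4-7), 3 (7-10)
  wl <- independent_tasks(c(5, 4, 3, 3, 3))
  sim <- run_simulation(wl, toy_pool(n = 2), noise_sigma = 0, seed = 1)
  sched <- sim$schedule[order(sim$schedule$task_id), ]
  expect_equal(sched$start_min, c(0, 0, 4, 5, 7))
  expect_equal(sim$metrics$tts_min, 10)
})

test_that("twenty equal tasks on sixteen cores run in exactly two rounds", {
  wl <- independent_tasks(rep(1, 20))
  pool <- toy_pool(cores = 16)
  sim <- run_simulation(wl, pool, noise_sigma = 0, seed = 1)
  starts <- table(sim$schedule$start_min)
  expect_equal(as.integer(starts), c(16L, 4L))
  expect_equal(sim$metrics$tts_min, 2)
  expect_equal(sim$metrics$idle_core_min, 12)     # 12 cores idle in round two
  expect_equal(sim$metrics$utilization, 20 / 32)  # 62.5%
})

test_that("zero noise makes actual durations equal predictions", {
  case <- random_workload_case(101)
  sim <- run_simulation(case$workload, case$pool, noise_sigma = 0, seed = 9)
  expect_equal(sim$schedule$actual_min, sim$schedule$predicted_min)
})

test_that("identical seeds give byte-identical event logs", {
  case <- random_workload_case(55)
  run <- function() run_simulation(case$workload, case$pool,
                                   policy = case$policy, noise_sigma = 0.3,
                                   seed = 77)
  expect_identical(run()$events, run()$events)
})

test_that("busy core-minutes equal the sum of actual task durations", {
  case <- random_workload_case(7)
  sim <- run_simulation(case$workload, case$pool, noise_sigma = 0.2, seed = 3)
  expect_equal(sum(sim$vms$busy_core_min),
               sum(sim$schedule$actual_min))
})

test_that("an empty workload still bills the launch window", {
  wl <- build_workload(tibble::tibble(id = character(0), length_aa = integer(0)),
                       TOOL_CATALOG)
  pool <- toy_pool(launch_mean = 2, relative_cost = 30)
  sim <- run_simulation(wl, pool, seed = 1)
  expect_equal(sim$metrics$tts_min, 2)
  expect_equal(sim$metrics$cts_usd, billed_cost(2, 30 * 0.02))
  expect_setequal(sim$events$kind, c("vm_launched", "vm_shutdown"))
})

test_that("a task feasible on no VM fails before any event is emitted", {
  wl <- build_workload(tibble::tibble(id = "s1", length_aa = 100L),
                       dplyr::filter(TOOL_CATALOG, name == "SAM-T2K"))
  pool <- vm_pool("t1.micro")
  expect_error(run_simulation(wl, pool, noise_sigma = 0, seed = 1),
               class = "ethreadsim_unschedulable")
  expect_error(run_simulation(wl, pool[0, ], seed = 1),
               class = "ethreadsim_validation")
})

test_that("memory caps serialise concurrent high-memory tasks", {
  # SAM-T2K is High memory (6 GB); a 6.5 GB VM fits one at a time even with
  # four idle cores.
  wl <- independent_tasks(rep(1, 4), tool = "SAM-T2K")
  pool <- toy_pool(cores = 4, mem_gb = 6.5)
  sim <- run_simulation(wl, pool, noise_sigma = 0, seed = 1)
  expect_equal(sim$metrics$tts_min, 4)
  roomy <- toy_pool(cores = 4, mem_gb = 60)
  expect_equal(run_simulation(wl, roomy, noise_sigma = 0,
                              seed = 1)$metrics$tts_min, 1)
})

test_that("greedy never loses to serial and extra VMs never hurt", {
  for (seed in c(3, 17, 29)) {
    case <- random_workload_case(seed)
    serial <- run_simulation(case$workload, case$pool, policy = "serial",
                             noise_sigma = 0, seed = 5)
    greedy <- run_simulation(case$workload, case$pool, policy = "greedy_lpt",
                             noise_sigma = 0, seed = 5)
    expect_lte(greedy$metrics$tts_min, serial$metrics$tts_min + 1e-9)

    bigger <- dplyr::bind_rows(case$pool, case$pool[1, ])
    more <- run_simulation(case$workload, bigger, policy = "greedy_lpt",
                           noise_sigma = 0, seed = 5)
    expect_lte(more$metrics$tts_min, greedy$metrics$tts_min + 1e-9)
  }
})

test_that("dynamic scheduling with zero noise reduces to static greedy", {
  for (seed in c(2, 11)) {
    case <- random_workload_case(seed)
    static <- run_simulation(case$workload, case$pool, policy = "greedy_lpt",
                             noise_sigma = 0, seed = 4)
    dynamic <- run_simulation(case$workload, case$pool,
                              policy = "greedy_lpt_dynamic",
                              noise_sigma = 0, seed = 4)
    expect_identical(static$events, dynamic$events)
  }
})

test_that("the per-tool static policy pins each tool to one VM", {
  seqs <- tibble::tibble(id = c("s1", "s2"), length_aa = c(100L, 200L))
  tools <- dplyr::filter(TOOL_CATALOG, name %in% c("pfTools", "HMMER") | prereq_only)
  wl <- build_workload(seqs, tools)
  wl$predicted_min <- 1
  sim <- run_simulation(wl, toy_pool(n = 2, cores = 2), seed = 1,
                        policy = "per_tool_static", noise_sigma = 0)
  placement <- sim$schedule[!is.na(sim$schedule$tool), c("tool", "vm")]
  expect_true(all(tapply(placement$vm, placement$tool,
                         function(v) length(unique(v)) == 1)))
  expect_gt(length(unique(placement$vm)), 1)
})

test_that("random workloads always produce structurally valid schedules", {
  for (seed in 200:230) {
    case <- random_workload_case(seed)
    sim <- run_simulation(case$workload, case$pool, policy = case$policy,
                          noise_sigma = case$noise_sigma, seed = case$seed,
                          tools = TOOL_CATALOG)
    expect_valid_schedule(sim, case$workload)
  }
})
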