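test_that("LPT ordering sorts by descending prediction with stable tie-breaks", {
  tasks <- independent_tasks(c(5, 9, 9))
  tasks$task_id <- c("a", "b", "c")
  ordered <- order_tasks_lpt(tasks)
  expect_equal(ordered$task_id, c("b", "c", "a"))
  expect_equal(nrow(order_tasks_lpt(tasks[0, ])), 0)
})

test_that("under the length-linear model the longest sequences lead the queue", {
  seqs <- generate_benchmark_sequences(sequence_bin_spec("20"), seed = 2)
  wl <- build_workload(seqs, dplyr::filter(TOOL_CATALOG, name == "THREADER"))
  model <- fit_runtime_model(load_benchmark_records())
  ordered <- order_tasks_lpt(wl, model, "m1.small")
  first_seq_len <- seqs$length_aa[seqs$id == ordered$seq_id[1]]
  expect_equal(first_seq_len, max(seqs$length_aa))
  expect_equal(ordered$kind[1], "chain_main")
})

test_that("brute-force oracle matches exhaustive enumeration", {
  expect_equal(brute_force_optimal(c(5, 4, 3, 3, 3), machines = c(1, 1)), 9)
  expect_equal(two_machine_optimum(c(5, 4, 3, 3, 3)), 9)
  expect_equal(brute_force_optimal(7.5, machines = c(1, 1, 1)), 7.5)
  # n equal tasks on one m-core machine: ceil(n/m) rounds
  expect_equal(brute_force_optimal(rep(2, 7), machines = 3), ceiling(7 / 3) * 2)
  set.seed(31)
  for (rep in 1:40) {
    d <- round(runif(sample(2:8, 1), 1, 20), 2)
    expect_equal(brute_force_optimal(d, machines = c(1, 1)),
                 two_machine_optimum(d))
  }
})

test_that("the oracle refuses instances beyond its exhaustive bound", {
  expect_error(brute_force_optimal(1:11, machines = c(1, 1)),
               class = "ethreadsim_validation")
  expect_error(brute_force_optimal(1:5, machines = c(1, 1, 1, 1)),
               class = "ethreadsim_validation")
})

test_that("deviation below threshold leaves the queue untouched", {
  rdy <- independent_tasks(c(10, 8, 6))
  out <- reschedule_on_deviation(rdy, actual_min = 10, predicted_min = 10,
                                 tool = "X")
  expect_false(out$triggered)
  expect_identical(out$ready, rdy)
})

test_that("large deviations correct predictions and re-sort the queue", {
  rdy <- independent_tasks(c(10, 8, 6))
  rdy$tool <- c("X", "Y", "Y")
  out <- reschedule_on_deviation(rdy, actual_min = 2, predicted_min = 10,
                                 tool = "X", threshold = 0.1)
  expect_true(out$triggered)
  # X's prediction shrinks by the observed ratio 0.2: 10 -> 2, queue resorts
  expect_equal(out$ready$task_id[1:2], c("t002", "t003"))
  expect_equal(out$ready$predicted_min[out$ready$tool == "X"], 2)
})

test_that("rescheduling after an overprediction strictly reduces makespan", {
  # Tool X is 5x overpredicted; static LPT runs all X first and only then the
  # accurate 30-min Y task, while dynamic mode learns the ratio from the
  # first X completion and promotes Y.
  wl <- independent_tasks(c(50, 45, 40, 30))
  wl$tool <- c("X", "X", "X", "Y")
  wl$actual_min <- c(10, 9, 8, 30)
  pool <- toy_pool(n = 2)
  static <- run_simulation(wl, pool, policy = "greedy_lpt",
                           noise_sigma = 0, seed = 1)
  dynamic <- run_simulation(wl, pool, policy = "greedy_lpt_dynamic",
                            reschedule_threshold = 0.1,
                            noise_sigma = 0, seed = 1)
  expect_equal(static$metrics$tts_min, 40)
  expect_equal(dynamic$metrics$tts_min, 39)
  expect_lt(dynamic$metrics$tts_min, static$metrics$tts_min)
  expect_true("reschedule" %in% dynamic$events$kind)
})
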