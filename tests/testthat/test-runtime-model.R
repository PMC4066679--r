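fitted_model <- fit_runtime_model(load_benchmark_records())

synthetic_truth <- function(seed = 1) {
  set.seed(seed)
  tools <- c("A", "B", "C")
  instances <- c("ref", "fast", "slow")
  list(
    base = tibble::tibble(tool = tools,
                          base_min_per_aa = runif(3, 0.01, 0.5)),
    speed = tidyr::expand_grid(tool = tools, instance = instances) |>
      dplyr::mutate(speed_factor = ifelse(instance == "ref", 1,
                                          runif(dplyr::n(), 0.3, 3)))
  )
}

test_that("a single record per pair is fitted exactly", {
  rec <- tibble::tibble(tool = "A", instance = "ref", subtask = "total",
                        n_sequences = 1L, minutes = 123.4, total_aa = 6160)
  model <- fit_runtime_model(rec, reference = "ref")
  expect_equal(predict_total_work(model, "A", "ref", 6160), 123.4)
})

test_that("noise-free parameter recovery is exact to machine precision", {
  truth <- synthetic_truth(4)
  recs <- simulate_benchmark_records(truth$base, truth$speed,
                                     noise_sigma = 0, seed = 2)
  model <- fit_runtime_model(recs, reference = "ref")
  got <- dplyr::arrange(tidy(model), tool, instance)
  want <- dplyr::arrange(dplyr::left_join(truth$speed, truth$base, by = "tool"),
                         tool, instance)
  expect_equal(got$speed_factor, want$speed_factor, tolerance = 1e-12)
  expect_equal(got$base_min_per_aa, want$base_min_per_aa, tolerance = 1e-12)
})

test_that("5% noise with 50 records per pair recovers factors within 10%", {
  truth <- synthetic_truth(5)
  recs <- simulate_benchmark_records(truth$base, truth$speed, n_per_pair = 50,
                                     noise_sigma = 0.05, seed = 3)
  model <- fit_runtime_model(recs, reference = "ref")
  got <- dplyr::arrange(tidy(model), tool, instance)
  want <- dplyr::arrange(dplyr::left_join(truth$speed, truth$base, by = "tool"),
                         tool, instance)
  expect_true(all(abs(got$speed_factor / want$speed_factor - 1) < 0.10))
  expect_true(all(abs(got$base_min_per_aa / want$base_min_per_aa - 1) < 0.10))
})

test_that("recovery error shrinks as the record count grows", {
  truth <- synthetic_truth(6)
  err <- sapply(c(2, 200), function(n) {
    recs <- simulate_benchmark_records(truth$base, truth$speed, n_per_pair = n,
                                       noise_sigma = 0.2, seed = 8)
    model <- fit_runtime_model(recs, reference = "ref")
    got <- dplyr::arrange(tidy(model), tool, instance)
    want <- dplyr::arrange(dplyr::left_join(truth$speed, truth$base, by = "tool"),
                           tool, instance)
    max(abs(log(got$speed_factor / want$speed_factor)))
  })
  expect_lt(err[2], err[1])
})

test_that("calibrated speed factors rank t1.micro slowest", {
  sp <- fitted_model$speed
  micro <- sp$speed_factor[sp$tool == "pfTools" & sp$instance == "t1.micro"]
  cx <- sp$speed_factor[sp$tool == "pfTools" & sp$instance == "c1.xlarge"]
  expect_lt(micro, cx)
  expect_equal(sp$speed_factor[sp$instance == "m1.small" & sp$tool == "THREADER"], 1)
})

test_that("missing calibration raises an explicit error, never extrapolates", {
  expect_error(predict_total_work(fitted_model, "HHpred", "m1.small", 1000),
               class = "ethreadsim_missing_calibration")
  expect_error(fit_runtime_model(
    tibble::tibble(tool = "A", instance = "x", subtask = "chain_main",
                   n_sequences = 1L, minutes = 5, total_aa = 100)),
    class = "ethreadsim_missing_calibration")
})

test_that("predictions are linear in length and conserve the chain/domain split", {
  tools <- dplyr::filter(TOOL_CATALOG, name == "THREADER")
  wl1 <- build_workload(tibble::tibble(id = "s1", length_aa = 150L), tools)
  wl2 <- build_workload(tibble::tibble(id = "s1", length_aa = 300L), tools)
  p1 <- predict_duration(wl1, "c1.xlarge", fitted_model)
  p2 <- predict_duration(wl2, "c1.xlarge", fitted_model)
  non_meta <- wl1$kind != "meta_analysis"
  expect_equal(p2[non_meta], 2 * p1[non_meta])
  expect_equal(p2[wl1$kind == "meta_analysis"], p1[wl1$kind == "meta_analysis"])

  mains <- wl1$kind %in% c("chain_main", "domain_main")
  total_main <- sum(p1[mains])
  split <- split_chain_domain(total_main, "c1.xlarge", model = fitted_model)
  expect_equal(p1[wl1$kind == "chain_main"], split$chain_min)
  expect_equal(p1[wl1$kind == "domain_main"], split$domain_min)
})

test_that("chain/domain split uses 60/40 by default and 49/51 on t1.micro", {
  expect_equal(split_chain_domain(100, "m1.small"),
               tibble::tibble(chain_min = 60, domain_min = 40))
  expect_equal(split_chain_domain(100, "t1.micro"),
               tibble::tibble(chain_min = 49, domain_min = 51))
  expect_equal(split_chain_domain(0, "c1.xlarge"),
               tibble::tibble(chain_min = 0, domain_min = 0))
  set.seed(2)
  totals <- runif(20, 0, 1e4)
  s <- split_chain_domain(totals, sample(INSTANCE_CATALOG$name, 20, TRUE),
                          model = fitted_model)
  expect_equal(s$chain_min + s$domain_min, totals)
})

test_that("ideal limit divides single-core work by core count", {
  expect_equal(ideal_limit(23744.0, 1), 23744.0)
  expect_equal(ideal_limit(17446.4, 16), 1090.4)
  x <- runif(10, 1, 1e5)
  expect_equal(ideal_limit(x, 1), x)
  expect_error(ideal_limit(100, 0), class = "ethreadsim_validation")
})

test_that("per-core predictions preserve the measured time-to-solution ordering", {
  tts <- load_tts_benchmark()
  cores <- setNames(INSTANCE_CATALOG$cores, INSTANCE_CATALOG$name)
  for (tool in c("HMMER", "SP3", "THREADER")) {
    sub <- tts[tts$tool == tool & tts$instance %in%
                 c("m1.small", "c1.xlarge", "hi1.4xlarge"), ]
    pred <- predict_total_work(fitted_model, tool, sub$instance, 6160) /
      cores[sub$instance]
    expect_equal(order(pred), order(sub$tts_min))
  }
})

test_that("a fitted model survives a text round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_runtime_model(fitted_model, path)
  back <- read_runtime_model(path)
  wl <- build_workload(tibble::tibble(id = "s1", length_aa = 321L),
                       dplyr::filter(TOOL_CATALOG, name == "pfTools"))
  expect_equal(predict_duration(wl, "hi1.4xlarge", back),
               predict_duration(wl, "hi1.4xlarge", fitted_model))
  expect_equal(glance(back)$reference, glance(fitted_model)$reference)
})
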