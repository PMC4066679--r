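one_seq <- tibble::tibble(id = "s1", length_aa = 200L)

test_that("a tool without prerequisites expands to four core tasks plus meta", {
  tools <- dplyr::filter(TOOL_CATALOG, name == "pfTools")
  wl <- build_workload(one_seq, tools)
  expect_equal(nrow(wl), 5)
  expect_setequal(wl$kind, c("chain_main", "domain_main", "chain_post",
                             "domain_post", "meta_analysis"))
  # postprocessing depends on the matching-library main task
  cp <- wl[wl$kind == "chain_post", ]
  expect_equal(cp$deps[[1]], wl$task_id[wl$kind == "chain_main"])
  dp <- wl[wl$kind == "domain_post", ]
  expect_equal(dp$deps[[1]], wl$task_id[wl$kind == "domain_main"])
})

test_that("separable prerequisites become explicit preprocessing tasks", {
  wl <- build_workload(one_seq, dplyr::filter(TOOL_CATALOG, name == "THREADER"))
  expect_equal(nrow(wl), 7)  # PSIPRED + BLAST + 4 core + meta
  expect_setequal(wl$kind[grepl("prereq", wl$kind)],
                  c("prereq_blast", "prereq_psipred"))
  mains <- wl[wl$kind %in% c("chain_main", "domain_main"), ]
  prereq_ids <- wl$task_id[grepl("prereq", wl$kind)]
  for (d in mains$deps) expect_setequal(d, prereq_ids)

  # embedded-BLAST tools get no preprocessing task at all
  wl2 <- build_workload(one_seq, dplyr::filter(TOOL_CATALOG, name == "HHpred"))
  expect_equal(nrow(wl2), 5)
  expect_false(any(grepl("prereq", wl2$kind)))
})

test_that("meta-analysis depends on every postprocessing task of its sequence", {
  tools <- dplyr::filter(TOOL_CATALOG, name %in% c("pfTools", "HMMER") | prereq_only)
  wl <- build_workload(one_seq, tools)
  meta <- wl[wl$kind == "meta_analysis", ]
  expect_equal(nrow(meta), 1)
  expect_setequal(meta$deps[[1]],
                  wl$task_id[wl$kind %in% c("chain_post", "domain_post")])
})

test_that("empty inputs yield an empty graph", {
  wl <- build_workload(tibble::tibble(id = character(0), length_aa = integer(0)),
                       TOOL_CATALOG)
  expect_equal(nrow(wl), 0)
})

test_that("task counts follow |seqs| x sum(4 + separable prereqs) + |seqs|", {
  for (seed in 1:10) {
    set.seed(seed)
    n_seq <- sample(1:4, 1)
    seqs <- tibble::tibble(id = sprintf("r%d", seq_len(n_seq)),
                           length_aa = sample(51:600, n_seq))
    picked <- sample(TOOL_CATALOG$name[!TOOL_CATALOG$prereq_only], sample(1:5, 1))
    tools <- dplyr::filter(TOOL_CATALOG, name %in% picked)
    wl <- build_workload(seqs, tools)
    per_tool <- 4 + ifelse(tools$blast_separable,
                           lengths(tools$prerequisites), 0)
    expect_equal(nrow(wl), n_seq * sum(per_tool) + n_seq)
    expect_silent(validate_workload(wl))
  }
})

test_that("duplicate sequence ids and cyclic graphs are rejected", {
  dup <- tibble::tibble(id = c("a", "a"), length_aa = c(100L, 120L))
  expect_error(build_workload(dup, TOOL_CATALOG), class = "ethreadsim_validation")

  cyc <- tibble::tibble(
    task_id = c("x", "y"), kind = "chain_main", tool = "HMMER",
    seq_id = "s", length_aa = 100L, deps = list("y", "x"))
  expect_error(validate_workload(cyc), class = "ethreadsim_validation")
})

test_that("workload TSV round trip preserves the graph", {
  seqs <- generate_benchmark_sequences(sequence_bin_spec("20"), seed = 5)[1:4, ]
  wl <- build_workload(seqs, TOOL_CATALOG)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_workload(wl, path)
  back <- read_workload(path)
  expect_equal(back$task_id, wl$task_id)
  expect_equal(back$deps, wl$deps)
  expect_equal(back$length_aa, wl$length_aa)
})
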