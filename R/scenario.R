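#' Read a scenario configuration
#'
#' A scenario is a YAML key-value file naming everything one run needs:
#' where sequences come from (`fasta:` path, or `sequence_set: "110"/"20"`
#' with a `seed:`), which tools to run (`tools:` list or `"all"`), the VM
#' pool (`pool:` map of instance type to count), the `policy`, the billing
#' `mode` and `base_unit_usd`, the duration `noise_sigma` and the
#' `reschedule_threshold`.  Missing keys fall back to package defaults
#' (greedy LPT, linear billing, noise 0.1, threshold 0.1), and every default
#' in force is echoed into the metrics output for provenance.
#'
#' @param path Path to a YAML scenario file.
#' @return A validated scenario list.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Scenario file not found: ", path),
          class = "ethreadsim_validation")
  }
  sc <- yaml::read_yaml(path)
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  sc$seed <- as.integer(sc$seed %||% 1L)
  sc$policy <- sc$policy %||% "greedy_lpt"
  sc$noise_sigma <- sc$noise_sigma %||% 0.1
  sc$reschedule_threshold <- sc$reschedule_threshold %||% 0.1
  sc$billing_mode <- sc$billing_mode %||% "linear"
  sc$base_unit_usd <- sc$base_unit_usd %||% 0.02
  sc$tools <- sc$tools %||% "all"
  if (is.null(sc$fasta) && is.null(sc$sequence_set) && is.null(sc$bins)) {
    abort("Scenario needs a sequence source: fasta, sequence_set or bins.",
          class = "ethreadsim_validation")
  }
  if (is.null(sc$pool) || length(sc$pool) == 0) {
    abort("no virtual machines configured", class = "ethreadsim_validation")
  }
  catalog <- load_instance_catalog()
  unknown <- setdiff(names(sc$pool), catalog$name)
  if (length(unknown) > 0) {
    abort(paste0("Scenario pool names unknown instance types: ",
                 paste(unknown, collapse = ", ")),
          class = "ethreadsim_validation")
  }
  tools <- load_tool_catalog()
  if (!identical(sc$tools, "all")) {
    unknown <- setdiff(unlist(sc$tools), tools$name)
    if (length(unknown) > 0) {
      abort(paste0("Scenario names unknown tools: ",
                   paste(unknown, collapse = ", ")),
            class = "ethreadsim_validation")
    }
  }
  sc
}

scenario_sequences <- function(sc) {
  if (!is.null(sc$fasta)) return(read_sequences_fasta(sc$fasta))
  bins <- if (!is.null(sc$sequence_set)) {
    sequence_bin_spec(as.character(sc$sequence_set))
  } else {
    tibble::as_tibble(do.call(rbind.data.frame, sc$bins))
  }
  generate_benchmark_sequences(bins, seed = sc$seed)
}

scenario_tools <- function(sc) {
  tools <- load_tool_catalog()
  if (identical(sc$tools, "all")) tools
  else dplyr::filter(tools, .data$prereq_only | .data$name %in% unlist(sc$tools))
}

#' Run a scenario end to end
#'
#' Resolves a scenario configuration into sequences, workload, model, pool
#' and policy, runs the simulation and (optionally) writes the event log,
#' schedule and metrics under `output_dir`.
#'
#' @param scenario A scenario list ([read_scenario()]) or a YAML path.
#' @param model A fitted runtime model; defaults to one calibrated from the
#'   packaged benchmark records.
#' @param output_dir Optional directory for `events.csv`, `schedule.csv` and
#'   `metrics.json`.
#' @return The `ethread_sim` object, invisibly when writing files.
#' @export
run_scenario <- function(scenario, model = NULL, output_dir = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  scenario <- validate_scenario(scenario)
  model <- model %||% fit_runtime_model(load_benchmark_records(), complete = TRUE)
  sequences <- scenario_sequences(scenario)
  tools <- scenario_tools(scenario)
  workload <- build_workload(sequences, tools)
  pool <- vm_pool(unlist(scenario$pool))
  billing <- billing_policy(base_unit_usd = scenario$base_unit_usd,
                            mode = scenario$billing_mode)
  sim <- run_simulation(workload, pool, model,
                        policy = scenario$policy,
                        reschedule_threshold = scenario$reschedule_threshold,
                        noise_sigma = scenario$noise_sigma,
                        seed = scenario$seed, billing = billing)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_event_log(sim, file.path(output_dir, "events.csv"))
    readr::write_csv(sim$schedule, file.path(output_dir, "schedule.csv"))
    jsonlite::write_json(as.list(sim$metrics),
                         file.path(output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(sim))
  }
  sim
}

#' Enumerate single-type VM pools and rank them
#'
#' Simulates the same workload on a pool of `count` VMs of each instance
#' type able to run every task, and reports each candidate's
#' time-to-solution and cost-to-solution together with whether it sits on
#' the Pareto front; the cost-minimal and time-minimal choices are flagged.
#'
#' @param workload A workload tibble.
#' @param model A fitted runtime model.
#' @param instances Instance catalog to draw candidates from.
#' @param count VMs per candidate pool.
#' @param policy,noise_sigma,seed,billing Passed to [run_simulation()].
#' @return A tibble with one row per candidate: `instance`, `n_vms`,
#'   `tts_min`, `cts_usd`, `utilization`, `on_front`, `best_time`,
#'   `best_cost`.
#' @export
plan_pools <- function(workload, model, instances = load_instance_catalog(),
                       count = 1, policy = "greedy_lpt", noise_sigma = 0,
                       seed = 1L, billing = billing_policy()) {
  tools_used <- unique(workload$tool[!is.na(workload$tool)])
  feasible <- purrr::map_lgl(instances$nonsupport_tools,
                             ~ length(intersect(.x, tools_used)) == 0)
  cand <- instances[feasible, , drop = FALSE]
  if (nrow(cand) == 0) {
    abort("No instance type can run every tool in this workload.",
          class = "ethreadsim_unschedulable")
  }
  rows <- purrr::map(cand$name, function(nm) {
    pool <- vm_pool(setNames(count, nm), instances)
    sim <- run_simulation(workload, pool, model, policy = policy,
                          noise_sigma = noise_sigma, seed = seed,
                          billing = billing)
    dplyr::mutate(sim$metrics[, c("tts_min", "cts_usd", "utilization")],
                  instance = nm, n_vms = count, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  front <- pareto_front(out)
  dplyr::mutate(out,
                on_front = .data$instance %in% front$instance,
                best_time = .data$tts_min == min(.data$tts_min),
                best_cost = .data$cts_usd == min(.data$cts_usd))
}

# ---------------------------------------------------------------------------
# Command-line dispatcher.  inst/cli/ethreadsim.R wraps this in an Rscript;
# it returns an exit status instead of quitting so tests can call it
# in-process.

cli_usage <- function() {
  paste(
    "usage: ethreadsim <command> [--flag value ...]",
    "commands:",
    "  gen-sequences  --set 110|20 --seed N --out FILE.fasta",
    "  build-workload --fasta FILE --tools all|A,B --out FILE.tsv",
    "  fit-model      [--records FILE.csv] --out FILE.yaml",
    "  simulate       --scenario FILE.yaml --out DIR",
    "  plan           --fasta FILE | --set 110|20 [--tools A,B] [--count N]",
    "                 [--seed N] --out FILE.json",
    "  report         --metrics FILE.json [FILE.json ...]",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  positional <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        abort(paste0("Flag --", key, " needs a value."),
              class = "ethreadsim_validation")
      }
      if (is.null(flags[[key]])) flags[[key]] <- args[i + 1]
      else flags[[key]] <- c(flags[[key]], args[i + 1])
      i <- i + 2
    } else {
      positional <- c(positional, a)
      i <- i + 1
    }
  }
  list(flags = flags, positional = positional)
}

cli_require <- function(flags, keys) {
  missing <- setdiff(keys, names(flags))
  if (length(missing) > 0) {
    abort(paste0("Missing required flag(s): ",
                 paste0("--", missing, collapse = ", ")),
          class = "ethreadsim_validation")
  }
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `ethreadsim` command-line tool (see
#' `inst/cli/ethreadsim.R`).  Validation failures print a diagnostic to
#' standard error and yield a nonzero status instead of raising.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) {
      message(cli_usage())
      return(invisible(1L))
    }
    cmd <- args[1]
    parsed <- parse_cli_flags(args[-1])
    flags <- parsed$flags
    switch(
      cmd,
      "gen-sequences" = {
        cli_require(flags, c("set", "out"))
        seed <- as.integer(flags$seed %||% 1L)
        seqs <- generate_benchmark_sequences(sequence_bin_spec(flags$set),
                                             seed = seed)
        write_sequences_fasta(seqs, flags$out, seed = seed)
        message(sprintf("wrote %d sequences to %s", nrow(seqs), flags$out))
      },
      "build-workload" = {
        cli_require(flags, c("fasta", "out"))
        seqs <- read_sequences_fasta(flags$fasta)
        tools <- load_tool_catalog()
        sel <- flags$tools %||% "all"
        if (!identical(sel, "all")) {
          wanted <- strsplit(sel, ",", fixed = TRUE)[[1]]
          unknown <- setdiff(wanted, tools$name)
          if (length(unknown) > 0) {
            abort(paste0("Unknown tools: ", paste(unknown, collapse = ", ")),
                  class = "ethreadsim_validation")
          }
          tools <- dplyr::filter(tools, .data$prereq_only | .data$name %in% wanted)
        }
        wl <- build_workload(seqs, tools)
        write_workload(wl, flags$out)
        message(sprintf("wrote %d tasks to %s", nrow(wl), flags$out))
      },
      "fit-model" = {
        cli_require(flags, "out")
        records <- if (is.null(flags$records)) load_benchmark_records() else {
          readr::read_csv(flags$records, show_col_types = FALSE)
        }
        model <- fit_runtime_model(records)
        write_runtime_model(model, flags$out)
        message(sprintf("wrote runtime model (%d records) to %s",
                        model$n_records, flags$out))
      },
      "simulate" = {
        cli_require(flags, c("scenario", "out"))
        sim <- run_scenario(flags$scenario, output_dir = flags$out)
        message(sprintf("TTS %.2f min, CTS $%.2f; outputs in %s",
                        sim$metrics$tts_min, sim$metrics$cts_usd, flags$out))
      },
      "plan" = {
        cli_require(flags, "out")
        seqs <- if (!is.null(flags$fasta)) read_sequences_fasta(flags$fasta)
        else if (!is.null(flags$set)) {
          generate_benchmark_sequences(sequence_bin_spec(flags$set),
                                       seed = as.integer(flags$seed %||% 1L))
        } else {
          abort("plan needs --fasta or --set.", class = "ethreadsim_validation")
        }
        tools <- load_tool_catalog()
        if (!is.null(flags$tools)) {
          wanted <- strsplit(flags$tools, ",", fixed = TRUE)[[1]]
          tools <- dplyr::filter(tools, .data$prereq_only | .data$name %in% wanted)
        }
        wl <- build_workload(seqs, tools)
        model <- fit_runtime_model(load_benchmark_records(), complete = TRUE)
        plan <- plan_pools(wl, model, count = as.integer(flags$count %||% 1L),
                           seed = as.integer(flags$seed %||% 1L))
        jsonlite::write_json(plan, flags$out, auto_unbox = TRUE, digits = NA)
        best <- plan[plan$on_front, ]
        message(sprintf("%d candidates, %d on the Pareto front; wrote %s",
                        nrow(plan), nrow(best), flags$out))
      },
      "report" = {
        cli_require(flags, "metrics")
        for (f in flags$metrics) {
          m <- jsonlite::read_json(f)
          message(sprintf(
            "%s: policy %s, TTS %.2f min, CTS $%.2f, utilization %.1f%%",
            f, m$policy, as.numeric(m$tts_min), as.numeric(m$cts_usd),
            100 * as.numeric(m$utilization)))
        }
      },
      {
        message("Unknown command: ", cmd, "\n", cli_usage())
        return(invisible(1L))
      }
    )
    0L
  }, error = function(e) {
    message("ethreadsim error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
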