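#' Load the threading-tool catalog
#'
#' Reads the packaged catalog of the ten threading/fold-recognition tools that
#' make up the eThread meta-threading pipeline, plus BLAST and PSIPRED as
#' prerequisite-only entries.  Each tool carries its published subtask count,
#' its prerequisites, qualitative computational-load and memory classes, and
#' whether its BLAST prerequisite can be run as a separate one-time
#' preprocessing task (`blast_separable`).  HHpred, SP3, SPARKS and
#' pGenTHREADER embed BLAST inside iterative profile construction and are not
#' separable; their BLAST time is folded into the main-task durations.
#'
#' @param path Optional path to an alternative catalog CSV with the same
#'   schema; defaults to the packaged fixture.
#' @return A tibble with one row per tool: `name`, `n_subtasks`,
#'   `prerequisites` (list column of character vectors), `load_class`,
#'   `mem_class`, `blast_separable`, `prereq_only`.
#' @examples
#' load_tool_catalog()
#' @export
load_tool_catalog <- function(path = NULL) {
  path <- path %||% ext_file("tool_catalog.csv")
  raw <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(),
    n_subtasks = readr::col_integer(),
    prerequisites = readr::col_character(),
    load_class = readr::col_character(),
    mem_class = readr::col_character(),
    blast_separable = readr::col_logical(),
    prereq_only = readr::col_logical()
  ))
  tools <- dplyr::mutate(raw, prerequisites = split_semicolon(.data$prerequisites))
  validate_tool_catalog(tools)
  tools
}

validate_tool_catalog <- function(tools) {
  required <- c("name", "n_subtasks", "prerequisites", "load_class",
                "mem_class", "blast_separable", "prereq_only")
  missing <- setdiff(required, names(tools))
  if (length(missing) > 0) {
    abort(paste0("Tool catalog is missing columns: ", paste(missing, collapse = ", ")),
          class = "ethreadsim_fixture_error")
  }
  if (anyDuplicated(tools$name)) {
    abort("Tool catalog has duplicated tool names.", class = "ethreadsim_fixture_error")
  }
  if (!all(tools$load_class %in% LOAD_CLASSES) || !all(tools$mem_class %in% MEM_CLASSES)) {
    abort("Tool catalog uses an unknown load or memory class.",
          class = "ethreadsim_fixture_error")
  }
  if (any(tools$n_subtasks < 1)) {
    abort("Tool catalog subtask counts must be positive.",
          class = "ethreadsim_fixture_error")
  }
  # blast_separable may be TRUE only for tools with a BLAST prerequisite or no
  # prerequisites at all (nothing to separate).
  ok <- purrr::map2_lgl(tools$blast_separable, tools$prerequisites, function(sep, pre) {
    !sep || "BLAST" %in% pre || length(pre) == 0
  })
  if (!all(ok)) {
    abort("blast_separable = TRUE requires a BLAST prerequisite or none at all.",
          class = "ethreadsim_fixture_error")
  }
  invisible(tools)
}

#' Load the cloud instance-type catalog
#'
#' Reads the packaged catalog of the seven EC2-style instance types used
#' throughout the package: core count, memory, cost relative to the base
#' (t1.micro) hourly unit, measured launch-time statistics, and the set of
#' threading tools each instance cannot support (memory-infeasible tools).
#'
#' @param path Optional path to an alternative catalog CSV with the same
#'   schema; defaults to the packaged fixture.
#' @return A tibble with one row per instance type: `name`, `category`,
#'   `cores`, `mem_gb`, `relative_cost`, `launch_mean_min`, `launch_sd_min`,
#'   `nonsupport_tools` (list column).
#' @examples
#' load_instance_catalog()
#' @export
load_instance_catalog <- function(path = NULL) {
  path <- path %||% ext_file("instance_catalog.csv")
  raw <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(),
    category = readr::col_character(),
    cores = readr::col_integer(),
    mem_gb = readr::col_double(),
    relative_cost = readr::col_double(),
    launch_mean_min = readr::col_double(),
    launch_sd_min = readr::col_double(),
    nonsupport_tools = readr::col_character()
  ))
  instances <- dplyr::mutate(raw, nonsupport_tools = split_semicolon(.data$nonsupport_tools))
  validate_instance_catalog(instances)
  instances
}

validate_instance_catalog <- function(instances) {
  required <- c("name", "cores", "mem_gb", "relative_cost",
                "launch_mean_min", "launch_sd_min", "nonsupport_tools")
  missing <- setdiff(required, names(instances))
  if (length(missing) > 0) {
    abort(paste0("Instance catalog is missing columns: ", paste(missing, collapse = ", ")),
          class = "ethreadsim_fixture_error")
  }
  if (anyDuplicated(instances$name)) {
    abort("Instance catalog has duplicated instance names.",
          class = "ethreadsim_fixture_error")
  }
  stopifnot_positive <- function(x, what) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      abort(paste0("Instance catalog column '", what, "' must be positive."),
            class = "ethreadsim_fixture_error")
    }
  }
  stopifnot_positive(instances$cores, "cores")
  stopifnot_positive(instances$mem_gb, "mem_gb")
  stopifnot_positive(instances$relative_cost, "relative_cost")
  stopifnot_positive(instances$launch_mean_min, "launch_mean_min")
  if (any(instances$launch_sd_min < 0)) {
    abort("Launch-time standard deviations must be nonnegative.",
          class = "ethreadsim_fixture_error")
  }
  invisible(instances)
}

#' Instance types able to run a tool
#'
#' Filters the instance catalog down to the instance types whose nonsupport
#' list does not include `tool`.  Nonsupport is driven by memory: e.g.
#' SAM-T2K's 6 GB BLAST step rules out every instance below m1.large.
#'
#' @param tool A single tool name.
#' @param instances Instance catalog, as from [load_instance_catalog()].
#' @param tools Tool catalog used to validate `tool`; defaults to the packaged
#'   catalog.
#' @return The subset of `instances` that can run `tool`.
#' @examples
#' feasible_instances("SAM-T2K")$name
#' @export
feasible_instances <- function(tool, instances = load_instance_catalog(),
                               tools = load_tool_catalog()) {
  if (length(tool) != 1 || !tool %in% tools$name) {
    abort(paste0("Unknown tool: ", paste(tool, collapse = ", ")),
          class = "ethreadsim_validation")
  }
  dplyr::filter(instances, !purrr::map_lgl(.data$nonsupport_tools, ~ tool %in% .x))
}

#' Hourly rates for instance types
#'
#' Adds an hourly dollar rate to an instance catalog: relative cost times the
#' base unit (the t1.micro price, $0.02/h by default) plus any flat surcharge
#' configured in the billing policy (e.g. for an enterprise-Linux image).
#'
#' @param instances Instance catalog tibble.
#' @param billing A [billing_policy()].
#' @return `instances` with an added `rate_usd_hr` column.
#' @examples
#' hourly_rate(load_instance_catalog())[, c("name", "rate_usd_hr")]
#' @export
hourly_rate <- function(instances, billing = billing_policy()) {
  dplyr::mutate(instances,
                rate_usd_hr = .data$relative_cost * billing$base_unit_usd +
                  billing$surcharge_usd_hr)
}

#' Benchmark sequence-set bin specifications
#'
#' Returns the length-bin composition of the packaged benchmark sequence sets:
#' a 110-sequence set with 10 sequences in each of 11 fifty-residue bins
#' spanning 51-600 aa, and its 20-sequence subset.
#'
#' @param set `"110"` or `"20"`.
#' @return A tibble with `min_aa`, `max_aa`, `count`.
#' @examples
#' sum(sequence_bin_spec("20")$count)
#' @export
sequence_bin_spec <- function(set = c("110", "20")) {
  set <- match.arg(set)
  bins <- readr::read_csv(ext_file("sequence_bins.csv"), col_types = readr::cols(
    min_aa = readr::col_integer(), max_aa = readr::col_integer(),
    n110 = readr::col_integer(), n20 = readr::col_integer()
  ))
  col <- if (set == "110") "n110" else "n20"
  tibble::tibble(min_aa = bins$min_aa, max_aa = bins$max_aa, count = bins[[col]])
}

# Expected total residue count of a bin-specified set, taking each sequence at
# its bin midpoint (lengths are uniform within bins, so this is the mean).
expected_total_aa <- function(bins) {
  sum((bins$min_aa + bins$max_aa) / 2 * bins$count)
}

#' Load calibration benchmark records
#'
#' Assembles the packaged benchmark-profile records used to calibrate the
#' runtime model:
#' * per-subtask durations of the pfTools pipeline (chain/domain main and
#'   postprocessing) on all seven instance types, used for the chain/domain
#'   split and postprocessing fractions;
#' * single-core-equivalent total durations for seven tools on three instance
#'   types, reconstructed as the published per-instance ideal limit times the
#'   instance's core count, used for the per-(tool, instance) speed factors;
#' * additional single-core-equivalent totals for instances the ideal-limit
#'   table does not cover, formed by summing the pfTools subtask durations
#'   and multiplying by the instance's cores — exact on one-core instances,
#'   the same core-count arithmetic the ideal limits themselves use
#'   elsewhere.
#'
#' All records come from runs of the 20-sequence benchmark set; `total_aa` is
#' that set's expected residue count under its bin specification.
#'
#' @return A tibble with `tool`, `instance`, `subtask`, `n_sequences`,
#'   `minutes`, `total_aa`.
#' @examples
#' dplyr::count(load_benchmark_records(), subtask)
#' @export
load_benchmark_records <- function() {
  parts <- readr::read_csv(ext_file("subtask_profile.csv"), col_types = readr::cols(
    tool = readr::col_character(), instance = readr::col_character(),
    subtask = readr::col_character(), n_sequences = readr::col_integer(),
    minutes = readr::col_double()
  ))
  ideals <- load_ideal_limits()
  cores <- load_instance_catalog()[, c("name", "cores")]
  totals <- ideals |>
    dplyr::left_join(cores, by = c(instance = "name")) |>
    dplyr::transmute(.data$tool, .data$instance, subtask = "total",
                     n_sequences = 20L,
                     minutes = .data$ideal_limit_min * .data$cores)
  part_totals <- parts |>
    dplyr::group_by(.data$tool, .data$instance) |>
    dplyr::summarise(subtask = "total", n_sequences = 20L,
                     minutes = sum(.data$minutes), .groups = "drop") |>
    dplyr::left_join(cores, by = c(instance = "name")) |>
    dplyr::mutate(minutes = .data$minutes * .data$cores, cores = NULL) |>
    dplyr::anti_join(totals, by = c("tool", "instance"))
  records <- dplyr::bind_rows(parts, totals, part_totals)
  records$total_aa <- expected_total_aa(sequence_bin_spec("20"))
  records
}

#' Load the published time/cost benchmark table
#'
#' The measured time-to-solution (TTS, minutes) and cost-to-solution (CTS, US
#' dollars) of the 20-sequence benchmark for HMMER, SP3 and THREADER across
#' the seven instance types.  These are measurements, used as calibration and
#' cross-check inputs only; SP3 cannot run on t1.micro (NA row).
#'
#' @return A tibble with `tool`, `instance`, `tts_min`, `cts_usd`.
#' @export
load_tts_benchmark <- function() {
  readr::read_csv(ext_file("tts_benchmark.csv"), col_types = readr::cols(
    tool = readr::col_character(), instance = readr::col_character(),
    tts_min = readr::col_double(), cts_usd = readr::col_double()
  ))
}

#' Load the published ideal-limit table
#'
#' Pipeline makespans and ideal limits (single-core total divided by core
#' count) of the 20-sequence benchmark for seven tools on m1.small, c1.xlarge
#' and hi1.4xlarge.
#'
#' @return A tibble with `tool`, `instance`, `pipeline_min`,
#'   `ideal_limit_min`.
#' @export
load_ideal_limits <- function() {
  readr::read_csv(ext_file("ideal_limits.csv"), col_types = readr::cols(
    tool = readr::col_character(), instance = readr::col_character(),
    pipeline_min = readr::col_double(), ideal_limit_min = readr::col_double()
  ))
}
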