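#' Fit the sequence-length runtime model
#'
#' Calibrates per-task duration predictions from benchmark records.  The model
#' is linear in residue count: the total single-core work of a tool on a
#' sequence set of `total_aa` residues is
#'
#' \deqn{T(tool, instance) = total\_aa \times base(tool) / speed(tool, instance)}
#'
#' where `base` is the tool's minutes-per-residue on a reference instance and
#' `speed` is a dimensionless per-core rate multiplier, pinned to 1 on the
#' reference.  Fitting is least squares in log space (with one record per
#' pair this reproduces the record exactly; with replicates it is the
#' geometric mean, the maximum-likelihood fit under the multiplicative noise
#' model the simulator uses).
#'
#' Records with `subtask == "total"` drive the speed factors.  Records for
#' chain/domain main tasks estimate the per-instance chain fraction of main
#' work, and postprocessing records estimate each tool's postprocessing
#' fraction; both fall back to canonical defaults (chain 60%, 49% on
#' t1.micro; post fraction pooled across calibrated tools) where no records
#' exist.
#'
#' @param records Benchmark records: a tibble with `tool`, `instance`,
#'   `subtask` (`"total"`, `"chain_main"`, `"domain_main"`, `"chain_post"`,
#'   `"domain_post"`), `minutes` and, for `"total"` rows, `total_aa`.
#' @param reference Reference instance name whose speed factor is pinned to
#'   1; defaults to `"m1.small"` when present for every tool, otherwise the
#'   first instance covering all tools.
#' @param prereq_fraction Fraction of a tool's main time charged for each
#'   separable preprocessing task (BLAST/PSIPRED); not measurable from the
#'   published profiles, so a small default.
#' @param meta_minutes Fixed duration of the per-sequence meta-analysis task.
#' @param complete If `TRUE`, (tool, instance) pairs without records are
#'   filled in with an instance-effect estimate: the geometric mean of the
#'   instance's speed factors across the tools that were profiled on it.
#'   Relies on the observation that relative instance speed is largely
#'   tool-independent; the default (`FALSE`) keeps predictions strict, with
#'   missing pairs raising an explicit error.
#' @return An object of class `runtime_model`.
#' @examples
#' model <- fit_runtime_model(load_benchmark_records())
#' model
#' @export
fit_runtime_model <- function(records, reference = NULL,
                              prereq_fraction = 0.05, meta_minutes = 1,
                              complete = FALSE) {
  if (any(records$minutes <= 0)) {
    abort("Benchmark record durations must be positive.",
          class = "ethreadsim_validation")
  }
  totals <- dplyr::filter(records, .data$subtask == "total")
  if (nrow(totals) == 0) {
    abort("No 'total' benchmark records; cannot calibrate speed factors.",
          class = "ethreadsim_missing_calibration")
  }
  if (!"total_aa" %in% names(totals) || any(is.na(totals$total_aa))) {
    abort("'total' benchmark records need a total_aa column.",
          class = "ethreadsim_validation")
  }
  rates <- totals |>
    dplyr::group_by(.data$tool, .data$instance) |>
    dplyr::summarise(rate = exp(mean(log(.data$minutes / .data$total_aa))),
                     n = dplyr::n(), .groups = "drop")

  tools <- unique(rates$tool)
  if (is.null(reference)) {
    cover <- rates |>
      dplyr::group_by(.data$instance) |>
      dplyr::summarise(n_tools = dplyr::n_distinct(.data$tool), .groups = "drop") |>
      dplyr::filter(.data$n_tools == length(tools))
    reference <- if ("m1.small" %in% cover$instance) "m1.small" else cover$instance[1]
    if (is.na(reference)) {
      abort("No instance has records for every tool; pass `reference` explicitly.",
            class = "ethreadsim_missing_calibration")
    }
  }
  ref_rates <- dplyr::filter(rates, .data$instance == reference)
  missing_ref <- setdiff(tools, ref_rates$tool)
  if (length(missing_ref) > 0) {
    abort(paste0("No records on reference instance '", reference, "' for: ",
                 paste(missing_ref, collapse = ", ")),
          class = "ethreadsim_missing_calibration")
  }
  base <- dplyr::transmute(ref_rates, .data$tool, base_min_per_aa = .data$rate)
  speed <- rates |>
    dplyr::left_join(base, by = "tool") |>
    dplyr::transmute(.data$tool, .data$instance,
                     speed_factor = .data$base_min_per_aa / .data$rate)
  if (complete) {
    effect <- speed |>
      dplyr::group_by(.data$instance) |>
      dplyr::summarise(speed_factor = exp(mean(log(.data$speed_factor))),
                       .groups = "drop")
    filled <- tidyr::expand_grid(tool = tools, instance = effect$instance) |>
      dplyr::anti_join(speed, by = c("tool", "instance")) |>
      dplyr::left_join(effect, by = "instance")
    speed <- dplyr::bind_rows(speed, filled)
  }

  mains <- dplyr::filter(records, .data$subtask %in% c("chain_main", "domain_main"))
  chain <- mains |>
    dplyr::group_by(.data$instance) |>
    dplyr::summarise(
      chain_fraction = sum(.data$minutes[.data$subtask == "chain_main"]) /
        sum(.data$minutes),
      .groups = "drop")

  posts <- dplyr::filter(records, .data$subtask %in% c("chain_post", "domain_post"))
  post <- dplyr::bind_rows(mains, posts) |>
    dplyr::group_by(.data$tool) |>
    dplyr::summarise(
      main_min = sum(.data$minutes[.data$subtask %in% c("chain_main", "domain_main")]),
      post_min = sum(.data$minutes[.data$subtask %in% c("chain_post", "domain_post")]),
      .groups = "drop") |>
    dplyr::filter(.data$main_min > 0, .data$post_min > 0) |>
    dplyr::transmute(.data$tool, post_fraction = .data$post_min / .data$main_min)
  post_default <- if (nrow(post) > 0) mean(post$post_fraction) else 0.10

  structure(list(
    base = base,
    speed = speed,
    chain_fraction = chain,
    post_fraction = post,
    post_fraction_default = post_default,
    prereq_fraction = prereq_fraction,
    meta_minutes = meta_minutes,
    reference = reference,
    n_records = nrow(records)
  ), class = "runtime_model")
}

#' @export
print.runtime_model <- function(x, ...) {
  cat(sprintf(paste0("<runtime_model> %d tools x %d instances ",
                     "(reference %s, %d records)\n"),
              dplyr::n_distinct(x$speed$tool),
              dplyr::n_distinct(x$speed$instance),
              x$reference, x$n_records))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy runtime_model
#' @export
tidy.runtime_model <- function(x, ...) {
  dplyr::left_join(x$speed, x$base, by = "tool")
}

#' @method glance runtime_model
#' @export
glance.runtime_model <- function(x, ...) {
  tibble::tibble(
    n_tools = dplyr::n_distinct(x$speed$tool),
    n_instances = dplyr::n_distinct(x$speed$instance),
    reference = x$reference,
    n_records = x$n_records,
    post_fraction_default = x$post_fraction_default,
    prereq_fraction = x$prereq_fraction,
    meta_minutes = x$meta_minutes
  )
}

# Canonical chain fractions when no calibration records exist for an
# instance: 60% of main work goes to the chain library, except the burstable
# t1.micro where the observed balance flips to 49/51.
default_chain_fraction <- function(instance) {
  ifelse(instance == "t1.micro", 0.49, 0.60)
}

model_chain_fraction <- function(model, instance) {
  if (!is.null(model) && nrow(model$chain_fraction) > 0) {
    hit <- match(instance, model$chain_fraction$instance)
    out <- model$chain_fraction$chain_fraction[hit]
    out[is.na(hit)] <- default_chain_fraction(instance[is.na(hit)])
    return(out)
  }
  default_chain_fraction(instance)
}

model_post_fraction <- function(model, tool) {
  hit <- match(tool, model$post_fraction$tool)
  out <- model$post_fraction$post_fraction[hit]
  out[is.na(hit)] <- model$post_fraction_default
  out
}

#' Split main-task work between chain and domain libraries
#'
#' Divides a total main-processing duration into its chain-library and
#' domain-library parts using the per-instance chain fraction: 60/40 on every
#' instance except t1.micro, where the observed split is 49/51.
#'
#' @param total_main_min Total main-task minutes (vectorized).
#' @param instance Instance name(s), used to look up the fraction.
#' @param chain_fraction Optional explicit fraction in `(0, 1)`, overriding
#'   the lookup.
#' @param model Optional fitted [fit_runtime_model()] whose estimated
#'   fractions take precedence over the canonical defaults.
#' @return A tibble with `chain_min` and `domain_min`;
#'   `chain_min + domain_min` always equals the input total.
#' @examples
#' split_chain_domain(100, "m1.small")   # 60 / 40
#' split_chain_domain(100, "t1.micro")   # 49 / 51
#' @export
split_chain_domain <- function(total_main_min, instance = NULL,
                               chain_fraction = NULL, model = NULL) {
  if (any(total_main_min < 0)) {
    abort("total_main_min must be nonnegative.", class = "ethreadsim_validation")
  }
  f <- chain_fraction %||%
    (if (!is.null(model)) model_chain_fraction(model, instance)
     else default_chain_fraction(instance))
  if (any(f <= 0) || any(f >= 1)) {
    abort("chain_fraction must lie in (0, 1).", class = "ethreadsim_validation")
  }
  tibble::tibble(chain_min = f * total_main_min,
                 domain_min = (1 - f) * total_main_min)
}

#' Ideal parallel limit
#'
#' The single-core total runtime divided by the number of cores: a lower
#' bound on the makespan any schedule can reach on that instance, attained
#' only under perfect load balance with no launch overhead.
#'
#' @param single_core_total_min Total single-core minutes (vectorized).
#' @param cores Core count, `>= 1`.
#' @return Minutes.
#' @examples
#' ideal_limit(17446.4, 16)  # 1090.4
#' @export
ideal_limit <- function(single_core_total_min, cores) {
  if (any(cores < 1)) {
    abort("cores must be >= 1.", class = "ethreadsim_validation")
  }
  if (any(single_core_total_min < 0)) {
    abort("single_core_total_min must be nonnegative.",
          class = "ethreadsim_validation")
  }
  single_core_total_min / cores
}

#' Predicted total single-core work of a tool on an instance
#'
#' @param model A fitted [fit_runtime_model()].
#' @param tool Tool name(s).
#' @param instance Instance name(s).
#' @param total_aa Total residue count(s).
#' @return Minutes (vectorized over the longest argument).
#' @export
predict_total_work <- function(model, tool, instance, total_aa) {
  key <- paste(model$speed$tool, model$speed$instance)
  hit <- match(paste(tool, instance), key)
  if (anyNA(hit)) {
    bad <- unique(paste0(tool, " on ", instance)[is.na(hit)])
    abort(paste0("No calibration for: ", paste(bad, collapse = "; ")),
          class = "ethreadsim_missing_calibration")
  }
  base <- model$base$base_min_per_aa[match(model$speed$tool[hit], model$base$tool)]
  total_aa * base / model$speed$speed_factor[hit]
}

#' Predict per-task durations on an instance
#'
#' Maps each workload task to its predicted duration on one instance type.
#' A tool's total per-sequence work (main plus postprocessing) is linear in
#' sequence length; main work is the total divided by `1 + post_fraction`,
#' split between chain and domain libraries by the instance's chain fraction,
#' postprocessing scales each main task by the tool's postprocessing
#' fraction, separable prerequisites are charged `prereq_fraction` of main
#' work each, and meta-analysis is a fixed small constant.
#'
#' If the workload carries a `predicted_min` column it overrides the model
#' entirely (useful for oracle-style scheduling experiments).
#'
#' @param tasks A workload tibble ([build_workload()]).
#' @param instance A single instance name.
#' @param model A fitted [fit_runtime_model()]; may be `NULL` when
#'   `predicted_min` is present.
#' @return Numeric vector of predicted minutes, one per task row.
#' @export
predict_duration <- function(tasks, instance, model = NULL) {
  if ("predicted_min" %in% names(tasks)) {
    return(as.numeric(tasks$predicted_min))
  }
  if (is.null(model)) {
    abort("Need a runtime model (or a predicted_min column).",
          class = "ethreadsim_missing_calibration")
  }
  n <- nrow(tasks)
  out <- numeric(n)
  is_meta <- tasks$kind == "meta_analysis"
  out[is_meta] <- model$meta_minutes
  reg <- which(!is_meta)
  if (length(reg) > 0) {
    total <- predict_total_work(model, tasks$tool[reg], instance,
                                tasks$length_aa[reg])
    post_f <- model_post_fraction(model, tasks$tool[reg])
    main_total <- total / (1 + post_f)
    chain_f <- model_chain_fraction(model, instance)
    kind <- tasks$kind[reg]
    out[reg] <- dplyr::case_when(
      kind == "chain_main" ~ chain_f * main_total,
      kind == "domain_main" ~ (1 - chain_f) * main_total,
      kind == "chain_post" ~ post_f * chain_f * main_total,
      kind == "domain_post" ~ post_f * (1 - chain_f) * main_total,
      kind %in% c("prereq_blast", "prereq_psipred") ~
        model$prereq_fraction * main_total
    )
  }
  out
}

#' Serialize / restore a runtime model
#'
#' Round-trips a fitted model through a structured YAML text file.
#'
#' @param model A `runtime_model`.
#' @param path File path.
#' @return `write_runtime_model()` returns `path` invisibly;
#'   `read_runtime_model()` returns the model.
#' @export
write_runtime_model <- function(model, path) {
  payload <- list(
    base = as.list(model$base),
    speed = as.list(model$speed),
    chain_fraction = as.list(model$chain_fraction),
    post_fraction = as.list(model$post_fraction),
    post_fraction_default = model$post_fraction_default,
    prereq_fraction = model$prereq_fraction,
    meta_minutes = model$meta_minutes,
    reference = model$reference,
    n_records = model$n_records
  )
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_runtime_model
#' @export
read_runtime_model <- function(path) {
  p <- yaml::read_yaml(path)
  structure(list(
    base = tibble::as_tibble(p$base),
    speed = tibble::as_tibble(p$speed),
    chain_fraction = tibble::as_tibble(p$chain_fraction),
    post_fraction = tibble::as_tibble(p$post_fraction),
    post_fraction_default = p$post_fraction_default,
    prereq_fraction = p$prereq_fraction,
    meta_minutes = p$meta_minutes,
    reference = p$reference,
    n_records = p$n_records
  ), class = "runtime_model")
}

#' Generate synthetic benchmark records from known factors
#'
#' Produces `"total"` benchmark records from a known base-rate/speed-factor
#' configuration with optional multiplicative lognormal noise.  Used to study
#' parameter recovery of [fit_runtime_model()]: with zero noise the fit
#' reproduces the generating factors exactly; with noise the error shrinks as
#' the per-pair record count grows.
#'
#' @param base Tibble with `tool`, `base_min_per_aa`.
#' @param speed Tibble with `tool`, `instance`, `speed_factor`.
#' @param total_aa Residue total each record represents.
#' @param n_per_pair Records per (tool, instance) pair.
#' @param noise_sigma Lognormal sigma of the multiplicative noise.
#' @param seed Integer seed.
#' @return A benchmark-record tibble accepted by [fit_runtime_model()].
#' @export
simulate_benchmark_records <- function(base, speed, total_aa = 6160,
                                       n_per_pair = 1, noise_sigma = 0,
                                       seed = 1L) {
  set.seed(seed)
  grid <- dplyr::left_join(speed, base, by = "tool")
  records <- tidyr::expand_grid(grid, rep = seq_len(n_per_pair))
  records$total_aa <- total_aa
  mu <- total_aa * records$base_min_per_aa / records$speed_factor
  records$minutes <- mu * rlnorm(nrow(records), 0, noise_sigma)
  dplyr::transmute(records, .data$tool, .data$instance, subtask = "total",
                   n_sequences = NA_integer_, .data$minutes, .data$total_aa)
}
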