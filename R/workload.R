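#' Build the per-sequence, per-tool task graph
#'
#' Expands a sequence set and a tool catalog into the task DAG of the
#' meta-threading pipeline.  Every (sequence, tool) pair contributes four core
#' tasks — threading against the chain and domain template libraries
#' (`chain_main`, `domain_main`) and their postprocessing (`chain_post`,
#' `domain_post`) — plus one preprocessing task per separable prerequisite
#' (BLAST and/or PSIPRED).  Tools that embed BLAST inside iterative profile
#' construction get no separate BLAST task; that time lives in their main
#' tasks.  Each sequence closes with a single `meta_analysis` task depending
#' on all of its postprocessing tasks.
#'
#' @param sequences A tibble with `id` and `length_aa` (unique ids).
#' @param tools Tool catalog rows to include, as from [load_tool_catalog()];
#'   prerequisite-only entries (BLAST, PSIPRED) are ignored as tools.
#' @return A workload tibble with columns `task_id`, `kind`, `tool`
#'   (`NA` for meta-analysis), `seq_id`, `length_aa` and `deps` (list column
#'   of prerequisite task ids).  Rows are emitted in a topological order.
#' @examples
#' tools <- dplyr::filter(load_tool_catalog(), name == "pfTools")
#' seqs <- tibble::tibble(id = "s1", length_aa = 200L)
#' build_workload(seqs, tools)
#' @export
build_workload <- function(sequences, tools) {
  if (anyDuplicated(sequences$id)) {
    abort("Duplicate sequence ids in workload input.",
          class = "ethreadsim_validation")
  }
  if (nrow(sequences) > 0 && any(sequences$length_aa < 1)) {
    abort("Sequence lengths must be >= 1.", class = "ethreadsim_validation")
  }
  threading <- dplyr::filter(tools, !.data$prereq_only)
  if (nrow(sequences) == 0 || nrow(threading) == 0) {
    return(empty_workload())
  }

  pairs <- tidyr::expand_grid(
    sequences[, c("id", "length_aa")],
    tibble::tibble(tool = threading$name,
                   prerequisites = threading$prerequisites,
                   blast_separable = threading$blast_separable)
  )
  names(pairs)[names(pairs) == "id"] <- "seq_id"

  task_id <- function(seq_id, tool, kind) {
    if (length(kind) == 0) return(character(0))  # paste() would recycle to ""
    paste(seq_id, tool, kind, sep = "|")
  }

  rows <- purrr::pmap(pairs, function(seq_id, length_aa, tool, prerequisites,
                                      blast_separable) {
    prereqs <- if (blast_separable) intersect(prerequisites, c("BLAST", "PSIPRED")) else character(0)
    prereq_kind <- c(BLAST = "prereq_blast", PSIPRED = "prereq_psipred")[prereqs]
    prereq_ids <- task_id(seq_id, tool, prereq_kind)
    chain_main <- task_id(seq_id, tool, "chain_main")
    domain_main <- task_id(seq_id, tool, "domain_main")
    tibble::tibble(
      task_id = c(prereq_ids, chain_main, domain_main,
                  task_id(seq_id, tool, c("chain_post", "domain_post"))),
      kind = c(unname(prereq_kind), "chain_main", "domain_main",
               "chain_post", "domain_post"),
      tool = tool,
      seq_id = seq_id,
      length_aa = length_aa,
      deps = c(purrr::map(seq_along(prereq_ids), ~ character(0)),
               list(prereq_ids, prereq_ids, chain_main, domain_main))
    )
  })
  tasks <- dplyr::bind_rows(rows)

  post <- dplyr::filter(tasks, .data$kind %in% c("chain_post", "domain_post"))
  meta <- post |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(deps = list(.data$task_id), .groups = "drop") |>
    dplyr::left_join(sequences, by = c(seq_id = "id")) |>
    dplyr::transmute(task_id = paste(.data$seq_id, "meta_analysis", sep = "|"),
                     kind = "meta_analysis", tool = NA_character_,
                     .data$seq_id, .data$length_aa, .data$deps)
  workload <- dplyr::bind_rows(tasks, meta)
  validate_workload(workload)
  workload
}

empty_workload <- function() {
  tibble::tibble(task_id = character(0), kind = character(0),
                 tool = character(0), seq_id = character(0),
                 length_aa = integer(0), deps = list())
}

#' Validate a workload task graph
#'
#' Checks the structural invariants of a workload tibble: unique task ids,
#' known task kinds, dependencies referencing existing tasks, and acyclicity
#' (a topological order exists).
#'
#' @param workload A workload tibble as from [build_workload()].
#' @return `workload`, invisibly; aborts on violation.
#' @export
validate_workload <- function(workload) {
  if (anyDuplicated(workload$task_id)) {
    abort("Task ids are not unique.", class = "ethreadsim_validation")
  }
  if (!all(workload$kind %in% TASK_KINDS)) {
    abort("Unknown task kind in workload.", class = "ethreadsim_validation")
  }
  deps <- unlist(workload$deps, use.names = FALSE)
  if (length(deps) > 0 && !all(deps %in% workload$task_id)) {
    abort("Workload dependencies reference unknown tasks.",
          class = "ethreadsim_validation")
  }
  topological_order(workload)  # aborts on cycles
  invisible(workload)
}

# Kahn's algorithm; returns row indices of `workload` in a valid topological
# order, aborting if the dependency graph has a cycle.
topological_order <- function(workload) {
  n <- nrow(workload)
  if (n == 0) return(integer(0))
  idx <- setNames(seq_len(n), workload$task_id)
  indeg <- lengths(workload$deps)
  dependents <- vector("list", n)
  for (i in seq_len(n)) {
    for (d in workload$deps[[i]]) {
      j <- idx[[d]]
      dependents[[j]] <- c(dependents[[j]], i)
    }
  }
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (j in dependents[[i]]) {
      indeg[j] <- indeg[j] - 1
      if (indeg[j] == 0) queue <- c(queue, j)
    }
  }
  if (length(out) != n) {
    abort("Workload dependency graph has a cycle.",
          class = "ethreadsim_validation")
  }
  out
}

#' Write / read a workload as an edge-list TSV
#'
#' The on-disk form has one row per task with dependency ids collapsed by
#' `;`; [read_workload()] restores the list column and validates the graph.
#'
#' @param workload A workload tibble.
#' @param path File path.
#' @return `write_workload()` returns `path` invisibly; `read_workload()`
#'   returns the workload tibble.
#' @export
write_workload <- function(workload, path) {
  flat <- dplyr::mutate(workload,
                        deps = purrr::map_chr(.data$deps, paste, collapse = ";"))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_workload
#' @export
read_workload <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    task_id = readr::col_character(), kind = readr::col_character(),
    tool = readr::col_character(), seq_id = readr::col_character(),
    length_aa = readr::col_integer(), deps = readr::col_character()
  ))
  workload <- dplyr::mutate(flat, deps = split_semicolon(.data$deps))
  validate_workload(workload)
  workload
}
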