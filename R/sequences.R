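#' Generate a synthetic benchmark sequence set
#'
#' Draws protein sequence lengths from a bin specification: for each length
#' bin, exactly `count` sequences are generated with lengths uniform on
#' `[min_aa, max_aa]`.  This emulates the curated benchmark sets used to
#' profile the pipeline (110 sequences of 51-600 aa, and a 20-sequence
#' subset); only the lengths matter downstream, since every runtime model is a
#' function of residue count.
#'
#' @param bins A tibble with columns `min_aa`, `max_aa`, `count`
#'   (non-overlapping bins), e.g. from [sequence_bin_spec()].
#' @param seed Integer seed; the same seed always yields the same set.
#' @param prefix Prefix for generated sequence ids.
#' @return A tibble with `id` and `length_aa`, one row per sequence.
#' @examples
#' generate_benchmark_sequences(sequence_bin_spec("20"), seed = 1)
#' @export
generate_benchmark_sequences <- function(bins, seed = 1L, prefix = "seq") {
  required <- c("min_aa", "max_aa", "count")
  if (!all(required %in% names(bins))) {
    abort("Bin specification needs columns min_aa, max_aa, count.",
          class = "ethreadsim_validation")
  }
  if (any(bins$count < 0) || any(bins$min_aa < 1) || any(bins$max_aa < bins$min_aa)) {
    abort("Bins must satisfy min_aa >= 1, max_aa >= min_aa, count >= 0.",
          class = "ethreadsim_validation")
  }
  ord <- order(bins$min_aa)
  if (nrow(bins) > 1 &&
      any(bins$min_aa[ord][-1] <= bins$max_aa[ord][-nrow(bins)])) {
    abort("Length bins overlap.", class = "ethreadsim_validation")
  }
  set.seed(seed)
  lengths <- unlist(purrr::pmap(bins[required], function(min_aa, max_aa, count) {
    sample(seq.int(min_aa, max_aa), count, replace = TRUE)
  }))
  n <- length(lengths)
  tibble::tibble(
    id = sprintf("%s%0*d", prefix, max(3L, nchar(n)), seq_len(n)),
    length_aa = as.integer(lengths)
  )
}

#' Read protein sequences from a FASTA file
#'
#' Only the record id (first whitespace-delimited token of the header) and the
#' sequence length are retained; residues themselves play no role in the
#' scheduling model.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with `id` and `length_aa`.
#' @export
read_sequences_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  out <- tibble::tibble(id = ids, length_aa = Biostrings::width(seqs))
  if (anyDuplicated(out$id)) {
    abort("FASTA record ids are not unique.", class = "ethreadsim_validation")
  }
  out
}

#' Write a sequence set to FASTA
#'
#' Emits one record per row of `sequences`, filling the residues with a
#' reproducible random amino-acid string of the requested length (the
#' downstream model only ever consumes lengths, so the composition is
#' arbitrary but deterministic).
#'
#' @param sequences A tibble with `id` and `length_aa`.
#' @param path Output FASTA path.
#' @param seed Seed for the residue fill.
#' @return `path`, invisibly.
#' @export
write_sequences_fasta <- function(sequences, path, seed = 1L) {
  if (anyDuplicated(sequences$id)) {
    abort("Sequence ids are not unique.", class = "ethreadsim_validation")
  }
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  residues <- vapply(sequences$length_aa, function(n) {
    paste(sample(aa, n, replace = TRUE), collapse = "")
  }, character(1))
  xs <- Biostrings::AAStringSet(setNames(residues, sequences$id))
  Biostrings::writeXStringSet(xs, filepath = path)
  invisible(path)
}
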