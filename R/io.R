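#' Write a classification report
#'
#' Writes the ranked candidate table as TSV (one row per candidate:
#' haplogroup, rank group, Vp, Vm, Vs, identity, score, extras, missing) and
#' a JSON mirror including rank groups and QC flags.
#'
#' @param result an \code{hg_classification}.
#' @param stem output path stem; writes \code{<stem>.tsv} and
#'   \code{<stem>.json}.
#' @return invisibly, the two paths written.
#' @export
write_classification <- function(result, stem) {
  stopifnot(inherits(result, "hg_classification"))
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  utils::write.table(result$candidates, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(sample_id = result$sample_id,
         rank_groups = result$rank_groups,
         candidates = result$candidates,
         n_dropped_groups = result$n_dropped_groups,
         qc_flags = lapply(result$qc_flags, function(f)
           f[c("message", "fragments", "fragment_hgs", "mrca")])),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}

#' Write a tracking report
#'
#' JSON report mirroring per-track accounting: candidates, amplicons added
#' and totals for each track cycle.
#'
#' @param state a \code{tracking_state} or \code{tracking_outcome}.
#' @param path output JSON path.
#' @export
write_tracking_report <- function(state, path) {
  payload <- if (inherits(state, "tracking_state")) {
    list(sample_id = state$profile$sample_id,
         finished = state$finished, stalled = state$stalled,
         final_hg = state$final_hg,
         amplicons_used = state$amplicons_used,
         tracks = state$history)
  } else unclass(state)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write fragments to FASTA
#'
#' @param fragments named character vector of sequences.
#' @param path output FASTA path.
#' @export
write_fragments_fasta <- function(fragments, path) {
  ss <- Biostrings::DNAStringSet(unname(fragments))
  names(ss) <- names(fragments)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
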