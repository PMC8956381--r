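#' Construct a sample profile directly from called variants
#'
#' For pre-called input (e.g. HSD rows) where alignment is not needed.
#'
#' @param sample_id sample identifier.
#' @param variants character vector of Phylotree variant tokens.
#' @param ranges two-column matrix (or vector \code{c(start, end)}) of
#'   1-based inclusive covered reference intervals.
#' @param fragment_calls optional per-fragment call list (kept for QC).
#' @return object of class \code{sample_profile}: \code{sample_id},
#'   \code{variants} (canonical tokens, position-sorted), \code{ranges}
#'   (merged, sorted, disjoint), \code{Vs}, \code{fragment_calls}.
#' @export
sample_profile <- function(sample_id, variants, ranges,
                           fragment_calls = list()) {
  if (is.null(dim(ranges))) ranges <- matrix(ranges, ncol = 2L, byrow = TRUE)
  ranges <- merge_ranges(ranges)
  variants <- unique(canonical_tokens(variants))
  if (length(variants)) {
    v <- parse_variant(variants)
    variants <- variants[order(v$position, v$kind, v$ins_index)]
    sub_del <- v$kind %in% c("transition", "transversion", "deletion")
    out <- sub_del & !pos_in_ranges(v$position, ranges)[seq_len(nrow(v))]
    if (any(out))
      stop("variant(s) outside covered ranges: ",
           paste(v$token[out], collapse = ", "))
  }
  structure(list(sample_id = sample_id, variants = variants, ranges = ranges,
                 Vs = length(variants), fragment_calls = fragment_calls),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  rng <- apply(x$ranges, 1L, function(r) paste0(r[1L], "-", r[2L]))
  cat("Sample '", x$sample_id, "': Vs = ", x$Vs, ", ranges ",
      paste(rng, collapse = "; "), "\n", sep = "")
  if (x$Vs) cat("  variants: ", paste(x$variants, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Build a sample profile from sequence fragments
#'
#' Aligns each fragment to the reference ([align_gotoh()]), calls variants in
#' Phylotree notation ([call_variants()]), unions the calls and merges the
#' covered ranges. The reference is treated as circular by default: fragments
#' are aligned against a doubled reference and coordinates re-mapped, so
#' fragments spanning the 16569/1 origin (the control region does) align in
#' one piece and report an origin-split range pair. Fragments scoring below
#' \code{min_score_frac * match * length} are rejected with a warning.
#' Overlapping fragments that disagree at a position (one calls a variant the
#' other, covering the same position, does not) are an error.
#'
#' @param fragments named character vector of sequences, or a data.frame with
#'   columns \code{id} and \code{sequence}.
#' @param reference reference sequence string.
#' @param params alignment parameters, see [alignment_params()].
#' @param mask hotspot mask rules, see [default_hotspot_mask()].
#' @param sample_id sample identifier.
#' @param circular treat the reference as circular (doubled-reference trick).
#' @param min_score_frac alignment score floor as a fraction of the maximum
#'   attainable score for the fragment.
#' @return a \code{sample_profile}.
#' @export
build_sample_profile <- function(fragments, reference,
                                 params = alignment_params(),
                                 mask = default_hotspot_mask(),
                                 sample_id = "sample",
                                 circular = TRUE,
                                 min_score_frac = 0.5) {
  frs <- as_fragments(fragments)
  if (length(frs) == 0L) stop("need at least one fragment")
  L <- nchar(reference)
  target <- if (circular) paste0(reference, reference) else reference
  calls <- list()
  for (id in names(frs)) {
    seq <- frs[[id]]
    aln <- align_gotoh(seq, target, params)
    floor_score <- min_score_frac * params$match * nchar(seq)
    if (aln$score < floor_score) {
      warning("fragment '", id, "' rejected: score ", aln$score,
              " below floor ", floor_score)
      next
    }
    cl <- call_variants(aln, hotspot_mask = mask, reference = target)
    remapped <- remap_circular(cl$variants, cl$range, L, circular)
    calls[[id]] <- list(id = id, variants = remapped$variants,
                        ranges = remapped$ranges)
  }
  if (length(calls) == 0L) stop("no fragment passed the alignment score floor")
  check_fragment_conflicts(calls)
  sample_profile(sample_id,
                 variants = unique(unlist(lapply(calls, `[[`, "variants"))),
                 ranges = do.call(rbind, lapply(calls, `[[`, "ranges")),
                 fragment_calls = calls)
}

as_fragments <- function(fragments) {
  if (is.data.frame(fragments)) {
    stopifnot(all(c("id", "sequence") %in% names(fragments)))
    return(stats::setNames(as.character(fragments$sequence),
                           as.character(fragments$id)))
  }
  fr <- as.character(fragments)
  nm <- names(fragments)
  if (is.null(nm)) nm <- paste0("frag", seq_along(fr))
  stats::setNames(fr, nm)
}

## Map doubled-reference coordinates back onto [1, L]; ranges crossing the
## origin split into two intervals.
remap_circular <- function(tokens, range, L, circular) {
  if (!circular)
    return(list(variants = tokens,
                ranges = matrix(range, ncol = 2L,
                                dimnames = list(NULL, c("start", "end")))))
  wrap_pos <- function(p) ((p - 1L) %% L) + 1L
  if (length(tokens)) {
    v <- parse_variant(tokens)
    for (i in seq_len(nrow(v))) v$position[i] <- wrap_pos(v$position[i])
    tokens <- format_variant(v)
  }
  s <- range[["start"]]; e <- range[["end"]]
  if (e - s + 1L >= L) {                     # full circle
    ranges <- matrix(c(1L, L), ncol = 2L)
  } else {
    s2 <- wrap_pos(s); e2 <- wrap_pos(e)
    ranges <- if (s2 <= e2) matrix(c(s2, e2), ncol = 2L)
              else matrix(c(s2, L, 1L, e2), ncol = 2L, byrow = TRUE)
  }
  dimnames(ranges) <- list(NULL, c("start", "end"))
  list(variants = tokens, ranges = ranges)
}

## Overlapping fragments must agree wherever one of them calls a
## substitution or deletion: every other fragment covering that position
## must carry the identical token.
check_fragment_conflicts <- function(calls) {
  if (length(calls) < 2L) return(invisible())
  for (i in seq_along(calls)) {
    vi <- calls[[i]]$variants
    if (length(vi) == 0L) next
    pv <- parse_variant(vi)
    keep <- pv$kind %in% c("transition", "transversion", "deletion")
    for (k in which(keep)) {
      p <- pv$position[k]
      for (j in seq_along(calls)) {
        if (j == i) next
        if (!any(pos_in_ranges(p, calls[[j]]$ranges))) next
        if (!pv$token[k] %in% calls[[j]]$variants)
          stop("conflicting calls at position ", p, " between fragments '",
               calls[[i]]$id, "' (", pv$token[k], ") and '", calls[[j]]$id,
               "' (reference or different call)")
      }
    }
  }
  invisible()
}

#' Read sample fragments from a FASTA file
#'
#' All records are treated as fragments of one sample unless a sample map is
#' supplied.
#'
#' @param path FASTA path.
#' @param sample_map optional data.frame (\code{fragment}, \code{sample})
#'   assigning records to samples.
#' @return a named character vector of sequences (single sample), or a named
#'   list of such vectors (with \code{sample_map}).
#' @export
read_fragments_fasta <- function(path, sample_map = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(toupper(as.character(ss)), ids)
  if (is.null(sample_map)) return(seqs)
  stopifnot(all(c("fragment", "sample") %in% names(sample_map)))
  idx <- match(ids, sample_map$fragment)
  if (anyNA(idx)) stop("fragments missing from sample map: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  split(seqs, sample_map$sample[idx])
}

#' Read pre-called variant profiles from an HSD-style file
#'
#' Tab-separated: sample id, covered range(s) (\code{"16024-16365;72-340"};
#' a range such as \code{"16024-576"} wraps the circular origin and is split),
#' an optional haplogroup column, then variant tokens (remaining columns
#' and/or space-separated). A header line whose first field is
#' \code{SampleId} is skipped.
#'
#' @param path HSD path.
#' @return list of \code{sample_profile} objects; any haplogroup column is
#'   kept in attribute \code{"haplogroup"} of each profile.
#' @export
read_hsd <- function(path, ref_length = 16569L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(SampleId|#)", lines, ignore.case = TRUE)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed HSD line: ", ln)
    id <- trimws(f[1L])
    ranges <- parse_hsd_ranges(trimws(f[2L]), ref_length)
    rest <- f[-(1:2)]
    hap <- NA_character_
    if (length(rest) && !grepl("^[0-9(]", trimws(rest[1L])) &&
        nzchar(trimws(rest[1L]))) {
      hap <- trimws(rest[1L]); rest <- rest[-1L]
    }
    toks <- unlist(strsplit(trimws(rest), "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    prof <- sample_profile(id, toks, ranges)
    attr(prof, "haplogroup") <- hap
    out[[id]] <- prof
  }
  out
}

parse_hsd_ranges <- function(txt, ref_length) {
  parts <- unlist(strsplit(txt, "[;,]"))
  parts <- trimws(parts[nzchar(trimws(parts))])
  rows <- list()
  for (p in parts) {
    ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    if (ab[1L] <= ab[2L]) rows[[length(rows) + 1L]] <- ab
    else {                                   # wraps the origin
      rows[[length(rows) + 1L]] <- c(ab[1L], ref_length)
      rows[[length(rows) + 1L]] <- c(1L, ab[2L])
    }
  }
  do.call(rbind, rows)
}
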