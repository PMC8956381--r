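#' Call variants from an alignment in Phylotree notation
#'
#' Walks the gapped alignment columns against reference coordinates.
#' Substitutions are classified transition (purine-purine or
#' pyrimidine-pyrimidine, bare-position token) versus transversion
#' (position+base token); insertions and deletions are right-shifted to their
#' 3'-most equivalent placement before naming, so tie-broken tracebacks that
#' place a gap anywhere within a repeat yield one canonical call. Ambiguous
#' IUPAC query bases and the reference placeholder 'N' produce no call.
#'
#' @param aln an \code{alignment_result} against reference coordinates.
#' @param hotspot_mask character vector of mask rules (see
#'   [default_hotspot_mask()]); empty by default.
#' @param reference the reference string the alignment was computed against
#'   (needed for indel normalisation); if \code{NULL}, taken from the gapped
#'   reference (sufficient when indels are internal).
#' @return list with \code{variants} (character vector of canonical tokens)
#'   and \code{range} (integer \code{c(start, end)} covered interval).
#' @export
call_variants <- function(aln, hotspot_mask = character(), reference = NULL) {
  stopifnot(inherits(aln, "alignment_result"))
  q <- strsplit(aln$aligned_query, "")[[1L]]
  r <- strsplit(aln$aligned_reference, "")[[1L]]
  stopifnot(length(q) == length(r))
  start <- aln$ref_span[["start"]]
  refseq <- if (is.null(reference)) NULL else toupper(reference)
  pos <- start - 1L
  subs <- list(); dels <- list(); inss <- list()
  i <- 1L
  n <- length(q)
  while (i <= n) {
    if (r[i] != "-" && q[i] != "-") {
      pos <- pos + 1L
      if (q[i] != r[i] && q[i] %in% c("A", "C", "G", "T") &&
          r[i] %in% c("A", "C", "G", "T")) {
        subs[[length(subs) + 1L]] <- c(pos, q[i], r[i])
      }
      i <- i + 1L
    } else if (q[i] == "-") {          # deletion of reference bases
      j <- i
      while (j <= n && q[j] == "-") j <- j + 1L
      len <- j - i
      dels[[length(dels) + 1L]] <- c(pos + 1L, len)  # first deleted ref pos
      pos <- pos + len
      i <- j
    } else {                            # insertion relative to reference
      j <- i
      while (j <= n && r[j] == "-") j <- j + 1L
      inss[[length(inss) + 1L]] <- list(anchor = pos, bases = q[i:(j - 1L)])
      i <- j
    }
  }
  lookup <- function(p) {
    if (!is.null(refseq)) {
      if (p >= 1L && p <= nchar(refseq)) substr(refseq, p, p) else ""
    } else {
      # reconstruct from gapped reference, valid within the span
      rr <- r[r != "-"]
      k <- p - start + 1L
      if (k >= 1L && k <= length(rr)) rr[k] else ""
    }
  }
  toks <- character()
  for (s in subs) {
    p <- as.integer(s[1L]); qb <- s[2L]; rb <- s[3L]
    tok <- if (is_purine(qb) == is_purine(rb)) as.character(p) else paste0(p, qb)
    toks <- c(toks, tok)
  }
  for (d in dels) {
    p <- as.integer(d[1L]); len <- as.integer(d[2L])
    # right-shift: deletion of ref[p..p+len-1] can move right while the base
    # entering from the left equals the base leaving on the right
    repeat {
      nxt <- lookup(p + len)
      if (nzchar(nxt) && nxt == lookup(p)) p <- p + 1L else break
    }
    toks <- c(toks, paste0(seq(p, p + len - 1L), "d"))
  }
  for (ins in inss) {
    anchor <- as.integer(ins$anchor)
    bases <- ins$bases
    if (!all(bases %in% c("A", "C", "G", "T"))) next  # ambiguous: no call
    # right-rotate: inserting S after anchor equals inserting
    # rotate(S) after anchor+1 when S[1] == ref[anchor+1]
    repeat {
      nxt <- lookup(anchor + 1L)
      if (nzchar(nxt) && nxt == bases[1L]) {
        bases <- c(bases[-1L], nxt)
        anchor <- anchor + 1L
      } else break
    }
    if (anchor < 1L) anchor <- 1L
    toks <- c(toks, paste0(anchor, ".", seq_along(bases), bases))
  }
  toks <- apply_hotspot_mask(toks, hotspot_mask)
  list(variants = toks,
       range = c(start = start, end = aln$ref_span[["end"]]))
}

#' Default hotspot mask
#'
#' Mask rules for mutational hotspots conventionally excluded in mtDNA
#' haplotyping: position 16519, length variation of the poly-C tracts
#' (insertions anchored at 309 and 315), the 523-524 AC indel region, and
#' the rCRS placeholder position 3107 (never called). Rules are either a bare
#' position (masks every variant at that position) or \code{"<pos>."} (masks
#' insertions anchored there).
#'
#' @return character vector of mask rules.
#' @export
default_hotspot_mask <- function() {
  c("16519", "3107", "309.", "315.", "523", "524")
}

apply_hotspot_mask <- function(tokens, mask) {
  if (length(tokens) == 0L || length(mask) == 0L) return(tokens)
  v <- parse_variant(tokens)
  pos_rules <- suppressWarnings(as.integer(mask[grepl("^[0-9]+$", mask)]))
  ins_rules <- suppressWarnings(as.integer(sub("\\.$", "", mask[grepl("^[0-9]+\\.$", mask)])))
  drop <- (v$position %in% pos_rules) |
    (v$kind == "insertion" & v$position %in% ins_rules)
  tokens[!drop]
}

## Merge 1-based inclusive intervals: sorted, disjoint matrix with columns
## start, end.
merge_ranges <- function(ranges) {
  if (is.null(ranges) || NROW(ranges) == 0L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.integer(ranges), ncol = 2L)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1L]) {
    last <- nrow(out)
    if (m[i, 1L] <= out[last, 2L] + 1L) {
      out[last, 2L] <- max(out[last, 2L], m[i, 2L])
    } else out <- rbind(out, m[i, ])
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

pos_in_ranges <- function(pos, ranges) {
  if (NROW(ranges) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= ranges[, 1L] & p <= ranges[, 2L]), TRUE)
}
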