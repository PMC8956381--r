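#' Parse variant tokens in Phylotree notation
#'
#' Phylotree writes mtDNA variants relative to the rCRS coordinate frame:
#' transitions as a bare position (\code{"263"}), transversions as position
#' plus derived base (\code{"16318T"}), insertions as
#' \code{"<anchor>.<ordinal><base>"} (\code{"573.1C"}), deletions as
#' \code{"<pos>d"} (\code{"249d"}, ranges \code{"290-291d"} expand to one
#' deletion per position) and back-mutations with a trailing \code{"!"}.
#'
#' @param tokens character vector of variant tokens.
#' @return A data.frame with one row per variant: \code{token} (canonical
#'   form), \code{position} (1-based rCRS coordinate; the anchor for
#'   insertions), \code{kind} (\code{"transition"}, \code{"transversion"},
#'   \code{"insertion"} or \code{"deletion"}), \code{derived} (base(s); empty
#'   for deletions and bare transitions), \code{ins_index} (ordinal of the
#'   inserted base, 0 otherwise) and \code{back} (logical back-mutation flag).
#' @examples
#' parse_variant(c("263", "16318T", "573.1C", "249d", "16093!"))
#' @export
parse_variant <- function(tokens) {
  stopifnot(is.character(tokens), all(nzchar(tokens)))
  rows <- lapply(tokens, parse_variant_one)
  do.call(rbind, rows)
}

parse_variant_one <- function(token) {
  raw <- token
  back <- grepl("!$", token)
  tok <- sub("!+$", "", token)
  bang <- if (back) "!" else ""
  if (grepl("^[0-9]+$", tok)) {
    pos <- as.integer(tok)
    return(variant_row(paste0(pos, bang), pos, "transition", "", 0L, back, raw))
  }
  if (grepl("^[0-9]+[ACGT]$", tok)) {
    pos <- as.integer(sub("[ACGT]$", "", tok))
    base <- substr(tok, nchar(tok), nchar(tok))
    return(variant_row(paste0(pos, base, bang), pos, "transversion", base, 0L, back, raw))
  }
  if (grepl("^[0-9]+\\.[0-9]+[ACGT]+$", tok)) {
    pos <- as.integer(sub("\\..*$", "", tok))
    rest <- sub("^[0-9]+\\.", "", tok)
    idx <- as.integer(sub("[ACGT]+$", "", rest))
    base <- sub("^[0-9]+", "", rest)
    if (idx < 1L) stop("malformed variant token (insertion ordinal must be >= 1): ", raw)
    return(variant_row(paste0(pos, ".", idx, base, bang), pos, "insertion", base, idx, back, raw))
  }
  if (grepl("^[0-9]+d$", tok, ignore.case = TRUE)) {
    pos <- as.integer(sub("d$", "", tok, ignore.case = TRUE))
    return(variant_row(paste0(pos, "d", bang), pos, "deletion", "", 0L, back, raw))
  }
  if (grepl("^[0-9]+-[0-9]+d$", tok, ignore.case = TRUE)) {
    ab <- as.integer(strsplit(sub("d$", "", tok, ignore.case = TRUE), "-", fixed = TRUE)[[1L]])
    if (ab[1L] > ab[2L]) stop("malformed variant token (empty deletion range): ", raw)
    rows <- lapply(seq(ab[1L], ab[2L]), function(p)
      variant_row(paste0(p, "d", bang), p, "deletion", "", 0L, back, raw))
    return(do.call(rbind, rows))
  }
  stop("malformed variant token: ", raw)
}

variant_row <- function(token, pos, kind, derived, idx, back, raw) {
  data.frame(token = token, position = pos, kind = kind, derived = derived,
             ins_index = idx, back = back, stringsAsFactors = FALSE)
}

#' Format variants back to canonical Phylotree tokens
#'
#' Inverse of [parse_variant()]: `format_variant(parse_variant(x)) == x` for
#' canonical tokens.
#'
#' @param v data.frame as returned by [parse_variant()].
#' @return character vector of canonical tokens.
#' @export
format_variant <- function(v) {
  stopifnot(is.data.frame(v))
  bang <- ifelse(v$back, "!", "")
  out <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    out[i] <- switch(v$kind[i],
      transition   = paste0(v$position[i], bang[i]),
      transversion = paste0(v$position[i], v$derived[i], bang[i]),
      insertion    = paste0(v$position[i], ".", v$ins_index[i], v$derived[i], bang[i]),
      deletion     = paste0(v$position[i], "d", bang[i]),
      stop("unknown variant kind: ", v$kind[i]))
  }
  out
}

## Canonicalise a vector of tokens (expands range deletions, normalises case).
canonical_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character())
  parse_variant(tokens)$token
}

## 1-based positions of tokens (anchor position for insertions).
variant_positions <- function(tokens) {
  if (length(tokens) == 0L) return(integer())
  parse_variant(tokens)$position
}

## Cancellation/overwrite key: substitutions share a slot per position,
## insertions are keyed by (anchor, ordinal), deletions by position.
variant_keys <- function(tokens) {
  if (length(tokens) == 0L) return(character())
  v <- parse_variant(tokens)
  cls <- ifelse(v$kind %in% c("transition", "transversion"), "s",
                ifelse(v$kind == "insertion", paste0("i", v$ins_index), "d"))
  paste0(v$position, cls)
}

.TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

is_purine <- function(b) b %in% c("A", "G")
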