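#' Load the packaged reference sequence
#'
#' Returns the packaged synthetic stand-in for the rCRS coordinate frame
#' (16,569 bp; position 3107 is the historical placeholder 'N'). The file is
#' a deterministic synthetic sequence carrying the structural features the
#' coordinate conventions rely on, not the NC_012920.1 sequence itself; any
#' single-record FASTA can be substituted via \code{path}.
#'
#' @param path optional path to a single-record reference FASTA.
#' @return upper-case character string of the reference sequence.
#' @export
load_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rCRS_synthetic.fasta",
                        package = "haplogrouper", mustWork = TRUE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("reference FASTA must contain exactly one record: ", path)
  toupper(as.character(ss[[1L]]))
}

## Control region of the rCRS frame: 16024..16569 wrapping to 1..576.
CR_RANGES <- rbind(c(16024L, 16569L), c(1L, 576L))

in_control_region <- function(pos) {
  (pos >= 16024L & pos <= 16569L) | (pos >= 1L & pos <= 576L)
}
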