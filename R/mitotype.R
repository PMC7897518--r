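# Mitotype data model: rCRS-relative variant lists in forensic (EMPOP-style)
# nomenclature, with IUPAC mixed-base support and circular-genome ordering.

IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an observed base character to the set of bases it denotes
#'
#' @param obs single character: a base, an IUPAC ambiguity code, or `"-"`
#'   (deletion).
#' @return Character vector of plain bases (length >= 2 for ambiguity
#'   codes); `"-"` expands to itself.
#' @export
iupac_expand <- function(obs) {
  if (obs == "-") return("-")
  out <- IUPAC_BASES[[obs]]
  if (is.null(out)) stop("not a base or IUPAC code: ", obs)
  out
}

#' IUPAC code covering a set of bases
#'
#' @param bases character vector of plain bases (A/C/G/T).
#' @return The single character whose IUPAC expansion equals the set.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(IUPAC_BASES))
    if (identical(sort(IUPAC_BASES[[code]]), bases)) return(code)
  stop("no IUPAC code for base set: ", paste(bases, collapse = ","))
}

is_ambiguous_obs <- function(obs) {
  vapply(obs, function(o) o != "-" && length(IUPAC_BASES[[o]]) >= 2, TRUE,
         USE.NAMES = FALSE)
}

variant_kind <- function(ins, obs) {
  ifelse(ins > 0L, "insertion", ifelse(obs == "-", "deletion", "substitution"))
}

empty_variant_frame <- function() {
  data.frame(pos = integer(), ins = integer(), obs = character(),
             kind = character(), stringsAsFactors = FALSE)
}

#' Construct a mitotype
#'
#' A mitotype is a set of rCRS-relative variant records over one or more
#' (possibly origin-spanning) covered intervals. Variants are stored in
#' canonical circular order: control-region mitotypes start at the lowest
#' covered position of the 16024-16569 arc and wrap through the origin
#' (the conventional "16179 ... 72 73 ..." listing order); full-genome
#' mitotypes are in plain numeric order.
#'
#' @param variants data frame with columns `pos` (1-based rCRS position),
#'   `ins` (0 for substitutions/deletions, k for the k-th inserted base
#'   after `pos`), `obs` (observed base, IUPAC code, or `"-"`).
#' @param range covered range: a [circular_interval()] or list of them
#'   (default the control region).
#' @param label free-text sample or haplotype name.
#' @return Object of class `mitotype`.
#' @export
mitotype <- function(variants = empty_variant_frame(),
                     range = control_region(), label = "") {
  range <- as_interval_list(range)
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(v) == 0) v <- empty_variant_frame()
  stopifnot(all(c("pos", "ins", "obs") %in% names(v)))
  v$pos <- as.integer(v$pos); v$ins <- as.integer(v$ins)
  v$obs <- toupper(as.character(v$obs))
  L <- range[[1]]$L
  bad <- is.na(v$pos) | v$pos < 1L | v$pos > L
  if (any(bad)) stop("variant position out of 1..", L, ": ", v$pos[bad][1])
  if (any(is.na(v$ins) | v$ins < 0L)) stop("insertion index must be >= 0")
  ok_obs <- v$obs %in% c(names(IUPAC_BASES), "-")
  if (!all(ok_obs)) stop("invalid observed base: ", v$obs[!ok_obs][1])
  if (any(v$ins > 0L & v$obs == "-"))
    stop("an inserted base cannot be a deletion")
  v$kind <- variant_kind(v$ins, v$obs)
  if (anyDuplicated(v[c("pos", "ins")]))
    stop("duplicate variant record at position ",
         v$pos[duplicated(v[c("pos", "ins")])][1])
  if (!all(in_covered_range(v$pos, range)))
    stop("variant position outside covered range: ",
         v$pos[!in_covered_range(v$pos, range)][1])
  m <- structure(list(variants = v, range = range, label = label),
                 class = "mitotype")
  m$variants <- v[order(canonical_key(m, v$pos), v$ins), , drop = FALSE]
  rownames(m$variants) <- NULL
  m
}

# Circular ordering key. Origin is the start of the wrapping covered
# interval when one exists (16024 for the control region), else 1.
canonical_key <- function(m, pos) {
  L <- m$range[[1]]$L
  wraps <- vapply(m$range, function(iv) iv$start > iv$end, TRUE)
  origin <- if (any(wraps)) min(vapply(m$range[wraps], `[[`, 1L, "start")) else 1L
  (pos - origin) %% L
}

#' @export
print.mitotype <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" '", x$label, "'") else ""
  cat(sprintf("<mitotype%s: %d variants, %d ambiguous>\n", lab,
              nrow(x$variants), sum(is_ambiguous_obs(x$variants$obs))))
  if (nrow(x$variants)) cat(" ", serialize_mitotype(x), "\n")
  invisible(x)
}

#' Parse a mitotype string
#'
#' Accepts whitespace-separated EMPOP-style tokens: substitutions
#' (`263G`), insertions (`315.1C`), deletions (`249DEL` or `249-`), and
#' IUPAC mixed-base calls (`16179Y`, `73R`).
#'
#' @param text the mitotype string; `""` yields an rCRS-identical
#'   mitotype over the covered range.
#' @param range covered range (default the control region 16024-576).
#' @param label sample or haplotype name.
#' @return A [mitotype()].
#' @examples
#' parse_mitotype("263G 315.1C")
#' parse_mitotype("16298C 72C 200G 263G 315.1C", label = "hg HV0")
#' @export
parse_mitotype <- function(text, range = control_region(), label = "") {
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(mitotype(range = range, label = label))
  rx <- "^([0-9]+)(?:\\.([0-9]+))?([ACGTRYSWKMBDHVNacgtryswkmbdhvn]|-|DEL|del)$"
  mm <- regmatches(tokens, regexec(rx, tokens))
  bad <- lengths(mm) == 0
  if (any(bad)) stop("malformed mitotype token: '", tokens[bad][1], "'")
  pos <- vapply(mm, function(g) as.integer(g[2]), 1L)
  ins <- vapply(mm, function(g) if (nzchar(g[3])) as.integer(g[3]) else 0L, 1L)
  obs <- vapply(mm, function(g) {
    o <- toupper(g[4]); if (o == "DEL") "-" else o
  }, "")
  dup <- duplicated(data.frame(pos, ins))
  if (any(dup)) stop("duplicate variant token: '", tokens[dup][1], "'")
  out_of_range <- !in_covered_range(pos, as_interval_list(range))
  if (any(out_of_range))
    stop("position outside covered range in token: '", tokens[out_of_range][1], "'")
  mitotype(data.frame(pos = pos, ins = ins, obs = obs,
                      stringsAsFactors = FALSE), range, label)
}

#' Serialize a mitotype to its canonical string
#'
#' Inverse of [parse_mitotype()]; deletions are written as `<pos>DEL`.
#'
#' @param m a [mitotype()].
#' @return Single character string; `""` for an empty mitotype.
#' @export
serialize_mitotype <- function(m) {
  stopifnot(inherits(m, "mitotype"))
  v <- m$variants
  if (!nrow(v)) return("")
  obs <- ifelse(v$obs == "-", "DEL", v$obs)
  tok <- paste0(v$pos, ifelse(v$ins > 0L, paste0(".", v$ins), ""), obs)
  paste(tok, collapse = " ")
}

#' Ambiguous (IUPAC mixed-base) variants of a mitotype
#'
#' @param m a [mitotype()].
#' @return Data frame of the ambiguous variant records, canonical order.
#' @export
ambiguous_variants <- function(m) {
  stopifnot(inherits(m, "mitotype"))
  m$variants[is_ambiguous_obs(m$variants$obs), , drop = FALSE]
}

#' Is a mitotype free of mixed-base calls?
#' @param m a [mitotype()].
#' @return `TRUE` if no variant carries an IUPAC ambiguity code.
#' @export
is_unambiguous <- function(m) nrow(ambiguous_variants(m)) == 0

# Allele lookup table keyed by (pos, ins): observed allele per site for
# the union of two mitotypes, with absence meaning the reference allele.
site_alleles <- function(a, b) {
  keys <- unique(rbind(a$variants[c("pos", "ins")], b$variants[c("pos", "ins")]))
  get_obs <- function(m, pos, ins) {
    hit <- m$variants$pos == pos & m$variants$ins == ins
    if (any(hit)) m$variants$obs[hit][1] else NA_character_
  }
  keys$obs_a <- mapply(get_obs, pos = keys$pos, ins = keys$ins,
                       MoreArgs = list(m = a))
  keys$obs_b <- mapply(get_obs, pos = keys$pos, ins = keys$ins,
                       MoreArgs = list(m = b))
  keys
}

#' Positions at which two mitotypes differ
#'
#' Symmetric: a site differs when the two mitotypes imply different
#' alleles there, counting absence of a record as the reference allele.
#'
#' @param a,b mitotypes over the same covered range.
#' @return Data frame with columns `pos`, `ins` in canonical order;
#'   zero rows iff the mitotypes are equal.
#' @export
diff_positions <- function(a, b) {
  stopifnot(inherits(a, "mitotype"), inherits(b, "mitotype"))
  if (!range_identical(a$range, b$range))
    stop("mitotypes cover different ranges")
  s <- site_alleles(a, b)
  differs <- is.na(s$obs_a) != is.na(s$obs_b) |
    (!is.na(s$obs_a) & !is.na(s$obs_b) & s$obs_a != s$obs_b)
  out <- s[differs, c("pos", "ins"), drop = FALSE]
  out <- out[order(canonical_key(a, out$pos), out$ins), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mix two haplotypes into the mitotype a mixed Sanger trace would show
#'
#' The in-silico inverse of two-source deconvolution: where the
#' haplotypes agree the shared variant is kept; where they differ by a
#' substitution the IUPAC code covering both alleles is emitted, using
#' the reference base where one haplotype carries no variant. An
#' insertion present in only one haplotype is carried through
#' unambiguously (Sanger nomenclature cannot IUPAC-encode an indel
#' mixture); a deletion conflicting with a base is an error.
#'
#' @param a,b mitotypes over the same covered range.
#' @param reference reference sequence (see [mt_reference()]).
#' @return A [mitotype()], ambiguous wherever `a` and `b` differ.
#' @examples
#' hv0 <- parse_mitotype("16298C 72C 200G 263G 315.1C")
#' u4  <- parse_mitotype("16179T 16356C 16512C 16519C 73G 189G 195C 263G 315.1C 499A")
#' serialize_mitotype(mix_mitotypes(hv0, u4))
#' @export
mix_mitotypes <- function(a, b, reference = mt_reference()) {
  stopifnot(inherits(a, "mitotype"), inherits(b, "mitotype"))
  if (!range_identical(a$range, b$range))
    stop("mitotypes cover different ranges")
  s <- site_alleles(a, b)
  rows <- lapply(seq_len(nrow(s)), function(i) {
    pos <- s$pos[i]; ins <- s$ins[i]
    oa <- s$obs_a[i]; ob <- s$obs_b[i]
    if (ins > 0L) {
      # one-sided insertions carried through; two-sided must agree or mix
      base_set <- unique(unlist(lapply(c(oa, ob)[!is.na(c(oa, ob))],
                                       iupac_expand)))
      if ("-" %in% base_set) stop("cannot mix a deletion with an insertion")
      return(data.frame(pos = pos, ins = ins, obs = iupac_code(base_set)))
    }
    ref <- mt_ref_base(pos, reference)
    ea <- if (is.na(oa)) ref else iupac_expand(oa)
    eb <- if (is.na(ob)) ref else iupac_expand(ob)
    if ("-" %in% c(ea, eb) && !identical(ea, eb))
      stop("cannot IUPAC-encode a deletion mixed with a base at ", pos)
    set <- unique(c(ea, eb))
    if (identical(set, "-")) return(data.frame(pos = pos, ins = ins, obs = "-"))
    code <- iupac_code(set)
    if (code == ref) return(NULL)  # both resolve to reference: no record
    data.frame(pos = pos, ins = ins, obs = code)
  })
  v <- do.call(rbind, rows)
  if (is.null(v)) v <- empty_variant_frame()
  mitotype(v, a$range, label = trimws(paste(a$label, b$label, sep = " + ")))
}

#' Apply a mitotype to the reference to obtain its sequence
#'
#' Emits the haplotype sequence over the covered range in circular order.
#'
#' @param m an unambiguous [mitotype()] (set `allow_ambiguous = TRUE` to
#'   emit IUPAC characters instead of erroring).
#' @param reference reference sequence (see [mt_reference()]).
#' @param allow_ambiguous emit IUPAC codes for mixed-base calls.
#' @return Single character string of length
#'   covered length + insertions - deletions.
#' @export
apply_to_reference <- function(m, reference = mt_reference(),
                               allow_ambiguous = FALSE) {
  stopifnot(inherits(m, "mitotype"))
  if (!allow_ambiguous && !is_unambiguous(m))
    stop("mitotype contains mixed-base calls; deconvolve first ",
         "or set allow_ambiguous = TRUE")
  v <- m$variants
  out <- character(0)
  for (iv in m$range) {
    for (pos in circular_positions(iv)) {
      here <- v[v$pos == pos, , drop = FALSE]
      sub <- here[here$ins == 0L, , drop = FALSE]
      base <- if (nrow(sub)) sub$obs[1] else reference[pos]
      if (base != "-") out <- c(out, base)
      ins <- here[here$ins > 0L, , drop = FALSE]
      if (nrow(ins)) out <- c(out, ins$obs[order(ins$ins)])
    }
  }
  paste(out, collapse = "")
}

#' Equality of two mitotypes
#' @param a,b mitotypes.
#' @return `TRUE` when ranges and variant records coincide.
#' @export
mitotype_equal <- function(a, b) {
  range_identical(a$range, b$range) && nrow(diff_positions(a, b)) == 0
}
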