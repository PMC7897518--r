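# Haplogroup motif tables and plausibility scoring.
#
# A motif table is a tiny rooted fragment of the mtDNA phylogeny: each
# haplogroup names its parent and its defining variants; the cumulative
# motif of a haplogroup is the union of defining variants along the path
# from the root. The packaged "family-study" table carries the two clades
# relevant to the bundled family dataset (HV0 with nested V, and U4c1),
# transcribed from the study's printed component haplotypes; users load
# richer tables from TSV.

#' Load a haplogroup motif table from TSV
#'
#' Expects tab-separated columns `haplogroup`, `parent`, `variants`
#' (space-separated EMPOP-style tokens; empty for the root). Parent
#' links must be acyclic and resolve within the table (use `root` with
#' no parent for the top).
#'
#' @param path TSV file path.
#' @return Object of class `motif_table`.
#' @export
load_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("haplogroup", "parent", "variants") %in% names(df)))
    stop("motif table needs columns haplogroup, parent, variants")
  motif_table(df)
}

#' Construct a motif table from a data frame
#'
#' @param entries data frame with columns `haplogroup`, `parent`
#'   (empty/NA for the root), `variants` (space-separated tokens).
#' @return Object of class `motif_table`.
#' @export
motif_table <- function(entries) {
  df <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(structure(list(entries = df), class = "motif_table"))
  df$parent[is.na(df$parent)] <- ""
  if (anyDuplicated(df$haplogroup))
    stop("duplicate haplogroup name in motif table")
  # validate variant tokens and parent acyclicity
  parsed <- lapply(seq_len(nrow(df)), function(i) {
    parse_mitotype(df$variants[i], range = full_genome(),
                   label = df$haplogroup[i])
  })
  names(parsed) <- df$haplogroup
  depth <- integer(nrow(df)); names(depth) <- df$haplogroup
  for (hg in df$haplogroup) {
    seen <- character(0); cur <- hg; d <- 0L
    while (nzchar(p <- df$parent[df$haplogroup == cur])) {
      if (p %in% seen || p == cur)
        stop("cyclic parent link at haplogroup ", cur)
      if (!p %in% df$haplogroup)
        stop("unknown parent haplogroup: ", p)
      seen <- c(seen, cur); cur <- p; d <- d + 1L
    }
    depth[hg] <- d
  }
  t <- structure(list(entries = df, motifs = parsed, depth = depth),
                 class = "motif_table")
  # precompute cumulative motifs once; scoring is called in the inner
  # loop of the deconvolution search
  t$cum <- lapply(stats::setNames(df$haplogroup, df$haplogroup), function(hg)
    cumulative_motif_uncached(t, hg)$variants[c("pos", "ins", "obs")])
  t
}

#' @export
print.motif_table <- function(x, ...) {
  cat(sprintf("<motif table: %d haplogroups>\n", nrow(x$entries)))
  invisible(x)
}

#' Cumulative motif of a haplogroup
#'
#' Union of the defining variants along the root-to-haplogroup path.
#'
#' @param t a [motif_table()].
#' @param hg haplogroup name.
#' @return A full-genome [mitotype()] holding the cumulative motif.
#' @export
cumulative_motif <- function(t, hg) {
  stopifnot(inherits(t, "motif_table"))
  if (!hg %in% t$entries$haplogroup) stop("unknown haplogroup: ", hg)
  if (!is.null(t$cum[[hg]]))
    return(mitotype(t$cum[[hg]], range = full_genome(), label = hg))
  cumulative_motif_uncached(t, hg)
}

cumulative_motif_uncached <- function(t, hg) {
  v <- empty_variant_frame()
  cur <- hg
  repeat {
    v <- rbind(v, t$motifs[[cur]]$variants[c("pos", "ins", "obs")])
    p <- t$entries$parent[t$entries$haplogroup == cur]
    if (!nzchar(p)) break
    cur <- p
  }
  v <- v[!duplicated(v[c("pos", "ins")]), , drop = FALSE]
  mitotype(v, range = full_genome(), label = hg)
}

#' The packaged family-study motif table
#'
#' Covers the haplogroups relevant to the bundled family dataset: HV0
#' and its nested clade V (coding-region defining variant 4580A), and
#' U4c1, plus the root. HV0 and U4c1 motifs are the study's deconvolved
#' component haplotypes minus the universal hotspots 263G and 315.1C.
#'
#' @return A [motif_table()].
#' @export
family_motif_table <- function() {
  path <- system.file("extdata", "motifs_family_study.tsv",
                      package = "meganumt", mustWork = TRUE)
  load_motif_table(path)
}

#' Default hypervariable hotspot mask
#'
#' Positions present in virtually every non-rCRS mitotype (the 263 and
#' 309/310/315 poly-C region) and therefore uninformative for clade
#' assignment. 16519 is deliberately not masked: it is a defining
#' variant of the packaged U4c1 motif.
#'
#' @return Integer vector of masked rCRS positions.
#' @export
default_hotspot_mask <- function() c(263L, 309L, 310L, 315L)

#' Score a haplotype against every haplogroup of a motif table
#'
#' For each haplogroup, the cumulative motif is restricted to the
#' haplotype's covered range and the hotspot mask is removed from both
#' motif and observation; then with `matches` motif variants observed,
#' `missing` motif variants absent and `private` observed variants not
#' in the motif, the plausibility score is
#' `matches / (expected + 0.5 * private)`. A haplogroup with an empty
#' in-range motif scores 1 for a (masked-)empty haplotype and 0
#' otherwise.
#'
#' @param m an unambiguous [mitotype()] (mixed-base calls must be
#'   deconvolved first).
#' @param t a [motif_table()].
#' @param hotspot_mask integer positions excluded from scoring
#'   (default [default_hotspot_mask()]).
#' @return Data frame ranked by score (desc), then clade depth (desc),
#'   then name, with columns `haplogroup`, `score`, `matches`,
#'   `missing`, `private`, `depth`.
#' @export
assign_haplogroup <- function(m, t, hotspot_mask = default_hotspot_mask()) {
  stopifnot(inherits(m, "mitotype"), inherits(t, "motif_table"))
  if (!is_unambiguous(m))
    stop("mitotype contains mixed-base calls; run deconvolve_two_source() ",
         "before haplogroup assignment")
  if (nrow(t$entries) == 0)
    return(data.frame(haplogroup = character(), score = numeric(),
                      matches = integer(), missing = integer(),
                      private = integer(), depth = integer()))
  obs <- m$variants[!m$variants$pos %in% hotspot_mask, , drop = FALSE]
  obs_key <- paste(obs$pos, obs$ins, obs$obs)
  motif_keys <- masked_motif_keys(t, m$range, hotspot_mask)
  rows <- lapply(t$entries$haplogroup, function(hg) {
    mo_key <- motif_keys[[hg]]
    matches <- sum(mo_key %in% obs_key)
    missing <- sum(!mo_key %in% obs_key)
    private <- sum(!obs_key %in% mo_key)
    expected <- length(mo_key)
    score <- if (expected == 0) as.numeric(private == 0)
             else matches / (expected + 0.5 * private)
    data.frame(haplogroup = hg, score = score, matches = matches,
               missing = missing, private = private,
               depth = unname(t$depth[hg]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, -out$depth, out$haplogroup), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Cumulative motif keys per haplogroup, restricted to a covered range and
# stripped of hotspot positions.
masked_motif_keys <- function(t, range, hotspot_mask) {
  lapply(t$cum, function(mo) {
    mo <- mo[in_covered_range(mo$pos, range) & !mo$pos %in% hotspot_mask, ,
             drop = FALSE]
    paste(mo$pos, mo$ins, mo$obs)
  })
}
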