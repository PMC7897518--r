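# Two-source deconvolution of mixed mitotypes.
#
# A mixed Sanger call (IUPAC codes at several sites) is assumed to arise
# from exactly two contributing haplotypes. Every allele assignment over
# the ambiguous sites is enumerated (swap symmetry collapsed by fixing
# the first site), each candidate pair is scored for phylogenetic
# plausibility against a motif table, and the best-scoring pair wins
# with a deterministic tie-break.

#' Mixed-base positions of a mitotype
#'
#' @param m a [mitotype()].
#' @return Data frame of ambiguous variant records in canonical order
#'   (columns `pos`, `ins`, `obs`, `kind`).
#' @export
detect_mixed_positions <- function(m) ambiguous_variants(m)

#' Deconvolve a mixed mitotype into two haplotypes
#'
#' Enumerates all `2^(k-1)` assignments of the two alleles at each of
#' the `k` ambiguous sites (the first site's alphabetically first
#' allele is fixed to component A to collapse the A/B swap symmetry).
#' Where an assigned allele equals the reference base the component
#' simply carries no record there: reference alleles are absence of
#' variant. Each candidate pair is scored by the sum of the two top
#' [assign_haplogroup()] scores; ties break toward the lexicographically
#' smaller serialization of component A.
#'
#' @param m a [mitotype()] whose ambiguity codes each denote exactly two
#'   bases (three-or-more-allele codes are rejected: such a mixture is
#'   not a two-source problem).
#' @param t a [motif_table()] supplying phylogenetic plausibility.
#' @param hotspot_mask positions excluded from scoring (default
#'   [default_hotspot_mask()]).
#' @param max_ambiguous cap on `k` (default 20; the search is `2^(k-1)`).
#' @param reference reference sequence for reference-allele dropping.
#' @return List of class `deconvolution_result` with `component_a`,
#'   `component_b`, `hg_a`, `hg_b` (top-ranked score rows), `pair_score`,
#'   `n_ambiguous`, `n_candidates_evaluated`.
#' @examples
#' mixed <- parse_mitotype(
#'   "16179Y 16298Y 16356Y 16512Y 16519Y 72Y 73R 189R 195Y 200R 263G 315.1C 499R")
#' res <- deconvolve_two_source(mixed, family_motif_table())
#' serialize_mitotype(res$component_a)
#' serialize_mitotype(res$component_b)
#' @export
deconvolve_two_source <- function(m, t, hotspot_mask = default_hotspot_mask(),
                                  max_ambiguous = 20L,
                                  reference = mt_reference()) {
  stopifnot(inherits(m, "mitotype"), inherits(t, "motif_table"))
  if (nrow(t$entries) == 0) stop("empty motif table")
  amb <- ambiguous_variants(m)
  k <- nrow(amb)
  if (k > max_ambiguous)
    stop("mixture has ", k, " ambiguous sites, above the cap of ",
         max_ambiguous)
  allele_sets <- lapply(amb$obs, iupac_expand)
  if (any(lengths(allele_sets) > 2))
    stop("IUPAC code denoting three or more bases at position ",
         amb$pos[lengths(allele_sets) > 2][1],
         ": not a two-source mixture")
  shared <- m$variants[!is_ambiguous_obs(m$variants$obs), , drop = FALSE]

  build_component <- function(alleles, label) {
    v <- shared[c("pos", "ins", "obs")]
    if (k > 0) {
      keep <- alleles != mt_ref_base(amb$pos, reference)  # ref = no record
      if (any(keep))
        v <- rbind(v, data.frame(pos = amb$pos[keep], ins = amb$ins[keep],
                                 obs = alleles[keep]))
    }
    mitotype(v, m$range, label = label)
  }

  if (k == 0) {
    hg <- assign_haplogroup(m, t, hotspot_mask)
    comp <- build_component(character(0), m$label)
    return(structure(list(component_a = comp, component_b = comp,
                          hg_a = hg[1, ], hg_b = hg[1, ],
                          pair_score = 2 * hg$score[1], n_ambiguous = 0L,
                          n_candidates_evaluated = 1L),
                     class = "deconvolution_result"))
  }

  # The search is vectorized: for every haplogroup, each ambiguous site
  # contributes a fixed (match, private) increment per allele choice, so
  # all 2^(k-1) candidates are scored with matrix products rather than
  # by building mitotype objects.
  motif_keys <- masked_motif_keys(t, m$range, hotspot_mask)
  hgs <- names(motif_keys)
  ref_amb <- mt_ref_base(amb$pos, reference)
  allele1 <- vapply(allele_sets, `[`, "", 1L)
  allele2 <- vapply(allele_sets, `[`, "", 2L)

  masked_shared <- !shared$pos %in% hotspot_mask
  shared_key <- paste(shared$pos, shared$ins, shared$obs)[masked_shared]
  live_amb <- !amb$pos %in% hotspot_mask      # masked sites never score
  key1 <- paste(amb$pos, amb$ins, allele1)
  key2 <- paste(amb$pos, amb$ins, allele2)

  H <- length(hgs)
  expected <- vapply(motif_keys, length, 1L)
  base_m <- vapply(motif_keys, function(kk) sum(shared_key %in% kk), 1L)
  base_p <- vapply(motif_keys, function(kk) sum(!shared_key %in% kk), 1L)
  # per-site (match, private) increments: rows = sites, cols = haplogroups
  nonref1 <- allele1 != ref_amb & live_amb
  nonref2 <- allele2 != ref_amb & live_amb
  hit1 <- vapply(motif_keys, function(kk) key1 %in% kk, logical(k))
  hit2 <- vapply(motif_keys, function(kk) key2 %in% kk, logical(k))
  hit1 <- matrix(hit1, nrow = k); hit2 <- matrix(hit2, nrow = k)
  dm1 <- hit1 * nonref1; dp1 <- (!hit1) * nonref1   # k x H
  dm2 <- hit2 * nonref2; dp2 <- (!hit2) * nonref2

  n_cand <- as.integer(2^(k - 1))
  # candidate c (0-based) picks allele 1 for component A at site 1 and at
  # site j+1 iff bit j of c is 0 (swap symmetry collapsed at site 1)
  P <- matrix(1, nrow = n_cand, ncol = k)
  if (k > 1)
    for (j in 2:k)
      P[, j] <- 1 - bitwAnd(bitwShiftR(seq_len(n_cand) - 1L, j - 2L), 1L)

  score_matrix <- function(Psel) {
    mm <- sweep(Psel %*% dm1 + (1 - Psel) %*% dm2, 2, base_m, `+`)
    pp <- sweep(Psel %*% dp1 + (1 - Psel) %*% dp2, 2, base_p, `+`)
    sc <- mm / sweep(0.5 * pp, 2, expected, `+`)
    zero <- expected == 0
    if (any(zero)) sc[, zero] <- as.numeric(pp[, zero, drop = FALSE] == 0)
    sc
  }
  pair_scores <- apply(score_matrix(P), 1, max) +
                 apply(score_matrix(1 - P), 1, max)
  top <- max(pair_scores)
  tied <- which(pair_scores == top)
  if (length(tied) > 1) {
    # lexicographic tie-break on component A's serialization
    ser <- vapply(tied, function(i) {
      a <- ifelse(P[i, ] == 1, allele1, allele2)
      serialize_mitotype(build_component(a, ""))
    }, "")
    tied <- tied[order(ser)]
  }
  pick <- P[tied[1], ] == 1
  comp_a <- build_component(ifelse(pick, allele1, allele2), "component A")
  comp_b <- build_component(ifelse(pick, allele2, allele1), "component B")
  best <- list(component_a = comp_a, component_b = comp_b,
               hg_a = assign_haplogroup(comp_a, t, hotspot_mask)[1, ],
               hg_b = assign_haplogroup(comp_b, t, hotspot_mask)[1, ],
               pair_score = top,
               n_ambiguous = k,
               n_candidates_evaluated = n_cand)
  # invariant: remixing the components reproduces the input
  stopifnot(mitotype_equal(
    mix_mitotypes(best$component_a, best$component_b, reference), m))
  structure(best, class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("<two-source deconvolution>\n")
  cat(sprintf("  A [%s, score %.3f]: %s\n", x$hg_a$haplogroup, x$hg_a$score,
              serialize_mitotype(x$component_a)))
  cat(sprintf("  B [%s, score %.3f]: %s\n", x$hg_b$haplogroup, x$hg_b$score,
              serialize_mitotype(x$component_b)))
  cat(sprintf("  pair score %.3f over %d candidates (%d mixed sites)\n",
              x$pair_score, x$n_candidates_evaluated, x$n_ambiguous))
  invisible(x)
}

#' Mixture fraction from clone or single-cell counts
#'
#' Point estimate and exact (Clopper-Pearson) 95% confidence interval
#' for the minor-component fraction among sequenced clones or single
#' cells.
#'
#' @param n_minor count of minor-component observations.
#' @param n_total total observations (>= 1).
#' @param conf_level confidence level (default 0.95).
#' @return List of class `fraction_estimate`: `n_minor`, `n_total`,
#'   `point`, `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' estimate_fraction(35, 100)   # blood clones
#' estimate_fraction(0, 249)    # how much minor could 249 negatives hide?
#' @export
estimate_fraction <- function(n_minor, n_total, conf_level = 0.95) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_minor < 0 || n_minor > n_total)
    stop("n_minor must lie in 0..n_total")
  ci <- stats::binom.test(n_minor, n_total,
                          conf.level = conf_level)$conf.int
  structure(list(n_minor = as.integer(n_minor),
                 n_total = as.integer(n_total),
                 point = n_minor / n_total,
                 ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat(sprintf("%d/%d minor = %.3f [%.4f, %.4f] (%d%% exact binomial)\n",
              x$n_minor, x$n_total, x$point, x$ci_low, x$ci_high,
              round(100 * x$conf_level)))
  invisible(x)
}

#' Simulate the direct Sanger call for a two-haplotype template mixture
#'
#' Sanger sequencing shows the minor component as mixed-base positions
#' only above its limit of detection (around a 20% minor fraction);
#' below it only the major haplotype is called.
#'
#' @param major,minor unambiguous mitotypes over the same range.
#' @param minor_fraction fraction of templates carrying the minor
#'   haplotype, in `[0, 1]`.
#' @param lod detection limit applied as `minor_fraction >= lod`
#'   (default 0.20).
#' @param reference reference sequence for IUPAC mixing.
#' @return A [mitotype()]: the IUPAC mixture when detectable, otherwise
#'   the major haplotype.
#' @export
sanger_call <- function(major, minor, minor_fraction, lod = 0.20,
                        reference = mt_reference()) {
  if (minor_fraction < 0 || minor_fraction > 1)
    stop("minor_fraction must lie in [0, 1]")
  if (minor_fraction >= lod) mix_mitotypes(major, minor, reference)
  else major
}
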