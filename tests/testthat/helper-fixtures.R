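# Shared fixtures: the family-study haplotypes, motif table, and helpers
# for building random mitotypes over positions with known reference bases.

hap <- family_haplotypes()
motifs <- family_motif_table()

MIXED_STRING <- paste(
  "16179Y 16298Y 16356Y 16512Y 16519Y 72Y 73R 189R 195Y 200R",
  "263G 315.1C 499R")
HV0_STRING <- "16298C 72C 200G 263G 315.1C"
U4C1_STRING <- "16179T 16356C 16512C 16519C 73G 189G 195C 263G 315.1C 499A"

# positions with documented reference alleles, available for random
# private variants (excludes positions used by the packaged motifs)
FREE_ANCHOR_POSITIONS <- c(146L, 150L, 152L, 194L, 198L, 204L, 207L,
                           16093L, 16224L, 16256L, 16270L, 16311L, 16362L)

random_private_variants <- function(n_max = 2L) {
  k <- sample(0:n_max, 1)
  if (k == 0) return(NULL)
  pos <- sample(FREE_ANCHOR_POSITIONS, k)
  obs <- vapply(pos, function(p)
    sample(setdiff(c("A", "C", "G", "T"), mt_ref_base(p)), 1), "")
  data.frame(pos = pos, ins = 0L, obs = obs, stringsAsFactors = FALSE)
}

# a clade haplotype: cumulative motif restricted to the control region,
# plus the universal hotspots, plus optional private substitutions
clade_haplotype <- function(hg, private = NULL) {
  v <- cumulative_motif(motifs, hg)$variants
  v <- v[in_covered_range(v$pos, control_region()), c("pos", "ins", "obs")]
  v <- rbind(v, data.frame(pos = c(263L, 315L), ins = c(0L, 1L),
                           obs = c("G", "C")))
  if (!is.null(private)) v <- rbind(v, private)
  mitotype(v, control_region(), label = hg)
}

unordered_pair <- function(a, b) sort(c(serialize_mitotype(a),
                                        serialize_mitotype(b)))

# Independent brute-force deconvolver used as oracle: enumerates all 2^k
# allele assignments with no symmetry collapse and no caching.
is_ambiguous_obs_oracle <- function(obs)
  obs %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

brute_force_deconvolve <- function(m, t, hotspot_mask = default_hotspot_mask()) {
  amb <- ambiguous_variants(m)
  k <- nrow(amb)
  shared <- m$variants[!is_ambiguous_obs_oracle(m$variants$obs), , drop = FALSE]
  sets <- lapply(amb$obs, iupac_expand)
  build <- function(alleles) {
    v <- shared[c("pos", "ins", "obs")]
    keep <- alleles != mt_ref_base(amb$pos)
    if (any(keep))
      v <- rbind(v, data.frame(pos = amb$pos[keep], ins = amb$ins[keep],
                               obs = alleles[keep]))
    mitotype(v, m$range)
  }
  best <- NULL
  for (code in seq_len(2^k) - 1L) {
    bits <- as.integer(intToBits(code))[1:k]
    a <- build(mapply(function(s, b) s[b + 1L], sets, bits))
    b <- build(mapply(function(s, b) s[2L - b], sets, bits))
    sc <- assign_haplogroup(a, t, hotspot_mask)$score[1] +
          assign_haplogroup(b, t, hotspot_mask)$score[1]
    if (is.null(best) || sc > best$score)
      best <- list(score = sc, pair = unordered_pair(a, b))
  }
  best
}
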