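# The packaged family-study dataset: a transcription of the published
# multi-generation pedigree in which a tandem multi-copy mitogenome
# insertion (Mega-NUMT) on chromosome 14 segregates.

#' Control-region haplotypes of the packaged family study
#'
#' The reference individual's mixed blood call and its two deconvolved
#' components: the authentic matrilineal mtDNA (hg HV0, nested V) and
#' the nuclear-insert haplotype (hg U4c1).
#'
#' @return Named list of [mitotype()]s: `mixed`, `hv0`, `u4c1`.
#' @export
family_haplotypes <- function() {
  list(
    mixed = parse_mitotype(
      paste("16179Y 16298Y 16356Y 16512Y 16519Y 72Y 73R 189R 195Y 200R",
            "263G 315.1C 499R"),
      label = "IV.3 blood (mixed)"),
    hv0 = parse_mitotype("16298C 72C 200G 263G 315.1C", label = "hg HV0"),
    u4c1 = parse_mitotype(
      "16179T 16356C 16512C 16519C 73G 189G 195C 263G 315.1C 499A",
      label = "hg U4c1"))
}

#' Load the packaged family-study dataset
#'
#' Twenty pedigree members over five generations; eleven are maternally
#' related, eight of whom show the U/V mixed mitotype (the insertion
#' carriers). Observation records transcribe the study's tissue-contrast
#' experiments: 113 single thrombocytes and 55 of 56 hair shafts showing
#' only the mtDNA (V) haplotype, 249 bone-derived clones of founder I.2
#' without any minor component, mtDNA-depleted (rho-zero) fibroblasts of
#' III.4 yielding only the insert (U) haplotype, and per-tissue clone
#' counts for the reference individual IV.3 (35% minor in blood, 4% in
#' buccal cells). Records whose exact denominators were not published
#' are flagged `approximate`; mitotypes of married-in individuals are
#' synthetic placeholders (only mother-child equality matters for the
#' matriline check).
#'
#' @return List with `pedigree` ([pedigree()]), `observations`
#'   ([observation_table()], with an `approximate` flag column),
#'   `true_mitotypes` (named list of per-individual haplotypes),
#'   `mixed_call` (IV.3's mixed blood call), `haplotypes`
#'   ([family_haplotypes()]), `numt` (carrier metadata: chromosome
#'   label, reported per-method copy estimates).
#' @export
load_family_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "meganumt",
                                 mustWork = TRUE)
  ped <- read_pedigree(ext("family_pedigree.tsv"))
  obs_df <- utils::read.delim(ext("family_observations.tsv"),
                              stringsAsFactors = FALSE)
  obs <- observation_table(obs_df)
  mito <- read_mitotype_table(ext("family_mitotypes.tsv"))
  hap <- family_haplotypes()
  list(pedigree = ped,
       observations = obs,
       true_mitotypes = mito,
       mixed_call = hap$mixed,
       haplotypes = hap,
       numt = list(chromosome = "chr14", band = "14q31",
                   copies_ddpcr = c(mean = 45.00, sd = 5.27, n = 20),
                   copies_qpcr = c(mean = 56.16, sd = 4.35, n = 76)))
}
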