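# Seeded generative model of family datasets with (or without) a
# segregating multi-copy mitogenome insertion.
#
# The generative assumptions mirror the biology the analysis exploits:
# the true mtDNA haplotype follows the strict matriline; a heterozygous
# nuclear-insert allele drops Mendelianly (probability 1/2 per child per
# carrier allele); each nucleated cell carries one nucleus but a
# tissue-dependent number of mtDNA copies, so the expected minor
# fraction in a tissue with m mtDNA copies per cell is
#   f = A * C / (A * C + m)
# with A the insert allele count and C the tandem copy number. Anucleate
# cells have f = 0 (hair shafts optionally contaminated with nuclear
# remnants); mtDNA-depleted cells show only the insert haplotype.

SPOUSE_HAPLOTYPE_TOKENS <- c(
  "146C", "150T", "152C", "194T", "198T", "204C", "207A",
  "16093C", "16224C", "16256T", "16270T", "16311C", "16362C")

#' Simulation configuration
#'
#' Defaults reproduce the regime of the packaged family study: tandem
#' copy number 45 on a heterozygous autosomal allele, per-tissue mtDNA
#' copies per cell of 84 (blood), 1080 (buccal) and 5000 (hair roots)
#' back-solved from the observed clone fractions (35% minor in blood,
#' 4% in buccal at C = 45), a 20% Sanger detection limit, 20,000-droplet
#' ddPCR wells, and a 1/56 per-shaft probability of nuclear remnants in
#' hair shafts.
#'
#' @param seed integer seed; mandatory, every stochastic output derives
#'   from it.
#' @param mode `"numt"` (minor component on a nuclear insert) or
#'   `"heteroplasmy"` (minor component in the mtDNA pool of the
#'   matriline, present at `heteroplasmy_fraction` in every tissue).
#' @param pedigree optional explicit [pedigree()]; otherwise one is
#'   generated from `generations` and `sibship`.
#' @param generations,sibship shape of the generated pedigree (founder
#'   couple, `sibship` children per couple, spouses married in).
#' @param tandem_copies tandem mitogenome copies C of the insert.
#' @param founder_allele_count insert alleles of the founder carrier
#'   (1 = heterozygous, 2 = homozygous, 0 = no insert).
#' @param chromosome_label metadata label for the insert location.
#' @param mt_haplotype,numt_haplotype mitotypes of the authentic mtDNA
#'   and of the insert (defaults: the packaged HV0 and U4c1 components).
#' @param mt_copies_per_cell named numeric: mean mtDNA copies per cell
#'   for `blood`, `buccal`, `hair_root`.
#' @param heteroplasmy_fraction minor fraction in heteroplasmy mode.
#' @param sanger_lod direct-Sanger detection limit (minor fraction).
#' @param counts named list of per-individual observation counts:
#'   `clones_blood`, `clones_buccal`, `single_cells`, `thrombocytes`,
#'   `hair_shafts`, `hair_roots`.
#' @param hair_remnant_prob per-shaft probability of nuclear remnants.
#' @param ddpcr list: `n_droplets`, `n_replicates` (wells per mtDNA
#'   target), `lambda_ref` (mean reference-target copies per droplet).
#' @param qpcr list: `efficiency` (carried for the amplification model;
#'   it cancels between sample and standard curve), `lognormal_cv`
#'   (net measurement noise), `n_replicates`.
#' @param rho0 list: `residual_mt_fraction` of surviving true mtDNA in
#'   depleted cells.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       mode = c("numt", "heteroplasmy"),
                       pedigree = NULL, generations = 3L, sibship = 3L,
                       tandem_copies = 45, founder_allele_count = 1L,
                       chromosome_label = "chr14",
                       mt_haplotype = family_haplotypes()$hv0,
                       numt_haplotype = family_haplotypes()$u4c1,
                       mt_copies_per_cell = c(blood = 84, buccal = 1080,
                                              hair_root = 5000),
                       heteroplasmy_fraction = 0.35,
                       sanger_lod = 0.20,
                       counts = list(),
                       hair_remnant_prob = 1 / 56,
                       ddpcr = list(), qpcr = list(), rho0 = list()) {
  if (missing(seed)) stop("seed is mandatory")
  mode <- match.arg(mode)
  counts <- utils::modifyList(
    list(clones_blood = 100L, clones_buccal = 100L, single_cells = 100L,
         thrombocytes = 113L, hair_shafts = 6L, hair_roots = 5L), counts)
  ddpcr <- utils::modifyList(
    list(n_droplets = 20000L, n_replicates = 5L, lambda_ref = 0.5), ddpcr)
  qpcr <- utils::modifyList(
    list(efficiency = 0.95, lognormal_cv = 0.15, n_replicates = 76L), qpcr)
  rho0 <- utils::modifyList(list(residual_mt_fraction = 0), rho0)
  stopifnot(tandem_copies >= 0, founder_allele_count %in% 0:2,
            sanger_lod >= 0, sanger_lod <= 1,
            heteroplasmy_fraction >= 0, heteroplasmy_fraction <= 1,
            hair_remnant_prob >= 0, hair_remnant_prob <= 1,
            all(unlist(counts) >= 0))
  structure(list(seed = as.integer(seed), mode = mode, pedigree = pedigree,
                 generations = as.integer(generations),
                 sibship = as.integer(sibship),
                 tandem_copies = tandem_copies,
                 founder_allele_count = as.integer(founder_allele_count),
                 chromosome_label = chromosome_label,
                 mt_haplotype = mt_haplotype,
                 numt_haplotype = numt_haplotype,
                 mt_copies_per_cell = mt_copies_per_cell,
                 heteroplasmy_fraction = heteroplasmy_fraction,
                 sanger_lod = sanger_lod, counts = counts,
                 hair_remnant_prob = hair_remnant_prob,
                 ddpcr = ddpcr, qpcr = qpcr, rho0 = rho0),
            class = "sim_config")
}

# Generate a pedigree skeleton: founder couple, `sibship` children per
# couple, each child below the last generation marries in a spouse.
generate_pedigree_skeleton <- function(generations, sibship) {
  rows <- list(
    data.frame(id = "1.1", father = "", mother = "", sex = "M",
               stringsAsFactors = FALSE),
    data.frame(id = "1.2", father = "", mother = "", sex = "F",
               stringsAsFactors = FALSE))
  couples <- data.frame(father = "1.1", mother = "1.2",
                        stringsAsFactors = FALSE)
  for (g in seq(2L, length.out = max(0L, generations - 1L))) {
    idx <- 0L
    next_couples <- list()
    for (ci in seq_len(nrow(couples))) {
      for (s in seq_len(sibship)) {
        idx <- idx + 1L
        sex <- if (idx %% 2L == 1L) "F" else "M"
        id <- sprintf("%d.%d", g, idx)
        rows[[length(rows) + 1L]] <-
          data.frame(id = id, father = couples$father[ci],
                     mother = couples$mother[ci], sex = sex,
                     stringsAsFactors = FALSE)
        if (g < generations) {
          sp <- paste0(id, "s")
          rows[[length(rows) + 1L]] <-
            data.frame(id = sp, father = "", mother = "",
                       sex = if (sex == "F") "M" else "F",
                       stringsAsFactors = FALSE)
          next_couples[[length(next_couples) + 1L]] <-
            data.frame(father = if (sex == "F") sp else id,
                       mother = if (sex == "F") id else sp,
                       stringsAsFactors = FALSE)
        }
      }
    }
    couples <- if (length(next_couples)) do.call(rbind, next_couples)
               else couples[0, ]
  }
  do.call(rbind, rows)
}

#' Simulate a family dataset
#'
#' Draws a pedigree with a segregating insert allele (or a matrilineal
#' heteroplasmy), per-tissue observations (direct Sanger calls, clone
#' and single-cell counts, thrombocytes, hair shafts and roots,
#' mtDNA-depleted fibroblasts of the proband), and ddPCR/qPCR
#' quantification wells for the proband's depleted-cell extract.
#' Identical seed and configuration give an identical dataset.
#'
#' @param cfg a [sim_config()].
#' @return List: `pedigree`, `true_mitotypes` (mtDNA haplotype per
#'   individual), `observations`, `quant` (`ddpcr` and `qpcr` data
#'   frames), `mixed_call` (the proband's direct blood call when mixed,
#'   else NULL), `truth_log` (latent variables: allele counts, copy
#'   number, per-tissue minor fractions, proband, mode, seed).
#' @export
simulate_pedigree_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  C <- cfg$tandem_copies

  skel <- if (!is.null(cfg$pedigree)) as.data.frame(cfg$pedigree)
          else generate_pedigree_skeleton(cfg$generations, cfg$sibship)

  n <- nrow(skel)
  ord <- skel$id
  mother_of <- stats::setNames(skel$mother, skel$id)
  father_of <- stats::setNames(skel$father, skel$id)

  # matriline membership and true mtDNA haplotype: strict maternal descent
  matriline_root <- "1.2"
  if (!matriline_root %in% skel$id) matriline_root <- skel$id[skel$sex == "F"][1]
  in_matriline <- stats::setNames(rep(FALSE, n), ord)
  spouse_i <- 0L
  mito <- stats::setNames(vector("list", n), ord)
  for (id in ord) {  # founders first in generation order by construction
    mo <- mother_of[[id]]
    if (id == matriline_root) {
      in_matriline[[id]] <- TRUE
      mito[[id]] <- cfg$mt_haplotype
    } else if (nzchar(mo)) {
      in_matriline[[id]] <- in_matriline[[mo]]
      mito[[id]] <- mito[[mo]]
    } else {
      spouse_i <- spouse_i + 1L
      tok <- SPOUSE_HAPLOTYPE_TOKENS[
        (spouse_i - 1L) %% length(SPOUSE_HAPLOTYPE_TOKENS) + 1L]
      mito[[id]] <- parse_mitotype(paste(tok, "263G 315.1C"),
                                   label = paste0("founder-", id))
    }
  }

  # Mendelian drop of the insert allele from the founder carrier
  alleles <- stats::setNames(rep(0L, n), ord)
  founder_carrier <- matriline_root
  if (cfg$mode == "numt") alleles[[founder_carrier]] <- cfg$founder_allele_count
  for (id in ord) {
    mo <- mother_of[[id]]; fa <- father_of[[id]]
    if (!nzchar(mo) && !nzchar(fa)) next
    inherited <- 0L
    for (par in c(mo, fa))
      if (nzchar(par))
        inherited <- inherited + stats::rbinom(1L, 1L, alleles[[par]] / 2)
    alleles[[id]] <- inherited
  }

  het_carrier <- if (cfg$mode == "heteroplasmy") in_matriline
                 else stats::setNames(rep(FALSE, n), ord)

  minor_fraction <- function(id, tissue) {
    if (cfg$mode == "heteroplasmy")
      return(if (het_carrier[[id]]) cfg$heteroplasmy_fraction else 0)
    A <- alleles[[id]]
    if (A == 0L) return(0)
    m <- cfg$mt_copies_per_cell[[tissue]]
    A * C / (A * C + m)
  }

  # proband: the youngest affected individual, falling back to the root
  affected <- if (cfg$mode == "numt") ord[alleles[ord] > 0L]
              else ord[het_carrier[ord]]
  proband <- if (length(affected)) affected[length(affected)]
             else matriline_root

  obs <- list()
  add_obs <- function(id, tissue, assay, call, n) {
    if (n > 0)
      obs[[length(obs) + 1L]] <<- c(id, tissue, assay, call, n)
  }
  bern_split <- function(id, tissue, assay, n, f, hit_call) {
    k <- stats::rbinom(1L, n, f)
    add_obs(id, tissue, assay, hit_call, k)
    add_obs(id, tissue, assay, "major_only", n - k)
  }

  for (id in ord) {
    for (tissue in c("blood", "buccal")) {
      f <- minor_fraction(id, tissue)
      add_obs(id, tissue, "direct_sanger",
              if (f >= cfg$sanger_lod) "mixed" else "major_only", 1L)
    }
    bern_split(id, "blood", "clone", cfg$counts$clones_blood,
               minor_fraction(id, "blood"), "minor_only")
    bern_split(id, "buccal", "clone", cfg$counts$clones_buccal,
               minor_fraction(id, "buccal"), "minor_only")
    bern_split(id, "pbmc", "single_cell", cfg$counts$single_cells,
               minor_fraction(id, "blood"), "mixed")
    # hair shafts: anucleate; in numt mode the minor appears only through
    # nuclear remnants, in heteroplasmy mode at the mtDNA fraction
    shaft_f <- if (cfg$mode == "heteroplasmy") {
      if (het_carrier[[id]]) cfg$heteroplasmy_fraction else 0
    } else if (alleles[[id]] > 0L) cfg$hair_remnant_prob else 0
    bern_split(id, "hair_shaft", "direct_sanger", cfg$counts$hair_shafts,
               shaft_f, "mixed")
    f_root <- minor_fraction(id, "hair_root")
    add_obs(id, "hair_root", "direct_sanger",
            if (f_root >= cfg$sanger_lod) "mixed" else "major_only",
            cfg$counts$hair_roots)
  }

  # thrombocytes and depleted fibroblasts for the proband
  thr_f <- if (cfg$mode == "heteroplasmy" && het_carrier[[proband]])
    cfg$heteroplasmy_fraction else 0
  bern_split(proband, "thrombocyte", "single_cell", cfg$counts$thrombocytes,
             thr_f, "mixed")
  if (cfg$mode == "numt" && alleles[[proband]] > 0L) {
    resid <- cfg$rho0$residual_mt_fraction
    add_obs(proband, "rho0_fibroblast", "direct_sanger",
            if (resid >= cfg$sanger_lod) "mixed" else "minor_only", 1L)
  } else {
    add_obs(proband, "rho0_fibroblast", "direct_sanger", "none", 1L)
  }
  add_obs("control", "blank", "direct_sanger", "none", 1L)

  obs_mat <- do.call(rbind, obs)
  observations <- observation_table(data.frame(
    individual_id = obs_mat[, 1], tissue = obs_mat[, 2],
    assay = obs_mat[, 3], call = obs_mat[, 4],
    n = as.integer(obs_mat[, 5]), stringsAsFactors = FALSE))

  # quantification of the proband's depleted-cell extract:
  # per diploid cell the reference target has 2 copies and the
  # mtDNA-like targets A*C (+ residual true mtDNA) copies
  A_pro <- alleles[[proband]]
  mt_per_cell <- if (cfg$mode == "numt")
    A_pro * C + cfg$rho0$residual_mt_fraction else 0
  quant <- NULL
  if (mt_per_cell > 0) {
    # the high-copy mtDNA-like aliquot is pre-diluted so both targets sit
    # in the informative occupancy range; the dilution factor is recorded
    # per well and folded back into the ratio estimate
    lam_ref <- cfg$ddpcr$lambda_ref
    dilution_mt <- max(1, mt_per_cell / 2)
    lam_mt <- lam_ref * (mt_per_cell / 2) / dilution_mt
    dd <- expand.grid(target = c("ND1", "KAV", "BATZ", "AND"),
                      replicate = seq_len(cfg$ddpcr$n_replicates),
                      stringsAsFactors = FALSE)
    nd <- cfg$ddpcr$n_droplets
    dd$n_droplets <- nd
    dd$dilution_mt <- dilution_mt
    dd$n_pos_mt <- stats::rbinom(nrow(dd), nd, 1 - exp(-lam_mt))
    dd$n_pos_ref <- stats::rbinom(nrow(dd), nd, 1 - exp(-lam_ref))
    # the qPCR assay is a single-tube multiplex: well-loading noise is
    # shared by both targets and cancels in the ratio; per-target
    # amplification noise enters the ratio as a mean-one lognormal factor
    cv <- cfg$qpcr$lognormal_cv
    sdlog <- sqrt(log(1 + cv^2))
    nq <- cfg$qpcr$n_replicates
    well <- stats::rlnorm(nq, -sdlog^2 / 2, sdlog)
    ratio_noise <- stats::rlnorm(nq, -sdlog^2 / 2, sdlog)
    qp <- data.frame(
      replicate = seq_len(nq),
      mt_quantity = mt_per_cell * well * ratio_noise,
      nuclear_quantity = 2 * well)
    quant <- list(ddpcr = dd, qpcr = qp)
  }

  blood_f_pro <- minor_fraction(proband, "blood")
  mixed_call <- if (cfg$mode == "numt" && blood_f_pro >= cfg$sanger_lod)
    sanger_call(cfg$mt_haplotype, cfg$numt_haplotype, blood_f_pro,
                cfg$sanger_lod) else NULL

  ped <- pedigree(data.frame(
    skel[c("id", "father", "mother", "sex")],
    status = ifelse(alleles[ord] > 0L, "carrier", "non_carrier"),
    stringsAsFactors = FALSE))

  list(pedigree = ped,
       true_mitotypes = mito,
       observations = observations,
       quant = quant,
       mixed_call = mixed_call,
       truth_log = list(
         mode = cfg$mode, seed = cfg$seed, proband = proband,
         alleles = alleles, tandem_copies = C,
         in_matriline = in_matriline,
         minor_fraction_blood = blood_f_pro,
         mt_per_cell_rho0 = mt_per_cell))
}

#' Replicate mtDNA-like:reference ratios from simulated ddPCR wells
#'
#' @param dd data frame with columns `n_droplets`, `n_pos_mt`,
#'   `n_pos_ref` (one row per duplex well) and optionally `dilution_mt`
#'   (pre-dilution factor of the mtDNA-like aliquot, default 1).
#' @return Numeric vector of per-well concentration ratios.
#' @export
ratios_from_ddpcr <- function(dd) {
  dil <- if (is.null(dd$dilution_mt)) rep(1, nrow(dd)) else dd$dilution_mt
  mapply(function(np_mt, np_ref, nd, d)
    d * ddpcr_lambda(np_mt, nd) / ddpcr_lambda(np_ref, nd),
    dd$n_pos_mt, dd$n_pos_ref, dd$n_droplets, dil)
}

#' Replicate mtDNA-like:reference ratios from simulated qPCR runs
#'
#' @param qp data frame with columns `mt_quantity`, `nuclear_quantity`.
#' @return Numeric vector of per-replicate quantity ratios.
#' @export
ratios_from_qpcr <- function(qp) qp$mt_quantity / qp$nuclear_quantity
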