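obs_row <- function(id, tissue, assay, call, n = 1L)
  data.frame(individual_id = id, tissue = tissue, assay = assay,
             call = call, n = n, stringsAsFactors = FALSE)

numt_like_raw <- function() rbind(
  obs_row("P", "blood", "direct_sanger", "mixed"),
  obs_row("P", "thrombocyte", "single_cell", "major_only", 50L),
  obs_row("P", "hair_shaft", "direct_sanger", "major_only", 12L),
  obs_row("P", "rho0_fibroblast", "direct_sanger", "minor_only"))
numt_like_obs <- function() observation_table(numt_like_raw())

test_that("observation tables validate and derive the cell class", {
  obs <- numt_like_obs()
  expect_equal(obs$cell_class,
               c("nucleated", "anucleate", "anucleate", "mtDNA_depleted"))
  expect_error(observation_table(obs_row("P", "muscle", "clone", "mixed")),
               "tissue")
  expect_error(observation_table(obs_row("P", "blood", "clone", "perhaps")),
               "call")
  expect_error(observation_table(obs_row("P", "blood", "pcr", "mixed")),
               "assay")
  bad_n <- obs_row("P", "blood", "clone", "mixed"); bad_n$n <- 0L
  expect_error(observation_table(bad_n), "positive")
})

test_that("tissue-contrast rules separate nuclear inserts from heteroplasmy", {
  expect_equal(classify_minor_source(numt_like_obs())$verdict, "NUCLEAR_NUMT")

  het <- observation_table(rbind(
    obs_row("P", "blood", "direct_sanger", "mixed"),
    obs_row("P", "thrombocyte", "single_cell", "mixed", 50L),
    obs_row("P", "hair_shaft", "direct_sanger", "mixed", 12L)))
  expect_equal(classify_minor_source(het)$verdict, "MT_HETEROPLASMY")

  no_anuc <- observation_table(obs_row("P", "blood", "direct_sanger", "mixed"))
  expect_equal(classify_minor_source(no_anuc)$verdict, "INCONCLUSIVE")

  contaminated <- observation_table(rbind(
    numt_like_raw(), obs_row("ctrl", "blank", "direct_sanger", "mixed")))
  expect_equal(classify_minor_source(contaminated)$verdict,
               "CONTAMINATION_SUSPECTED")

  only_anuc <- observation_table(
    obs_row("P", "thrombocyte", "single_cell", "major_only", 20L))
  expect_error(classify_minor_source(only_anuc), "nucleated")
})

test_that("the anucleate tolerance absorbs an isolated contaminated hair shaft", {
  one_shaft <- observation_table(rbind(
    obs_row("P", "blood", "direct_sanger", "mixed"),
    obs_row("P", "thrombocyte", "single_cell", "major_only", 113L),
    obs_row("P", "hair_shaft", "direct_sanger", "major_only", 55L),
    obs_row("P", "hair_shaft", "direct_sanger", "mixed", 1L)))
  expect_equal(classify_minor_source(one_shaft)$verdict, "NUCLEAR_NUMT")
  # but a depleted cell showing the major haplotype blocks the nuclear call
  blocked <- observation_table(rbind(
    as.data.frame(one_shaft)[names(one_shaft) != "cell_class"],
    obs_row("P", "rho0_fibroblast", "direct_sanger", "mixed")))
  expect_true(classify_minor_source(blocked)$verdict != "NUCLEAR_NUMT")
})

test_that("classification is invariant to observation order", {
  obs <- numt_like_obs()
  set.seed(3)
  for (i in 1:5) {
    shuffled <- observation_table(as.data.frame(obs)[sample(nrow(obs)), ])
    expect_equal(classify_minor_source(shuffled)$verdict,
                 classify_minor_source(obs)$verdict)
  }
})

make_ped <- function(...) pedigree(do.call(rbind, list(...)))
ped_row <- function(id, father = "", mother = "", sex = "F",
                    status = "unknown")
  data.frame(id = id, father = father, mother = mother, sex = sex,
             status = status, stringsAsFactors = FALSE)

test_that("pedigree validation catches malformed structures", {
  expect_error(make_ped(ped_row("A"), ped_row("A")), "duplicate")
  expect_error(make_ped(ped_row("kid", father = "ghost")), "not in pedigree")
  expect_error(make_ped(ped_row("mum", sex = "F"),
                        ped_row("kid", father = "mum")), "female")
  expect_error(make_ped(ped_row("A", status = "maybe")), "status")
})

test_that("a carrier child of two non-carrier parents is the only conflict source", {
  p <- make_ped(
    ped_row("F1", sex = "M", status = "non_carrier"),
    ped_row("M1", sex = "F", status = "non_carrier"),
    ped_row("C1", father = "F1", mother = "M1", status = "carrier"))
  rep <- check_segregation(p)
  expect_false(rep$consistent)
  expect_equal(rep$conflicts$id, "C1")

  lone <- make_ped(ped_row("F1", sex = "M", status = "carrier"))
  expect_true(check_segregation(lone)$consistent)

  # unknown parents are never treated as non-carriers
  p_unk <- make_ped(
    ped_row("F1", sex = "M", status = "unknown"),
    ped_row("M1", sex = "F", status = "non_carrier"),
    ped_row("C1", father = "F1", mother = "M1", status = "carrier"))
  expect_true(check_segregation(p_unk)$consistent)
})

test_that("obligate carriers sit on carrier-to-carrier descent paths", {
  p <- make_ped(
    ped_row("G", sex = "F", status = "carrier"),
    ped_row("Gs", sex = "M", status = "non_carrier"),
    ped_row("U", father = "Gs", mother = "G", sex = "F", status = "unknown"),
    ped_row("Us", sex = "M", status = "non_carrier"),
    ped_row("K", father = "Us", mother = "U", sex = "M", status = "carrier"))
  rep <- check_segregation(p)
  expect_equal(rep$obligate_carriers, "U")
  expect_true(rep$consistent)
})

test_that("Mendelian simulations segregate cleanly; corrupted parents conflict", {
  for (s in 1:20) {
    d <- simulate_pedigree_dataset(sim_config(seed = 6000 + s))
    rep <- check_segregation(d$pedigree)
    expect_true(rep$consistent)
  }
  # force a conflict: mark a carrier's parents non_carrier
  d <- simulate_pedigree_dataset(sim_config(seed = 6001))
  p <- as.data.frame(d$pedigree)
  kid <- p$id[p$status == "carrier" & nzchar(p$father)][1]
  p$status[p$id %in% c(p$father[p$id == kid], p$mother[p$id == kid])] <-
    "non_carrier"
  expect_gte(nrow(check_segregation(pedigree(p))$conflicts), 1)
})

test_that("matriline checking flags mother-child mitotype mismatches only", {
  p <- make_ped(
    ped_row("M1", sex = "F", status = "unknown"),
    ped_row("K1", mother = "M1", status = "unknown"),
    ped_row("K2", status = "unknown"))
  mt <- list(M1 = parse_mitotype("73G 263G"),
             K1 = parse_mitotype("73G 263G"),
             K2 = parse_mitotype("152C"))
  expect_equal(nrow(check_matriline(p, mt)), 0)
  mt$K1 <- parse_mitotype("73G 263G 152C")
  v <- check_matriline(p, mt)
  expect_equal(v$id, "K1")
  expect_error(check_matriline(p, list(M1 = parse_mitotype("73R"))),
               "mixed-base")
})
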