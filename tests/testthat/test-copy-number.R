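test_that("the target registry reproduces the printed amplicon lengths", {
  t <- quant_targets()
  len <- setNames(t$length, t$name)
  expect_equal(len[["ND1"]], 69L)
  expect_equal(len[["KAV"]], 105L)
  expect_equal(len[["BATZ"]], 79L)
  expect_equal(len[["AND"]], 143L)
  expect_equal(len[["ND14"]], 109L)
  expect_equal(t$copy_class[t$name == "ND14"], "single_copy_autosomal")
  expect_setequal(t$name[t$copy_class == "multi_copy_autosomal"],
                  c("RNU2", "AluYb8"))
  expect_true(all(t$chromosome[t$copy_class == "mt_like"] == "chrM"))
})

test_that("the ddPCR Poisson estimator matches closed forms and errors on bad input", {
  expect_equal(ddpcr_lambda(0, 20000), 0)
  expect_equal(ddpcr_lambda(10000, 20000), log(2))
  expect_equal(ddpcr_lambda(12642, 20000), -log(1 - 0.6321), tolerance = 1e-12)
  expect_error(ddpcr_lambda(20000, 20000), "saturated")
  expect_error(ddpcr_lambda(1, 0), "n_droplets")
  expect_error(ddpcr_lambda(-1, 100), "n_positive")
  # monotone in the positive count
  lams <- sapply(seq(0, 19999, by = 500), ddpcr_lambda, n_droplets = 20000)
  expect_true(all(diff(lams) > 0))
  expect_equal(ddpcr_concentration(10000, 20000, 0.85), log(2) / 0.85)
})

test_that("ddPCR estimator agrees with a Monte-Carlo partitioning oracle", {
  # oracle: physically distribute N molecules over droplets uniformly at
  # random and count occupied droplets; repeat and average
  set.seed(123)
  n_droplets <- 20000
  for (lam in c(0.05, 0.5, 1, 2)) {
    est <- replicate(20, {
      n_molecules <- rpois(1, lam * n_droplets)
      occupied <- length(unique(sample.int(n_droplets, n_molecules,
                                           replace = TRUE)))
      ddpcr_lambda(occupied, n_droplets)
    })
    expect_equal(mean(est), lam, tolerance = 0.02)
  }
})

test_that("copies-per-NUMT arithmetic follows the diploid correction", {
  expect_equal(copies_per_numt(22.50, 2), 45.00)
  expect_equal(copies_per_numt(0, 2), 0)
  expect_equal(copies_per_numt(7.3, 1), 7.3)
  expect_error(copies_per_numt(-1), ">= 0")
})

test_that("aggregate_copies reports mean, sample SD and n over replicates", {
  est <- aggregate_copies(rep(22.5, 20))
  expect_equal(est$copies_per_numt, 45)
  expect_equal(est$sd, 0)
  expect_equal(est$n, 20)
  expect_warning(single <- aggregate_copies(21), "single replicate")
  expect_true(is.na(single$sd))
  expect_equal(single$copies_per_numt, 42)
  expect_error(aggregate_copies(numeric(0)), "at least one")
  per <- aggregate_copies(c(22, 23, 24, 25),
                          target_names = c("ND1", "ND1", "KAV", "KAV"))
  expect_equal(unname(per$per_target["ND1"]), 22.5)
})

test_that("insert size scales linearly with the repeat-unit length", {
  expect_equal(insert_size(45), 745605)
  expect_gte(insert_size(45), 7e5)
  expect_equal(insert_size(0), 0)
  expect_equal(insert_size(1), 16569)
  expect_error(insert_size(-2), ">= 0")
})

test_that("template topology decides which long-range amplicons can form", {
  amp_a <- circular_interval(2480, 10858)       # within the linear run
  amp_b <- circular_interval(10653, 2688)       # wraps the origin
  lin <- list(type = "linear_single_unit", span = circular_interval(1, 16569))
  expect_true(template_supports(lin, amp_a))
  expect_false(template_supports(lin, amp_b))   # only one of the two products
  expect_true(template_supports(list(type = "tandem_repeat", n = 2), amp_b))
  expect_error(template_supports(list(type = "tandem_repeat", n = 1), amp_b),
               "n >= 2")
  set.seed(8)
  for (i in 1:20) {
    amp <- circular_interval(sample(16569, 1), sample(16569, 1))
    expect_true(template_supports(list(type = "circular"), amp))
    expect_true(template_supports(list(type = "tandem_repeat", n = 2), amp))
  }
  # a linear unit beginning mid-genome contains the wrap amplicon it spans
  lin2 <- list(type = "linear_single_unit", span = circular_interval(10653, 2688))
  expect_true(template_supports(lin2, amp_b))
  expect_false(template_supports(lin2, amp_a))
})

test_that("simulated depleted-cell assays recover the tandem copy number", {
  # quick recovery check at the study's copy number; the full sweep over
  # {10, 45, 100} runs in the acceptance suite
  ests <- sapply(1:10, function(s) {
    d <- simulate_pedigree_dataset(sim_config(seed = 3000 + s))
    aggregate_copies(ratios_from_ddpcr(d$quant$ddpcr))$copies_per_numt
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 45), 3 * se)  # 3 SE at this reduced n
})
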