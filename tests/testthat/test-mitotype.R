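test_that("parse_mitotype handles substitutions, insertions and the empty string", {
  m <- parse_mitotype("263G 315.1C")
  expect_equal(nrow(m$variants), 2)
  expect_equal(m$variants$kind, c("substitution", "insertion"))
  expect_equal(m$variants$pos, c(263L, 315L))
  expect_equal(m$variants$ins, c(0L, 1L))

  e <- parse_mitotype("")
  expect_equal(nrow(e$variants), 0)
  expect_equal(serialize_mitotype(e), "")

  d <- parse_mitotype("249DEL")
  expect_equal(d$variants$kind, "deletion")
  expect_equal(serialize_mitotype(d), "249DEL")
})

test_that("the reference individual's mixed call parses to 13 records, 11 ambiguous", {
  m <- parse_mitotype(MIXED_STRING)
  expect_equal(nrow(m$variants), 13)
  expect_equal(nrow(ambiguous_variants(m)), 11)
  expect_equal(sum(!m$variants$pos %in% ambiguous_variants(m)$pos), 2)
})

test_that("parse errors name the offending token", {
  expect_error(parse_mitotype("263G banana"), "banana")
  expect_error(parse_mitotype("5000G"), "5000G")       # outside the CR
  expect_error(parse_mitotype("263G 263A"), "263A")
  expect_error(parse_mitotype("0G", range = full_genome()), "0G")
})

test_that("serialization uses circular order starting at the 16024 arc", {
  m <- mitotype(data.frame(pos = c(72L, 16298L, 263L), ins = 0L,
                           obs = c("C", "C", "G")))
  expect_equal(serialize_mitotype(m), "16298C 72C 263G")
  # full-genome mitotypes in plain numeric order
  f <- mitotype(data.frame(pos = c(16298L, 72L), ins = 0L, obs = c("C", "C")),
                range = full_genome())
  expect_equal(serialize_mitotype(f), "72C 16298C")
})

test_that("parse/serialize round-trips every packaged family haplotype", {
  fx <- load_family_fixture()
  for (m in fx$true_mitotypes)
    expect_equal(serialize_mitotype(parse_mitotype(serialize_mitotype(m))),
                 serialize_mitotype(m))
  for (m in fx$haplotypes)
    expect_equal(serialize_mitotype(parse_mitotype(serialize_mitotype(m))),
                 serialize_mitotype(m))
})

test_that("parse/serialize round-trips random mitotypes", {
  set.seed(42)
  for (i in 1:50) {
    m <- clade_haplotype(sample(c("HV0", "U4c1"), 1), random_private_variants())
    expect_equal(serialize_mitotype(parse_mitotype(serialize_mitotype(m))),
                 serialize_mitotype(m))
  }
})

test_that("circular_length matches printed amplicon lengths and a counting oracle", {
  expect_equal(circular_length(circular_interval(3485, 3553)), 69)
  expect_equal(circular_length(circular_interval(1, 16569)), 16569)
  expect_equal(circular_length(circular_interval(16024, 576)), 1122)
  set.seed(1)
  for (i in 1:1000) {
    iv <- circular_interval(sample(16569, 1), sample(16569, 1))
    expect_equal(circular_length(iv), length(circular_positions(iv)))
  }
})

test_that("apply_to_reference obeys the length arithmetic", {
  ref <- mt_reference()
  full <- parse_mitotype("", range = full_genome())
  expect_equal(apply_to_reference(full), paste(ref, collapse = ""))

  ins <- parse_mitotype("315.1C")
  expect_equal(nchar(apply_to_reference(ins)), 1122 + 1)

  sub <- parse_mitotype("263G")
  s <- apply_to_reference(sub)
  base <- apply_to_reference(parse_mitotype(""))
  expect_equal(nchar(s), nchar(base))
  diffs <- which(strsplit(s, "")[[1]] != strsplit(base, "")[[1]])
  expect_length(diffs, 1)

  del <- parse_mitotype("249DEL")
  expect_equal(nchar(apply_to_reference(del)), 1122 - 1)

  expect_error(apply_to_reference(parse_mitotype("73R")), "mixed-base")
  expect_equal(nchar(apply_to_reference(parse_mitotype("73R"),
                                        allow_ambiguous = TRUE)), 1122)
})

test_that("diff_positions is symmetric and empty iff equal", {
  h <- parse_mitotype(HV0_STRING)
  u <- parse_mitotype(U4C1_STRING)
  expect_equal(nrow(diff_positions(h, h)), 0)
  expect_equal(nrow(diff_positions(h, u)), 11)
  expect_equal(diff_positions(h, u), diff_positions(u, h))
  one <- diff_positions(parse_mitotype(""), parse_mitotype("263G"))
  expect_equal(one$pos, 263L)
  expect_equal(one$ins, 0L)
  expect_error(diff_positions(h, parse_mitotype("72C", range = full_genome())),
               "ranges")
})

test_that("mixing the deconvolved components reproduces the printed mixed call", {
  mixed <- mix_mitotypes(parse_mitotype(HV0_STRING), parse_mitotype(U4C1_STRING))
  expect_equal(serialize_mitotype(mixed), MIXED_STRING)
})

test_that("mix uses the reference allele where one haplotype has no variant", {
  out <- mix_mitotypes(parse_mitotype(""), parse_mitotype("73G"))
  expect_equal(serialize_mitotype(out), "73R")   # reference base at 73 is A
  h <- parse_mitotype(HV0_STRING)
  expect_true(mitotype_equal(mix_mitotypes(h, h), h))
})

test_that("mix/diff agree on random haplotype pairs", {
  set.seed(99)
  for (i in 1:50) {
    a <- clade_haplotype("HV0", random_private_variants())
    b <- clade_haplotype("U4c1", random_private_variants())
    mixed <- mix_mitotypes(a, b)
    expect_equal(nrow(ambiguous_variants(mixed)), nrow(diff_positions(a, b)))
    expect_true(mitotype_equal(mix_mitotypes(a, a), a))
  }
})

test_that("IUPAC helpers expand and encode consistently", {
  expect_equal(sort(iupac_expand("R")), c("A", "G"))
  expect_equal(iupac_code(c("C", "T")), "Y")
  expect_equal(iupac_code(c("A", "C", "G", "T")), "N")
  for (code in c("A", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"))
    expect_equal(iupac_code(iupac_expand(code)), code)
})
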