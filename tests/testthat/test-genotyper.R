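test_that("the read filter keeps variants at exactly the threshold", {
  v <- data.frame(variant_seq = c("A", "C"), read_count = c(990, 10))
  kept <- filter_low_frequency(v)
  expect_equal(nrow(kept), 2)           # 10/1000 = 1%, not below
  expect_equal(sum(kept$frequency), 1)

  v2 <- data.frame(variant_seq = c("A", "C"), read_count = c(995, 5))
  kept2 <- filter_low_frequency(v2)
  expect_equal(nrow(kept2), 1)
  expect_equal(kept2$frequency, 1.0)    # renormalised over retained reads

  v3 <- data.frame(variant_seq = c("A", "C"), read_count = c(995, 5))
  raw <- filter_low_frequency(v3, renormalize = FALSE)
  expect_equal(raw$frequency, 0.995)    # pre-filter denominator on request
})

test_that("the read filter matches a brute-force threshold oracle and is idempotent", {
  set.seed(51)
  for (i in 1:10) {
    v <- data.frame(variant_seq = paste0("v", 1:8),
                    read_count = rpois(8, c(5000, rep(30, 7))))
    total <- sum(v$read_count)
    oracle <- v$variant_seq[v$read_count / total >= 0.01]
    kept <- filter_low_frequency(v)
    expect_setequal(kept$variant_seq, oracle)
    expect_equal(filter_low_frequency(kept), kept)  # idempotent
    expect_equal(sum(kept$frequency), 1, tolerance = 1e-9)
  }
})

test_that("a locus with no surviving variants is a no-call error", {
  v <- data.frame(variant_seq = paste0("v", 1:3), read_count = c(0, 0, 0))
  expect_error(filter_low_frequency(v), class = "calluscope_no_call")
  v2 <- data.frame(variant_seq = paste0("v", 1:200),
                   read_count = rep(1, 200))
  expect_error(filter_low_frequency(v2), class = "calluscope_no_call")
})

test_that("variant classification by alignment recognises the four classes", {
  tg <- fixture_target()
  wt <- classify_variant(tg, tg$reference_amplicon)
  expect_equal(wt$mutation_class, "wildtype")
  expect_equal(wt$length_delta, 0L)

  sub <- classify_variant(tg, fixture_substituted(tg, 5, "T"))
  expect_equal(sub$mutation_class, "substitution")
  expect_equal(sub$substitutions$position, 5)
  expect_equal(sub$substitutions$ref, "C")
  expect_equal(sub$substitutions$alt, "T")
  expect_true(sub$substitutions$in_protospacer)

  del <- classify_variant(tg, fixture_deleted(tg, 10))
  expect_equal(del$mutation_class, "indel")
  expect_equal(del$length_delta, -1L)

  # substitution inside the protospacer plus a deletion elsewhere -> complex
  sub5 <- fixture_substituted(tg, 5, "T")
  both <- paste0(substring(sub5, 1, 5), substring(sub5, 7, nchar(sub5)))
  cx <- classify_variant(tg, both)
  expect_equal(cx$mutation_class, "complex")
  expect_equal(cx$length_delta, -1L)

  expect_error(classify_variant(tg, "ACGTX"), "non-DNA")
})

test_that("substitutions outside the protospacer are flagged with amplicon coordinates", {
  tg <- fixture_target()
  ref <- tg$reference_amplicon
  outside <- paste0("T", substring(ref, 2, nchar(ref)))  # position 1, far 5'
  out <- classify_variant(tg, outside)
  expect_equal(out$mutation_class, "substitution")
  expect_false(out$substitutions$in_protospacer)
  expect_equal(out$substitutions$position, 1)
})

test_that("cumulative locus frequencies split edited and indel mass", {
  v <- data.frame(frequency = c(0.6, 0.3, 0.1),
                  mutation_class = c("wildtype", "substitution", "indel"))
  f <- locus_mutation_frequency(v)
  expect_equal(unname(f), c(0.4, 0.1))

  allwt <- data.frame(frequency = 1, mutation_class = "wildtype")
  expect_equal(unname(locus_mutation_frequency(allwt)), c(0, 0))

  set.seed(52)
  for (i in 1:10) {
    cls <- sample(c("wildtype", "substitution", "indel", "complex"), 6,
                  replace = TRUE)
    fr <- as.vector(rmultinom(1, 1000, rep(1, 6))) / 1000
    got <- locus_mutation_frequency(data.frame(frequency = fr,
                                               mutation_class = cls))
    expect_equal(got[["mutation_frequency"]], sum(fr[cls != "wildtype"]))
    expect_equal(got[["indel_frequency"]],
                 sum(fr[cls %in% c("indel", "complex")]))
  }
})

test_that("zygosity classes partition [0,1] with strict boundaries", {
  expect_equal(classify_zygosity(0.95), "homozygous")
  expect_equal(classify_zygosity(0.90), "heterozygous")  # 'exceeded' is strict
  expect_equal(classify_zygosity(0.20), "heterozygous")
  expect_equal(classify_zygosity(0.0), "wildtype")
  expect_error(classify_zygosity(1.2), "\\[0, 1\\]")
  expect_error(classify_zygosity(-0.1), "\\[0, 1\\]")

  grid <- seq(0, 1, length.out = 10001)
  cls <- classify_zygosity(grid)
  expect_true(all(cls %in% c("wildtype", "chimeric", "heterozygous",
                             "homozygous")))
  # each frequency gets exactly one class and the classes are contiguous
  expect_equal(sum(cls == "wildtype"), 1)
  expect_true(all(diff(match(cls, c("wildtype", "chimeric", "heterozygous",
                                    "homozygous"))) >= 0))
})

test_that("line calls require heterozygous-or-better loci", {
  calls <- data.frame(line_id = "L1", locus_id = c("A", "B"),
                      zygosity = c("homozygous", "wildtype"),
                      indel_frequency = c(0, 0),
                      has_indel_call = c(FALSE, FALSE))
  lc <- call_line(calls)
  expect_true(lc$edited && lc$homozygous)

  chim <- data.frame(line_id = "L2", locus_id = c("A", "B"),
                     zygosity = c("chimeric", "chimeric"),
                     indel_frequency = c(0.05, 0.1),
                     has_indel_call = c(TRUE, TRUE))
  lc2 <- call_line(chim)
  expect_false(lc2$edited)
  expect_false(lc2$indel_line)                       # frequency rule
  expect_true(call_line(chim, indel_rule = "any")$indel_line)

  set.seed(53)
  for (i in 1:20) {
    f <- runif(2)
    ind <- runif(2, 0, f)
    calls <- data.frame(line_id = "L", locus_id = c("A", "B"),
                        zygosity = classify_zygosity(f),
                        indel_frequency = ind,
                        has_indel_call = ind > 0)
    lc <- call_line(calls)
    expect_equal(lc$edited, any(f >= 0.20))
    expect_equal(lc$homozygous, any(f > 0.90))
    expect_equal(lc$indel_line, any(ind >= 0.20))
  }
})

test_that("cohort rates are percentages rounded half away from zero", {
  cs <- cohort_summary("c", 28, 4, 2, 2)
  expect_equal(cs$editing_efficiency, 14.3)
  expect_equal(cs$homozygous_rate, 7.1)
  cs2 <- cohort_summary("c", 24, 5, 3, 3)
  expect_equal(unlist(cs2[, 6:8], use.names = FALSE), c(20.8, 12.5, 12.5))
  cs3 <- cohort_summary("c", 10, 0, 0, 0)
  expect_equal(unlist(cs3[, 6:8], use.names = FALSE), c(0, 0, 0))
  expect_error(cohort_summary("c", 10, 5, 6, 0), "n_homozygous")
  # explicit half cases round away from zero
  expect_equal(cohort_summary("c", 8, 1, 0, 0)$editing_efficiency, 12.5)
  expect_equal(round_half_up(0.125 * 100, 1), 12.5)
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(-2.25, 1), -2.3)
})

test_that("genotype_cohort reproduces simulated designs end to end", {
  tg <- default_targets()
  designs <- data.frame(line_id = sprintf("L%02d", 1:6),
                        `ALS2-A` = c("homozygous", "heterozygous", "chimeric",
                                     "wildtype", "wildtype", "heterozygous"),
                        `ALS2-B` = c("wildtype", "wildtype", "heterozygous",
                                     "wildtype", "chimeric", "homozygous"),
                        indel = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
                        check.names = FALSE)
  sim <- simulate_amplicon_cohort(tg, designs, depth = 4000,
                                  noise_rate = 0.02, seed = 54)
  res <- genotype_cohort(sim$variants, tg)
  truth <- sim$manifest$truth
  got <- merge(res$locus_calls, truth, by = c("line_id", "locus_id"))
  expect_equal(got$zygosity.x, got$zygosity.y)
  expect_equal(unname(unlist(
    res$cohorts[, c("n_genotyped", "n_edited", "n_homozygous", "n_indel")])),
    unname(sim$manifest$expected_counts))
  # noise variants never survive the filter in this design
  expect_true(all(res$variants$frequency >= 0.01 |
                    res$variants$mutation_class == "wildtype"))
})

test_that("genotype_cohort errors on unknown loci and warns on no-calls", {
  tg <- default_targets()
  v <- data.frame(line_id = "L1", locus_id = "nope",
                  variant_seq = "ACGT", read_count = 10)
  expect_error(genotype_cohort(v, tg), "no target spec")

  v2 <- data.frame(line_id = c("L1", "L1"), locus_id = c("ALS2-A", "ALS2-B"),
                   variant_seq = c(tg[["ALS2-A"]]$reference_amplicon,
                                   tg[["ALS2-B"]]$reference_amplicon),
                   read_count = c(100, 0))
  expect_warning(res <- genotype_cohort(v2, tg), "no-call")
  expect_true(is.na(res$locus_calls$zygosity[
    res$locus_calls$locus_id == "ALS2-B"]))
  expect_equal(res$line_calls$edited, FALSE)
})

test_that("target_spec validates spacer placement and PAM", {
  tg <- fixture_target()
  expect_error(target_spec("x", tg$reference_amplicon, tg$spacer,
                           protospacer_start = 5), "does not occur")
  bad_pam <- paste0(substring(tg$reference_amplicon, 1, 40), "TTT",
                    substring(tg$reference_amplicon, 44,
                              nchar(tg$reference_amplicon)))
  expect_error(target_spec("x", bad_pam, tg$spacer,
                           protospacer_start = 21), "PAM")
  expect_error(target_spec("x", tg$reference_amplicon,
                           substring(tg$spacer, 1, 19),
                           protospacer_start = 21), "20 nt")
})
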