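test_that("generators are pure functions of their arguments and seed", {
  a1 <- simulate_expression_atlas(n_genes = 200, n_specific = 4, seed = 71)
  a2 <- simulate_expression_atlas(n_genes = 200, n_specific = 4, seed = 71)
  a3 <- simulate_expression_atlas(n_genes = 200, n_specific = 4, seed = 72)
  expect_identical(a1$values, a2$values)
  expect_identical(a1$manifest, a2$manifest)
  expect_false(identical(a1$values, a3$values))

  tg <- default_targets()
  d <- design_cohort(4, 2, 1, 1)
  c1 <- simulate_amplicon_cohort(tg, d, depth = 500, seed = 71)
  c2 <- simulate_amplicon_cohort(tg, d, depth = 500, seed = 71)
  expect_identical(c1$variants, c2$variants)

  p1 <- simulate_promoters(2, 300, seed = 71)
  p2 <- simulate_promoters(2, 300, seed = 71)
  expect_identical(p1$sequences, p2$sequences)

  g1 <- simulate_genome_with_offtargets("GATTCCAGTACGGCTAGTCA", c(1),
                                        length = 5000, seed = 71)
  g2 <- simulate_genome_with_offtargets("GATTCCAGTACGGCTAGTCA", c(1),
                                        length = 5000, seed = 71)
  expect_identical(g1$sequences, g2$sequences)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_expression_atlas(n_genes = 50, n_specific = 2, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("an atlas with nothing planted has an empty truth set", {
  sim <- simulate_expression_atlas(n_genes = 100, n_specific = 0, seed = 73)
  expect_length(sim$manifest$specific_genes, 0)
  out <- tissue_specificity_filter(rownames(sim$values), sim$atlas)
  expect_equal(nrow(out), 0)
})

test_that("atlas invariants hold and bad sizes error", {
  sim <- simulate_expression_atlas(n_genes = 150, n_specific = 3, seed = 74)
  expect_true(all(sim$values >= 0))
  expect_equal(sort(unique(sim$samples$tissue[sim$samples$tissue != "callus"])),
               sort(unique(unname(sim$atlas$tissue_of[sim$atlas$tissue_of != "callus"]))))
  expect_error(simulate_expression_atlas(n_genes = 10, n_specific = 20),
               "n_specific")
})

test_that("an all-wildtype cohort genotypes to zero efficiency", {
  tg <- default_targets()
  d <- design_cohort(6, 0, 0, 0)
  sim <- simulate_amplicon_cohort(tg, d, depth = 1000, noise_rate = 0.02,
                                  seed = 75)
  res <- genotype_cohort(sim$variants, tg)
  expect_equal(res$cohorts$editing_efficiency, 0)
  expect_true(all(res$locus_calls$zygosity == "wildtype"))
})

test_that("random cohort designs are recovered exactly from the manifest", {
  tg <- default_targets()
  set.seed(76)
  classes <- c("wildtype", "chimeric", "heterozygous", "homozygous")
  designs <- data.frame(line_id = sprintf("L%03d", 1:40),
                        `ALS2-A` = sample(classes, 40, replace = TRUE),
                        `ALS2-B` = sample(classes, 40, replace = TRUE),
                        indel = sample(c(TRUE, FALSE), 40, replace = TRUE),
                        check.names = FALSE)
  sim <- simulate_amplicon_cohort(tg, designs, depth = 2000,
                                  noise_rate = 0.01, seed = 77)
  res <- genotype_cohort(sim$variants, tg)
  got <- merge(res$locus_calls, sim$manifest$truth,
               by = c("line_id", "locus_id"))
  expect_equal(nrow(got), 80)
  expect_equal(got$zygosity.x, got$zygosity.y)
  expect_equal(
    unname(unlist(res$cohorts[, c("n_genotyped", "n_edited", "n_homozygous",
                                  "n_indel")])),
    unname(sim$manifest$expected_counts))
})

test_that("realised variant frequencies converge to the design at high depth", {
  tg <- default_targets()[1]
  d <- data.frame(line_id = "L1", `ALS2-A` = "heterozygous", indel = FALSE,
                  check.names = FALSE)
  sim <- simulate_amplicon_cohort(tg, d, depth = 1e5, seed = 78)
  v <- sim$variants
  edited <- v$variant_seq != tg[["ALS2-A"]]$reference_amplicon
  emp <- sum(v$read_count[edited]) / sum(v$read_count)
  expect_equal(emp, sim$manifest$truth$design_frequency, tolerance = 0.01)
})

test_that("inconsistent cohort designs error", {
  tg <- default_targets()
  d <- design_cohort(4, 2, 1, 1)
  d$`ALS2-A`[1] <- "triploid"
  expect_error(simulate_amplicon_cohort(tg, d), "zygosity")
  expect_error(design_cohort(4, 5, 1, 0), "n_homozygous")
  expect_error(design_cohort(4, 2, 1, 3), "n_indel")
  expect_error(simulate_amplicon_cohort(tg, design_cohort(2, 0, 0, 0),
                                        depth = 10), "depth")
})

test_that("promoter generator plants at stated coordinates and rejects overlap", {
  pl <- data.frame(motif_name = "TATA-box", pattern = "TATA",
                   position = 50, strand = "+")
  sim <- simulate_promoters(2, 100, pl, seed = 79)
  for (id in names(sim$sequences)) {
    expect_equal(substring(sim$sequences[[id]], 50, 53),
                 sim$manifest$planted$planted_seq[
                   sim$manifest$planted$promoter_id == id])
    expect_true(50 %in% iupac_matches("TATA", sim$sequences[[id]]))
  }
  bad <- data.frame(motif_name = c("a", "b"), pattern = c("TATAT", "ACGTG"),
                    position = c(10, 12), strand = "+")
  expect_error(simulate_promoters(1, 100, bad, seed = 79), "overlap")
  off <- data.frame(motif_name = "a", pattern = "TATA", position = 99,
                    strand = "+")
  expect_error(simulate_promoters(1, 100, off, seed = 79), "fit")
})

test_that("staged atlas reproduces its designed set sizes", {
  st <- simulate_staged_atlas(n_genes = 1500, top_n = 300,
                              stage_sizes = c(t5 = 380, t11 = 350),
                              overlap = 320, seed = 80)
  res <- run_expression_screen(st$values, st$samples,
                               screen_config(top_n = 300))
  expect_equal(unname(res$summary[["consensus_t5"]]), 380)
  expect_equal(unname(res$summary[["consensus_t11"]]), 350)
  expect_equal(unname(res$summary[["cross_stage"]]), 320)
  expect_setequal(res$cross_stage, st$manifest$overlap_genes)
  for (col in names(st$manifest$replicate_tops)) {
    expect_setequal(res$per_replicate_top[[col]],
                    st$manifest$replicate_tops[[col]])
  }
  expect_error(simulate_staged_atlas(stage_sizes = c(a = 100, b = 500),
                                     overlap = 50), "stage size")
})

test_that("planted off-target manifests record exact mismatch counts", {
  spacer <- "GATTCCAGTACGGCTAGTCA"
  sim <- simulate_genome_with_offtargets(spacer, c(0, 2, 4), length = 9000,
                                         seed = 81)
  spacer_chars <- strsplit(spacer, "")[[1]]
  for (i in seq_len(nrow(sim$manifest$sites))) {
    row <- sim$manifest$sites[i, ]
    s <- substring(sim$sequences[[row$seq_id]], row$start, row$end)
    if (row$strand == "-") s <- revcomp(s)
    expect_equal(sum(strsplit(s, "")[[1]] != spacer_chars),
                 row$n_mismatches)
    expect_equal(s, row$site_seq)
  }
})
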