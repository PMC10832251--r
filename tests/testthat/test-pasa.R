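# In-silico PASA: primer binding, band prediction, gel interpretation.

test_that("allele-specific primers discriminate at their 3' end", {
  sus_hap <- render_haplotypes(c(L1014F = "SS"),
                               reference = test_reference)$haplotype_a
  res_hap <- render_haplotypes(c(L1014F = "RR"),
                               reference = test_reference)$haplotype_a
  kdr2 <- test_assay$primers$kdr2  # resistant-specific
  kdr3 <- test_assay$primers$kdr3  # susceptible-specific
  expect_gte(nrow(find_binding_sites(sus_hap, kdr3)), 1)
  expect_equal(nrow(find_binding_sites(sus_hap, kdr2)), 0)
  expect_gte(nrow(find_binding_sites(res_hap, kdr2)), 1)
  expect_equal(nrow(find_binding_sites(res_hap, kdr3)), 0)
  # a primer absent from the template yields an empty site list
  expect_equal(nrow(find_binding_sites("ACGTACGTACGTACGTACGTACGT", kdr2)), 0)
})

test_that("internal mismatches are tolerated up to the configured maximum", {
  pr <- primer("p", "GGATCCTTAGCAGCAT", "forward")
  set.seed(11)
  bg <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  tpl <- paste0(substr(bg, 1, 80), pr$sequence, substr(bg, 81, 200))
  # mutate an internal base (not the 3' terminus)
  mut <- tpl
  substr(mut, 85, 85) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 85, 85))[1]
  expect_equal(nrow(find_binding_sites(mut, pr,
                                       max_internal_mismatches = 0)), 0)
  hit <- find_binding_sites(mut, pr, max_internal_mismatches = 1)
  hit <- hit[hit$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches, 1L)
  expect_equal(hit$start, 81L)
  # 3'-terminal mismatch always blocks priming
  mut3 <- tpl
  substr(mut3, 96, 96) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mut3, 96, 96))[1]
  expect_equal(nrow(find_binding_sites(mut3, pr,
                                       max_internal_mismatches = 3)[
    find_binding_sites(mut3, pr, max_internal_mismatches = 3)$strand == "+",
  ]), 0)
})

test_that("predict_bands reproduces the per-genotype gel patterns", {
  patterns <- list(SS = c(213, 480), RS = c(213, 299, 480),
                   RR = c(299, 480))
  for (g in names(patterns)) {
    tpl <- render_haplotypes(c(L1014F = g), reference = test_reference)
    bp <- predict_bands(tpl, test_assay, insect_id = g)
    expect_equal(bp$band_sizes, as.integer(patterns[[g]]), label = g)
    # the control amplicon is exactly the published 480 bp
    expect_true(480L %in% bp$band_sizes)
  }
  # gDNA templates give identical bands (the intron sits outside the
  # amplified region, as in the real gene)
  tpl_g <- render_haplotypes(c(L1014F = "RS"), form = "gDNA",
                             reference = test_reference)
  expect_equal(predict_bands(tpl_g, test_assay)$band_sizes,
               as.integer(c(213, 299, 480)))
  # template lacking all primer sites -> no bands
  expect_equal(predict_bands("ACGTACGTACGTACGTACGT",
                             test_assay)$band_sizes, integer())
})

test_that("genotype_from_bands applies the interpretation table", {
  gt <- function(sizes) {
    genotype_from_bands(band_pattern("fly", sizes), test_assay)$genotype
  }
  expect_equal(gt(c(480, 280, 200)), "RS")
  expect_equal(gt(c(480, 200)), "SS")
  expect_equal(gt(c(480, 280)), "RR")
  expect_equal(gt(200), "INDETERMINATE")        # no control: failed assay
  expect_equal(gt(c(200, 280)), "INDETERMINATE")
  expect_equal(gt(480), "INDETERMINATE")        # control only
  # sizes off by less than the 10% gel tolerance still match
  expect_equal(gt(c(470, 290, 195)), "RS")
  # an unmatched band is ignored with a warning
  expect_warning(g <- gt(c(480, 200, 999)), "match no expected size")
  expect_equal(g, "SS")
})

test_that("bands_for_genotype inverts the interpretation", {
  expect_equal(bands_for_genotype("SS", test_assay), c(200L, 480L))
  expect_equal(bands_for_genotype("RR", test_assay), c(280L, 480L))
  expect_equal(bands_for_genotype("RS", test_assay), c(200L, 280L, 480L))
  expect_error(bands_for_genotype("INDETERMINATE", test_assay), "genotype")
  # consistency loop
  for (g in c("SS", "RS", "RR")) {
    expect_equal(
      genotype_from_bands(band_pattern("x", bands_for_genotype(g,
                                                               test_assay)),
                          test_assay)$genotype, g)
  }
})

test_that("PASA and the sequence caller agree end to end", {
  f_site <- test_model$sites$L1014F
  for (g in c("SS", "RS", "RR")) {
    tpl <- render_haplotypes(c(L1014F = g), reference = test_reference)
    from_bands <- genotype_from_bands(predict_bands(tpl, test_assay),
                                      test_assay)$genotype
    consensus <- render_sequences(
      data.frame(id = "x", L1014F = g, stringsAsFactors = FALSE),
      reference = test_reference)[[1]]
    from_seq <- call_site(consensus, f_site)$genotype
    expect_equal(from_bands, g)
    expect_equal(from_seq, g)
  }
})

test_that("band patterns round-trip through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("insect_id,band_sizes", "a,480;280;200", "b,480;200"), tmp)
  pats <- read_band_patterns(tmp)
  expect_length(pats, 2)
  expect_equal(genotype_from_bands(pats[[1]], test_assay)$genotype, "RS")
  expect_equal(genotype_from_bands(pats[[2]], test_assay)$genotype, "SS")
})
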