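test_that("exact generator produces the requested ITS variant sites", {
  u <- make_reference_unit(seed = 3)
  hs <- make_haplotypes_exact(u, n_substitutions = 10, n_indels = 5,
                              n_haplotypes = 4, seed = 11)
  tv <- hs$true_variant_sites
  expect_identical(nrow(tv), 15L)
  expect_identical(sum(tv$type == "sub"), 10L)
  expect_identical(sum(tv$type %in% c("del", "ins")), 5L)
  b <- region_bounds(u, "ITS")
  expect_true(all(tv$pos >= b[1] & tv$pos <= b[2]))
  # every allele is carried by a proper, non-empty subset of copies
  expect_true(all(tv$freq >= 1 / sum(hs$copy_counts)))
  expect_true(all(tv$freq < 1))
  expect_identical(sum(hs$copy_counts), 8L)
  expect_identical(length(hs$haplotypes), 4L)
})

test_that("true variant table is recovered from the sequences themselves", {
  u <- make_reference_unit(seed = 3)
  hs <- make_haplotypes_exact(u, 10, 5, 4, seed = 11)
  # error-free 'clones', one per haplotype: realignment must reconstruct
  # exactly the truth table's (position, allele) set
  cls <- structure(list(clones = setNames(hap_region_seq(hs, "ITS"),
                                          paste0("clone", 1:4)),
                        source = names(hs$haplotypes), region = "ITS",
                        error_rate = 0, n_errors = 0L),
                   class = "clone_set")
  det <- detect_clone_variants(cls, u)
  got <- sort(paste(det$table$position, det$table$alt))
  want <- sort(paste(hs$true_variant_sites$pos, hs$true_variant_sites$alt))
  expect_identical(got, want)
})

test_that("truth frequencies equal carrier copies over total copies", {
  u <- make_reference_unit(seed = 5)
  hs <- make_haplotypes_exact(u, 6, 3, 3, copy_counts = c(h1 = 5L, h2 = 2L,
                                                          h3 = 1L), seed = 4)
  tv <- hs$true_variant_sites
  for (i in seq_len(nrow(tv))) {
    carriers <- vapply(hs$edits, function(e) {
      if (!nrow(e)) return(FALSE)
      allele <- mapply(rdnavar:::edit_allele, e$type, e$norm_alt,
                       USE.NAMES = FALSE)
      any(e$norm_pos == tv$pos[i] & allele == tv$alt[i])
    }, TRUE)
    expect_equal(tv$freq[i],
                 sum(hs$copy_counts[carriers]) / sum(hs$copy_counts))
  }
})

test_that("accumulated mutation mode scatters region-specific variation", {
  u <- make_reference_unit(seed = 1)
  m <- heterogeneity_model("accumulated_mutation", n_haplotypes = 4,
                           region_rates = c(ITS = 0.01, SSU18S = 0,
                                            LSU28S = 0))
  hs <- evolve_haplotypes(u, m, seed = 2)
  tv <- hs$true_variant_sites
  expect_gt(nrow(tv), 0)
  b <- region_bounds(u, "ITS")
  expect_true(all(tv$pos >= b[1] & tv$pos <= b[2]))
})

test_that("hybridization mode yields two diverged clusters", {
  u <- make_reference_unit(seed = 1)
  m <- heterogeneity_model("hybridization", n_haplotypes = 4,
                           hybrid_divergence = 0.02)
  hs <- evolve_haplotypes(u, m, seed = 6)
  D <- haplotype_p_distances(hs)
  # within-cluster distances are zero up to private mutations; between
  # clusters near the divergence level
  expect_gt(max(D), 0.01)
  grp <- cutree(hclust(as.dist(D)), k = 2)
  expect_identical(length(unique(grp)), 2L)
})

test_that("foreign element mode inserts the element in one haplotype", {
  u <- make_reference_unit(seed = 1)
  m <- heterogeneity_model("foreign_element", n_haplotypes = 3,
                           insert_length = 30)
  hs <- evolve_haplotypes(u, m, seed = 7)
  lens <- nchar(hs$haplotypes)
  expect_identical(sum(lens == unit_length(u) + 30L), 1L)
})

test_that("model validation rejects bad parameters", {
  expect_error(heterogeneity_model("hybridization", n_haplotypes = 1),
               "requires")
  expect_error(heterogeneity_model("accumulated_mutation",
                                   region_rates = c(ITS = 0.5)),
               "rates")
  expect_error(heterogeneity_model("accumulated_mutation",
                                   region_rates = c(XXX = 0.01)),
               "region")
})

test_that("haplotype sets are deterministic in the seed", {
  u <- make_reference_unit(seed = 1)
  h1 <- make_haplotypes_exact(u, 8, 4, 4, seed = 42)
  h2 <- make_haplotypes_exact(u, 8, 4, 4, seed = 42)
  expect_identical(h1$haplotypes, h2$haplotypes)
  expect_identical(h1$true_variant_sites, h2$true_variant_sites)
})
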