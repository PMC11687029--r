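vt_make <- function(pos = integer(0), ref = character(0),
                    alt = character(0), alt_count = integer(0),
                    status = "pass", method = "amplicon",
                    run_id = NA_integer_, len = 300L, depth = 2000L,
                    n_clones = NA_integer_) {
  d <- NULL
  if (length(pos)) {
    d <- data.frame(position = as.integer(pos), ref = ref, alt = alt,
                    depth = as.integer(depth),
                    alt_count = as.integer(alt_count),
                    frequency = alt_count / depth,
                    qual = 1000, qd = 10, fs = 0,
                    method = method, run_id = run_id,
                    filter_status = status, stringsAsFactors = FALSE)
  }
  rdnavar:::new_variant_table(d, method, run_id, mean_depth = depth,
                              depth_by_pos = rep(as.integer(depth), len),
                              offset = 0L, dp_threshold = 200,
                              n_clones = n_clones)
}

test_that("run consistency averages frequencies over covering runs", {
  r1 <- vt_make(c(50, 80), c("A", "C"), c("G", "T"), c(240, 30),
                run_id = 1L)                       # freqs 0.12, 0.015
  r2 <- vt_make(50, "A", "G", 280, run_id = 2L)    # freq 0.14
  rc <- compute_run_consistency(list(r1, r2))
  s <- rc$sites
  expect_identical(nrow(s), 2L)
  i <- which(s$position == 50)
  expect_equal(s$mean_freq[i], (0.12 + 0.14) / 2)  # = 0.13
  expect_identical(s$n_runs_present[i], 2)
  expect_true(s$consistent[i])
  j <- which(s$position == 80)
  # covered by both runs but called in one: inconsistent, freq averaged
  # with an explicit zero
  expect_identical(s$n_runs_present[j], 1)
  expect_identical(s$n_runs_covered[j], 2)
  expect_false(s$consistent[j])
  expect_equal(s$mean_freq[j], 0.015 / 2)
  # a single run is trivially consistent
  rc1 <- compute_run_consistency(list(r1))
  expect_true(all(rc1$sites$consistent))
})

test_that("two-method presence rescues hard-filter-failed calls", {
  clo <- vt_make(100, "A", "G", 3, method = "cloning", depth = 15,
                 n_clones = 15L)
  amp <- list(vt_make(100, "A", "G", 4, status = "fail_qual", run_id = 1L,
                      depth = 40),
              vt_make(100, "A", "G", 5, status = "fail_depth", run_id = 2L,
                      depth = 45))
  wgs <- vt_make(100, "A", "G", 6, status = "fail_qual", method = "wgs",
                 depth = 30)
  rec <- classify_conflicts(merge_methods(clo, amp, wgs))
  expect_identical(nrow(rec), 1L)
  expect_true(rec$consensus)
  expect_identical(as.character(rec$verdict), "consensus_variant")
  # the same failed calls with no second method are not consensus
  rec2 <- classify_conflicts(merge_methods(NULL, amp, NULL))
  expect_false(rec2$consensus)
})

test_that("singleton clone alleles are excluded and named artifacts", {
  clo <- vt_make(c(100, 130), c("A", "C"), c("G", "T"), c(4, 1),
                 method = "cloning", depth = 15, n_clones = 15L)
  amp <- list(vt_make(100, "A", "G", 300, run_id = 1L),
              vt_make(100, "A", "G", 310, run_id = 2L))
  wgs <- vt_make(100, "A", "G", 10, method = "wgs", depth = 30)
  rec <- classify_conflicts(merge_methods(clo, amp, wgs))
  rec <- rec[order(rec$position), ]
  expect_identical(as.character(rec$verdict),
                   c("consensus_variant", "cloning_artifact"))
  expect_false(rec$consensus[2])
  cv <- consensus_variants(rec)
  expect_identical(cv$position, 100L)
})

test_that("sole-method defaults: clone support two, hard filters for reads", {
  clo1 <- vt_make(c(10, 20), c("A", "C"), c("G", "T"), c(1, 2),
                  method = "cloning", depth = 15, n_clones = 15L)
  rec <- merge_methods(cloning = clo1)
  expect_identical(rec$consensus, c(FALSE, TRUE))
  amp <- list(vt_make(c(10, 20), c("A", "C"), c("G", "T"), c(300, 200),
                      status = c("pass", "fail_qd"), run_id = 1L))
  rec2 <- merge_methods(amplicon = amp)
  expect_identical(rec2$consensus, c(TRUE, FALSE))
  wgs <- vt_make(c(10, 20), c("A", "C"), c("G", "T"), c(9, 8),
                 status = c("fail_qual", "pass"), method = "wgs", depth = 30)
  rec3 <- merge_methods(wgs = wgs)
  expect_identical(rec3$consensus, c(FALSE, TRUE))
  expect_error(merge_methods(), "at least one")
})

test_that("verdicts follow the documented precedence", {
  # five alleles exercising distinct branches:
  #   pos 40: all read support is the alternate base -> reference_error
  #   pos 100: clones + both runs -> consensus_variant
  #   pos 140: both runs pass, absent from clones -> clone_undersampling
  #            (amplicon is the only read method here)
  #   pos 200: run 1 only, no WGS corroboration -> run_inconsistent
  #   pos 260: clones only, 2 clones, 15 bp from the amplicon 3' end
  #            -> amplicon_edge
  clo <- vt_make(c(40, 100, 260), c("G", "A", "T"), c("A", "G", "C"),
                 c(15, 5, 2), method = "cloning", depth = 15,
                 n_clones = 15L)
  amp <- list(
    vt_make(c(40, 100, 140, 200), c("G", "A", "C", "T"),
            c("A", "G", "T", "G"), c(2000, 250, 260, 240), run_id = 1L),
    vt_make(c(40, 100, 140), c("G", "A", "C"), c("A", "G", "T"),
            c(2000, 255, 250), run_id = 2L))
  rec <- classify_conflicts(merge_methods(clo, amp, NULL),
                            amplicon_geometry = list(end = 275, window = 50))
  rec <- rec[order(rec$position), ]
  expect_identical(as.character(rec$verdict),
                   c("reference_error", "consensus_variant",
                     "clone_undersampling", "run_inconsistent",
                     "amplicon_edge"))
  # the reference-error site outranks consensus despite 3-way presence
  expect_true(rec$consensus[rec$position == 40])
  # far from the edge the same cloning-only allele is ambiguous
  rec2 <- classify_conflicts(merge_methods(clo, amp, NULL),
                             amplicon_geometry = list(end = 1000,
                                                      window = 50))
  expect_identical(as.character(rec2$verdict[rec2$position == 260]),
                   "ambiguous")
})

test_that("consistent amplicon-only alleles contradicted by WGS are false calls", {
  amp <- list(vt_make(90, "A", "C", 300, run_id = 1L),
              vt_make(90, "A", "C", 310, run_id = 2L))
  wgs <- vt_make(len = 300L, method = "wgs", depth = 30)  # covered, no call
  rec <- classify_conflicts(merge_methods(NULL, amp, wgs))
  expect_identical(as.character(rec$verdict), "amplicon_false_call")
})

test_that("consensus variants missed by cloning are annotated", {
  amp <- list(vt_make(100, "A", "G", 300, run_id = 1L),
              vt_make(100, "A", "G", 310, run_id = 2L))
  wgs <- vt_make(100, "A", "G", 10, method = "wgs", depth = 30)
  clo <- vt_make(method = "cloning", depth = 15, n_clones = 15L)
  rec <- classify_conflicts(merge_methods(clo, amp, wgs))
  expect_identical(as.character(rec$verdict), "consensus_variant")
  expect_identical(rec$conflict, "inadequate_clone_sampling")
})

test_that("every record receives exactly one verdict from the taxonomy", {
  cfg <- rdna_pipeline_config(seed = 6L)
  res <- run_pipeline(cfg)
  v <- res$records$verdict
  expect_false(anyNA(v))
  expect_true(all(as.character(v) %in%
                    rdnavar:::CONFLICT_VERDICTS))
})

test_that("artefact correction masks singleton columns only", {
  u <- tiny_unit()
  its <- substr(u$sequence, 61, 170)
  ref_chars <- strsplit(its, "")[[1]]
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  hapB <- its
  true_pos <- c(10L, 30L, 50L, 70L, 90L)
  for (p in true_pos) substr(hapB, p, p) <- other(ref_chars[p])
  clones <- c(rep(its, 10), rep(hapB, 5))
  err_pos <- c(20L, 42L, 66L)
  for (i in 1:3) {
    substr(clones[i], err_pos[i], err_pos[i]) <- other(ref_chars[err_pos[i]])
  }
  cls <- structure(list(clones = setNames(clones, paste0("c", 1:15)),
                        source = rep("h1", 15), region = "ITS",
                        error_rate = 5e-4, n_errors = 3L),
                   class = "clone_set")
  det <- detect_clone_variants(cls, u)
  expect_identical(nrow(det$table), 8L)
  # read methods corroborate the five true alleles only
  tp <- det$table[det$table$alt_count == 5, ]
  amp <- list(vt_make(tp$position, tp$ref, tp$alt, 600, run_id = 1L),
              vt_make(tp$position, tp$ref, tp$alt, 620, run_id = 2L))
  wgs <- vt_make(tp$position, tp$ref, tp$alt, 10, method = "wgs",
                 depth = 30)
  rec <- classify_conflicts(merge_methods(det$table, amp, wgs))
  expect_identical(sum(rec$verdict == "cloning_artifact"), 3L)
  corr <- correct_clone_alignment(det$alignment, rec, u)
  expect_identical(corr$report$n_masked, 3L)
  expect_identical(corr$report$raw_variant_sites, 8L)
  expect_identical(corr$report$corrected_variant_sites, 5L)
  # the corrected alignment carries the consensus variation only
  expect_identical(ncol(corr$alignment$matrix),
                   ncol(det$alignment$matrix) - 3L)
  # masking removed mismatch columns, so max p-distance cannot grow
  expect_lte(corr$report$corrected_max_p, corr$report$raw_max_p)
})
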