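SC <- list(match = 2L, mismatch = -3L, gap_open = -5L, gap_extend = -2L)

test_that("global aligner matches the exhaustive affine oracle", {
  withr::with_seed(101, {
    for (i in 1:60) {
      a <- random_seq(sample(2:7, 1))
      b <- random_seq(sample(2:7, 1))
      got <- rdnavar:::nw_align_cpp(a, b, SC$match, SC$mismatch, SC$gap_open,
                                    SC$gap_extend, FALSE)
      want <- brute_affine_global(a, b, SC$match, SC$mismatch, SC$gap_open,
                                  SC$gap_extend)
      expect_identical(got$score, as.integer(want))
      # returned alignment must rescore to the reported optimum
      qa <- strsplit(got$a_aln, "")[[1]]
      ra <- strsplit(got$b_aln, "")[[1]]
      expect_identical(rescore_alignment(qa, ra, SC), got$score)
    }
  })
})

test_that("semiglobal aligner matches the exhaustive oracle", {
  withr::with_seed(102, {
    for (i in 1:40) {
      a <- random_seq(sample(2:6, 1))
      b <- random_seq(sample(3:9, 1))
      got <- rdnavar:::nw_align_cpp(a, b, SC$match, SC$mismatch, SC$gap_open,
                                    SC$gap_extend, TRUE)
      want <- brute_affine_semiglobal(a, b, SC$match, SC$mismatch,
                                      SC$gap_open, SC$gap_extend)
      expect_identical(got$score, as.integer(want))
    }
  })
})

test_that("banded semiglobal equals full semiglobal on indel reads", {
  withr::with_seed(103, {
    for (i in 1:50) {
      ref <- random_seq(300)
      st <- sample(1:140, 1)
      q <- substr(ref, st, st + 119)
      p <- sample(20:100, 1)
      q <- if (runif(1) < 0.5) {
        paste0(substr(q, 1, p), substr(q, p + 2, nchar(q)))      # deletion
      } else {
        paste0(substr(q, 1, p), sample(DNA_BASES, 1),
               substr(q, p + 1, nchar(q)))                        # insertion
      }
      for (e in sample(seq_len(nchar(q)), 2)) {
        substr(q, e, e) <- sample(DNA_BASES, 1)
      }
      full <- rdnavar:::nw_align_cpp(q, ref, SC$match, SC$mismatch,
                                     SC$gap_open, SC$gap_extend, TRUE)
      band <- rdnavar:::nw_banded_cpp(q, ref, SC$match, SC$mismatch,
                                      SC$gap_open, SC$gap_extend,
                                      st - 1L, 16L)
      expect_identical(band$score, full$score)
    }
  })
})

test_that("align_to_reference returns equal-length gapped strings", {
  a <- align_to_reference("ACGTACGT", "ACGTTACGT")
  expect_s3_class(a, "pairwise_alignment")
  expect_identical(nchar(a$query_aln), nchar(a$ref_aln))
  expect_identical(gsub("-", "", a$query_aln), "ACGTACGT")
  expect_identical(gsub("-", "", a$ref_aln), "ACGTTACGT")
  expect_error(align_to_reference("", "ACGT"), "non-empty")
})

test_that("pileup from error-free reads reproduces allele frequencies", {
  u <- make_reference_unit(seed = 21)
  hs <- make_haplotypes_exact(u, 6, 2, 3, seed = 22)
  runs <- simulate_amplicon_reads(hs, "ITS", depth = 400, read_length = 150,
                                  error_rate = 0, n_runs = 1, seed = 23)
  pu <- build_pileup(runs[[1]], u, region = "ITS", band = 16)
  expect_s3_class(pu, "pileup")
  expect_identical(pu$n_unmapped, 0L)
  vt <- call_variants(pu, base_error = 1e-4, min_alt_count = 5)
  tv <- hs$true_variant_sites
  got <- sort(paste(vt$position, vt$alt))
  want <- sort(paste(tv$pos, tv$alt))
  expect_identical(got, want)
  # observed frequencies close to truth (binomial noise at depth ~400)
  m <- match(paste(vt$position, vt$alt), paste(tv$pos, tv$alt))
  expect_lt(max(abs(vt$frequency - tv$freq[m])), 0.08)
})

test_that("reverse-complement reads map to the same pileup columns", {
  u <- tiny_unit()
  ref <- u$sequence
  fwd_read <- substr(ref, 50, 149)
  rc_read <- rdnavar:::revcomp_cpp(fwd_read)
  pu <- build_pileup(c(fwd_read, rc_read), ref, end_trim = 0)
  expect_identical(sum(pu$fwd), 100L)
  expect_identical(sum(pu$rev), 100L)
  expect_identical(unname(pu$depth[50:149]), rep(2L, 100))
})

test_that("identity floor rejects foreign reads", {
  u <- tiny_unit()
  junk <- withr::with_seed(5, random_seq(100))
  pu <- build_pileup(c(substr(u$sequence, 1, 100), junk), u$sequence)
  expect_identical(pu$n_mapped, 1L)
  expect_identical(pu$n_unmapped, 1L)
})

test_that("end trimming suppresses the deletion edge artifact", {
  # reference ...TT...; template carries a deletion of one T; a read ending
  # exactly one base past the deletion has a score-optimal gapless
  # alignment ending in a spurious substitution
  withr::with_seed(31, {
    left <- random_seq(120)
    right <- paste0("A", random_seq(119))  # first base after the TT run != T
    ref <- paste0(left, "TT", right)
    template <- paste0(left, "T", right)  # one T deleted
    # read of 101 bp ending exactly one base after the deleted T
    read <- substr(template, 22, 122)
    expect_identical(nchar(read), 101L)
    pu0 <- build_pileup(read, ref, end_trim = 0)
    pu2 <- build_pileup(read, ref, end_trim = 2)
    # untrimmed: terminal base lands as a substitution on the second T
    expect_identical(sum(pu0$fwd["del", ]) + sum(pu0$rev["del", ]), 0L)
    # trimmed: no spurious substitution survives at the TT site
    mism0 <- unname(sum(pu0$fwd[1:4, 122] + pu0$rev[1:4, 122]) -
                      (pu0$fwd["T", 122] + pu0$rev["T", 122]))
    mism2 <- unname(sum(pu2$fwd[1:4, 122] + pu2$rev[1:4, 122]) -
                      (pu2$fwd["T", 122] + pu2$rev["T", 122]))
    expect_identical(mism0, 1L)
    expect_identical(mism2, 0L)
  })
})

test_that("empty read vector yields an empty pileup", {
  u <- tiny_unit()
  pu <- build_pileup(character(0), u)
  expect_identical(pu$n_reads, 0L)
  expect_identical(sum(pu$depth), 0L)
})
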