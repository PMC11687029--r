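make_pileup <- function(ref_seq, fwd, rev,
                        insertions = data.frame(pos = integer(),
                                                seq = character(),
                                                strand = character())) {
  rownames(fwd) <- rownames(rev) <- c("A", "C", "G", "T", "del")
  structure(list(ref_seq = ref_seq, offset = 0L, fwd = fwd, rev = rev,
                 depth = as.integer(colSums(fwd) + colSums(rev)),
                 insertions = insertions, n_reads = sum(fwd) + sum(rev),
                 n_mapped = NA_integer_, n_unmapped = 0L),
            class = "pileup")
}

# balanced-strand count matrices for a reference string, depth per site
ref_counts <- function(ref_seq, depth) {
  chars <- strsplit(ref_seq, "")[[1]]
  m <- matrix(0L, 5, length(chars),
              dimnames = list(c("A", "C", "G", "T", "del"), NULL))
  for (i in seq_along(chars)) m[chars[i], i] <- as.integer(depth / 2)
  m
}

test_that("qual, qd and fs match direct binomial and Fisher computations", {
  ref <- "ACGTACGTAC"
  fwd <- ref_counts(ref, 1000)
  rev <- ref_counts(ref, 1000)
  # site 4 (ref T): alt G with 60 fwd / 40 rev reads
  fwd["T", 4] <- 440L; rev["T", 4] <- 460L
  fwd["G", 4] <- 60L; rev["G", 4] <- 40L
  pu <- make_pileup(ref, fwd, rev)
  vt <- call_variants(pu, base_error = 0.001, min_alt_count = 5)
  expect_identical(nrow(vt), 1L)
  expect_identical(vt$position, 4L)
  expect_identical(vt$alt, "G")
  expect_identical(vt$depth, 1000L)
  expect_identical(vt$alt_count, 100L)
  expect_equal(vt$frequency, 0.1)
  qual_o <- -10 * log10(pbinom(99, 1000, 0.001, lower.tail = FALSE))
  expect_equal(vt$qual, qual_o, tolerance = 1e-10)
  expect_equal(vt$qd, qual_o / 1000, tolerance = 1e-10)
  fs_o <- -10 * log10(stats::fisher.test(
    matrix(c(440, 460, 60, 40), 2))$p.value)
  expect_equal(vt$fs, fs_o, tolerance = 1e-8)
  # at 10% frequency and depth 1000 the call is strong but quality does
  # not scale with depth: QD = QUAL/1000 < 2, so the qd filter fires
  expect_lt(qual_o / 1000, 2)
  expect_identical(vt$filter_status, "fail_qd")

  # a balanced 50% allele at depth 200 passes every filter
  fwd2 <- ref_counts(ref, 200); rev2 <- ref_counts(ref, 200)
  fwd2["T", 4] <- 50L; rev2["T", 4] <- 50L
  fwd2["G", 4] <- 50L; rev2["G", 4] <- 50L
  vt2 <- call_variants(make_pileup(ref, fwd2, rev2),
                       base_error = 0.001, min_alt_count = 5)
  expect_identical(vt2$filter_status, "pass")
  expect_equal(vt2$frequency, 0.5)
})

test_that("min_alt_count gates emission", {
  ref <- "ACGTACGTAC"
  fwd <- ref_counts(ref, 1000); rev <- ref_counts(ref, 1000)
  fwd["A", 2] <- 2L; rev["A", 2] <- 2L   # 4 alt reads
  fwd["T", 6] <- 3L; rev["T", 6] <- 2L   # 5 alt reads
  pu <- make_pileup(ref, fwd, rev)
  vt <- call_variants(pu, min_alt_count = 5)
  expect_identical(vt$position, 6L)
  vt2 <- call_variants(pu, min_alt_count = 4)
  expect_identical(vt2$position, c(2L, 6L))
})

test_that("depth threshold is 10% of mean called-site depth with a floor", {
  ref <- strrep("ACGT", 5)
  # two called sites with very different depths: 5750 and 250
  fwd <- ref_counts(ref, 5750); rev <- ref_counts(ref, 5750)
  fwd[, 7] <- fwd[, 7] %/% 23L; rev[, 7] <- rev[, 7] %/% 23L  # depth 250
  fwd["A", 3] <- 2875L; rev["A", 3] <- 2875L   # 50% allele, depth 11500
  fwd["C", 7] <- 10L; rev["C", 7] <- 10L
  pu <- make_pileup(ref, fwd, rev)
  vt <- call_variants(pu, min_alt_count = 5)
  expect_identical(nrow(vt), 2L)
  # mean depth over called sites = (11500 + 270)/2 = 5885 -> threshold 588.5
  expect_equal(attr(vt, "dp_threshold"), 588.5)
  expect_identical(vt$filter_status[vt$position == 7], "fail_depth")
  expect_identical(vt$filter_status[vt$position == 3], "pass")
  # the floor applies when depths are moderate
  expect_equal(variant_filters()$dp_floor, 200)
  # a fixed dp threshold overrides the rule
  vt3 <- call_variants(pu, min_alt_count = 5,
                       thresholds = variant_filters(dp = 20000))
  expect_true(all(vt3$filter_status == "fail_depth"))
})

test_that("filter cascade matches an independent re-derivation", {
  withr::with_seed(44, {
    for (rep in 1:10) {
      ref <- random_seq(12)
      d <- sample(c(100, 400, 3000), 12, replace = TRUE)
      fwd <- ref_counts(ref, 0); rev <- ref_counts(ref, 0)
      chars <- strsplit(ref, "")[[1]]
      for (i in 1:12) {
        fr <- sample(0:d[i], 1)
        fwd[chars[i], i] <- fr; rev[chars[i], i] <- d[i] - fr
      }
      # sprinkle alt alleles with varied support and strand balance
      for (i in sample(1:12, 4)) {
        al <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
        ac <- sample(c(5, 8, 30, 300), 1)
        af <- sample(0:ac, 1)
        fwd[al, i] <- af; rev[al, i] <- ac - af
      }
      pu <- make_pileup(ref, fwd, rev)
      vt <- call_variants(pu, base_error = 0.002, min_alt_count = 5)
      if (!nrow(vt)) next
      thr <- max(200, 0.10 * mean(vt$depth))
      for (j in seq_len(nrow(vt))) {
        p <- vt$position[j]
        qual <- -10 / log(10) * pbinom(vt$alt_count[j] - 1, vt$depth[j],
                                       0.002, lower.tail = FALSE,
                                       log.p = TRUE)
        fs <- -10 * log10(max(stats::fisher.test(matrix(c(
          fwd[chars[p], p], rev[chars[p], p],
          fwd[vt$alt[j], p], rev[vt$alt[j], p]), 2))$p.value, 1e-300))
        want <- if (vt$depth[j] < thr) "fail_depth"
          else if (qual / vt$depth[j] < 2.0) "fail_qd"
          else if (qual < 30.0) "fail_qual"
          else if (fs > 200.0) "fail_fs"
          else "pass"
        expect_identical(vt$filter_status[j], want)
      }
    }
  })
})

test_that("indel calls are left-aligned in homopolymers", {
  ref <- "GGCAAATTCC"
  fwd <- ref_counts(ref, 100); rev <- ref_counts(ref, 100)
  fwd["del", 6] <- 10L; rev["del", 6] <- 10L   # deletes the 3rd A
  ins <- data.frame(pos = rep(6L, 12),
                    seq = rep("A", 12),
                    strand = rep(c("+", "-"), 6),
                    stringsAsFactors = FALSE)
  pu <- make_pileup(ref, fwd, rev, insertions = ins)
  vt <- call_variants(pu, min_alt_count = 5,
                      thresholds = variant_filters(dp = 10))
  del <- vt[vt$alt == "-", ]
  expect_identical(del$position, 4L)   # leftmost A of the run
  expect_identical(del$ref, "A")
  insc <- vt[startsWith(vt$alt, "+"), ]
  expect_identical(insc$position, 3L)  # anchored before the A run
  expect_identical(insc$alt, "+A")
  expect_identical(insc$alt_count, 12L)
})

test_that("three of ten clones sharing an allele give frequency 0.3", {
  u <- tiny_unit()
  its <- substr(u$sequence, 61, 170)
  pos_local <- 40L
  ref_base <- substr(its, pos_local, pos_local)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  mut <- its
  substr(mut, pos_local, pos_local) <- alt_base
  cls <- structure(list(clones = setNames(c(rep(its, 7), rep(mut, 3)),
                                          paste0("c", 1:10)),
                        source = rep("h1", 10), region = "ITS",
                        error_rate = 0, n_errors = 0L),
                   class = "clone_set")
  det <- detect_clone_variants(cls, u)
  expect_identical(nrow(det$table), 1L)
  expect_identical(det$table$position, 60L + pos_local)
  expect_identical(det$table$alt, alt_base)
  expect_identical(det$table$alt_count, 3L)
  expect_equal(det$table$frequency, 0.3)
  expect_identical(attr(det$table, "n_clones"), 10L)
})

test_that("a single erroneous clone among twelve yields one singleton call", {
  u <- tiny_unit()
  its <- substr(u$sequence, 61, 170)
  bad <- its
  substr(bad, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                 substr(its, 20, 20))[1]
  cls <- structure(list(clones = setNames(c(rep(its, 11), bad),
                                          paste0("c", 1:12)),
                        source = rep("h1", 12), region = "ITS",
                        error_rate = 5e-4, n_errors = 1L),
                   class = "clone_set")
  det <- detect_clone_variants(cls, u)
  expect_identical(nrow(det$table), 1L)
  expect_identical(det$table$alt_count, 1L)
  expect_equal(det$table$frequency, 1 / 12)
  # clone calls carry no read-level quality annotations
  expect_true(is.na(det$table$qual))
  expect_error(detect_clone_variants(
    structure(list(clones = c(c1 = its), region = "ITS"),
              class = "clone_set"), u), "2 clones")
})
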