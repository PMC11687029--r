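# End-to-end pipeline: generate a ground-truth rDNA array, observe it
# through the three detection arms, call and filter variants, reconcile
# across methods, and summarize distances, haplotypes and copy number.

#' Pipeline configuration
#'
#' Defaults describe the study conditions the package is calibrated
#' around: a ~4.7 kb rDNA unit (partial 18S 1683 bp, ITS 846 bp, partial
#' 28S 2165 bp), 4 haplotypes over 8 total repeat copies (so every carried
#' allele has frequency >= 1/8), 15 ITS variant sites (10 substitutions,
#' 5 single-base indels), 15 sequenced clones with 5e-4 per-base process
#' error, two amplicon runs at nominal depth 2000 with 20% run-to-run
#' depth jitter, and WGS at 10x genome coverage.
#'
#' @param seed Master seed; all stages derive their seeds from it.
#' @param region_lengths Named region lengths for [make_reference_unit()].
#' @param gc GC fraction of unit and background.
#' @param n_haplotypes,copy_counts Haplotype structure (see
#'   [make_haplotypes_exact()]).
#' @param its_substitutions,its_indels Exact ITS variant-site counts.
#' @param region Region cloned/amplified (default `"ITS"`).
#' @param n_clones,clone_error Clone library size and per-base error.
#' @param amplicon_depth,read_length,amplicon_error,n_runs,run_depth_jitter
#'   Amplicon arm parameters.
#' @param wgs_coverage,background_len,wgs_error WGS arm parameters.
#' @param base_error,min_alt_count,filters Variant-caller parameters (see
#'   [call_variants()]).
#' @param identity_floor Mapper identity floor.
#' @param band Mapper band half-width; must exceed the largest indel a read
#'   can span (the default generator introduces single-base indels only).
#' @param gap_mode p-distance gap handling.
#' @param edge_window Amplicon 3'-end window for conflict classification.
#' @return An object of class `rdna_pipeline_config`.
#' @export
rdna_pipeline_config <- function(seed = 1L,
                                 region_lengths = c(SSU18S = 1683, ITS1 = 300,
                                                    R5_8S = 160, ITS2 = 386,
                                                    LSU28S = 2165),
                                 gc = 0.5,
                                 n_haplotypes = 4L, copy_counts = NULL,
                                 its_substitutions = 10L, its_indels = 5L,
                                 region = "ITS",
                                 n_clones = 15L, clone_error = 5e-4,
                                 amplicon_depth = 2000, read_length = 150L,
                                 amplicon_error = 0.001, n_runs = 2L,
                                 run_depth_jitter = 0.2,
                                 wgs_coverage = 10, background_len = 1e5,
                                 wgs_error = 0.001,
                                 base_error = 0.001, min_alt_count = 5L,
                                 filters = variant_filters(),
                                 identity_floor = 0.9, band = 16L,
                                 gap_mode = "pairwise_deletion",
                                 edge_window = 50L) {
  cfg <- as.list(environment())
  structure(cfg, class = "rdna_pipeline_config")
}

#' @export
print.rdna_pipeline_config <- function(x, ...) {
  cat("rdna_pipeline_config (seed", x$seed, ")\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes generate -> simulate (cloning, amplicon, WGS) -> align/call ->
#' reconcile -> distances/trees/haplotypes -> copy number. The result is a
#' pure function of the configuration (including its seed).
#'
#' @param config An `rdna_pipeline_config`.
#' @param out_dir Optional directory; when given, all artifacts (FASTA,
#'   truth TSV, VCFs, consensus report, distance matrices, newick trees,
#'   summary tables, config YAML) are written there as plain text.
#' @return An object of class `rdna_pipeline` holding every intermediate
#'   and summary (see `summary()` and `print()` methods).
#' @export
run_pipeline <- function(config = rdna_pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "rdna_pipeline_config"))
  cfg <- config
  sc <- default_scoring()

  unit <- run_stage("generate_unit",
    make_reference_unit(cfg$region_lengths, cfg$gc, cfg$seed))
  hapset <- run_stage("generate_haplotypes",
    make_haplotypes_exact(unit, cfg$its_substitutions, cfg$its_indels,
                          cfg$n_haplotypes, cfg$copy_counts, cfg$region,
                          seed = cfg$seed + 1L))
  genome <- run_stage("assemble_genome",
    assemble_genome(hapset, cfg$background_len, TRUE, cfg$gc,
                    seed = cfg$seed + 2L))

  clones <- run_stage("sample_clones",
    sample_clones(hapset, cfg$n_clones, cfg$clone_error,
                  seed = cfg$seed + 3L, region = cfg$region))
  amp_reads <- run_stage("simulate_amplicon",
    simulate_amplicon_reads(hapset, cfg$region, cfg$amplicon_depth,
                            cfg$read_length, cfg$amplicon_error,
                            cfg$n_runs, cfg$run_depth_jitter,
                            seed = cfg$seed + 4L))
  wgs_reads <- run_stage("simulate_wgs",
    simulate_wgs_reads(genome, cfg$wgs_coverage, cfg$read_length,
                       cfg$wgs_error, seed = cfg$seed + 5L))

  clone_det <- run_stage("detect_clone_variants",
    detect_clone_variants(clones, unit, sc))
  amp_tables <- run_stage("call_amplicon", lapply(seq_along(amp_reads),
    function(r) {
      pu <- build_pileup(amp_reads[[r]], unit, sc, region = cfg$region,
                         band = cfg$band, identity_floor = cfg$identity_floor)
      call_variants(pu, cfg$base_error, cfg$min_alt_count, cfg$filters,
                    method = "amplicon", run_id = r)
    }))
  wgs_table <- run_stage("call_wgs", {
    pu <- build_pileup(wgs_reads, unit, sc, band = cfg$band,
                       identity_floor = cfg$identity_floor)
    call_variants(pu, cfg$base_error, cfg$min_alt_count, cfg$filters,
                  method = "wgs")
  })

  rc <- run_stage("run_consistency", compute_run_consistency(amp_tables))
  records <- run_stage("merge_methods",
    merge_methods(cloning = clone_det$table, amplicon = rc,
                  wgs = wgs_table))
  amp_end <- region_bounds(unit, cfg$region)[2]
  records <- run_stage("classify_conflicts",
    classify_conflicts(records,
                       amplicon_geometry = list(end = amp_end,
                                                window = cfg$edge_window)))
  corr <- run_stage("correct_alignment",
    correct_clone_alignment(clone_det$alignment, records, unit,
                            gap_mode = cfg$gap_mode))

  dist_raw <- p_distance_matrix(clone_det$alignment, cfg$gap_mode)
  dist_cor <- p_distance_matrix(corr$alignment, cfg$gap_mode)
  tree_raw <- tryCatch(neighbor_joining(dist_raw), error = function(e) NULL)
  tree_cor <- tryCatch(neighbor_joining(dist_cor), error = function(e) NULL)
  haps_raw <- count_haplotypes(clone_det$alignment)
  haps_cor <- count_haplotypes(corr$alignment)

  cn_stats <- run_stage("copy_number",
    mapping_stats_from_reads(wgs_reads, unit, genome$assembly,
                             cfg$identity_floor, sc))
  cn_est <- estimate_rdna_copy_number(cn_stats)

  result <- structure(list(
    config = cfg, unit = unit, hapset = hapset, genome = genome,
    clones = clones, amplicon_reads = amp_reads, wgs_reads = wgs_reads,
    clone_table = clone_det$table, clone_alignment = clone_det$alignment,
    amplicon_tables = amp_tables, wgs_table = wgs_table,
    run_consistency = rc, records = records,
    corrected_alignment = corr$alignment, correction = corr$report,
    dist_raw = dist_raw, dist_corrected = dist_cor,
    tree_raw = tree_raw, tree_corrected = tree_cor,
    haplotypes_raw = haps_raw, haplotypes_corrected = haps_cor,
    copy_number = cn_est,
    variant_summary = NULL, conflict_summary = NULL, recovery = NULL),
    class = "rdna_pipeline")
  result$variant_summary <- variant_site_summary(result)
  result$conflict_summary <- conflict_tally(result)
  result$recovery <- consensus_vs_truth(result)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

is_indel_allele <- function(alt) alt == "-" | startsWith(alt, "+")

# per-region, per-method discovered variant-site counts in the
# "substitutions/indels [runs or clones]" cell format
variant_site_summary <- function(result) {
  unit <- result$unit
  cell <- function(df, n_lab) {
    if (!nrow(df)) return(sprintf("0/0 [%d]", n_lab))
    sprintf("%d/%d [%d]", sum(!is_indel_allele(df$alt)),
            sum(is_indel_allele(df$alt)), n_lab)
  }
  regions <- c("18S", "ITS", "28S")
  # amplicon: union of PASS calls over runs
  amp <- unique(do.call(rbind, lapply(result$amplicon_tables, function(t) {
    as.data.frame(t)[t$filter_status == "pass", c("position", "alt")]
  })))
  wgs <- as.data.frame(result$wgs_table)
  wgs <- wgs[wgs$filter_status == "pass", c("position", "alt")]
  clo <- as.data.frame(result$clone_table)
  clo <- clo[clo$alt_count >= 2, c("position", "alt")]  # singletons excluded
  n_runs <- length(result$amplicon_tables)
  n_clones <- length(result$clones$clones)
  out <- data.frame(region = regions, stringsAsFactors = FALSE)
  out$amplicon <- vapply(regions, function(rg) {
    cell(amp[region_of_position(unit, amp$position) == rg, , drop = FALSE],
         n_runs)
  }, "")
  out$wgs <- vapply(regions, function(rg) {
    cell(wgs[region_of_position(unit, wgs$position) == rg, , drop = FALSE], 1L)
  }, "")
  out$cloning <- vapply(regions, function(rg) {
    cell(clo[region_of_position(unit, clo$position) == rg, , drop = FALSE],
         n_clones)
  }, "")
  out
}

# verdict tally in the conflict-taxonomy rows
conflict_tally <- function(result) {
  v <- table(result$records$verdict)
  data.frame(verdict = names(v), n = as.integer(v), stringsAsFactors = FALSE)
}

#' Compare the consensus variant set against ground truth
#'
#' @param result An `rdna_pipeline` result.
#' @return List with `sensitivity` (fraction of true sites recovered as
#'   consensus variants), `n_true`, `n_consensus`, `n_false` (consensus
#'   alleles not in the truth table), and the missed/false allele tables.
#' @export
consensus_vs_truth <- function(result) {
  truth <- result$hapset$true_variant_sites
  cons <- consensus_variants(result$records)
  tk <- paste(truth$pos, truth$alt)
  ck <- paste(cons$position, cons$alt)
  list(sensitivity = if (nrow(truth)) mean(tk %in% ck) else NA_real_,
       n_true = nrow(truth), n_consensus = nrow(cons),
       n_false = sum(!ck %in% tk),
       missed = truth[!tk %in% ck, , drop = FALSE],
       false = cons[!ck %in% tk, , drop = FALSE])
}

#' @export
print.rdna_pipeline <- function(x, ...) {
  cat("rdna_pipeline result (seed", x$config$seed, ")\n")
  cat(sprintf("  true variant sites: %d | consensus variants: %d\n",
              x$recovery$n_true, x$recovery$n_consensus))
  cat(sprintf("  sensitivity %.3f, false consensus %d\n",
              x$recovery$sensitivity, x$recovery$n_false))
  cat(sprintf("  haplotypes: %d raw -> %d corrected (true: %d)\n",
              x$haplotypes_raw$n, x$haplotypes_corrected$n,
              length(x$hapset$haplotypes)))
  cat(sprintf("  max p-distance: %.4f raw -> %.4f corrected\n",
              x$correction$raw_max_p, x$correction$corrected_max_p))
  cat(sprintf("  rDNA copies: %.1f estimated (true: %d)\n",
              x$copy_number$estimate, x$genome$total_rdna_copies))
  invisible(x)
}

#' @export
summary.rdna_pipeline <- function(object, ...) {
  print(object)
  cat("\nDiscovered variant sites (substitutions/indels [runs or clones]):\n")
  print(object$variant_summary, row.names = FALSE)
  cat("\nConflict verdicts:\n")
  print(object$conflict_summary, row.names = FALSE)
  invisible(object)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_fasta(c(unit = result$unit$sequence), fp("reference_unit.fasta"))
  write_fasta(result$hapset$haplotypes, fp("haplotypes.fasta"))
  write_fasta(result$clones$clones, fp("clones.fasta"))
  write_report(result$hapset$true_variant_sites, fp("truth_sites.tsv"))
  for (i in seq_along(result$amplicon_tables)) {
    write_vcf(result$amplicon_tables[[i]],
              fp(sprintf("amplicon_run%d.vcf", i)), result$unit)
  }
  write_vcf(result$wgs_table, fp("wgs.vcf"), result$unit)
  write_vcf(result$clone_table, fp("cloning.vcf"), result$unit)
  write_report(result$records, fp("consensus_report.tsv"))
  write_report(result$variant_summary, fp("variant_summary.tsv"))
  write_report(result$conflict_summary, fp("conflict_summary.tsv"))
  write.table(result$dist_raw, fp("p_distance_raw.tsv"), sep = "\t",
              quote = FALSE)
  write.table(result$dist_corrected, fp("p_distance_corrected.tsv"),
              sep = "\t", quote = FALSE)
  if (!is.null(result$tree_raw)) {
    write_newick(result$tree_raw, fp("nj_raw.nwk"))
  }
  if (!is.null(result$tree_corrected)) {
    write_newick(result$tree_corrected, fp("nj_corrected.nwk"))
  }
  write_config(result$config, fp("config.yaml"))
  invisible(out_dir)
}
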