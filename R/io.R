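# Plain-text I/O: FASTA/FASTQ via Biostrings, minimal VCF v4.2 writing,
# newick trees via ape, TSV reports, and YAML pipeline configs.

#' Read a FASTA file
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) {
                  stop("FASTA parse error in '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path File path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a read set to FASTQ with constant quality
#' @param reads A `read_set` or character vector.
#' @param path File path.
#' @param quality Single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  ids <- names(seqs) %||% paste0("read", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(n) {
                      strrep(quality, n)
                    }, "")), con)
  invisible(path)
}

# convert an internal allele to VCF REF/ALT/POS (indels anchored on the
# preceding base)
vcf_ref_alt <- function(pos, ref, alt, ref_chars) {
  if (alt == "-") {
    if (pos > 1) {
      list(pos = pos - 1L, ref = paste0(ref_chars[pos - 1], ref_chars[pos]),
           alt = ref_chars[pos - 1])
    } else {
      list(pos = 1L, ref = paste0(ref_chars[1], ref_chars[2]),
           alt = ref_chars[2])
    }
  } else if (startsWith(alt, "+")) {
    list(pos = pos, ref = ref_chars[pos],
         alt = paste0(ref_chars[pos], substring(alt, 2)))
  } else {
    list(pos = pos, ref = ref, alt = alt)
  }
}

#' Write a variant table as minimal VCF v4.2
#'
#' One record per (position, alt allele); indels are anchored on the
#' preceding reference base in the usual VCF way. INFO carries DP, QD, FS,
#' AF, METHOD and RUN; FILTER mirrors the hard-filter status.
#'
#' @param table A `variant_table`.
#' @param path File path.
#' @param unit The `rdna_unit` (for the contig line and indel anchors).
#' @param contig Contig name used in CHROM.
#' @export
write_vcf <- function(table, path, unit, contig = "rDNA_unit") {
  ref_chars <- strsplit(unit$sequence, "")[[1]]
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, unit_length(unit)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred Fisher strand bias\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele frequency\">",
    "##INFO=<ID=METHOD,Number=1,Type=String,Description=\"Detection method\">",
    "##INFO=<ID=RUN,Number=1,Type=String,Description=\"Run id\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- hdr
  if (nrow(table)) {
    recs <- vapply(seq_len(nrow(table)), function(i) {
      va <- vcf_ref_alt(table$position[i], table$ref[i], table$alt[i],
                        ref_chars)
      info <- sprintf("DP=%d;QD=%s;FS=%s;AF=%.6g;METHOD=%s;RUN=%s",
                      table$depth[i],
                      ifelse(is.na(table$qd[i]), ".",
                             sprintf("%.4g", table$qd[i])),
                      ifelse(is.na(table$fs[i]), ".",
                             sprintf("%.4g", table$fs[i])),
                      table$frequency[i], table$method[i],
                      ifelse(is.na(table$run_id[i]), ".",
                             as.character(table$run_id[i])))
      filt <- if (table$filter_status[i] == "pass") "PASS"
              else table$filter_status[i]
      sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s", contig, va$pos, va$ref,
              va$alt,
              ifelse(is.na(table$qual[i]), ".",
                     sprintf("%.2f", table$qual[i])),
              filt, info)
    }, "")
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a tree in newick format
#' @param tree An ape `phylo` object.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a data.frame report as TSV
#' @param records A data.frame (e.g. classified `consensus_records`).
#' @param path File path.
#' @export
write_report <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read a pipeline configuration as YAML
#' @param config An `rdna_pipeline_config` (or plain list).
#' @param path File path.
#' @export
write_config <- function(config, path) {
  # named atomic vectors must become maps, or YAML drops their names
  x <- lapply(unclass(config), function(v) {
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("region_lengths", "copy_counts")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (!is.null(cfg$filters)) {
    cfg$filters <- do.call(variant_filters, cfg$filters)
  }
  do.call(rdna_pipeline_config, cfg)
}
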