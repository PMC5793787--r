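# Readers and writers for the package's plain-text exchange formats.

#' Write junction evidence as TSV
#'
#' Tab-separated, header line, 0-based half-open intron coordinates;
#' columns `chrom`, `intron_start`, `intron_end`, `strand`, `gene_id`,
#' `barcode`, `read_count`.
#'
#' @param evidence Junction-evidence tibble (see [build_evidence()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_tsv <- function(evidence, path) {
  evidence %>%
    transmute(.data$chrom, intron_start = .data$start,
              intron_end = .data$end, .data$strand, .data$gene_id,
              .data$barcode, .data$read_count) %>%
    arrange(.data$gene_id, .data$intron_start, .data$intron_end,
            .data$barcode) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Read junction evidence from TSV
#'
#' Inverse of [write_evidence_tsv()].
#'
#' @param path TSV path.
#' @return Junction-evidence tibble with internal column names.
#' @export
read_evidence_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = "c", intron_start = "d", intron_end = "d",
                    strand = "c", gene_id = "c", barcode = "c",
                    read_count = "d")) %>%
    rename(start = "intron_start", end = "intron_end")
}

#' Write an annotation tibble as GTF
#'
#' Emits exon and CDS records with `gene_id`, `transcript_id` and
#' `gene_type` attributes, converting the internal 0-based half-open
#' coordinates back to GTF's 1-based inclusive convention.
#'
#' @param annotation Exon/CDS tibble (see [read_gtf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_type "%s";',
    annotation$gene_id, annotation$tx_id,
    ifelse(is.na(annotation$gene_type), "other", annotation$gene_type))
  lines <- paste(annotation$chrom, "spliceclouds", annotation$feature,
                 format(annotation$start + 1, scientific = FALSE,
                        trim = TRUE),
                 format(annotation$end, scientific = FALSE, trim = TRUE),
                 ".", annotation$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write junction evidence as a minimal barcoded SAM file
#'
#' Expands each evidence row into `read_count` spliced reads whose CIGAR
#' spans the intron with equal anchors on both sides and whose barcode is
#' stored in the `BX` tag. Useful to exercise the alignment-based entry
#' point against evidence-level expectations.
#'
#' @param evidence Junction-evidence tibble (see [build_evidence()]).
#' @param path Output SAM path.
#' @param read_length Total aligned bases per read (split across the two
#'   anchors).
#' @return `path`, invisibly.
#' @export
write_evidence_sam <- function(evidence, path, read_length = 98) {
  anchor <- read_length %/% 2
  ev <- evidence %>% arrange(.data$chrom, .data$start, .data$barcode)
  seqs <- ev %>% group_by(.data$chrom) %>%
    summarise(len = max(.data$end) + read_length + 1000, .groups = "drop")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", seqs$chrom, as.integer(seqs$len)))
  idx <- rep.int(seq_len(nrow(ev)), ev$read_count)
  pos <- pmax(1L, as.integer(ev$start[idx] - anchor + 1))
  left <- as.integer(ev$start[idx]) - pos + 1L
  gap <- as.integer(ev$end[idx] - ev$start[idx])
  cigar <- sprintf("%dM%dN%dM", left, gap, anchor)
  lines <- paste(sprintf("r%07d", seq_along(idx)), 0L, ev$chrom[idx], pos,
                 60L, cigar, "*", 0L, 0L,
                 strrep("A", left + anchor), "*",
                 paste0("BX:Z:", ev$barcode[idx]), sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write per-gene QC table
#'
#' Combines collision and expression summaries into one TSV: barcodes,
#' collisions, collision fraction, molecule calls and MPM per gene.
#'
#' @param collisions Result of [detect_collisions()].
#' @param mpm Result of [compute_mpm()].
#' @param path Output path.
#' @return The combined tibble, invisibly.
#' @export
write_gene_qc_tsv <- function(collisions, mpm, path) {
  qc <- collisions$gene_summary %>%
    full_join(mpm, by = "gene_id") %>%
    arrange(.data$gene_id)
  readr::write_tsv(qc, path)
  invisible(qc)
}
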