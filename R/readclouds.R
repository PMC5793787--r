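#' Read barcoded spliced alignments from SAM/BAM
#'
#' Loads mapped records together with their droplet barcode. The barcode is
#' taken from the `barcode_tag` (default `BX`); when absent and `name_sep`
#' is given, the part of the read name after the last separator is used as
#' a fallback.
#'
#' @param path SAM or BAM file. SAM text is converted on the fly via
#'   Rsamtools.
#' @param barcode_tag Two-letter tag holding the barcode (default `"BX"`).
#' @param name_sep Optional separator character; barcode parsed from the
#'   read name after its last occurrence when the tag is missing.
#' @return Tibble of mapped records: `qname`, `chrom`, `pos` (1-based
#'   leftmost), `cigar`, `barcode` (`NA` when unrecoverable).
#' @export
read_barcoded_sam <- function(path, barcode_tag = "BX", name_sep = NULL) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = barcode_tag
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  barcode <- res$tag[[barcode_tag]]
  if (is.null(barcode)) barcode <- rep(NA_character_, length(res$qname))
  out <- tibble(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    barcode = as.character(barcode)
  )
  if (!is.null(name_sep)) {
    miss <- is.na(out$barcode)
    parsed <- stringr::str_extract(out$qname[miss],
                                   paste0("[^", name_sep, "]+$"))
    out$barcode[miss] <- parsed
  }
  out %>%
    filter(bitwAnd(.data$flag, 4L) == 0L, !is.na(.data$pos)) %>%
    select(-"flag")
}

# Walk one CIGAR string and return the reference-skipped (N) segments whose
# flanking aligned blocks each cover at least `min_anchor` reference bases.
# `pos` is the 1-based leftmost mapped position; returned coordinates are
# 0-based half-open on the reference.
cigar_junctions_one <- function(pos, cigar, min_anchor) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  if (nrow(m) == 0) return(NULL)
  len <- as.integer(m[, 2]); op <- m[, 3]
  ref_consuming <- op %in% c("M", "D", "N", "=", "X")
  aligned <- op %in% c("M", "=", "X")
  ref0 <- pos - 1  # 0-based cursor
  # anchors: aligned bases in the contiguous non-N run on each side of
  # every N operation
  n_idx <- which(op == "N")
  if (length(n_idx) == 0) return(NULL)
  starts <- ref0 + c(0, cumsum(len * ref_consuming))[seq_along(len)]
  run <- cumsum(op == "N")  # block id between N gaps
  block_of <- run - (op == "N")  # N belongs to neither side
  aligned_per_block <- tapply(len * aligned, block_of, sum)
  out <- purrr::map(n_idx, function(i) {
    left <- aligned_per_block[as.character(run[i] - 1)]
    right <- aligned_per_block[as.character(run[i])]
    if (is.na(left) || is.na(right) ||
        left < min_anchor || right < min_anchor) return(NULL)
    c(start = starts[i], end = starts[i] + len[i])
  })
  out <- purrr::compact(out)
  if (length(out) == 0) NULL else do.call(rbind, out)
}

#' Extract splice junctions from aligned records
#'
#' One junction per reference-skipped (CIGAR `N`) segment whose flanking
#' aligned blocks each cover at least `min_anchor` reference bases; the
#' anchor requirement suppresses false-positive junction mappings.
#' Unspliced records contribute nothing.
#'
#' @param alignments Tibble as returned by [read_barcoded_sam()].
#' @param min_anchor Minimum aligned reference bases required on either
#'   side of the junction (default 6).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open intron
#'   coordinates), `barcode`, `qname`, one row per junction observation.
#' @export
extract_junctions <- function(alignments, min_anchor = 6) {
  stopifnot(min_anchor >= 0)
  if (nrow(alignments) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  barcode = character(), qname = character()))
  }
  spliced <- grepl("N", alignments$cigar, fixed = TRUE)
  al <- alignments[spliced, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(al)), function(i) {
    j <- cigar_junctions_one(al$pos[i], al$cigar[i], min_anchor)
    if (is.null(j)) return(NULL)
    tibble(chrom = al$chrom[i], start = unname(j[, "start"]),
           end = unname(j[, "end"]),
           barcode = al$barcode[i], qname = al$qname[i])
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    tibble(chrom = character(), start = double(), end = double(),
           barcode = character(), qname = character())
  } else {
    out
  }
}

#' Build per-intron junction evidence and barcode statistics
#'
#' Assigns each extracted junction to the unique gene whose annotated
#' intron set (optionally extended by `extra_junctions`) contains it.
#' Junctions matching zero or several genes are dropped and counted, as
#' are records without a barcode. Reads sharing a barcode and gene are
#' treated as evidence for one molecule of that gene in that droplet.
#'
#' @param alignments Tibble as returned by [read_barcoded_sam()].
#' @param annotation Exon/CDS tibble as returned by [read_gtf()].
#' @param extra_junctions Optional tibble (`chrom`, `start`, `end`,
#'   `gene_id`) of additional accepted junctions (e.g. from long-read
#'   data).
#' @param min_anchor Passed to [extract_junctions()].
#' @return List with `evidence` (tibble: `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `barcode`, `read_count`), `barcode_stats`
#'   (tibble: `barcode`, `total_reads`, `spliced_gene_count`), and
#'   `counters` (barcode-less reads, unassigned and multi-gene junctions).
#' @export
build_evidence <- function(alignments, annotation, extra_junctions = NULL,
                           min_anchor = 6) {
  introns <- gene_introns(annotation)
  if (!is.null(extra_junctions)) {
    extra <- extra_junctions %>%
      transmute(.data$gene_id, .data$chrom,
                strand = if ("strand" %in% names(extra_junctions))
                  .data$strand else NA_character_,
                .data$start, .data$end)
    introns <- bind_rows(introns, extra) %>%
      distinct(.data$gene_id, .data$chrom, .data$start, .data$end,
               .keep_all = TRUE)
  }

  n_no_barcode <- sum(is.na(alignments$barcode))
  al <- filter(alignments, !is.na(.data$barcode))
  jx <- extract_junctions(al, min_anchor = min_anchor)

  hits <- jx %>%
    inner_join(introns, by = c("chrom", "start", "end"),
               relationship = "many-to-many")
  genes_per_jx <- hits %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop")
  ambiguous <- genes_per_jx %>% filter(.data$n_genes > 1)
  matched_keys <- genes_per_jx %>% filter(.data$n_genes == 1) %>%
    select("chrom", "start", "end")
  n_unassigned <- jx %>%
    anti_join(genes_per_jx, by = c("chrom", "start", "end")) %>% nrow()

  evidence <- hits %>%
    semi_join(matched_keys, by = c("chrom", "start", "end")) %>%
    group_by(.data$chrom, .data$start, .data$end, .data$strand,
             .data$gene_id, .data$barcode) %>%
    summarise(read_count = dplyr::n(), .groups = "drop")

  barcode_stats <- al %>%
    count(.data$barcode, name = "total_reads") %>%
    left_join(
      evidence %>% group_by(.data$barcode) %>%
        summarise(spliced_gene_count = dplyr::n_distinct(.data$gene_id),
                  .groups = "drop"),
      by = "barcode") %>%
    mutate(spliced_gene_count = dplyr::coalesce(.data$spliced_gene_count, 0L))

  list(
    evidence = evidence,
    barcode_stats = barcode_stats,
    counters = list(
      no_barcode = n_no_barcode,
      unassigned_junctions = n_unassigned,
      multi_gene_junctions = nrow(ambiguous)
    )
  )
}

#' Call molecules from junction evidence
#'
#' A molecule of a gene is called for a barcode when at least `k` spliced
#' reads of that barcode span an intron of the gene (reads summed across
#' the gene's introns). The number of calls is non-increasing in `k`.
#'
#' @param evidence Junction-evidence tibble (see [build_evidence()]).
#' @param k Minimum spliced-read support (default 1).
#' @return Tibble with `gene_id`, `barcode`, `spliced_read_support`.
#' @export
call_molecules <- function(evidence, k = 1) {
  stopifnot(k >= 1)
  if (nrow(evidence) == 0) {
    return(tibble(gene_id = character(), barcode = character(),
                  spliced_read_support = double()))
  }
  evidence %>%
    group_by(.data$gene_id, .data$barcode) %>%
    summarise(spliced_read_support = sum(.data$read_count),
              .groups = "drop") %>%
    filter(.data$spliced_read_support >= k)
}

#' Barcode quality control and misidentification rate
#'
#' Barcodes with few reads are likely false barcode identifications.
#' Retains barcodes with more than `read_cutoff` reads and reports the
#' fraction of molecule calls whose barcode falls at or below the cutoff.
#'
#' @param barcode_stats Tibble from [build_evidence()].
#' @param molecule_calls Tibble from [call_molecules()].
#' @param read_cutoff Read-count cutoff (e.g. 1000 or 100).
#' @return List with `retained` (character vector of barcodes) and
#'   `misidentification_rate`.
#' @export
barcode_qc <- function(barcode_stats, molecule_calls, read_cutoff) {
  stopifnot(read_cutoff >= 0)
  if (nrow(barcode_stats) == 0) abort("no barcode statistics supplied")
  retained <- barcode_stats$barcode[barcode_stats$total_reads > read_cutoff]
  rate <- if (nrow(molecule_calls) == 0) 0 else {
    low <- barcode_stats$barcode[barcode_stats$total_reads <= read_cutoff]
    mean(molecule_calls$barcode %in% low)
  }
  list(retained = retained, misidentification_rate = rate)
}

# Per-exon splicing status of every (exon, barcode) with evidence.
# Status: "included" (inclusion intron only), "skipped" (skip intron
# only), "conflict" (both). Barcodes with neither do not appear.
exon_barcode_status <- function(evidence, exons) {
  if (nrow(evidence) == 0 || nrow(exons) == 0) {
    return(tibble(gene_id = character(), exon_id = character(),
                  barcode = character(), status = character()))
  }
  inc <- bind_rows(
    exons %>% transmute(.data$gene_id, .data$exon_id,
                        start = .data$flank_start, end = .data$exon_start),
    exons %>% transmute(.data$gene_id, .data$exon_id,
                        start = .data$exon_end, end = .data$flank_end)
  ) %>% mutate(kind = "inclusion")
  skp <- exons %>%
    transmute(.data$gene_id, .data$exon_id,
              start = .data$flank_start, end = .data$flank_end,
              kind = "skip")
  bind_rows(inc, skp) %>%
    inner_join(evidence, by = c("gene_id", "start", "end"),
               relationship = "many-to-many") %>%
    group_by(.data$gene_id, .data$exon_id, .data$barcode) %>%
    summarise(has_inc = any(.data$kind == "inclusion"),
              has_skip = any(.data$kind == "skip"), .groups = "drop") %>%
    mutate(status = dplyr::case_when(
      .data$has_inc & .data$has_skip ~ "conflict",
      .data$has_inc ~ "included",
      TRUE ~ "skipped"
    )) %>%
    select("gene_id", "exon_id", "barcode", "status")
}

#' Detect collisions (conflicting spliced mappings per droplet)
#'
#' A gene-barcode pair is flagged as a collision when the barcode carries
#' evidence for an inclusion intron and the skipping intron of the same
#' skippable exon (mode `"exon"`, default), or more generally for any two
#' overlapping but non-identical introns of the gene (mode `"overlap"`).
#' Collisions indicate two non-identical molecules of the gene in one
#' droplet and are removed from coordination analysis.
#'
#' @param evidence Junction-evidence tibble (see [build_evidence()]).
#' @param exons Skippable exons from [pure_skipping_exons()] (used by mode
#'   `"exon"`).
#' @param mode `"exon"` or `"overlap"`.
#' @return List with `calls` (tibble `gene_id`, `barcode`, `collision`)
#'   and `gene_summary` (tibble `gene_id`, `barcodes`, `collisions`,
#'   `collision_fraction`).
#' @export
detect_collisions <- function(evidence, exons = NULL,
                              mode = c("exon", "overlap")) {
  mode <- match.arg(mode)
  pairs <- evidence %>% distinct(.data$gene_id, .data$barcode)
  if (mode == "exon") {
    if (is.null(exons)) abort("mode 'exon' requires skippable exons")
    st <- exon_barcode_status(evidence, exons)
    coll <- st %>% filter(.data$status == "conflict") %>%
      distinct(.data$gene_id, .data$barcode) %>%
      mutate(collision = TRUE)
  } else {
    coll <- evidence %>%
      distinct(.data$gene_id, .data$barcode, .data$start, .data$end) %>%
      arrange(.data$gene_id, .data$barcode, .data$start, .data$end) %>%
      group_by(.data$gene_id, .data$barcode) %>%
      summarise(
        collision = any(.data$start < dplyr::lag(cummax(.data$end)),
                        na.rm = TRUE),
        .groups = "drop") %>%
      filter(.data$collision) %>%
      select("gene_id", "barcode", "collision")
  }
  calls <- pairs %>%
    left_join(coll, by = c("gene_id", "barcode")) %>%
    mutate(collision = dplyr::coalesce(.data$collision, FALSE))
  gene_summary <- calls %>%
    group_by(.data$gene_id) %>%
    summarise(barcodes = dplyr::n(), collisions = sum(.data$collision),
              collision_fraction = mean(.data$collision), .groups = "drop")
  list(calls = calls, gene_summary = gene_summary)
}

#' Molecules per million (MPM)
#'
#' Expression of a gene as its molecule calls divided by the total number
#' of detected molecules in millions. Values over all genes sum to 1e6.
#'
#' @param molecule_calls Tibble from [call_molecules()].
#' @return Tibble with `gene_id`, `molecules`, `mpm`.
#' @export
compute_mpm <- function(molecule_calls) {
  if (nrow(molecule_calls) == 0) abort("no molecule calls")
  total <- nrow(molecule_calls)
  molecule_calls %>%
    count(.data$gene_id, name = "molecules") %>%
    mutate(mpm = .data$molecules / (total / 1e6))
}

#' Estimate total molecules from spliced molecules
#'
#' Spliced molecules are directly observable via junction-spanning reads;
#' about two-thirds of molecules in long-read data are spliced, so the
#' total is estimated by dividing by that fraction.
#'
#' @param spliced_count Number of spliced molecules detected.
#' @param spliced_fraction Assumed fraction of molecules that are spliced
#'   (default 2/3).
#' @return Estimated total molecule count.
#' @examples
#' estimate_total_molecules(11.6e6)  # 17.4e6
#' @export
estimate_total_molecules <- function(spliced_count, spliced_fraction = 2 / 3) {
  if (spliced_fraction <= 0 || spliced_fraction > 1) {
    abort("`spliced_fraction` must lie in (0, 1]")
  }
  stopifnot(spliced_count >= 0)
  spliced_count / spliced_fraction
}

#' Percent spliced-in per skippable exon
#'
#' Over non-collision barcodes of the gene, a barcode counts as inclusion
#' when it shows evidence for at least one inclusion intron and no
#' skipping intron, and as exclusion when it shows the skipping intron
#' only. Psi = inclusion / (inclusion + exclusion). Exons with no
#' informative barcode are absent from the result.
#'
#' @param evidence Junction-evidence tibble (see [build_evidence()]).
#' @param exons Skippable exons from [pure_skipping_exons()].
#' @param collisions Optional result of [detect_collisions()]; flagged
#'   gene-barcode pairs are excluded.
#' @return Tibble with `gene_id`, `exon_id`, `n_inclusion`, `n_exclusion`,
#'   `psi`.
#' @export
compute_psi <- function(evidence, exons, collisions = NULL) {
  st <- exon_barcode_status(evidence, exons)
  if (!is.null(collisions)) {
    bad <- collisions$calls %>% filter(.data$collision)
    st <- st %>% anti_join(bad, by = c("gene_id", "barcode"))
  }
  st %>%
    filter(.data$status != "conflict") %>%
    group_by(.data$gene_id, .data$exon_id) %>%
    summarise(n_inclusion = sum(.data$status == "included"),
              n_exclusion = sum(.data$status == "skipped"),
              .groups = "drop") %>%
    filter(.data$n_inclusion + .data$n_exclusion > 0) %>%
    mutate(psi = .data$n_inclusion / (.data$n_inclusion + .data$n_exclusion))
}
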