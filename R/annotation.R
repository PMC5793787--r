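#' Read a GTF annotation into a tidy exon/CDS table
#'
#' Parses a GENCODE-style GTF file and returns one row per exon or CDS
#' segment. Coordinates are converted from the GTF's 1-based inclusive
#' convention to the 0-based half-open convention used throughout the
#' package, so interval arithmetic (intron gaps, overlaps) needs no further
#' off-by-one bookkeeping.
#'
#' Transcripts whose exons overlap one another are rejected with a warning;
#' a structurally malformed line (fewer than nine tab-separated fields)
#' aborts with the offending line number.
#'
#' @param path Path to a GTF file. `gene_id` and `transcript_id` attribute
#'   keys are required on exon records; `gene_type` (or `gene_biotype`) is
#'   carried through when present.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `feature` (`"exon"` or `"CDS"`), `gene_id`,
#'   `tx_id`, `gene_type`.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
#'   "gene_id \"g1\"; transcript_id \"t1\";", sep = "\t"), gtf)
#' read_gtf(gtf)  # exon stored as [100, 200)
#' @export
read_gtf <- function(path) {
  empty <- tibble(
    chrom = character(), start = double(), end = double(),
    strand = character(), feature = character(),
    gene_id = character(), tx_id = character(), gene_type = character()
  )
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(data_idx) == 0) return(empty)
  nfield <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    abort(paste0("malformed GTF line ", data_idx[which(nfield < 9)[1]],
                 ": expected 9 tab-separated fields"))
  }

  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0) return(empty)

  gene_type <- if ("gene_type" %in% names(df)) {
    df$gene_type
  } else if ("gene_biotype" %in% names(df)) {
    df$gene_biotype
  } else {
    rep(NA_character_, nrow(df))
  }
  ann <- tibble(
    chrom = as.character(df$seqnames),
    start = as.double(df$start - 1L),
    end = as.double(df$end),
    strand = as.character(df$strand),
    feature = as.character(df$type),
    gene_id = df$gene_id,
    tx_id = df$transcript_id,
    gene_type = gene_type
  )
  if (any(is.na(ann$gene_id)) || any(is.na(ann$tx_id))) {
    abort("exon/CDS records must carry gene_id and transcript_id attributes")
  }

  # Reject transcripts with internally overlapping exons.
  bad_tx <- ann %>%
    filter(.data$feature == "exon") %>%
    arrange(.data$tx_id, .data$start) %>%
    group_by(.data$tx_id) %>%
    summarise(bad = any(.data$start < lag(.data$end), na.rm = TRUE),
              .groups = "drop") %>%
    filter(.data$bad) %>%
    pull(.data$tx_id)
  if (length(bad_tx) > 0) {
    warn(paste0("rejecting ", length(bad_tx),
                " transcript(s) with overlapping exons: ",
                paste(head(bad_tx, 5), collapse = ", ")))
    ann <- ann %>% filter(!.data$tx_id %in% bad_tx)
  }
  ann %>% arrange(.data$gene_id, .data$tx_id, .data$start)
}

#' Derive introns for every transcript
#'
#' Introns are the gaps between consecutive exons of a transcript, in
#' genomic order, 0-based half-open.
#'
#' @param annotation Exon/CDS tibble as returned by [read_gtf()].
#' @return Tibble with `gene_id`, `tx_id`, `chrom`, `strand`, `start`,
#'   `end`, one row per intron.
#' @export
transcript_introns <- function(annotation) {
  annotation %>%
    filter(.data$feature == "exon") %>%
    arrange(.data$gene_id, .data$tx_id, .data$start) %>%
    group_by(.data$gene_id, .data$tx_id, .data$chrom, .data$strand) %>%
    reframe(i_start = head(.data$end, -1), i_end = .data$start[-1]) %>%
    rename(start = "i_start", end = "i_end") %>%
    filter(.data$end > .data$start)
}

#' Distinct annotated introns per gene
#'
#' @param annotation Exon/CDS tibble as returned by [read_gtf()].
#' @return Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_introns <- function(annotation) {
  transcript_introns(annotation) %>%
    distinct(.data$gene_id, .data$chrom, .data$strand, .data$start, .data$end)
}

# Constitutive exons of one gene: exon intervals contained in every
# transcript whose genomic span covers them. `ex` is the gene's exon
# tibble.
constitutive_exons_one <- function(ex) {
  spans <- ex %>%
    group_by(.data$tx_id) %>%
    summarise(span_start = min(.data$start), span_end = max(.data$end),
              .groups = "drop")
  cand <- distinct(ex, .data$start, .data$end)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    s <- cand$start[i]; e <- cand$end[i]
    covering <- spans$tx_id[spans$span_start <= s & spans$span_end >= e]
    if (length(covering) == 0) return(FALSE)
    has <- ex %>%
      filter(.data$start == s, .data$end == e) %>%
      distinct(.data$tx_id) %>% pull(.data$tx_id)
    all(covering %in% has)
  }, logical(1))
  cand[keep, , drop = FALSE]
}

# Is exon interval [s, e) entirely coding in transcript `tx` given that
# transcript's CDS rows?
exon_fully_coding <- function(cds_tx, s, e) {
  if (nrow(cds_tx) == 0) return(FALSE)
  ov <- pmin(cds_tx$end, e) - pmax(cds_tx$start, s)
  sum(ov[ov > 0]) >= (e - s)
}

classify_pure_skipping_one <- function(ex, cds) {
  out <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    exon_start = double(), exon_end = double(),
    flank_start = double(), flank_end = double(),
    coding_status = character(), frame_preserving = logical()
  )
  if (dplyr::n_distinct(ex$tx_id) < 2) return(out)
  ex <- arrange(ex, .data$tx_id, .data$start)
  spans <- ex %>%
    group_by(.data$tx_id) %>%
    summarise(span_start = min(.data$start), span_end = max(.data$end),
              .groups = "drop")
  introns <- ex %>%
    group_by(.data$tx_id) %>%
    reframe(i_start = .data$end[-dplyr::n()], i_end = .data$start[-1]) %>%
    filter(.data$i_end > .data$i_start)

  # Internal exon occurrences with their per-transcript flanking introns.
  internal <- ex %>%
    group_by(.data$tx_id) %>%
    mutate(prev_end = lag(.data$end), next_start = lead(.data$start)) %>%
    ungroup() %>%
    filter(!is.na(.data$prev_end), !is.na(.data$next_start))
  if (nrow(internal) == 0) return(out)

  cand <- distinct(internal, .data$start, .data$end)
  rows <- purrr::pmap(cand, function(start, end) {
    s <- start; e <- end
    occ <- internal %>% filter(.data$start == s, .data$end == e)
    u_starts <- unique(occ$prev_end)
    d_ends <- unique(occ$next_start)
    # A unique pair of inclusion introns: alternative flanking splice
    # sites disqualify the exon as a pure skipping event.
    if (length(u_starts) != 1 || length(d_ends) != 1) return(NULL)
    us <- u_starts; de <- d_ends

    # Exon boundaries must be identical in every overlapping transcript.
    ov <- ex %>% filter(.data$start < e, .data$end > s)
    if (any(ov$start != s | ov$end != e)) return(NULL)
    # The exon must be internal wherever it appears.
    n_containing <- ex %>% filter(.data$start == s, .data$end == e) %>%
      distinct(.data$tx_id) %>% nrow()
    if (n_containing != nrow(distinct(occ, .data$tx_id))) return(NULL)

    # A transcript must splice directly across (skip intron).
    has_skip <- any(introns$i_start == us & introns$i_end == de)
    if (!has_skip) return(NULL)

    # No transcript may retain either inclusion intron.
    retained_u <- any(ex$start <= us & ex$end >= s & !(ex$start == s & ex$end == e))
    retained_d <- any(ex$start <= e & ex$end >= de & !(ex$start == s & ex$end == e))
    if (retained_u || retained_d) return(NULL)

    # No transcript may begin or end strictly inside the skip-intron span
    # (annotation-level proxy for alternative TSS / poly(A) interference).
    inside <- (spans$span_start > us & spans$span_start < de) |
      (spans$span_end > us & spans$span_end < de)
    if (any(inside)) return(NULL)

    # Every transcript spanning the region must either include the exon
    # (with introns u and d) or carry the skip intron.
    spanning <- spans$tx_id[spans$span_start <= us & spans$span_end >= de]
    includes <- occ$tx_id
    skips <- introns %>%
      filter(.data$i_start == us, .data$i_end == de) %>% pull(.data$tx_id)
    if (!all(spanning %in% c(includes, skips))) return(NULL)

    coding <- if (nrow(cds) == 0) {
      "contains_noncoding"
    } else {
      all_cov <- vapply(unique(occ$tx_id), function(t) {
        exon_fully_coding(cds[cds$tx_id == t, , drop = FALSE], s, e)
      }, logical(1))
      if (all(all_cov)) "entirely_coding" else "contains_noncoding"
    }
    tibble(
      gene_id = ex$gene_id[1], chrom = ex$chrom[1], strand = ex$strand[1],
      exon_start = s, exon_end = e, flank_start = us, flank_end = de,
      coding_status = coding,
      frame_preserving = ((e - s) %% 3) == 0
    )
  })
  bind_rows(out, purrr::compact(rows))
}

#' Classify pure exon-skipping events
#'
#' A pure exon-skipping event is an internal exon that is either included
#' or skipped in all transcripts overlapping it, with no interference from
#' annotated alternative splice sites, alternative transcript starts or
#' ends inside the skipped region, or retention of either flanking intron.
#' Each returned exon therefore has exactly one upstream inclusion intron
#' `[flank_start, exon_start)`, one downstream inclusion intron
#' `[exon_end, flank_end)`, and one skipping intron
#' `[flank_start, flank_end)` annotated in at least one transcript.
#'
#' Coding status is `"entirely_coding"` only when every base of the exon
#' lies within annotated CDS in every transcript containing it;
#' genes without CDS records (e.g. lincRNAs) yield
#' `"contains_noncoding"`. `frame_preserving` records whether the exon
#' length is divisible by three.
#'
#' @param annotation Exon/CDS tibble as returned by [read_gtf()].
#' @return Tibble with one row per skippable exon: `gene_id`, `chrom`,
#'   `strand`, `exon_start`, `exon_end`, `flank_start`, `flank_end`,
#'   `coding_status`, `frame_preserving`, `exon_id`.
#' @export
pure_skipping_exons <- function(annotation) {
  ex <- filter(annotation, .data$feature == "exon")
  cds <- filter(annotation, .data$feature == "CDS")
  res <- ex %>%
    group_split(.data$gene_id) %>%
    purrr::map(~ classify_pure_skipping_one(
      .x, cds[cds$gene_id == .x$gene_id[1], , drop = FALSE])) %>%
    bind_rows()
  if (nrow(res) == 0) {
    return(mutate(res, exon_id = character()))
  }
  res %>%
    mutate(exon_id = exon_key(.data$gene_id, .data$exon_start, .data$exon_end)) %>%
    arrange(.data$gene_id, .data$exon_start)
}

#' Enumerate skippable-exon pairs separated by constitutive exons
#'
#' Forms all pairs of distinct pure exon-skipping events of a gene that
#' have at least one constitutive exon strictly between them (a
#' constitutive exon being one contained, with identical boundaries, in
#' every transcript whose span covers it). Each unordered pair appears
#' once, with `first` the 5'-most event in transcript orientation.
#'
#' @param annotation Exon/CDS tibble as returned by [read_gtf()].
#' @param exons Optional precomputed result of [pure_skipping_exons()].
#' @return Tibble with one row per pair: exon coordinates and ids for the
#'   first and second event, `separated` (always `TRUE`),
#'   `intermediate_bases` (maximum over transcripts of annotated exonic
#'   bases strictly between the two exons), `pair_coding`
#'   (`"entirely_coding"` iff both exons are), and
#'   `both_frame_preserving`.
#' @export
separated_exon_pairs <- function(annotation, exons = NULL) {
  if (is.null(exons)) exons <- pure_skipping_exons(annotation)
  ex_all <- filter(annotation, .data$feature == "exon")
  empty <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    first_exon_id = character(), second_exon_id = character(),
    first_start = double(), first_end = double(),
    second_start = double(), second_end = double(),
    separated = logical(), intermediate_bases = double(),
    pair_coding = character(), both_frame_preserving = logical()
  )
  if (nrow(exons) == 0) return(empty)

  per_gene <- exons %>% group_split(.data$gene_id) %>% purrr::map(function(gx) {
    if (nrow(gx) < 2) return(NULL)
    g <- gx$gene_id[1]
    ex <- ex_all[ex_all$gene_id == g, , drop = FALSE]
    const <- constitutive_exons_one(ex)
    gx <- arrange(gx, .data$exon_start)
    combos <- utils::combn(nrow(gx), 2)
    rows <- purrr::map(seq_len(ncol(combos)), function(j) {
      a <- gx[combos[1, j], ]; b <- gx[combos[2, j], ]  # a genomically left
      sep <- any(const$start >= a$exon_end & const$end <= b$exon_start)
      if (!sep) return(NULL)
      inter <- ex %>%
        mutate(ov = pmin(.data$end, b$exon_start) - pmax(.data$start, a$exon_end)) %>%
        filter(.data$ov > 0) %>%
        group_by(.data$tx_id) %>%
        summarise(bases = sum(.data$ov), .groups = "drop")
      inter_bases <- if (nrow(inter) == 0) 0 else max(inter$bases)
      # transcript orientation: on "-" the genomically-right exon is first
      if (a$strand == "-") { tmp <- a; a <- b; b <- tmp }
      tibble(
        gene_id = g, chrom = a$chrom, strand = a$strand,
        first_exon_id = a$exon_id, second_exon_id = b$exon_id,
        first_start = a$exon_start, first_end = a$exon_end,
        second_start = b$exon_start, second_end = b$exon_end,
        separated = TRUE, intermediate_bases = as.double(inter_bases),
        pair_coding = if (a$coding_status == "entirely_coding" &&
                          b$coding_status == "entirely_coding")
          "entirely_coding" else "contains_noncoding",
        both_frame_preserving = a$frame_preserving && b$frame_preserving
      )
    })
    bind_rows(purrr::compact(rows))
  })
  res <- bind_rows(purrr::compact(per_gene))
  if (nrow(res) == 0) empty else arrange(res, .data$gene_id, .data$first_start)
}

# Build alternative donor/acceptor events of one gene. Returns a list of
# events; each event is a tibble of intron forms sharing the anchor side.
alt_site_events <- function(intr, strand, kind) {
  # kind "donor": forms differ on the donor side, share the acceptor.
  # On "+" the donor is the intron start and the acceptor its end;
  # on "-" the donor is the intron end and the acceptor its start.
  anchor_col <- if (kind == "donor") {
    if (strand == "+") "end" else "start"
  } else {
    if (strand == "+") "start" else "end"
  }
  split(intr, intr[[anchor_col]]) |>
    purrr::keep(~ nrow(distinct(.x, .data$start, .data$end)) >= 2) |>
    purrr::map(~ distinct(.x, .data$start, .data$end))
}

#' Find the terminal alternative donor/acceptor pair of each gene
#'
#' For each gene, builds alternative donor events (two or more donors
#' sharing one acceptor) and alternative acceptor events (two or more
#' acceptors sharing one donor), selects the most upstream donor event and
#' the most downstream acceptor event, and retains the pair only when the
#' donor event lies upstream of the acceptor event with at least one
#' constitutive exon guaranteed between the two splice sites in all
#' transcripts. When an event has more than two forms, the two with the
#' highest support are kept (support = distinct barcodes in `evidence`
#' when supplied, otherwise the number of annotated transcripts using the
#' form).
#'
#' `donor_class` is `"first"` when either retained donor form is the donor
#' of an annotated first exon; `acceptor_class` is `"last"` analogously.
#' `category` combines the two (`"first-last"`, `"first-internal"`,
#' `"internal-last"`, `"internal-internal"`).
#'
#' @param annotation Exon/CDS tibble as returned by [read_gtf()].
#' @param evidence Optional junction-evidence tibble (see
#'   [build_evidence()]) used to rank event forms by molecule support.
#' @return Tibble with at most one row per gene: anchors, the two retained
#'   forms of each event (`*_form1_*` is the better-supported), classes
#'   and `category`. Genes without a qualifying pair are absent.
#' @export
terminal_site_pairs <- function(annotation, evidence = NULL) {
  ex_all <- filter(annotation, .data$feature == "exon")
  tin <- transcript_introns(annotation)
  empty <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    donor_anchor = double(),
    donor_form1_start = double(), donor_form1_end = double(),
    donor_form2_start = double(), donor_form2_end = double(),
    donor_class = character(), acceptor_anchor = double(),
    acceptor_form1_start = double(), acceptor_form1_end = double(),
    acceptor_form2_start = double(), acceptor_form2_end = double(),
    acceptor_class = character(), category = character()
  )
  if (nrow(tin) == 0) return(empty)

  support_of <- function(g, intr) {
    if (!is.null(evidence)) {
      ev <- evidence %>% filter(.data$gene_id == g)
      counts <- ev %>%
        group_by(.data$start, .data$end) %>%
        summarise(n = dplyr::n_distinct(.data$barcode), .groups = "drop")
      intr %>% left_join(counts, by = c("start", "end")) %>%
        mutate(support = dplyr::coalesce(.data$n, 0L)) %>%
        select(-dplyr::any_of("n"))
    } else {
      counts <- tin %>% filter(.data$gene_id == g) %>%
        count(.data$start, .data$end, name = "support")
      intr %>% left_join(counts, by = c("start", "end"))
    }
  }

  res <- tin %>% group_split(.data$gene_id) %>% purrr::map(function(gi) {
    g <- gi$gene_id[1]; strand <- gi$strand[1]; chrom <- gi$chrom[1]
    intr <- distinct(gi, .data$start, .data$end)
    donors <- alt_site_events(intr, strand, "donor")
    acceptors <- alt_site_events(intr, strand, "acceptor")
    if (length(donors) == 0 || length(acceptors) == 0) return(NULL)

    # most upstream donor event / most downstream acceptor event
    d_pos <- vapply(donors, function(e)
      if (strand == "+") min(e$start) else -max(e$end), double(1))
    donor_ev <- donors[[which.min(d_pos)]]
    a_pos <- vapply(acceptors, function(e)
      if (strand == "+") -max(e$end) else min(e$start), double(1))
    acceptor_ev <- acceptors[[which.min(a_pos)]]

    if (strand == "+") {
      donor_anchor <- donor_ev$end[1]
      acceptor_anchor <- acceptor_ev$start[1]
      region <- c(donor_anchor, acceptor_anchor)
    } else {
      donor_anchor <- donor_ev$start[1]
      acceptor_anchor <- acceptor_ev$end[1]
      region <- c(acceptor_anchor, donor_anchor)
    }
    if (region[1] > region[2]) return(NULL)
    const <- constitutive_exons_one(ex_all[ex_all$gene_id == g, , drop = FALSE])
    if (!any(const$start >= region[1] & const$end <= region[2])) return(NULL)

    rank2 <- function(ev) {
      ev <- support_of(g, ev) %>%
        arrange(desc(.data$support), .data$start, .data$end)
      ev[1:2, ]
    }
    d2 <- rank2(donor_ev); a2 <- rank2(acceptor_ev)

    first_donors <- gi %>% group_by(.data$tx_id) %>%
      summarise(pos = if (strand[1] == "+")
        .data$start[which.min(.data$start)] else .data$end[which.max(.data$end)],
        .groups = "drop") %>% pull(.data$pos)
    last_acceptors <- gi %>% group_by(.data$tx_id) %>%
      summarise(pos = if (strand[1] == "+")
        .data$end[which.max(.data$end)] else .data$start[which.min(.data$start)],
        .groups = "drop") %>% pull(.data$pos)
    donor_side <- if (strand == "+") d2$start else d2$end
    acceptor_side <- if (strand == "+") a2$end else a2$start
    donor_class <- if (any(donor_side %in% first_donors)) "first" else "internal"
    acceptor_class <- if (any(acceptor_side %in% last_acceptors)) "last" else "internal"

    tibble(
      gene_id = g, chrom = chrom, strand = strand,
      donor_anchor = donor_anchor,
      donor_form1_start = d2$start[1], donor_form1_end = d2$end[1],
      donor_form2_start = d2$start[2], donor_form2_end = d2$end[2],
      donor_class = donor_class,
      acceptor_anchor = acceptor_anchor,
      acceptor_form1_start = a2$start[1], acceptor_form1_end = a2$end[1],
      acceptor_form2_start = a2$start[2], acceptor_form2_end = a2$end[2],
      acceptor_class = acceptor_class,
      category = paste0(donor_class, "-", acceptor_class)
    )
  })
  out <- bind_rows(purrr::compact(res))
  if (nrow(out) == 0) empty else out
}

#' Mature (spliced) gene length
#'
#' The length of a gene is the length of its longest transcript with
#' introns excluded, i.e. the maximum over transcripts of summed exon
#' lengths.
#'
#' @param annotation Exon/CDS tibble as returned by [read_gtf()].
#' @return Tibble with `gene_id` and `mature_length`.
#' @export
mature_lengths <- function(annotation) {
  ex <- filter(annotation, .data$feature == "exon")
  if (nrow(ex) == 0) abort("annotation contains no exon records")
  ex %>%
    group_by(.data$gene_id, .data$tx_id) %>%
    summarise(len = sum(.data$end - .data$start), .groups = "drop") %>%
    group_by(.data$gene_id) %>%
    summarise(mature_length = max(.data$len), .groups = "drop")
}

#' Export classified skippable exons as BED6
#'
#' One BED line per exon; name is `gene_id|coding_status`, score 0, strand
#' from the gene.
#'
#' @param exons Result of [pure_skipping_exons()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_skippable_bed <- function(exons, path) {
  bed <- exons %>%
    transmute(.data$chrom, start = .data$exon_start, end = .data$exon_end,
              name = paste0(.data$gene_id, "|", .data$coding_status),
              score = 0L, .data$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
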