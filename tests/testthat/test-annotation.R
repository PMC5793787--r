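test_that("GTF parsing converts coordinates and handles edge cases", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "g1"; transcript_id "%s"; gene_type "protein_coding";'
  lines <- c(
    paste("chr1", "x", "exon", 101, 200, ".", "+", ".",
          sprintf(attrs, "t1"), sep = "\t"),
    paste("chr1", "x", "exon", 301, 400, ".", "+", ".",
          sprintf(attrs, "t1"), sep = "\t"),
    paste("chr1", "x", "exon", 501, 600, ".", "+", ".",
          sprintf(attrs, "t1"), sep = "\t"),
    paste("chr1", "x", "exon", 101, 200, ".", "+", ".",
          sprintf(attrs, "t2"), sep = "\t"),
    paste("chr1", "x", "exon", 501, 600, ".", "+", ".",
          sprintf(attrs, "t2"), sep = "\t")
  )
  writeLines(lines, gtf)
  ann <- read_gtf(gtf)
  expect_equal(nrow(ann), 5)
  # 1-based [101,200] becomes [100,200)
  expect_equal(min(ann$start), 100)
  expect_equal(max(ann$end), 600)
  tin <- transcript_introns(ann)
  inc <- tin[tin$tx_id == "t1", c("start", "end")]
  expect_equal(as.data.frame(inc),
               data.frame(start = c(200, 400), end = c(300, 500)))
  skp <- tin[tin$tx_id == "t2", c("start", "end")]
  expect_equal(as.data.frame(skp), data.frame(start = 200, end = 500))

  # empty file parses to an empty tibble
  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines("# nothing here", empty)
  expect_equal(nrow(read_gtf(empty)), 0)

  # malformed line names its line number
  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(lines[1], "chr1\tonly\tthree"), bad)
  expect_error(read_gtf(bad), "line 2")

  # transcripts with overlapping exons are rejected with a warning
  ovl <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(lines,
               paste("chr1", "x", "exon", 101, 250, ".", "+", ".",
                     sprintf(attrs, "t3"), sep = "\t"),
               paste("chr1", "x", "exon", 201, 300, ".", "+", ".",
                     sprintf(attrs, "t3"), sep = "\t")), ovl)
  expect_warning(ann2 <- read_gtf(ovl), "overlapping")
  expect_false("t3" %in% ann2$tx_id)
})

test_that("pure skipping classification finds clean events only", {
  ann <- toy_skipping_gene()
  ex <- pure_skipping_exons(ann)
  expect_equal(nrow(ex), 1)
  expect_equal(ex$exon_start, 200)
  expect_equal(ex$exon_end, 300)
  expect_equal(ex$flank_start, 100)
  expect_equal(ex$flank_end, 400)
  expect_equal(ex$coding_status, "entirely_coding")
  # length 100 is not divisible by 3
  expect_false(ex$frame_preserving)
  # a frame-preserving variant
  ann3 <- toy_skipping_gene("gB", middle = c(200, 299))
  expect_true(pure_skipping_exons(ann3)$frame_preserving)

  # single-transcript gene yields nothing
  one_tx <- make_ann("gC", list(t1 = list(c(0, 100), c(200, 300))))
  expect_equal(nrow(pure_skipping_exons(one_tx)), 0)

  # alternative 3' splice site of the middle exon disqualifies it
  alt3 <- dplyr::bind_rows(
    toy_skipping_gene("gD"),
    make_ann("gD", list(alt = list(c(0, 100), c(180, 300), c(400, 500))))
  )
  expect_equal(nrow(pure_skipping_exons(alt3)), 0)

  # intron retention of the upstream inclusion intron disqualifies it
  ret <- dplyr::bind_rows(
    toy_skipping_gene("gE"),
    make_ann("gE", list(ret = list(c(0, 300), c(400, 500))))
  )
  expect_equal(nrow(pure_skipping_exons(ret)), 0)

  # transcript starting inside the skipped region disqualifies it
  tss <- dplyr::bind_rows(
    toy_skipping_gene("gF"),
    make_ann("gF", list(short = list(c(150, 300), c(400, 500))))
  )
  expect_equal(nrow(pure_skipping_exons(tss)), 0)

  # gene without CDS records is contains_noncoding
  nc <- toy_skipping_gene("gG", cds = FALSE)
  expect_equal(pure_skipping_exons(nc)$coding_status, "contains_noncoding")
})

test_that("every classified exon has an including and a skipping transcript", {
  cfg <- sim_config(n_genes = 5, n_skippable = 3, seed = 9)
  ann <- simulate_annotation(cfg)
  ex <- pure_skipping_exons(ann)
  tin <- transcript_introns(ann)
  for (i in seq_len(nrow(ex))) {
    g_ex <- ann[ann$gene_id == ex$gene_id[i] & ann$feature == "exon", ]
    including <- g_ex$tx_id[g_ex$start == ex$exon_start[i] &
                              g_ex$end == ex$exon_end[i]]
    skipping <- tin$tx_id[tin$gene_id == ex$gene_id[i] &
                            tin$start == ex$flank_start[i] &
                            tin$end == ex$flank_end[i]]
    expect_gt(length(including), 0)
    expect_gt(length(skipping), 0)
  }
})

test_that("separated pairs require an intervening constitutive exon", {
  # A - B(const) - C layout with both A and C skippable
  txs <- list(
    full = list(c(0, 90), c(200, 290), c(400, 490), c(600, 690),
                c(800, 890)),
    skipA = list(c(0, 90), c(400, 490), c(600, 690), c(800, 890)),
    skipC = list(c(0, 90), c(200, 290), c(400, 490), c(800, 890))
  )
  ann <- make_ann("gP", txs, cds = txs)
  ex <- pure_skipping_exons(ann)
  expect_equal(nrow(ex), 2)
  pairs <- separated_exon_pairs(ann, ex)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$first_start, 200)
  expect_equal(pairs$second_start, 600)
  # constitutive exon [400,490) lies between; its 90 bases are the
  # maximal intermediate exonic content
  expect_equal(pairs$intermediate_bases, 90)
  expect_equal(pairs$pair_coding, "entirely_coding")

  # adjacent alternative exons (no exon between) are excluded
  adj <- make_ann("gQ", list(
    full = list(c(0, 90), c(200, 290), c(400, 490), c(600, 690)),
    skipA = list(c(0, 90), c(400, 490), c(600, 690)),
    skipB = list(c(0, 90), c(200, 290), c(600, 690))
  ))
  expect_equal(nrow(separated_exon_pairs(adj)), 0)

  # three separated skippable exons give choose(3, 2) = 3 pairs,
  # each unordered pair exactly once with first upstream
  cfg <- sim_config(n_genes = 1, n_skippable = 3, seed = 1)
  ann3 <- simulate_annotation(cfg)
  p3 <- separated_exon_pairs(ann3)
  expect_equal(nrow(p3), 3)
  expect_true(all(p3$first_start < p3$second_start))
  expect_equal(nrow(dplyr::distinct(
    p3, pmin(first_start, second_start), pmax(first_start, second_start))), 3)
})

test_that("transcript orientation flips pair order on the minus strand", {
  txs <- list(
    full = list(c(0, 90), c(200, 290), c(400, 490), c(600, 690),
                c(800, 890)),
    skipA = list(c(0, 90), c(400, 490), c(600, 690), c(800, 890)),
    skipC = list(c(0, 90), c(200, 290), c(400, 490), c(800, 890))
  )
  ann <- make_ann("gM", txs, strand = "-")
  pairs <- separated_exon_pairs(ann)
  expect_equal(nrow(pairs), 1)
  # on the minus strand the genomically-right exon is 5' (first)
  expect_gt(pairs$first_start, pairs$second_start)
})

test_that("terminal site pairs pick extreme events and classify them", {
  ann <- simulate_terminal_annotation(1, "last")
  tp <- terminal_site_pairs(ann)
  expect_equal(nrow(tp), 1)
  expect_equal(tp$category, "first-last")
  expect_equal(tp$donor_class, "first")
  expect_equal(tp$acceptor_class, "last")

  ann2 <- simulate_terminal_annotation(1, "internal")
  tp2 <- terminal_site_pairs(ann2)
  expect_equal(tp2$category, "first-internal")

  # donor event downstream of the acceptor event: no qualifying pair
  down <- make_ann("gX", list(
    # acceptor event first (two acceptors sharing donor at 100),
    # donor event later (two donors sharing acceptor 900)
    t1 = list(c(0, 100), c(200, 290), c(400, 490), c(600, 650), c(900, 990)),
    t2 = list(c(0, 100), c(240, 290), c(400, 490), c(600, 650), c(900, 990)),
    t3 = list(c(0, 100), c(200, 290), c(400, 490), c(600, 680), c(900, 990))
  ))
  expect_equal(nrow(terminal_site_pairs(down)), 0)

  # alternative donor and acceptor on the same intron (no intermediate
  # exon between the two sites): no qualifying pair
  same <- make_ann("gY", list(
    t1 = list(c(0, 100), c(900, 990)),
    t2 = list(c(0, 150), c(900, 990)),
    t3 = list(c(0, 100), c(850, 990))
  ))
  expect_equal(nrow(terminal_site_pairs(same)), 0)
})

test_that("mature length is the exonic span of the longest transcript", {
  ann <- make_ann("gL", list(
    short = list(c(0, 400), c(1000, 1500)),     # 900
    long = list(c(0, 700), c(1000, 1800))       # 1500
  ))
  expect_equal(mature_lengths(ann)$mature_length, 1500)
  single <- make_ann("gS", list(t1 = list(c(0, 300))))
  expect_equal(mature_lengths(single)$mature_length, 300)
  tie <- make_ann("gT", list(a = list(c(0, 1000)), b = list(c(50, 1050))))
  expect_equal(mature_lengths(tie)$mature_length, 1000)
  expect_error(mature_lengths(ann[ann$feature == "CDS", ]), "no exon")
})

test_that("classification recovers planted events on simulated annotation", {
  cfg <- sim_config(n_genes = 8, n_skippable = 2, seed = 4)
  ann <- simulate_annotation(cfg)
  ex <- pure_skipping_exons(ann)
  # exactly the planted alternative exons: 2 per gene
  expect_equal(nrow(ex), 16)
  expect_equal(as.integer(table(ex$gene_id)), rep(2L, 8))
  pairs <- separated_exon_pairs(ann, ex)
  expect_equal(nrow(pairs), 8)
  expect_true(all(pairs$separated))
  # noncoding configuration propagates
  cfg_nc <- sim_config(n_genes = 2, coding = FALSE, seed = 4)
  ex_nc <- pure_skipping_exons(simulate_annotation(cfg_nc))
  expect_true(all(ex_nc$coding_status == "contains_noncoding"))
})

test_that("BED export writes one stranded line per classified exon", {
  ann <- toy_skipping_gene()
  ex <- pure_skipping_exons(ann)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_skippable_bed(ex, bed)
  got <- readr::read_tsv(bed, col_names = c("chrom", "start", "end",
                                            "name", "score", "strand"),
                         show_col_types = FALSE)
  expect_equal(nrow(got), 1)
  expect_equal(got$name, "gA|entirely_coding")
  expect_equal(got$strand, "+")
})
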