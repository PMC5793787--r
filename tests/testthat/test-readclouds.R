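test_that("junction extraction enforces the anchor rule", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_lines(sam, c(
    sam_record("r1", 1001, "20M100N20M", "B1"),
    sam_record("r2", 1016, "5M100N20M", "B1"),   # left anchor too short
    sam_record("r3", 1015, "6M50N6M", "B1"),     # boundary case: accepted
    sam_record("r4", 2000, "40M", "B1"),          # unspliced
    sam_record("r5", 3000, "20M100N20M", "B1", flag = 4)  # unmapped
  ))
  al <- read_barcoded_sam(sam)
  expect_false("r5" %in% al$qname)
  jx <- extract_junctions(al)
  expect_equal(nrow(jx), 2)
  r1 <- jx[jx$qname == "r1", ]
  expect_equal(c(r1$start, r1$end), c(1020, 1120))
  expect_true("r3" %in% jx$qname)
  expect_false("r2" %in% jx$qname)
  # a stricter anchor removes the boundary case too
  expect_false("r3" %in% extract_junctions(al, min_anchor = 7)$qname)
  # multi-junction read: both gaps, each with its own anchors
  sam2 <- withr::local_tempfile(fileext = ".sam")
  write_sam_lines(sam2, sam_record("m1", 101, "10M50N10M60N5M", "B2"))
  jx2 <- extract_junctions(read_barcoded_sam(sam2))
  # second junction right anchor is 5 bp: rejected
  expect_equal(nrow(jx2), 1)
  expect_equal(c(jx2$start, jx2$end), c(110, 160))
})

test_that("barcodes fall back to the read name when the tag is absent", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_lines(sam, c(
    sam_record("read1#BC77", 1001, "20M100N20M"),
    sam_record("read2", 1001, "20M100N20M", "B9")
  ))
  al <- read_barcoded_sam(sam, name_sep = "#")
  expect_equal(sort(al$barcode), c("B9", "BC77"))
  al2 <- read_barcoded_sam(sam)
  expect_true(any(is.na(al2$barcode)))
})

test_that("evidence building assigns junctions to unique genes", {
  ann <- toy_skipping_gene()  # introns (100,200),(300,400),(100,400)
  al <- tibble::tibble(
    qname = sprintf("r%d", 1:6),
    chrom = "chr1",
    pos = c(81, 81, 81, 281, 81, 5001),
    cigar = c(rep("20M100N20M", 3), "20M100N20M", "20M300N20M",
              "20M100N20M"),
    barcode = c("B1", "B1", "B1", "B1", "B2", "B3")
  )
  ev <- build_evidence(al, ann)
  # three identical reads of B1 collapse to read_count 3
  b1u <- ev$evidence[ev$evidence$barcode == "B1" &
                       ev$evidence$start == 100 & ev$evidence$end == 200, ]
  expect_equal(b1u$read_count, 3L)
  expect_equal(b1u$gene_id, "gA")
  # skip junction (100,400) from B2 matches the annotated skip intron
  expect_true(any(ev$evidence$barcode == "B2" & ev$evidence$start == 100 &
                    ev$evidence$end == 400))
  # junction at 5020-5120 matches nothing: dropped and counted
  expect_equal(ev$counters$unassigned_junctions, 1)
  expect_equal(ev$counters$multi_gene_junctions, 0)
  # barcode stats count all mapped reads and genes with evidence
  b1 <- ev$barcode_stats[ev$barcode_stats$barcode == "B1", ]
  expect_equal(b1$total_reads, 4L)
  expect_equal(b1$spliced_gene_count, 1L)

  # a junction present in two genes' intron sets is ambiguous
  ann2 <- dplyr::bind_rows(ann, toy_skipping_gene("gB"))
  ev2 <- build_evidence(al[1, ], ann2)
  expect_equal(nrow(ev2$evidence), 0)
  expect_equal(ev2$counters$multi_gene_junctions, 1)

  # reads without barcode are skipped and counted
  al3 <- al[1, ]; al3$barcode <- NA_character_
  ev3 <- build_evidence(al3, ann)
  expect_equal(ev3$counters$no_barcode, 1)
  expect_equal(nrow(ev3$evidence), 0)

  # extra junctions rescue otherwise unannotated introns
  extra <- tibble::tibble(chrom = "chr1", start = 5020, end = 5120,
                          gene_id = "gA", strand = "+")
  ev4 <- build_evidence(al, ann, extra_junctions = extra)
  expect_equal(ev4$counters$unassigned_junctions, 0)
  expect_true(any(ev4$evidence$start == 5020))
})

test_that("molecule calling thresholds and monotonicity hold", {
  ev <- make_evidence("gA", tibble::tibble(
    barcode = c("B1", "B1", "B2"),
    start = c(100, 300, 100), end = c(200, 400, 200),
    read_count = c(2L, 1L, 5L)))
  expect_equal(nrow(call_molecules(ev, 1)), 2)
  expect_equal(nrow(call_molecules(ev, 2)), 2)
  expect_equal(nrow(call_molecules(ev, 4)), 1)  # only B2 with 5 reads
  expect_equal(nrow(call_molecules(ev, 6)), 0)
  expect_equal(nrow(call_molecules(ev[0, ], 1)), 0)
  # support is summed across introns per (gene, barcode)
  b1 <- call_molecules(ev, 1)
  expect_equal(b1$spliced_read_support[b1$barcode == "B1"], 3)
  # monotone in k on simulated data
  sim <- simulate_dataset(sim_config(n_genes = 3, molecules_per_gene = 200,
                                     n_droplets = 2000, seed = 5))
  counts <- vapply(1:20, function(k) nrow(call_molecules(sim$evidence, k)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("barcode QC computes the misidentification rate", {
  stats <- tibble::tibble(barcode = c("B1", "B2", "B3"),
                          total_reads = c(5000L, 800L, 50L),
                          spliced_gene_count = c(10L, 3L, 1L))
  calls <- tibble::tibble(gene_id = "g", barcode = rep(c("B1", "B2", "B3"),
                                                       c(8, 1, 1)),
                          spliced_read_support = 1)
  qc0 <- barcode_qc(stats, calls, 0)
  expect_equal(sort(qc0$retained), c("B1", "B2", "B3"))
  expect_equal(qc0$misidentification_rate, 0)
  qc100 <- barcode_qc(stats, calls, 100)
  expect_equal(qc100$misidentification_rate, 0.1)
  qc1000 <- barcode_qc(stats, calls, 1000)
  expect_equal(qc1000$misidentification_rate, 0.2)
  qc_all <- barcode_qc(stats, calls, 10000)
  expect_equal(qc_all$misidentification_rate, 1)
  expect_equal(length(qc_all$retained), 0)
  expect_error(barcode_qc(stats[0, ], calls, 10), "barcode")
})

test_that("collisions are conflicting inclusion/skip evidence", {
  ann <- toy_skipping_gene()
  ex <- pure_skipping_exons(ann)
  ev <- make_evidence("gA", tibble::tibble(
    barcode = c("B1", "B1", "B2", "B3"),
    start = c(100, 100, 100, 100),
    end = c(200, 400, 200, 400)))
  coll <- detect_collisions(ev, ex)
  flags <- setNames(coll$calls$collision, coll$calls$barcode)
  expect_true(flags[["B1"]])   # inclusion intron + skip intron
  expect_false(flags[["B2"]])  # inclusion only
  expect_false(flags[["B3"]])  # skip only
  expect_equal(coll$gene_summary$collision_fraction, 1 / 3)
  # overlap mode flags any two overlapping non-identical introns
  ev2 <- make_evidence("gA", tibble::tibble(
    barcode = c("B1", "B1", "B2", "B2"),
    start = c(100, 150, 100, 300),
    end = c(200, 250, 200, 400)))
  co <- detect_collisions(ev2, mode = "overlap")
  f2 <- setNames(co$calls$collision, co$calls$barcode)
  expect_true(f2[["B1"]])
  expect_false(f2[["B2"]])
})

test_that("collision fraction grows with expression in simulation", {
  cfg <- sim_config(n_genes = 6, n_skippable = 4,
                    molecules_per_gene = c(50, 150, 400, 1000, 2500, 6000),
                    n_droplets = 4000, reads_per_molecule = 30,
                    unspliced_fraction = 0,
                    barcode_misassignment_rate = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  ex <- pure_skipping_exons(sim$annotation)
  gs <- detect_collisions(sim$evidence, ex)$gene_summary
  expect_gt(suppressWarnings(
    stats::cor(gs$barcodes, gs$collision_fraction, method = "spearman")), 0)
})

test_that("MPM is proportional and sums to one million", {
  calls <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), c(1, 3)),
    barcode = sprintf("B%d", 1:4), spliced_read_support = 1)
  mpm <- compute_mpm(calls)
  expect_equal(mpm$mpm[mpm$gene_id == "g1"], 250000)
  expect_equal(mpm$mpm[mpm$gene_id == "g2"], 750000)
  expect_equal(sum(mpm$mpm), 1e6)
  single <- compute_mpm(calls[1, ])
  expect_equal(single$mpm, 1e6)
  expect_error(compute_mpm(calls[0, ]), "no molecule calls")
  # on simulation
  sim <- simulate_dataset(sim_config(n_genes = 4, molecules_per_gene = 300,
                                     n_droplets = 3000, seed = 2))
  expect_equal(sum(compute_mpm(call_molecules(sim$evidence, 1))$mpm), 1e6)
})

test_that("total-molecule estimation divides by the spliced fraction", {
  expect_equal(estimate_total_molecules(11.6e6), 17.4e6)
  expect_equal(estimate_total_molecules(16.7e6), 25.05e6)
  expect_equal(estimate_total_molecules(5e6, 1), 5e6)
  expect_error(estimate_total_molecules(1e6, 0), "spliced_fraction")
  expect_error(estimate_total_molecules(1e6, -0.5), "spliced_fraction")
})

test_that("psi counts informative barcodes only", {
  ann <- toy_skipping_gene()
  ex <- pure_skipping_exons(ann)
  obs <- tibble::tibble(
    barcode = c(sprintf("I%d", 1:8), sprintf("E%d", 1:2)),
    start = c(rep(100, 8), rep(100, 2)),
    end = c(rep(200, 8), rep(400, 2)))
  psi <- compute_psi(make_evidence("gA", obs), ex)
  expect_equal(psi$psi, 0.8)
  expect_equal(psi$n_inclusion, 8L)
  expect_equal(psi$n_exclusion, 2L)
  # zero inclusion
  skp <- tibble::tibble(barcode = sprintf("E%d", 1:5), start = 100, end = 400)
  expect_equal(compute_psi(make_evidence("gA", skp), ex)$psi, 0)
  # a barcode with conflicting evidence is uninformative; with no other
  # barcode the exon is absent from the result
  conf <- tibble::tibble(barcode = c("B1", "B1"), start = c(100, 100),
                         end = c(200, 400))
  expect_equal(nrow(compute_psi(make_evidence("gA", conf), ex)), 0)
  # collision exclusion removes flagged barcodes
  both <- dplyr::bind_rows(make_evidence("gA", obs),
                           make_evidence("gA", conf))
  coll <- detect_collisions(both, ex)
  psi2 <- compute_psi(both, ex, coll)
  expect_equal(psi2$psi, 0.8)
})

test_that("simulated psi recovers the generating marginal", {
  cfg <- sim_config(n_genes = 1, molecules_per_gene = 4000,
                    n_droplets = 100000, psi1 = 0.3, psi2 = 0.7,
                    barcode_misassignment_rate = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  ex <- pure_skipping_exons(sim$annotation)
  coll <- detect_collisions(sim$evidence, ex)
  psi <- compute_psi(sim$evidence, ex, coll)
  ex <- ex[order(ex$exon_start), ]  # first pair exon, then second
  psi <- psi[match(ex$exon_id, psi$exon_id), ]
  # binomial 3-sigma bands around the generating marginals
  n <- psi$n_inclusion + psi$n_exclusion
  tol <- 3 * sqrt(c(0.3 * 0.7, 0.7 * 0.3) / n)
  expect_lt(abs(psi$psi[1] - 0.3), tol[1])
  expect_lt(abs(psi$psi[2] - 0.7), tol[2])
})
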