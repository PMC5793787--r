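# Shared fixtures and independent oracles, built in code.

# Exhaustive-enumeration oracle for the two-sided Fisher test: enumerate
# every 2x2 table with the observed margins, computing each probability
# from binomial coefficients (log scale), and sum those not exceeding the
# observed table's probability. Independent of the dhyper-based
# implementation path.
enum_fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p_obs <- logp[xs == a]
  sum(exp(logp[logp <= p_obs + log1p(1e-7)]))
}

# Build an annotation tibble by hand. `txs` is a named list; each element
# is a list/matrix of exon (start, end) rows. `cds` follows the same
# shape (named by transcript).
make_ann <- function(gene_id, txs, cds = NULL, chrom = "chr1",
                     strand = "+", gene_type = "protein_coding") {
  rows <- purrr::imap_dfr(txs, function(exons, tn) {
    m <- do.call(rbind, lapply(exons, as.numeric))
    tibble::tibble(
      chrom = chrom, start = m[, 1], end = m[, 2], strand = strand,
      feature = "exon", gene_id = gene_id,
      tx_id = paste0(gene_id, ".", tn), gene_type = gene_type
    )
  })
  if (!is.null(cds)) {
    rows <- dplyr::bind_rows(rows, purrr::imap_dfr(cds, function(iv, tn) {
      m <- do.call(rbind, lapply(iv, as.numeric))
      tibble::tibble(
        chrom = chrom, start = m[, 1], end = m[, 2], strand = strand,
        feature = "CDS", gene_id = gene_id,
        tx_id = paste0(gene_id, ".", tn), gene_type = gene_type
      )
    }))
  }
  dplyr::arrange(rows, gene_id, tx_id, feature, start)
}

# Canonical toy skipping gene: exons [0,100) [200,300) [400,500);
# transcript "inc" includes the middle exon, "skip" splices across it.
# CDS over all exons so the middle exon is entirely coding.
toy_skipping_gene <- function(gene_id = "gA", middle = c(200, 300),
                              cds = TRUE) {
  txs <- list(
    inc = list(c(0, 100), middle, c(400, 500)),
    skip = list(c(0, 100), c(400, 500))
  )
  make_ann(gene_id, txs, cds = if (cds) txs else NULL)
}

# Evidence rows for one gene from a barcode x intron specification:
# `obs` is a tibble with columns barcode, start, end (and optionally
# read_count).
make_evidence <- function(gene_id, obs, chrom = "chr1", strand = "+") {
  if (!"read_count" %in% names(obs)) obs$read_count <- 1L
  tibble::tibble(
    chrom = chrom, start = obs$start, end = obs$end, strand = strand,
    gene_id = gene_id, barcode = obs$barcode, read_count = obs$read_count
  )
}

# Random 2x2 tables drawn from the generating joint distribution.
random_tables <- function(n_tables, n_t, psi1 = 0.5, psi2 = 0.5,
                          odds_ratio = 1) {
  p <- unlist(joint_probs(psi1, psi2, odds_ratio))
  cells <- stats::rmultinom(n_tables, n_t, p)
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n_tables)),
    a = cells[1, ], b = cells[2, ], c = cells[3, ], d = cells[4, ]
  ) |>
    dplyr::mutate(n_t = a + b + c + d)
}

write_sam_lines <- function(path, records, sn = "chr1", ln = 100000) {
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", sn, ln),
               records), path)
}

sam_record <- function(qname, pos, cigar, barcode = NULL, flag = 0,
                       chrom = "chr1") {
  tag <- if (is.null(barcode)) NULL else paste0("BX:Z:", barcode)
  paste(c(qname, flag, chrom, pos, 60, cigar, "*", 0, 0, "*", "*", tag),
        collapse = "\t")
}
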