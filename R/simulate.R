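#' Configuration for the droplet-encapsulation simulator
#'
#' Bundles and validates the generator's parameters. The defaults emulate
#' a microfluidic linked-read run: a large droplet count relative to
#' molecules per gene (low per-droplet gene occupancy), linear
#' random-primed amplification modelled as independent junction-spanning
#' reads per molecule (Poisson, mean `reads_per_molecule`), 98-bp reads
#' whose junction offset determines whether both anchors reach
#' `min_anchor` bases, and one third of molecules unspliced (carrying no
#' junction reads).
#'
#' @param n_genes Number of genes.
#' @param molecules_per_gene Molecules per gene (recycled over genes).
#' @param psi1,psi2 Inclusion marginals of the first and second skippable
#'   exon (recycled over genes).
#' @param odds_ratio Generating odds ratio linking the two exons
#'   (recycled; 1 = independence, `Inf` = perfect coordination).
#' @param psi_extra Inclusion marginal of any additional skippable exons
#'   (included independently).
#' @param n_skippable Skippable exons per gene (>= 2; the first two form
#'   the coordinated pair).
#' @param n_droplets Number of droplets/barcodes (default 200000).
#' @param reads_per_molecule Mean junction-spanning reads per spliced
#'   molecule (default 20).
#' @param read_length Read length in bp (default 98); with `min_anchor`
#'   it sets the chance a junction read fails the anchor filter.
#' @param min_anchor Anchor requirement emulated by the read model
#'   (default 6).
#' @param unspliced_fraction Fraction of molecules without junctions
#'   (default 1/3).
#' @param barcode_misassignment_rate Per-read probability of the barcode
#'   being swapped to a random droplet (default 0.001).
#' @param coding Annotate CDS over all exons (`TRUE`, protein-coding
#'   genes) or none (`FALSE`, noncoding genes)?
#' @param exon_length,const_exon_length,intron_length Geometry of the
#'   synthetic gene models, in bp.
#' @param seed Integer seed; all randomness in [simulate_dataset()]
#'   derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 20, molecules_per_gene = 2000,
                       psi1 = 0.5, psi2 = 0.5, odds_ratio = 1,
                       psi_extra = 0.5, n_skippable = 2,
                       n_droplets = 200000, reads_per_molecule = 20,
                       read_length = 98, min_anchor = 6,
                       unspliced_fraction = 1 / 3,
                       barcode_misassignment_rate = 0.001,
                       coding = TRUE, exon_length = 120,
                       const_exon_length = 150, intron_length = 300,
                       seed = 1) {
  stopifnot(n_genes >= 1, n_droplets >= 1, n_skippable >= 2,
            reads_per_molecule > 0, read_length > 2 * min_anchor,
            all(molecules_per_gene >= 0), all(odds_ratio > 0))
  assert_fraction(psi1, "psi1"); assert_fraction(psi2, "psi2")
  assert_fraction(psi_extra, "psi_extra")
  assert_fraction(unspliced_fraction, "unspliced_fraction")
  assert_fraction(barcode_misassignment_rate, "barcode_misassignment_rate")
  structure(as.list(environment()), class = "sim_config")
}

#' Joint inclusion probabilities from marginals and an odds ratio
#'
#' Computes the 2x2 cell probabilities (both, first only, second only,
#' neither) of a pair of binary inclusion events with the given marginals
#' and odds ratio: the unique `p_both` in the feasible interval
#' `[max(0, psi1 + psi2 - 1), min(psi1, psi2)]` solving
#' `p(1 - psi1 - psi2 + p) = OR (psi1 - p)(psi2 - p)`. With `OR = 1` the
#' events are independent; `OR = Inf` yields the perfect-coordination
#' limit.
#'
#' @param psi1,psi2 Marginals in (0, 1).
#' @param odds_ratio Positive odds ratio (may be `Inf`); vectorised.
#' @return Tibble with `p_both`, `p_first_only`, `p_second_only`,
#'   `p_neither` (rows sum to 1).
#' @examples
#' joint_probs(0.5, 0.5, 1)   # all cells 0.25
#' joint_probs(0.6, 0.3, 4)   # p_both ~ 0.2421
#' @export
joint_probs <- function(psi1, psi2, odds_ratio) {
  n <- max(length(psi1), length(psi2), length(odds_ratio))
  psi1 <- rep_len(psi1, n); psi2 <- rep_len(psi2, n)
  odds_ratio <- rep_len(odds_ratio, n)
  stopifnot(all(psi1 > 0 & psi1 < 1), all(psi2 > 0 & psi2 < 1),
            all(odds_ratio > 0))
  p_both <- vapply(seq_len(n), function(i) {
    s1 <- psi1[i]; s2 <- psi2[i]; or <- odds_ratio[i]
    lo <- max(0, s1 + s2 - 1); hi <- min(s1, s2)
    if (is.infinite(or)) return(hi)
    if (or == 1) return(s1 * s2)
    A <- 1 - or
    B <- (1 - s1 - s2) + or * (s1 + s2)
    C <- -or * s1 * s2
    disc <- B^2 - 4 * A * C
    stopifnot(disc >= 0)
    roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    ok <- roots >= lo - 1e-9 & roots <= hi + 1e-9
    stopifnot(any(ok))
    min(max(roots[ok][1], lo), hi)
  }, double(1))
  tibble(
    p_both = p_both,
    p_first_only = psi1 - p_both,
    p_second_only = psi2 - p_both,
    p_neither = 1 - psi1 - psi2 + p_both
  )
}

# Base exon layout shared by all simulated genes: constitutive and
# skippable exons alternate (C A C A ... C), each separated by one
# intron. Coordinates are relative to the gene's offset.
gene_layout <- function(config) {
  k <- config$n_skippable
  n_el <- 2 * k + 1
  is_alt <- rep_len(c(FALSE, TRUE), n_el)
  lens <- ifelse(is_alt, config$exon_length, config$const_exon_length)
  starts <- cumsum(c(0, head(lens + config$intron_length, -1)))
  tibble(
    element = seq_len(n_el), is_alt = is_alt,
    alt_index = cumsum(is_alt) * is_alt,
    start = starts, end = starts + lens
  )
}

sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Synthetic annotation with planted pure exon-skipping pairs
#'
#' Builds gene models in which skippable exons alternate with
#' constitutive exons; every gene carries one full-inclusion transcript
#' plus one transcript skipping each alternative exon, so each planted
#' exon is a pure skipping event and every exon pair is separated by a
#' constitutive exon. With `coding = TRUE`, CDS records cover all exons.
#'
#' @param config A [sim_config()] object.
#' @return Annotation tibble in the format of [read_gtf()].
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- gene_layout(config)
  span <- max(layout$end) + 10000
  k <- config$n_skippable
  gid <- sim_gene_ids(config$n_genes)
  tx_sets <- c(list(layout$element),
               purrr::map(seq_len(k), function(j)
                 layout$element[!(layout$is_alt & layout$alt_index == j)]))
  tx_names <- c("t0", paste0("skip", seq_len(k)))

  per_gene <- purrr::map(seq_len(config$n_genes), function(g) {
    off <- (g - 1) * span
    purrr::map2_dfr(tx_sets, tx_names, function(els, tn) {
      ex <- layout[layout$element %in% els, , drop = FALSE]
      tibble(
        chrom = "chrS", start = off + ex$start, end = off + ex$end,
        strand = "+", feature = "exon", gene_id = gid[g],
        tx_id = paste0(gid[g], ".", tn),
        gene_type = if (config$coding) "protein_coding" else "lincRNA"
      )
    })
  })
  ann <- bind_rows(per_gene)
  if (config$coding) {
    ann <- bind_rows(ann, mutate(ann, feature = "CDS"))
  }
  arrange(ann, .data$gene_id, .data$tx_id, .data$start)
}

#' Synthetic annotation with terminal alternative splice sites
#'
#' One or more genes with two alternative first exons (an alternative
#' donor event whose donors belong to first exons) and either two
#' alternative last acceptors (`acceptor_kind = "last"`) or an internal
#' exon with two alternative 3' splice sites (`acceptor_kind =
#' "internal"`), separated by constitutive exons.
#'
#' @param n_genes Number of genes.
#' @param acceptor_kind `"last"` or `"internal"`.
#' @return Annotation tibble in the format of [read_gtf()].
#' @export
simulate_terminal_annotation <- function(n_genes = 1,
                                         acceptor_kind = c("last",
                                                           "internal")) {
  acceptor_kind <- match.arg(acceptor_kind)
  gid <- sprintf("T%04d", seq_len(n_genes))
  span <- 20000
  per_gene <- purrr::map(seq_len(n_genes), function(g) {
    off <- (g - 1) * span
    fa <- c(0, 100); fb <- c(500, 600)           # alternative first exons
    c1 <- c(1000, 1150); c2 <- c(1500, 1650); c3 <- c(2000, 2150)
    if (acceptor_kind == "last") {
      la <- c(2500, 2650); lb <- c(3000, 3150)   # alternative last exons
      mids <- list(c1, c2, c3)
      tx <- list(
        t1 = c(list(fa), mids, list(la)), t2 = c(list(fa), mids, list(lb)),
        t3 = c(list(fb), mids, list(la)), t4 = c(list(fb), mids, list(lb))
      )
    } else {
      # internal exon with two 3' splice sites sharing the upstream donor
      ea <- c(2500, 2650); eb <- c(2560, 2650)
      last <- c(3000, 3150)
      tx <- list(
        t1 = list(fa, c1, c2, ea, last), t2 = list(fa, c1, c2, eb, last),
        t3 = list(fb, c1, c2, ea, last), t4 = list(fb, c1, c2, eb, last)
      )
    }
    purrr::imap_dfr(tx, function(exons, tn) {
      m <- do.call(rbind, exons)
      tibble(chrom = "chrT", start = off + m[, 1], end = off + m[, 2],
             strand = "+", feature = "exon", gene_id = gid[g],
             tx_id = paste0(gid[g], ".", tn), gene_type = "protein_coding")
    })
  })
  arrange(bind_rows(per_gene), .data$gene_id, .data$tx_id, .data$start)
}

#' Simulate a droplet-barcoded junction-evidence dataset with known truth
#'
#' Generates molecules per gene with exon-inclusion patterns drawn from
#' [joint_probs()] (the first two skippable exons are linked by the
#' configured odds ratio; further exons are included independently),
#' assigns each molecule to a droplet uniformly at random (per-gene
#' droplet occupancy is approximately Poisson with rate molecules /
#' droplets, so collisions arise naturally from multi-occupancy), marks a
#' configurable fraction unspliced, and emits junction-spanning reads:
#' per molecule the read count is Poisson and reads fall uniformly on the
#' molecule's junctions, each failing the anchor filter with probability
#' `2 (min_anchor - 1) / (read_length - 1)`. A configurable fraction of
#' reads has its barcode swapped to a random droplet.
#'
#' @param config A [sim_config()] object.
#' @return List with `evidence` (junction-evidence tibble in the
#'   [build_evidence()] dialect), `annotation`, and `truth` (list:
#'   `pairs` with the generating marginals/odds ratios per gene,
#'   `molecules` with per-molecule droplet, barcode, spliced status and
#'   pair pattern, and the `config`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_skippable
  ng <- config$n_genes
  layout <- gene_layout(config)
  span <- max(layout$end) + 10000
  gid <- sim_gene_ids(ng)

  m_per <- rep_len(config$molecules_per_gene, ng)
  psi1 <- rep_len(config$psi1, ng)
  psi2 <- rep_len(config$psi2, ng)
  or <- rep_len(config$odds_ratio, ng)
  jp <- joint_probs(psi1, psi2, or)

  gene <- rep.int(seq_len(ng), m_per)
  n_mol <- length(gene)
  cat12 <- integer(n_mol)
  for (g in seq_len(ng)) {
    idx <- which(gene == g)
    if (length(idx) == 0) next
    cat12[idx] <- sample.int(4, length(idx), replace = TRUE,
                             prob = unlist(jp[g, ]))
  }
  incl <- matrix(0L, nrow = n_mol, ncol = k)
  incl[, 1] <- as.integer(cat12 %in% c(1L, 2L))
  incl[, 2] <- as.integer(cat12 %in% c(1L, 3L))
  if (k > 2) {
    incl[, 3:k] <- rbinom(n_mol * (k - 2), 1, config$psi_extra)
  }
  spliced <- runif(n_mol) >= config$unspliced_fraction
  droplet <- sample.int(config$n_droplets, n_mol, replace = TRUE)

  # junction coordinates relative to gene offset, per skippable exon
  alt <- layout[layout$is_alt, , drop = FALSE]
  cst <- layout[!layout$is_alt, , drop = FALSE]
  u_s <- cst$end[seq_len(k)];      u_e <- alt$start
  d_s <- alt$end;                  d_e <- cst$start[seq_len(k) + 1]
  s_s <- u_s;                      s_e <- d_e

  sp <- which(spliced)
  lam <- config$reads_per_molecule / (k + rowSums(incl))
  pieces <- purrr::map(seq_len(k), function(j) {
    inc <- incl[sp, j] == 1L
    bind_rows(
      tibble(mol = rep(sp[inc], 2L),
             start_rel = rep(c(u_s[j], d_s[j]), each = sum(inc)),
             end_rel = rep(c(u_e[j], d_e[j]), each = sum(inc)),
             lambda = rep(lam[sp[inc]], 2L)),
      tibble(mol = sp[!inc], start_rel = s_s[j], end_rel = s_e[j],
             lambda = lam[sp[!inc]])
    )
  })
  long <- bind_rows(pieces)
  long$count <- rpois(nrow(long), long$lambda)
  anchor_fail <- 2 * (config$min_anchor - 1) / (config$read_length - 1)
  long$count <- rbinom(nrow(long), long$count, 1 - anchor_fail)
  long <- long[long$count > 0, , drop = FALSE]
  long$gene <- gene[long$mol]
  long$droplet <- droplet[long$mol]

  # barcode misassignment at read level
  rate <- config$barcode_misassignment_rate
  if (rate > 0 && nrow(long) > 0) {
    moved <- rbinom(nrow(long), long$count, rate)
    extra_idx <- rep.int(seq_len(nrow(long)), moved)
    long$count <- long$count - moved
    if (length(extra_idx) > 0) {
      stray <- long[extra_idx, c("gene", "start_rel", "end_rel")]
      stray$droplet <- sample.int(config$n_droplets, nrow(stray),
                                  replace = TRUE)
      stray$count <- 1L
      long <- bind_rows(long[long$count > 0,
                             c("gene", "start_rel", "end_rel", "droplet",
                               "count")],
                        stray[, c("gene", "start_rel", "end_rel",
                                  "droplet", "count")])
    } else {
      long <- long[long$count > 0, c("gene", "start_rel", "end_rel",
                                     "droplet", "count")]
    }
  } else {
    long <- long[, c("gene", "start_rel", "end_rel", "droplet", "count")]
  }

  evidence <- long %>%
    mutate(
      chrom = "chrS",
      start = (.data$gene - 1) * span + .data$start_rel,
      end = (.data$gene - 1) * span + .data$end_rel,
      strand = "+",
      gene_id = gid[.data$gene],
      barcode = sprintf("BC%07d", .data$droplet)
    ) %>%
    group_by(.data$chrom, .data$start, .data$end, .data$strand,
             .data$gene_id, .data$barcode) %>%
    summarise(read_count = sum(.data$count), .groups = "drop")

  truth <- list(
    pairs = tibble(gene_id = gid, psi1 = psi1, psi2 = psi2,
                   odds_ratio = or, log2_or = log2(or)) %>%
      bind_cols(jp),
    molecules = tibble(
      gene_id = gid[gene], molecule = seq_len(n_mol), droplet = droplet,
      barcode = sprintf("BC%07d", droplet), spliced = spliced,
      incl1 = incl[, 1] == 1L, incl2 = incl[, 2] == 1L
    ),
    config = config
  )
  list(evidence = evidence, annotation = simulate_annotation(config),
       truth = truth)
}

#' Theoretical collision fraction under Poisson occupancy
#'
#' Probability that a droplet detecting a gene contains two or more
#' molecules of it, when per-droplet occupancy is Poisson(lambda):
#' `(1 - exp(-lambda) - lambda exp(-lambda)) / (1 - exp(-lambda))`.
#'
#' @param lambda Mean molecules of the gene per droplet.
#' @return Expected collision fraction.
#' @export
expected_collision_fraction <- function(lambda) {
  stopifnot(all(lambda > 0))
  (1 - exp(-lambda) - lambda * exp(-lambda)) / (1 - exp(-lambda))
}
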