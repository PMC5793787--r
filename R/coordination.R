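#' Two-sided Fisher's exact p-value for 2x2 tables
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, of tables whose probability does
#' not exceed that of the observed table. Ties are resolved with a
#' relative tolerance of 1e-7 for floating-point stability, matching the
#' conventional definition.
#'
#' @param a,b,c,d Cell counts (vectorised): `a` both events, `b` first
#'   only, `c` second only, `d` neither.
#' @return Vector of p-values in (0, 1].
#' @examples
#' fisher_two_sided(10, 0, 0, 10)  # 2 / choose(20, 10)
#' @export
fisher_two_sided <- function(a, b, c, d) {
  n <- a + b + c + d
  if (any(n < 1)) abort("empty contingency table: no informative units")
  vapply(seq_along(a), function(i) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    lo <- max(0, k - m2); hi <- min(k, m1)
    probs <- dhyper(lo:hi, m1, m2, k)
    p_obs <- dhyper(a[i], m1, m2, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, double(1))
}

#' Log2-odds-ratio with 0.5 pseudocount
#'
#' `log2((a+0.5)(d+0.5) / ((b+0.5)(c+0.5)))`. The Haldane-Anscombe
#' pseudocount of 0.5 keeps the value finite when a cell is zero.
#' Positive values indicate co-inclusion/co-exclusion association.
#'
#' @inheritParams fisher_two_sided
#' @return Vector of finite log2-odds-ratios.
#' @examples
#' log_odds(10, 0, 0, 10)  # log2(441)
#' @export
log_odds <- function(a, b, c, d) {
  log2((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
}

#' Step-up false discovery rate adjustment
#'
#' Benjamini-Yekutieli (`"BY"`, valid under arbitrary dependence; inflates
#' by `c(m) = sum(1/i)`) or Benjamini-Hochberg (`"BH"`) step-up adjusted
#' p-values, capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param method `"BY"` or `"BH"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_fdr <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = method)
}

#' Splicing status of exon pairs per barcode
#'
#' Classifies each non-collision barcode of a gene with respect to an
#' exon pair: `both`, `first_only`, `second_only`, `neither`, or
#' `uninformative` when either exon's status is undetermined. Per-exon
#' status follows the same inclusion-vs-skip evidence rule as
#' [compute_psi()]; barcodes with conflicting evidence for an exon are
#' uninformative for pairs involving it.
#'
#' @param evidence Junction-evidence tibble (see [build_evidence()]).
#' @param pairs Exon pairs from [separated_exon_pairs()].
#' @param exons Skippable exons from [pure_skipping_exons()].
#' @param collisions Optional result of [detect_collisions()].
#' @return Tibble with `gene_id`, `first_exon_id`, `second_exon_id`,
#'   `barcode`, `status` (uninformative barcodes omitted).
#' @export
pair_status <- function(evidence, pairs, exons, collisions = NULL) {
  st <- exon_barcode_status(evidence, exons)
  if (!is.null(collisions)) {
    bad <- collisions$calls %>% filter(.data$collision)
    st <- st %>% anti_join(bad, by = c("gene_id", "barcode"))
  }
  st <- st %>% filter(.data$status != "conflict")
  pairs %>%
    select("gene_id", "first_exon_id", "second_exon_id") %>%
    inner_join(st %>% rename(first_exon_id = "exon_id", s1 = "status"),
               by = c("gene_id", "first_exon_id"),
               relationship = "many-to-many") %>%
    inner_join(st %>% rename(second_exon_id = "exon_id", s2 = "status"),
               by = c("gene_id", "second_exon_id", "barcode")) %>%
    mutate(status = dplyr::case_when(
      .data$s1 == "included" & .data$s2 == "included" ~ "both",
      .data$s1 == "included" & .data$s2 == "skipped" ~ "first_only",
      .data$s1 == "skipped" & .data$s2 == "included" ~ "second_only",
      TRUE ~ "neither"
    )) %>%
    select("gene_id", "first_exon_id", "second_exon_id", "barcode", "status")
}

#' Build 2x2 contingency tables for exon pairs
#'
#' Counts informative molecules (barcodes) per pair: `a` both exons
#' included, `b` first only, `c` second only, `d` both skipped;
#' `n_t = a + b + c + d`. Pairs with no informative barcode get an
#' all-zero table.
#'
#' @inheritParams pair_status
#' @return `pairs` with columns `a`, `b`, `c`, `d`, `n_t` appended.
#' @export
build_pair_tables <- function(evidence, pairs, exons, collisions = NULL) {
  ps <- pair_status(evidence, pairs, exons, collisions)
  counts <- ps %>%
    count(.data$gene_id, .data$first_exon_id, .data$second_exon_id,
          .data$status) %>%
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("both", "first_only", "second_only", "neither")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  pairs %>%
    left_join(counts, by = c("gene_id", "first_exon_id", "second_exon_id")) %>%
    mutate(
      a = dplyr::coalesce(.data$both, 0L),
      b = dplyr::coalesce(.data$first_only, 0L),
      c = dplyr::coalesce(.data$second_only, 0L),
      d = dplyr::coalesce(.data$neither, 0L),
      n_t = .data$a + .data$b + .data$c + .data$d
    ) %>%
    select(-dplyr::any_of(c("both", "first_only", "second_only", "neither")))
}

#' Test coordination of separated exon pairs
#'
#' For every pair with at least `min_informative` informative molecules, a
#' two-sided Fisher's exact test of the 2x2 inclusion table is performed;
#' all tested pairs form one multiple-testing family, adjusted with the
#' Benjamini-Yekutieli method by default (the tables of one gene are not
#' independent). A pair is coordinated when its adjusted p-value is at or
#' below `fdr`.
#'
#' @param tables Tibble of pair tables from [build_pair_tables()] (or any
#'   tibble with `gene_id`, `a`, `b`, `c`, `d`).
#' @param min_informative Minimum informative molecules per tested pair
#'   (default 25).
#' @param fdr False discovery rate (default 0.05).
#' @param method FDR method, `"BY"` (default) or `"BH"`.
#' @return An object of class `coord_test`; see [tidy.coord_test()],
#'   [glance.coord_test()], [autoplot.coord_test()].
#' @export
test_coordination <- function(tables, min_informative = 25, fdr = 0.05,
                              method = "BY") {
  stopifnot(min_informative >= 0, fdr > 0, fdr < 1)
  if (!"n_t" %in% names(tables)) {
    tables <- mutate(tables, n_t = .data$a + .data$b + .data$c + .data$d)
  }
  tested <- filter(tables, .data$n_t >= min_informative)
  if (nrow(tested) == 0) {
    warn("no testable pairs at this informative-count threshold")
    results <- mutate(tested, p_value = double(), p_adjusted = double(),
                      lor = double(), significant = logical())
  } else {
    results <- tested %>%
      mutate(
        p_value = fisher_two_sided(.data$a, .data$b, .data$c, .data$d),
        p_adjusted = adjust_fdr(.data$p_value, method = method),
        lor = log_odds(.data$a, .data$b, .data$c, .data$d),
        significant = .data$p_adjusted <= fdr
      ) %>%
      arrange(.data$p_adjusted, .data$gene_id)
  }
  genes <- results %>%
    group_by(.data$gene_id) %>%
    summarise(n_pairs = dplyr::n(),
              n_significant = sum(.data$significant),
              coordinated = any(.data$significant), .groups = "drop")
  structure(
    list(results = results, genes = genes,
         params = list(min_informative = min_informative, fdr = fdr,
                       method = method, n_input_pairs = nrow(tables))),
    class = "coord_test"
  )
}

#' @export
print.coord_test <- function(x, ...) {
  cat("Splicing coordination test (", x$params$method, " FDR ",
      x$params$fdr, ")\n", sep = "")
  cat("  pairs tested: ", nrow(x$results), " of ", x$params$n_input_pairs,
      " (n_t >= ", x$params$min_informative, ")\n", sep = "")
  cat("  coordinated pairs: ", sum(x$results$significant),
      " in ", sum(x$genes$coordinated), " gene(s)\n", sep = "")
  invisible(x)
}

#' Tidy per-pair coordination results
#'
#' @param x A `coord_test` object.
#' @param ... Unused.
#' @return The per-pair results tibble (table counts, `p_value`,
#'   `p_adjusted`, `lor`, `significant`), ordered by adjusted p-value.
#' @method tidy coord_test
#' @export
tidy.coord_test <- function(x, ...) x$results

#' One-row summary of a coordination test
#'
#' @param x A `coord_test` object.
#' @param ... Unused.
#' @return Tibble with pairs/genes tested, significant counts, and the
#'   testing parameters.
#' @method glance coord_test
#' @export
glance.coord_test <- function(x, ...) {
  tibble(
    n_pairs_tested = nrow(x$results),
    n_genes_tested = nrow(x$genes),
    n_significant_pairs = sum(x$results$significant),
    n_coordinated_genes = sum(x$genes$coordinated),
    min_informative = x$params$min_informative,
    fdr = x$params$fdr,
    method = x$params$method
  )
}

#' Volcano-style plot of coordination results
#'
#' Log2-odds-ratio against -log10 adjusted p-value, coloured by
#' significance.
#'
#' @param object A `coord_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coord_test
#' @export
autoplot.coord_test <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$lor, y = -log10(pmax(.data$p_adjusted, 1e-300)),
    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(object$params$fdr),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(log[2] ~ "odds ratio"),
                  y = expression(-log[10] ~ "adjusted" ~ italic(P)),
                  colour = "coordinated") +
    ggplot2::theme_minimal()
}

#' Test coordination between terminal alternative splice sites
#'
#' For each gene's retained donor/acceptor event pair (see
#' [terminal_site_pairs()]), barcodes are classified by which of the two
#' donor forms and two acceptor forms they support (barcodes supporting
#' both forms of an event are uninformative). The resulting 2x2 table is
#' tested with Fisher's exact test; one test per gene, adjusted across
#' genes with Benjamini-Hochberg. A category enrichment table (two-sided
#' Fisher's exact test of category membership against significance) is
#' attached.
#'
#' @param evidence Junction-evidence tibble (see [build_evidence()]).
#' @param site_pairs Result of [terminal_site_pairs()].
#' @param fdr False discovery rate (default 0.05).
#' @param min_informative Minimum informative molecules per gene
#'   (default 25).
#' @param collisions Optional result of [detect_collisions()].
#' @return An object of class `terminal_test` (also `coord_test`), with a
#'   `$enrichment` tibble.
#' @export
test_terminal_coordination <- function(evidence, site_pairs, fdr = 0.05,
                                       min_informative = 25,
                                       collisions = NULL) {
  if (!is.null(collisions)) {
    bad <- collisions$calls %>% filter(.data$collision) %>%
      select("gene_id", "barcode")
    evidence <- evidence %>% anti_join(bad, by = c("gene_id", "barcode"))
  }
  form_status <- function(side) {
    f1 <- site_pairs %>%
      transmute(.data$gene_id,
                start = .data[[paste0(side, "_form1_start")]],
                end = .data[[paste0(side, "_form1_end")]], form = 1L)
    f2 <- site_pairs %>%
      transmute(.data$gene_id,
                start = .data[[paste0(side, "_form2_start")]],
                end = .data[[paste0(side, "_form2_end")]], form = 2L)
    bind_rows(f1, f2) %>%
      inner_join(evidence, by = c("gene_id", "start", "end")) %>%
      group_by(.data$gene_id, .data$barcode) %>%
      summarise(form = if (dplyr::n_distinct(.data$form) == 1)
        .data$form[1] else NA_integer_, .groups = "drop") %>%
      filter(!is.na(.data$form))
  }
  ds <- form_status("donor") %>% rename(donor_form = "form")
  as_ <- form_status("acceptor") %>% rename(acceptor_form = "form")
  tabs <- ds %>%
    inner_join(as_, by = c("gene_id", "barcode")) %>%
    group_by(.data$gene_id) %>%
    summarise(
      a = sum(.data$donor_form == 1 & .data$acceptor_form == 1),
      b = sum(.data$donor_form == 1 & .data$acceptor_form == 2),
      c = sum(.data$donor_form == 2 & .data$acceptor_form == 1),
      d = sum(.data$donor_form == 2 & .data$acceptor_form == 2),
      .groups = "drop") %>%
    mutate(n_t = .data$a + .data$b + .data$c + .data$d) %>%
    left_join(site_pairs %>% select("gene_id", "category", "donor_class",
                                    "acceptor_class"),
              by = "gene_id")
  fit <- test_coordination(tabs, min_informative = min_informative,
                           fdr = fdr, method = "BH")
  res <- fit$results
  enrichment <- if (nrow(res) == 0) {
    tibble(category = character(), in_category_sig = integer(),
           in_category_ns = integer(), other_sig = integer(),
           other_ns = integer(), p_value = double())
  } else {
    purrr::map_dfr(sort(unique(res$category)), function(cat) {
      inc <- res$category == cat
      tab <- c(sum(inc & res$significant), sum(inc & !res$significant),
               sum(!inc & res$significant), sum(!inc & !res$significant))
      tibble(category = cat,
             in_category_sig = tab[1], in_category_ns = tab[2],
             other_sig = tab[3], other_ns = tab[4],
             p_value = fisher_two_sided(tab[1], tab[2], tab[3], tab[4]))
    })
  }
  fit$enrichment <- enrichment
  class(fit) <- c("terminal_test", "coord_test")
  fit
}

#' Coordination frequency in coding versus noncoding exon pairs
#'
#' Compares the frequency of coordinated pairs between entirely-coding
#' pairs and pairs involving noncoding sequence, after matching the two
#' groups on informative-molecule counts (greedy nearest-neighbour
#' matching without replacement on `n_t`, deterministic given `seed`).
#'
#' @param results Tidy coordination results (see [tidy.coord_test()])
#'   with `pair_coding`, `n_t` and `significant` columns.
#' @param seed Integer seed controlling the matching order.
#' @return One-row tibble: matched group size, per-group coordination
#'   frequencies, their ratio (coding / noncoding), and the two-sided
#'   Fisher p-value of the group-by-coordination table.
#' @export
coding_noncoding_comparison <- function(results, seed = 1) {
  coding <- filter(results, .data$pair_coding == "entirely_coding")
  noncod <- filter(results, .data$pair_coding == "contains_noncoding")
  if (nrow(coding) == 0 || nrow(noncod) == 0) {
    abort("both coding and noncoding groups must be non-empty")
  }
  small <- if (nrow(coding) <= nrow(noncod)) coding else noncod
  large <- if (nrow(coding) <= nrow(noncod)) noncod else coding
  ord <- withr::with_seed(seed, sample.int(nrow(small)))
  used <- rep(FALSE, nrow(large))
  match_idx <- integer(nrow(small))
  for (i in ord) {
    dist <- abs(large$n_t - small$n_t[i])
    dist[used] <- Inf
    j <- which.min(dist)
    used[j] <- TRUE
    match_idx[i] <- j
  }
  matched_large <- large[match_idx, , drop = FALSE]
  if (nrow(coding) <= nrow(noncod)) {
    mc <- small; mn <- matched_large
  } else {
    mc <- matched_large; mn <- small
  }
  tab <- c(sum(mc$significant), sum(!mc$significant),
           sum(mn$significant), sum(!mn$significant))
  freq_c <- mean(mc$significant); freq_n <- mean(mn$significant)
  tibble(
    n_matched = nrow(mc),
    freq_coding = freq_c,
    freq_noncoding = freq_n,
    ratio = freq_c / freq_n,
    p_value = fisher_two_sided(tab[1], tab[2], tab[3], tab[4])
  )
}

#' Frame preservation among coordinated coding pairs
#'
#' Fraction of pairs in which both exon lengths are divisible by three, so
#' that inclusion or skipping leaves the reading frame intact.
#'
#' @param results Tidy coordination results with a
#'   `both_frame_preserving` column (typically filtered to significant,
#'   entirely-coding pairs).
#' @return One-row tibble with `n_pairs`, `n_frame_preserving`,
#'   `fraction` (`NA` when no pairs are supplied).
#' @export
frame_analysis <- function(results) {
  n <- nrow(results)
  tibble(
    n_pairs = n,
    n_frame_preserving = if (n == 0) 0L else
      sum(results$both_frame_preserving),
    fraction = if (n == 0) NA_real_ else
      mean(results$both_frame_preserving)
  )
}
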