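#' Stringent coordination criterion for extent estimation
#'
#' A table passes when its two-sided Fisher p-value is at most `p_cutoff`
#' and the absolute log2-odds-ratio (0.5 pseudocount) is at least
#' `lor_cutoff`. The default p cutoff of 5e-7 corresponds to a Bonferroni
#' correction of 0.05 for 100,000 tests, an upper bound on the number of
#' separated alternative exon pairs genome-wide.
#'
#' @param tables Tibble with cell counts `a`, `b`, `c`, `d` (columns
#'   `p_value`/`lor` are reused when already present).
#' @param p_cutoff P-value threshold (default 5e-7).
#' @param lor_cutoff Absolute log2-odds-ratio threshold (default 0.5).
#' @return Logical vector, one element per table.
#' @export
passes_criterion <- function(tables, p_cutoff = 5e-7, lor_cutoff = 0.5) {
  p <- if ("p_value" %in% names(tables)) tables$p_value else
    fisher_two_sided(tables$a, tables$b, tables$c, tables$d)
  l <- if ("lor" %in% names(tables)) tables$lor else
    log_odds(tables$a, tables$b, tables$c, tables$d)
  p <= p_cutoff & abs(l) >= lor_cutoff
}

#' Keep one table per gene: the one with most informative molecules
#'
#' Avoids over-weighting genes with many testable exon pairs. Ties are
#' broken by genomic position (the most upstream pair wins).
#'
#' @param tables Tibble with `gene_id`, `n_t` and (optionally)
#'   `first_start` for tie-breaking.
#' @return Tibble with one row per gene.
#' @export
select_max_pair_per_gene <- function(tables) {
  if (!"first_start" %in% names(tables)) tables$first_start <- 0
  tables %>%
    group_by(.data$gene_id) %>%
    arrange(desc(.data$n_t), .data$first_start, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
}

#' Fraction of genes with coordination across informative-count cutoffs
#'
#' For each cutoff, restricts to tables with `n_t` at or above the cutoff
#' (optionally one table per gene first) and reports the fraction of
#' genes with at least one table passing the stringent criterion of
#' [passes_criterion()], with a 95% confidence interval (Wilson score by
#' default).
#'
#' @param tables Tibble with `gene_id`, `a`, `b`, `c`, `d`, `n_t`.
#' @param cutoffs Ascending integer cutoffs
#'   (default `c(25, 50, 100, 200, 500, 1000)`).
#' @param per_gene Keep only each gene's largest table before sweeping?
#' @param ci_method `"wilson"` (default) or `"normal"`.
#' @param p_cutoff,lor_cutoff Passed to [passes_criterion()].
#' @return Tibble with `cutoff`, `genes_tested`, `fraction_coordinated`,
#'   `ci_low`, `ci_high`. Cutoffs retaining no gene are omitted with a
#'   warning.
#' @export
sweep_cutoffs <- function(tables, cutoffs = c(25, 50, 100, 200, 500, 1000),
                          per_gene = FALSE,
                          ci_method = c("wilson", "normal"),
                          p_cutoff = 5e-7, lor_cutoff = 0.5) {
  ci_method <- match.arg(ci_method)
  stopifnot(!is.unsorted(cutoffs))
  if (!"n_t" %in% names(tables)) {
    tables <- mutate(tables, n_t = .data$a + .data$b + .data$c + .data$d)
  }
  if (per_gene) tables <- select_max_pair_per_gene(tables)
  tables$.pass <- passes_criterion(tables, p_cutoff, lor_cutoff)
  rows <- purrr::map(cutoffs, function(co) {
    sub <- filter(tables, .data$n_t >= co)
    if (nrow(sub) == 0) {
      warn(paste0("cutoff ", co, " retains no genes; omitted"))
      return(NULL)
    }
    genes <- sub %>% group_by(.data$gene_id) %>%
      summarise(hit = any(.data$.pass), .groups = "drop")
    ci <- if (ci_method == "wilson") {
      wilson_ci(sum(genes$hit), nrow(genes))
    } else {
      normal_ci(sum(genes$hit), nrow(genes))
    }
    tibble(cutoff = co, genes_tested = nrow(genes),
           fraction_coordinated = mean(genes$hit),
           ci_low = ci$low, ci_high = ci$high)
  })
  bind_rows(purrr::compact(rows))
}

#' Plot the extent sweep
#'
#' Fraction of coordinated genes against the informative-count cutoff,
#' with 95% confidence bars.
#'
#' @param estimates Result of [sweep_cutoffs()].
#' @return A ggplot object.
#' @export
plot_extent <- function(estimates) {
  ggplot2::ggplot(estimates, ggplot2::aes(
    x = .data$cutoff, y = 100 * .data$fraction_coordinated)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * .data$ci_low,
                                        ymax = 100 * .data$ci_high),
                           width = 0.05) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "informative molecules per exon pair (cutoff)",
                  y = "% genes with coordination") +
    ggplot2::theme_minimal()
}

#' Down-sample a 2x2 table without replacement
#'
#' Draws `n` units from the table's four cells (multivariate
#' hypergeometric), preserving the total; when `n` equals the table total
#' the table is returned unchanged.
#'
#' @param cells Numeric vector of length 4 (`a`, `b`, `c`, `d`).
#' @param n Number of units to retain (`0 <= n <= sum(cells)`).
#' @return Integer vector of length 4 summing to `n`.
#' @export
downsample_table <- function(cells, n) {
  stopifnot(length(cells) == 4, all(cells >= 0))
  total <- sum(cells)
  if (n > total) abort("cannot down-sample: n exceeds the table total")
  if (n == total) return(as.integer(cells))
  if (n == 0) return(integer(4))
  drawn <- sample(rep.int(1:4, cells), n)
  tabulate(drawn, nbins = 4)
}

#' Down-sampling control for the extent estimate
#'
#' Tests whether deeply sequenced exon pairs behave like shallowly
#' sequenced ones once read depth is equalised. `L` is the list of tables
#' with `n_t >= low_cutoff` and `H` the list with `n_t >= high_cutoff`;
#' for every table in `L`, a donor table is drawn uniformly from the
#' members of `H` at least as large, and down-sampled to the target's
#' size, yielding a down-sampled list `DS` with the identical `n_t`
#' multiset as `L`. The fraction of `DS` genes passing the stringent
#' criterion is recorded; the procedure is repeated `replicates` times.
#'
#' @param tables Tibble with `gene_id`, `a`, `b`, `c`, `d`, `n_t`.
#' @param low_cutoff,high_cutoff Informative-count cutoffs defining `L`
#'   and `H` (defaults 25 and 500).
#' @param replicates Number of down-sampled lists (default 50).
#' @param seed Integer seed.
#' @param per_gene Keep only each gene's largest table first (default
#'   `TRUE`, avoiding genes with many significant tables dominating)?
#' @param p_cutoff,lor_cutoff Passed to [passes_criterion()].
#' @return An object of class `downsample_run`: list with `fractions`
#'   (one per replicate), `low_fraction` and `high_fraction` (the directly
#'   computed fractions for `L` and `H`), and `params`.
#' @export
downsample_experiment <- function(tables, low_cutoff = 25,
                                  high_cutoff = 500, replicates = 50,
                                  seed = 1, per_gene = TRUE,
                                  p_cutoff = 5e-7, lor_cutoff = 0.5) {
  if (!"n_t" %in% names(tables)) {
    tables <- mutate(tables, n_t = .data$a + .data$b + .data$c + .data$d)
  }
  if (per_gene) tables <- select_max_pair_per_gene(tables)
  L <- filter(tables, .data$n_t >= low_cutoff)
  H <- filter(tables, .data$n_t >= high_cutoff)
  if (nrow(L) == 0 || nrow(H) == 0) {
    abort("both table lists must be non-empty at the chosen cutoffs")
  }
  if (max(H$n_t) < max(L$n_t)) {
    abort(paste0("no donor table with n_t >= ", max(L$n_t),
                 " available in the high-count list"))
  }
  gene_fraction <- function(df, pass) {
    genes <- tibble(gene_id = df$gene_id, hit = pass) %>%
      group_by(.data$gene_id) %>%
      summarise(hit = any(.data$hit), .groups = "drop")
    mean(genes$hit)
  }
  low_fraction <- gene_fraction(L, passes_criterion(L, p_cutoff, lor_cutoff))
  high_fraction <- gene_fraction(H, passes_criterion(H, p_cutoff, lor_cutoff))

  fractions <- withr::with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      cells <- t(vapply(seq_len(nrow(L)), function(i) {
        elig <- which(H$n_t >= L$n_t[i])
        donor <- elig[sample.int(length(elig), 1)]
        downsample_table(c(H$a[donor], H$b[donor], H$c[donor], H$d[donor]),
                         L$n_t[i])
      }, integer(4)))
      ds <- tibble(gene_id = L$gene_id, a = cells[, 1], b = cells[, 2],
                   c = cells[, 3], d = cells[, 4])
      gene_fraction(ds, passes_criterion(ds, p_cutoff, lor_cutoff))
    }, double(1))
  })
  structure(
    list(fractions = fractions, low_fraction = low_fraction,
         high_fraction = high_fraction,
         params = list(low_cutoff = low_cutoff, high_cutoff = high_cutoff,
                       replicates = replicates, seed = seed,
                       n_low = nrow(L), n_high = nrow(H))),
    class = "downsample_run"
  )
}

#' @export
print.downsample_run <- function(x, ...) {
  cat("Down-sampling control (", x$params$replicates, " replicates, ",
      x$params$n_low, " low / ", x$params$n_high, " high tables)\n",
      sep = "")
  cat("  low-count fraction:   ", signif(x$low_fraction, 4), "\n", sep = "")
  cat("  high-count fraction:  ", signif(x$high_fraction, 4), "\n", sep = "")
  cat("  down-sampled mean:    ", signif(mean(x$fractions), 4),
      "  (range ", signif(min(x$fractions), 4), " - ",
      signif(max(x$fractions), 4), ")\n", sep = "")
  invisible(x)
}

#' Plot the down-sampling control distribution
#'
#' Histogram of the per-replicate down-sampled fractions, with the
#' directly computed low- and high-count fractions as vertical lines.
#'
#' @param run A `downsample_run` object.
#' @return A ggplot object.
#' @export
plot_downsample <- function(run) {
  df <- tibble(fraction = run$fractions)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$fraction)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 100 * run$low_fraction,
                        colour = "orange", linewidth = 1) +
    ggplot2::geom_vline(xintercept = 100 * run$high_fraction,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(x = "% genes with coordination (down-sampled lists)",
                  y = "replicates") +
    ggplot2::theme_minimal()
}
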