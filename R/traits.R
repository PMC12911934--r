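# Trait-table construction: completeness normalization, subsetting, and
# seasonal community-profile contrasts.

#' Completeness-normalized trait table
#'
#' Converts raw annotation hit counts into the normalized trait values used
#' for community profiles: each MAG's gene copy number is expressed as a
#' percentage of its total genes and divided by the mean genome completeness
#' (as a fraction) of quality-filtered MAGs from the same taxonomic order.
#' This corrects the systematic under-detection of genes in incomplete
#' genomes upward:
#'
#' `value(m, t) = 100 * hits(m, t) / total_genes(m) / (mean_completeness(order(m)) / 100)`
#'
#' @param hits A `raw_hit_table` (long data frame; see [read_hit_table()]).
#' @param meta MAG metadata, already quality-filtered ([filter_mags()]);
#'   the order means are computed over the MAGs supplied here.
#' @return Numeric matrix, MAG rows x trait columns (ids sorted), with an
#'   attribute `order_completeness` holding the per-order mean completeness.
#' @export
normalize_by_completeness <- function(hits, meta) {
  m <- hit_matrix(hits)
  missing_meta <- setdiff(rownames(m), meta$mag_id)
  if (length(missing_meta) > 0L) {
    fm_stop("MAG(s) without metadata: ", paste(utils::head(missing_meta, 5L), collapse = ", "),
            class = "fredmag_validation_error")
  }
  meta <- meta[match(rownames(m), meta$mag_id), ]
  if (any(meta$total_genes < 1)) fm_stop("total_genes must be >= 1", class = "fredmag_validation_error")
  order_mean <- tapply(meta$completeness, meta$order, mean)
  if (any(!is.finite(order_mean)) || any(order_mean <= 0)) {
    fm_stop("order with no usable completeness values after filtering",
            class = "fredmag_validation_error")
  }
  denom <- meta$total_genes * (order_mean[meta$order] / 100)
  out <- 100 * sweep(m, 1L, denom, "/")
  attr(out, "order_completeness") <- order_mean
  out
}

#' Column-subset a trait table by a trait category
#'
#' Keeps only the subset's traits, preserving MAG order. MAGs whose rows
#' become all-zero are retained: they may still carry abundance and they
#' contribute genuine functional distance. Trait ids in the subset that are
#' absent from the table (packaged subset lists are supersets of any given
#' annotation run) produce a warning, not an error.
#'
#' @param table Numeric MAG x trait matrix.
#' @param trait_ids Character vector of trait ids (one subset).
#' @return The column-filtered matrix.
#' @export
subset_traits <- function(table, trait_ids) {
  if (length(trait_ids) == 0L) fm_stop("empty trait subset", class = "fredmag_validation_error")
  known <- intersect(trait_ids, colnames(table))
  unknown <- setdiff(trait_ids, colnames(table))
  if (length(unknown) > 0L) {
    fm_warn(length(unknown), " subset trait(s) absent from table: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (length(known) == 0L) {
    fm_stop("no subset trait present in the trait table", class = "fredmag_validation_error")
  }
  table[, known, drop = FALSE]
}

#' Seasonal contrast of community-level gene abundance
#'
#' For each gene, the per-sample community abundance is the
#' abundance-weighted sum over the MAGs encoding it:
#' `A(s, g) = sum_m abundance(s, m) * value(m, g)`. Spring and summer are
#' contrasted per bay (when a `bay` column is present and `by_bay = TRUE`)
#' with a log2 fold change of season means, positive meaning higher in
#' spring, and a two-sided Wilcoxon rank-sum p-value on the per-sample
#' values. Raw p-values drive significance calls; Benjamini-Hochberg
#' adjusted values are reported alongside.
#'
#' @param table MAG x trait matrix (normalized trait values).
#' @param abundance Sample x MAG abundance matrix.
#' @param samples Sample metadata with `sample_id`, `season`, optionally `bay`.
#' @param traits Trait ids to contrast; default all columns of `table`.
#' @param by_bay Contrast within each bay separately (default) when a bay
#'   column exists.
#' @param eps Pseudocount added to both season means before the ratio.
#' @param transform `"log2_ratio"` (default): `log2((mean_sp + eps) / (mean_su + eps))`;
#'   `"log10_diff"`: difference of mean log10 abundances (alternative reading
#'   of the same contrast).
#' @return Data frame with columns `bay`, `trait_id`, `mean_spring`,
#'   `mean_summer`, `log2fc`, `p`, `p_adj`.
#' @export
seasonal_log2fc <- function(table, abundance, samples, traits = colnames(table),
                            by_bay = TRUE, eps = 1e-8,
                            transform = c("log2_ratio", "log10_diff")) {
  transform <- match.arg(transform)
  traits <- intersect(traits, colnames(table))
  if (length(traits) == 0L) fm_stop("no requested trait present", class = "fredmag_validation_error")
  common_mags <- intersect(colnames(abundance), rownames(table))
  if (length(common_mags) == 0L) fm_stop("no shared MAGs", class = "fredmag_validation_error")
  samples <- samples[match(rownames(abundance), samples$sample_id), ]
  # per-sample gene-level community abundance
  comm <- abundance[, common_mags, drop = FALSE] %*% table[common_mags, traits, drop = FALSE]

  groups <- if (by_bay && "bay" %in% names(samples)) unique(samples$bay) else NA_character_
  out <- do.call(rbind, lapply(groups, function(bay) {
    rows <- if (is.na(bay)) rep(TRUE, nrow(comm)) else samples$bay == bay
    season <- samples$season[rows]
    for (s in c("spring", "summer")) {
      if (!any(season == s)) {
        fm_stop("no ", s, " samples", if (!is.na(bay)) paste0(" in bay ", bay),
                class = "fredmag_validation_error")
      }
    }
    sub <- comm[rows, , drop = FALSE]
    res <- lapply(traits, function(tr) {
      sp <- sub[season == "spring", tr]
      su <- sub[season == "summer", tr]
      lfc <- if (transform == "log2_ratio") {
        log2((mean(sp) + eps) / (mean(su) + eps))
      } else {
        mean(log10(sp + eps)) - mean(log10(su + eps))
      }
      p <- if (all(sp == sp[1L]) && all(su == su[1L]) && sp[1L] == su[1L]) {
        1  # degenerate: constant identical values in both seasons
      } else {
        wilcoxon_rank_sum(sp, su)$p
      }
      data.frame(bay = bay, trait_id = tr, mean_spring = mean(sp),
                 mean_summer = mean(su), log2fc = lfc, p = p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    res
  }))
  rownames(out) <- NULL
  out
}
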