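# Expressed traits: TPM normalization of transcript counts and expressed
# FRed. Transcript abundance per gene stands in for trait expression; the
# community weights remain the metagenomic relative abundances.

#' TPM-normalize one sample's transcript counts
#'
#' Transcripts per million: length-normalized read rates rescaled to sum to
#' 1e6 per sample. `rate_g = count_g / (length_g / 1000)`;
#' `TPM_g = 1e6 * rate_g / sum(rate)`.
#'
#' @param counts Long data frame with columns `sample_id`, `gene_id`,
#'   `mag_id`, `trait_id`, `gene_length`, `read_count`.
#' @param sample Sample id to normalize.
#' @return Data frame `gene_id`, `mag_id`, `trait_id`, `tpm` for the sample.
#' @export
tpm_normalize <- function(counts, sample) {
  req <- c("sample_id", "gene_id", "mag_id", "trait_id", "gene_length", "read_count")
  miss <- setdiff(req, names(counts))
  if (length(miss) > 0L) {
    fm_stop("transcript table missing columns: ", paste(miss, collapse = ", "),
            class = "fredmag_validation_error")
  }
  sub <- counts[counts$sample_id == sample, , drop = FALSE]
  if (nrow(sub) == 0L) fm_stop("unknown sample: ", sample, class = "fredmag_validation_error")
  if (anyDuplicated(sub$gene_id)) {
    fm_stop("duplicated gene_id within sample ", sample, class = "fredmag_validation_error")
  }
  if (any(sub$gene_length < 1)) fm_stop("gene_length must be >= 1", class = "fredmag_validation_error")
  if (any(sub$read_count < 0)) fm_stop("negative read counts", class = "fredmag_validation_error")
  rate <- sub$read_count / (sub$gene_length / 1000)
  total <- sum(rate)
  if (total <= 0) {
    fm_stop("sample ", sample, " has no expressed genes", class = "fredmag_validation_error")
  }
  data.frame(gene_id = sub$gene_id, mag_id = sub$mag_id, trait_id = sub$trait_id,
             tpm = rate / total * 1e6, stringsAsFactors = FALSE)
}

#' Aggregate per-gene TPM into a MAG x trait expressed-trait table
#'
#' Gene variants mapping to the same (MAG, trait) cell have their TPM summed.
#' A gene annotated to several traits contributes its full TPM to each
#' (annotation multiplicity, not read double-counting).
#'
#' @param tpm Output of [tpm_normalize()] (columns `mag_id`, `trait_id`, `tpm`).
#' @param mag_ids,trait_ids Optional id universes fixing the output
#'   dimensions (absent cells are 0).
#' @return Numeric MAG x trait matrix of TPM values.
#' @export
aggregate_expressed_traits <- function(tpm, mag_ids = NULL, trait_ids = NULL) {
  mags <- if (is.null(mag_ids)) sort(unique(tpm$mag_id)) else mag_ids
  traits <- if (is.null(trait_ids)) sort(unique(tpm$trait_id)) else trait_ids
  dropped <- !(tpm$mag_id %in% mags & tpm$trait_id %in% traits)
  if (any(dropped & tpm$tpm > 0)) {
    fm_warn(sum(dropped & tpm$tpm > 0), " expressed gene(s) outside the id universe dropped")
  }
  tpm <- tpm[!dropped, , drop = FALSE]
  m <- matrix(0, length(mags), length(traits), dimnames = list(mags, traits))
  if (nrow(tpm) > 0L) {
    agg <- rowsum(tpm$tpm, group = paste(tpm$mag_id, tpm$trait_id, sep = "\r"))
    key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    m[cbind(match(key[, 1L], mags), match(key[, 2L], traits))] <- agg[, 1L]
  }
  m
}

#' Build per-sample expressed trait tables from a transcript count table
#'
#' @param counts Long transcript count table (see [tpm_normalize()]).
#' @param mag_ids,trait_ids Optional id universes for the output matrices.
#' @return Named list (sample id -> MAG x trait TPM matrix). Samples with no
#'   expressed gene are returned as all-zero matrices.
#' @export
expressed_trait_tables <- function(counts, mag_ids = NULL, trait_ids = NULL) {
  samples <- sort(unique(counts$sample_id))
  out <- lapply(samples, function(sid) {
    tryCatch(
      aggregate_expressed_traits(tpm_normalize(counts, sid), mag_ids, trait_ids),
      fredmag_validation_error = function(e) {
        mags <- if (is.null(mag_ids)) sort(unique(counts$mag_id)) else mag_ids
        traits <- if (is.null(trait_ids)) sort(unique(counts$trait_id)) else trait_ids
        matrix(0, length(mags), length(traits), dimnames = list(mags, traits))
      }
    )
  })
  names(out) <- samples
  out
}

#' Expressed FRed across samples and trait subsets
#'
#' Each sample has its own expressed (TPM) trait table, so trait distances
#' are built and max-scaled per sample — a documented asymmetry with
#' potential FRed, whose scaling is global. MAGs enter a sample's community
#' only if they both carry metagenomic abundance and express at least one
#' subset trait; community weights are the metagenomic relative abundances
#' renormalized over those MAGs (transcript-sum weighting is available for
#' sensitivity analysis). Raw TPM enters the distance by default; `log1p`
#' is available behind a flag. Communities with fewer than two expressing
#' MAGs are flagged as `NA` rows. The number of expressed subset traits per
#' community is reported (`n_expressed_traits`) so low-transcript
#' communities can be flagged downstream rather than silently suppressed.
#'
#' @param expressed Named list of per-sample MAG x trait TPM matrices
#'   (see [expressed_trait_tables()]).
#' @param abundance Sample x MAG metagenomic abundance matrix.
#' @param subsets Named list of trait-id vectors; `NULL` = one subset "all".
#' @param weights `"metagenome"` (default) or `"transcript"`.
#' @param transform `"identity"` (default) or `"log1p"` applied to TPM before
#'   the distance.
#' @return A `fred_result` data frame (mode `"expressed"`) with an extra
#'   `n_expressed_traits` column.
#' @export
expressed_fred <- function(expressed, abundance, subsets = NULL,
                           weights = c("metagenome", "transcript"),
                           transform = c("identity", "log1p")) {
  weights <- match.arg(weights)
  transform <- match.arg(transform)
  first <- expressed[[1L]]
  if (is.null(subsets)) subsets <- list(all = colnames(first))
  rows <- lapply(names(expressed), function(sid) {
    etab <- expressed[[sid]]
    do.call(rbind, lapply(names(subsets), function(sname) {
      res <- tryCatch({
        sub <- subset_traits(etab, subsets[[sname]])
        if (transform == "log1p") sub <- log1p(sub)
        if (!sid %in% rownames(abundance)) {
          fm_stop("sample ", sid, " absent from abundance matrix",
                  class = "fredmag_validation_error")
        }
        ab <- abundance[sid, intersect(colnames(abundance), rownames(sub))]
        active <- names(ab)[ab > 0 & rowSums(sub[names(ab), , drop = FALSE]) > 0]
        if (length(active) < 2L) {
          fm_stop("fewer than 2 expressing MAGs", class = "fredmag_undefined_community")
        }
        w <- if (weights == "metagenome") ab[active] else rowSums(sub[active, , drop = FALSE])
        p <- relative_abundance(w)
        d <- trait_distance(sub[active, , drop = FALSE], scale = "max")
        c(fred(p, d), list(n_traits = sum(colSums(sub[active, , drop = FALSE]) > 0)))
      }, fredmag_undefined_community = function(e) {
        list(N = NA_integer_, D = NA_real_, Q = NA_real_, U = NA_real_,
             FRed = NA_real_, n_traits = NA_integer_)
      })
      data.frame(sample_id = sid, subset_name = sname, mode = "expressed",
                 N = res$N, D = res$D, Q = res$Q, U = res$U, FRed = res$FRed,
                 n_expressed_traits = res$n_traits, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$subset_name), ]
  rownames(out) <- NULL
  class(out) <- c("fred_result", "data.frame")
  out
}
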