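# Redundancy core: trait distances, Gini-Simpson, Rao's quadratic entropy,
# uniqueness and FRed. FRed = 1 - Q/D following the uniqueness framework:
# 1 when all community members carry identical traits, 0 when all members
# sit at the maximal pairwise functional distance.

#' Pairwise functional distance matrix from a trait table
#'
#' Euclidean distances between MAG trait rows, divided by the maximum
#' observed pairwise distance so that distances lie in \[0, 1\] (uniqueness
#' U = Q/D is only bounded by 1 for unit-bounded dissimilarities). If all
#' rows are identical the matrix is all-zero. No per-trait standardization
#' is applied.
#'
#' @param table Numeric MAG x trait matrix with >= 2 rows.
#' @param scale `"max"` (default) rescales by the global maximum pairwise
#'   distance; `"none"` returns raw Euclidean distances.
#' @return Symmetric numeric matrix with zero diagonal, MAG ids as dimnames.
#' @export
trait_distance <- function(table, scale = c("max", "none")) {
  scale <- match.arg(scale)
  if (is.null(dim(table)) || nrow(table) < 2L) {
    fm_stop("trait distances need at least 2 MAGs", class = "fredmag_validation_error")
  }
  if (anyNA(table)) fm_stop("missing trait values", class = "fredmag_validation_error")
  d <- as.matrix(stats::dist(table, method = "euclidean"))
  if (scale == "max") {
    dmax <- max(d)
    if (dmax > 0) d <- d / dmax
  }
  d
}

#' Relative-abundance profile of one community
#'
#' Drops MAGs at or below the abundance threshold and renormalizes the rest
#' to sum to one. A community needs at least two retained MAGs for any
#' pairwise redundancy to be defined.
#'
#' @param x Named non-negative abundance vector (one sample's row).
#' @param min_abundance Drop MAGs with abundance `<=` this value (default 0).
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
relative_abundance <- function(x, min_abundance = 0) {
  if (any(x < 0, na.rm = TRUE) || anyNA(x)) {
    fm_stop("abundances must be non-negative and non-missing",
            class = "fredmag_validation_error")
  }
  keep <- x > min_abundance
  if (sum(keep) < 2L) {
    fm_stop("community undefined: fewer than 2 MAGs above the abundance threshold",
            class = "fredmag_undefined_community")
  }
  p <- x[keep] / sum(x[keep])
  p
}

#' Gini-Simpson diversity
#'
#' `D = 1 - sum(p_i^2)`: the probability that two randomly drawn individuals
#' belong to different species.
#'
#' @param p Relative-abundance profile (sums to 1).
#' @return Scalar in \[0, 1).
#' @export
gini_simpson <- function(p) {
  check_profile(p)
  1 - sum(p^2)
}

check_profile <- function(p) {
  if (any(p <= 0)) fm_stop("profile entries must be positive", class = "fredmag_validation_error")
  if (abs(sum(p) - 1) > 1e-12) {
    fm_stop("profile must sum to 1 (within 1e-12)", class = "fredmag_validation_error")
  }
  invisible(p)
}

#' Rao's quadratic entropy
#'
#' `Q = sum_i sum_j p_i p_j d_ij`: abundance-weighted mean pairwise
#' functional dissimilarity (the community's functional diversity).
#' Summation runs over sorted MAG ids for bitwise reproducibility.
#'
#' @param p Named relative-abundance profile.
#' @param d Symmetric distance matrix covering at least the profile's MAGs.
#' @return Scalar `Q >= 0`.
#' @export
rao_q <- function(p, d) {
  check_profile(p)
  ids <- sort(names(p))
  missing <- setdiff(ids, rownames(d))
  if (length(missing) > 0L) {
    fm_stop("MAG(s) absent from distance matrix: ", paste(missing, collapse = ", "),
            class = "fredmag_validation_error")
  }
  pv <- p[ids]
  dv <- d[ids, ids, drop = FALSE]
  as.numeric(pv %*% dv %*% pv)
}

#' Functional redundancy of one community
#'
#' Computes richness `N`, Gini-Simpson `D`, Rao's `Q`, uniqueness `U = Q/D`
#' and `FRed = 1 - U` for one relative-abundance profile against a
#' unit-scaled trait distance matrix.
#'
#' @inheritParams rao_q
#' @return A list with elements `N`, `D`, `Q`, `U`, `FRed`.
#' @export
fred <- function(p, d) {
  D <- gini_simpson(p)
  if (D <= 0) {
    fm_stop("FRed undefined: Gini-Simpson diversity is 0",
            class = "fredmag_undefined_community")
  }
  Q <- rao_q(p, d)
  U <- Q / D
  list(N = length(p), D = D, Q = Q, U = U, FRed = 1 - U)
}

#' Potential FRed across samples and trait subsets
#'
#' For each trait subset the distance matrix is recomputed over the full MAG
#' set and max-scaled once globally, so FRed values are comparable across
#' samples within a run; each sample's profile is then restricted to its
#' MAGs above the abundance threshold. Per-sample rescaling is available via
#' `scale_per_sample` for sensitivity analysis. Samples whose community is
#' undefined for a subset (fewer than two retained MAGs, or zero diversity)
#' are flagged as `NA` rows rather than aborting the run.
#'
#' @param table MAG x trait matrix (raw hit counts by default; see vignette).
#' @param abundance Sample x MAG matrix.
#' @param subsets Named list of trait-id vectors; `NULL` means one subset
#'   `"all"` holding every trait column.
#' @param mode Result label, `"potential"` by default.
#' @param min_abundance Abundance threshold passed to [relative_abundance()].
#' @param scale_per_sample Rescale distances within each sample's community
#'   instead of globally (default `FALSE`).
#' @return A `fred_result` data frame with columns `sample_id`,
#'   `subset_name`, `mode`, `N`, `D`, `Q`, `U`, `FRed`.
#' @export
community_fred <- function(table, abundance, subsets = NULL, mode = "potential",
                           min_abundance = 0, scale_per_sample = FALSE) {
  if (is.null(subsets)) subsets <- list(all = colnames(table))
  common <- intersect(colnames(abundance), rownames(table))
  if (length(common) < 2L) fm_stop("fewer than 2 shared MAGs", class = "fredmag_validation_error")
  rows <- lapply(names(subsets), function(sname) {
    sub <- subset_traits(table, subsets[[sname]])
    d <- trait_distance(sub[common, , drop = FALSE],
                        scale = if (scale_per_sample) "none" else "max")
    do.call(rbind, lapply(rownames(abundance), function(sid) {
      res <- tryCatch({
        p <- relative_abundance(abundance[sid, common], min_abundance)
        ds <- d
        if (scale_per_sample) {
          ds <- d[names(p), names(p), drop = FALSE]
          if (max(ds) > 0) ds <- ds / max(ds)
        }
        fred(p, ds)
      }, fredmag_undefined_community = function(e) {
        list(N = NA_integer_, D = NA_real_, Q = NA_real_, U = NA_real_, FRed = NA_real_)
      })
      data.frame(sample_id = sid, subset_name = sname, mode = mode,
                 N = res$N, D = res$D, Q = res$Q, U = res$U, FRed = res$FRed,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$subset_name), ]
  rownames(out) <- NULL
  class(out) <- c("fred_result", "data.frame")
  out
}
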