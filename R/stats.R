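# Comparative statistics: group contrasts (Wilcoxon, Cliff's delta),
# correlation, OLS models of FRed vs environment, and permutation PERMANOVA.

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks for ties; exact p-value when `n_x + n_y <= 20` and no ties,
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @return List with `statistic` (Mann-Whitney form of the rank-sum
#'   statistic) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    fm_stop("both groups must be non-empty", class = "fredmag_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`: the difference
#' between the probabilities that a value from x exceeds one from y and
#' vice versa. Computed by counting against the sorted y vector
#' (O((n_x + n_y) log n)), exactly equivalent to the all-pairs count.
#'
#' @param x,y Numeric vectors.
#' @return Scalar in \[-1, 1\].
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    fm_stop("both groups must be non-empty", class = "fredmag_validation_error")
  }
  sy <- sort(y)
  n_less <- findInterval(x, sy, left.open = TRUE)   # per x_i: #{y_j < x_i}
  n_leq <- findInterval(x, sy)                      # per x_i: #{y_j <= x_i}
  wins <- sum(n_less)
  losses <- sum(length(y) - n_leq)
  (wins - losses) / (length(x) * length(y))
}

#' Group contrast: Wilcoxon rank-sum plus Cliff's delta
#'
#' @param x,y Numeric value vectors.
#' @param labels Length-2 character vector naming the groups.
#' @return One-row data frame `group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic`, `p`, `delta`.
#' @export
group_contrast <- function(x, y, labels = c("a", "b")) {
  wt <- wilcoxon_rank_sum(x, y)
  data.frame(group_a = labels[1L], group_b = labels[2L],
             n_a = length(x), n_b = length(y),
             statistic = wt$statistic, p = wt$p,
             delta = cliffs_delta(x, y), stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors, `n >= 3`, finite.
#' @return List with `r`, `r2` and two-sided `p` from the t transform with
#'   n - 2 degrees of freedom.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    fm_stop("need paired vectors of length >= 3", class = "fredmag_validation_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    fm_stop("non-finite values", class = "fredmag_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    fm_stop("correlation undefined: zero variance", class = "fredmag_validation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, p = ct$p.value)
}

#' Linear model of FRed against environmental covariates
#'
#' Ordinary least squares with listwise exclusion of samples missing any
#' covariate. Before fitting, highly correlated numeric covariate pairs
#' (pairwise `|r| >` `cor_threshold`) are screened: the later term of each
#' offending pair is dropped and logged. Categorical terms are dummy-coded
#' against their first level.
#'
#' @param data Data frame holding the response and covariates.
#' @param response Response column name (e.g. `"FRed"`).
#' @param terms Character vector of covariate column names.
#' @param cor_threshold Collinearity screen threshold (default 0.9).
#' @return List of class `fred_model`: `fit` (the `lm` object),
#'   `coefficients`, `term_p`, `r2`, `adjusted_r2`, `f_stat`, `p`,
#'   `dropped_terms`, `n`.
#' @export
fit_fred_model <- function(data, response, terms, cor_threshold = 0.9) {
  stopifnot(response %in% names(data), all(terms %in% names(data)))
  keep <- stats::complete.cases(data[c(response, terms)])
  data <- data[keep, , drop = FALSE]
  # collinearity pre-screen on numeric covariates
  numeric_terms <- terms[vapply(data[terms], is.numeric, logical(1L))]
  dropped <- character(0)
  if (length(numeric_terms) >= 2L) {
    cm <- abs(stats::cor(data[numeric_terms]))
    for (i in seq_along(numeric_terms)[-1L]) {
      earlier <- numeric_terms[seq_len(i - 1L)]
      earlier <- setdiff(earlier, dropped)
      if (length(earlier) > 0L && any(cm[numeric_terms[i], earlier] > cor_threshold)) {
        dropped <- c(dropped, numeric_terms[i])
      }
    }
    if (length(dropped) > 0L) {
      fm_log("collinearity screen dropped: ", paste(dropped, collapse = ", "))
    }
  }
  terms <- setdiff(terms, dropped)
  if (nrow(data) <= length(terms) + 1L) {
    fm_stop("too few complete samples for the requested model",
            class = "fredmag_validation_error")
  }
  fml <- stats::reformulate(terms, response)
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    fm_stop("rank-deficient design; aliased terms: ", paste(aliased, collapse = ", "),
            class = "fredmag_validation_error")
  }
  sm <- summary(fit)
  fp <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L], lower.tail = FALSE)
  structure(list(
    fit = fit,
    response = response,
    terms = terms,
    dropped_terms = dropped,
    coefficients = stats::coef(fit),
    term_p = sm$coefficients[, "Pr(>|t|)"],
    r2 = sm$r.squared,
    adjusted_r2 = sm$adj.r.squared,
    f_stat = unname(if (is.null(sm$fstatistic)) NA_real_ else sm$fstatistic[1L]),
    p = unname(fp),
    n = nrow(data)
  ), class = "fred_model")
}

#' @export
print.fred_model <- function(x, ...) {
  cat("FRed linear model:", x$response, "~", paste(x$terms, collapse = " + "), "\n")
  cat(sprintf("n = %d, R2 = %.4f, adj. R2 = %.4f, F = %.3f, p = %.4g\n",
              x$n, x$r2, x$adjusted_r2, x$f_stat, x$p))
  if (length(x$dropped_terms) > 0L) {
    cat("dropped (collinearity):", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Community-weighted mean trait profile per sample
#'
#' The abundance-weighted mean of MAG trait rows, one profile per sample:
#' the sample-level functional trait structure used as PERMANOVA input.
#'
#' @param table MAG x trait matrix.
#' @param abundance Sample x MAG matrix.
#' @return Sample x trait matrix.
#' @export
community_trait_profile <- function(table, abundance) {
  common <- intersect(colnames(abundance), rownames(table))
  if (length(common) == 0L) fm_stop("no shared MAGs", class = "fredmag_validation_error")
  ab <- abundance[, common, drop = FALSE]
  tot <- rowSums(ab)
  if (any(tot <= 0)) fm_stop("sample with zero total abundance", class = "fredmag_validation_error")
  (ab / tot) %*% table[common, , drop = FALSE]
}

#' Permutation PERMANOVA (whole-model pseudo-F)
#'
#' Partitions the total sum of squared dissimilarities
#' (`SS_total = sum(d^2)/n` decomposition via the Gower-centered inner
#' product matrix) between the fitted design and the residual, and assesses
#' the pseudo-F by permuting sample labels:
#' `p = (#{F_perm >= F_obs} + 1) / (n_permutations + 1)`.
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`) over samples.
#' @param design Data frame of grouping factors / covariates (rows aligned
#'   with `d`), or a single factor/vector.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream (required).
#' @return List of class `permanova_result`: `pseudo_f`, `r2`, `p`,
#'   `df_model`, `df_residual`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, design, n_permutations = 999, seed) {
  if (missing(seed)) fm_stop("permanova requires an explicit seed", class = "fredmag_validation_error")
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-10)) {
    fm_stop("dissimilarity must be square and symmetric", class = "fredmag_validation_error")
  }
  if (!is.data.frame(design)) design <- data.frame(group = design)
  if (nrow(design) != n) fm_stop("design rows must match dissimilarity", class = "fredmag_validation_error")
  for (col in names(design)) {
    if (!is.numeric(design[[col]])) {
      design[[col]] <- factor(design[[col]])
      if (nlevels(design[[col]]) < 2L) {
        fm_stop("design term '", col, "' has a single level", class = "fredmag_validation_error")
      }
      if (any(table(design[[col]]) < 2L)) {
        fm_stop("design term '", col, "' has a group with < 2 members",
                class = "fredmag_validation_error")
      }
    }
  }
  # Gower-centered inner-product matrix G = -0.5 * C A C, A = d^2
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  X <- stats::model.matrix(stats::reformulate(names(design)), design)
  qr_x <- qr(X)
  H <- tcrossprod(qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE])
  df_model <- qr_x$rank - 1L
  df_res <- n - qr_x$rank
  if (df_model < 1L || df_res < 1L) {
    fm_stop("degenerate design: no model or residual degrees of freedom",
            class = "fredmag_validation_error")
  }
  ss_total <- sum(diag(G))
  f_of <- function(perm) {
    Gp <- G[perm, perm]
    ss_model <- sum(H * Gp)  # tr(H Gp), H symmetric idempotent
    (ss_model / df_model) / ((sum(diag(Gp)) - ss_model) / df_res)
  }
  f_obs <- f_of(seq_len(n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_permutations), function(i) f_of(sample.int(n)), numeric(1L))
  pval <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
  ss_model <- sum(H * G)
  structure(list(pseudo_f = f_obs, r2 = ss_model / ss_total, p = pval,
                 df_model = df_model, df_residual = df_res,
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.3f (df %d, %d), R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$df_model, x$df_residual, x$r2, x$p, x$n_permutations))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
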