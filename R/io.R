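# Readers and writers for the tabular interchange formats. All tables are
# TSV, UTF-8, with a header row; samples are rows and features are columns
# throughout (a transpose flag handles the other dialect on read).

read_tsv_checked <- function(path) {
  if (!file.exists(path)) fm_stop("file not found: ", path, class = "fredmag_io_error")
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) fm_stop("malformed TSV '", path, "': ", conditionMessage(e),
                                class = "fredmag_parse_error")
  )
  if (nrow(df) == 0L && ncol(df) == 0L) {
    fm_stop("empty file: ", path, class = "fredmag_parse_error")
  }
  df
}

#' Read a MAG x gene annotation hit table
#'
#' Reads HMM hit counts per MAG per gene, as produced by annotation
#' pipelines. Two layouts are auto-detected from the header: a long
#' three-column layout (`mag_id`, `trait_id`, `hit_count`) or a wide layout
#' with a `mag_id` column (or first column) and one numeric column per
#' gene/trait. Missing cells are treated as 0 hits.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame of class `raw_hit_table` with columns `mag_id`,
#'   `trait_id`, `hit_count` (one row per MAG x trait pair, zeros included).
#' @export
read_hit_table <- function(path) {
  df <- read_tsv_checked(path)
  long_cols <- c("mag_id", "trait_id", "hit_count")
  if (all(long_cols %in% names(df))) {
    extra <- setdiff(names(df), long_cols)
    if (length(extra) > 0L) {
      fm_warn("ignoring extra columns in hit table: ", paste(extra, collapse = ", "))
    }
    out <- df[long_cols]
  } else {
    id_col <- if ("mag_id" %in% names(df)) "mag_id" else names(df)[1L]
    trait_cols <- setdiff(names(df), id_col)
    if (length(trait_cols) == 0L) {
      fm_stop("hit table has no trait columns", class = "fredmag_validation_error")
    }
    out <- data.frame(
      mag_id = rep(as.character(df[[id_col]]), times = length(trait_cols)),
      trait_id = rep(trait_cols, each = nrow(df)),
      hit_count = unlist(lapply(df[trait_cols], as.numeric), use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  out$mag_id <- as.character(out$mag_id)
  out$trait_id <- as.character(out$trait_id)
  out$hit_count <- as.numeric(out$hit_count)
  out$hit_count[is.na(out$hit_count)] <- 0
  validate_hit_table(out)
}

validate_hit_table <- function(hits) {
  stopifnot(all(c("mag_id", "trait_id", "hit_count") %in% names(hits)))
  check_ids(unique(hits$mag_id), "MAG")
  check_ids(unique(hits$trait_id), "trait")
  if (anyDuplicated(hits[c("mag_id", "trait_id")])) {
    fm_stop("duplicated (mag_id, trait_id) pairs in hit table",
            class = "fredmag_validation_error")
  }
  bad <- which(hits$hit_count < 0)
  if (length(bad) > 0L) {
    fm_stop("negative hit count for (", hits$mag_id[bad[1L]], ", ",
            hits$trait_id[bad[1L]], ")", class = "fredmag_validation_error")
  }
  class(hits) <- c("raw_hit_table", "data.frame")
  hits
}

#' Pivot a long hit table to a MAG x trait matrix
#'
#' @param hits A `raw_hit_table` (see [read_hit_table()]).
#' @return Numeric matrix, MAG rows x trait columns, ids sorted, absent
#'   pairs filled with 0.
#' @export
hit_matrix <- function(hits) {
  mags <- sort(unique(hits$mag_id))
  traits <- sort(unique(hits$trait_id))
  m <- matrix(0, nrow = length(mags), ncol = length(traits),
              dimnames = list(mags, traits))
  m[cbind(match(hits$mag_id, mags), match(hits$trait_id, traits))] <- hits$hit_count
  m
}

#' Read a sample x MAG abundance matrix
#'
#' Abundance values are consumed as produced upstream (e.g. CoverM-style
#' normalized coverage); they are not recomputed here.
#'
#' @param path TSV path; first column holds ids, remaining columns numeric.
#' @param samples_as_rows If `FALSE` the file is transposed on read
#'   (MAG rows x sample columns dialect).
#' @param mag_metadata Optional MAG metadata data frame; MAGs present in the
#'   abundance table but absent from the metadata trigger a warning and are
#'   retained.
#' @return Numeric matrix with samples as rows, MAGs as columns.
#' @export
read_abundance_matrix <- function(path, samples_as_rows = TRUE, mag_metadata = NULL) {
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) {
    fm_stop("non-numeric abundance values in ", path, class = "fredmag_validation_error")
  }
  rownames(m) <- ids
  if (!samples_as_rows) m <- t(m)
  check_ids(rownames(m), "sample")
  check_ids(colnames(m), "MAG")
  if (anyNA(m)) fm_stop("missing abundance values", class = "fredmag_validation_error")
  if (any(m < 0)) fm_stop("negative abundance values", class = "fredmag_validation_error")
  if (!is.null(mag_metadata)) {
    unknown <- setdiff(colnames(m), mag_metadata$mag_id)
    if (length(unknown) > 0L) {
      fm_warn(length(unknown), " MAG(s) in abundance matrix have no metadata: ",
              paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  m
}

#' Read MAG metadata
#'
#' @param path TSV with columns `mag_id`, `total_genes`, `completeness`,
#'   `contamination`, `order`, `fraction`.
#' @return Validated data frame.
#' @export
read_mag_metadata <- function(path) {
  df <- read_tsv_checked(path)
  req <- c("mag_id", "total_genes", "completeness", "contamination", "order")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    fm_stop("MAG metadata missing columns: ", paste(miss, collapse = ", "),
            class = "fredmag_validation_error")
  }
  df$mag_id <- as.character(df$mag_id)
  check_ids(df$mag_id, "MAG")
  if (any(df$total_genes < 1)) fm_stop("total_genes must be >= 1", class = "fredmag_validation_error")
  if (any(df$completeness <= 0 | df$completeness > 100)) {
    fm_stop("completeness must lie in (0, 100]", class = "fredmag_validation_error")
  }
  if (any(df$contamination < 0 | df$contamination >= 100)) {
    fm_stop("contamination must lie in [0, 100)", class = "fredmag_validation_error")
  }
  df
}

#' Read sample metadata
#'
#' Categorical fields are checked against their vocabularies; continuous
#' covariates may be missing (`NA`) and are excluded listwise per model fit.
#'
#' @param path TSV with a `sample_id` column plus categorical and continuous
#'   covariates.
#' @return Validated data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_checked(path)
  if (!"sample_id" %in% names(df)) {
    fm_stop("sample metadata needs a sample_id column", class = "fredmag_validation_error")
  }
  df$sample_id <- as.character(df$sample_id)
  check_ids(df$sample_id, "sample")
  enums <- list(bay = c("Chesapeake", "Delaware"),
                season = c("spring", "summer"),
                salinity_class = c("low", "medium", "high"),
                fraction = c("PA", "FL"))
  for (col in names(enums)) {
    if (col %in% names(df)) {
      bad <- setdiff(unique(df[[col]]), c(enums[[col]], NA))
      if (length(bad) > 0L) {
        fm_stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "),
                class = "fredmag_validation_error")
      }
    }
  }
  df
}

#' Quality-filter MAGs on completeness and contamination
#'
#' Retains MAGs with completeness strictly above `min_completeness` and
#' contamination strictly below `max_contamination` (the standard
#' high-quality bin rule: >70% complete, <5% contaminated).
#'
#' @param meta MAG metadata data frame.
#' @param min_completeness,max_contamination Thresholds in (0, 100).
#' @return The filtered metadata; the number of removed MAGs is logged.
#' @export
filter_mags <- function(meta, min_completeness = 70, max_contamination = 5) {
  stopifnot(min_completeness > 0, min_completeness < 100,
            max_contamination > 0, max_contamination < 100)
  keep <- meta$completeness > min_completeness & meta$contamination < max_contamination
  n_removed <- sum(!keep)
  fm_log("filter_mags: removed ", n_removed, " of ", nrow(meta), " MAGs")
  meta[keep, , drop = FALSE]
}

#' Read trait-subset definitions
#'
#' @param path TSV with columns `subset_name`, `trait_id`.
#' @return Named list of character vectors (trait ids per subset).
#' @export
read_trait_subsets <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("subset_name", "trait_id") %in% names(df))) {
    fm_stop("subset file needs subset_name and trait_id columns",
            class = "fredmag_validation_error")
  }
  subsets <- split(as.character(df$trait_id), df$subset_name)
  if (any(lengths(subsets) == 0L)) fm_stop("empty trait subset", class = "fredmag_validation_error")
  lapply(subsets, unique)
}

#' Default illustrative trait-subset definitions
#'
#' Returns the packaged marker-gene subset lists (energy, substrate, CO, H2,
#' N, S, CAZy). These are illustrative defaults built from field-standard
#' marker names, not the gene universe of any particular annotation run;
#' supply your own subset TSV for real analyses.
#'
#' @return Named list of character vectors.
#' @export
default_trait_subsets <- function() {
  read_trait_subsets(system.file("extdata", "trait_subsets.tsv",
                                 package = "fredmag", mustWork = TRUE))
}

#' Write (and read back) FRed result tables
#'
#' Writes the standard eight-column result TSV (`sample_id`, `subset_name`,
#' `mode`, `N`, `D`, `Q`, `U`, `FRed`) with deterministic row order
#' (sample_id, then subset_name, then mode), so identical inputs always
#' produce byte-identical files.
#'
#' @param results A `fred_result` data frame (see [community_fred()]).
#' @param path Output path.
#' @export
write_fred_results <- function(results, path) {
  cols <- c("sample_id", "subset_name", "mode", "N", "D", "Q", "U", "FRed")
  if (is.null(results) || nrow(results) == 0L) {
    fm_stop("no results to write", class = "fredmag_validation_error")
  }
  miss <- setdiff(cols, names(results))
  if (length(miss) > 0L) {
    fm_stop("results missing columns: ", paste(miss, collapse = ", "),
            class = "fredmag_validation_error")
  }
  out <- results[order(results$sample_id, results$subset_name, results$mode), cols]
  for (col in c("D", "Q", "U", "FRed")) out[[col]] <- sprintf("%.15g", out[[col]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fm_stop("cannot write to ", path, class = "fredmag_io_error")
  invisible(path)
}

#' @rdname write_fred_results
#' @return `read_fred_results()` returns the parsed `fred_result` data frame.
#' @export
read_fred_results <- function(path) {
  df <- read_tsv_checked(path)
  num <- c("N", "D", "Q", "U", "FRed")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  class(df) <- c("fred_result", "data.frame")
  df
}

# generic TSV matrix writer used by the CLI (row ids in first column)
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# matching reader: first column becomes rownames
read_matrix_tsv <- function(path) {
  df <- read_tsv_checked(path)
  m <- as.matrix(df[-1L])
  rownames(m) <- as.character(df[[1L]])
  m
}
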