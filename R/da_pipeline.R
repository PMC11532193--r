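#' Read a count table and sample metadata into an abundance study
#'
#' Reads a taxa-by-samples count table (first column taxon identifiers,
#' remaining columns one per sample) and a per-sample metadata table (first
#' column sample identifiers) from TSV or CSV files, matches samples, and
#' records library sizes as the column sums of the full, unfiltered count
#' matrix.
#'
#' @param counts_file path to the count table (TSV by default; `.csv`
#'   extension switches to comma separation).
#' @param metadata_file path to the metadata table.
#' @return list of class `"abundance_study"` with `counts` (integer matrix,
#'   taxa x samples), `metadata` (data frame, rows aligned with the columns
#'   of `counts`), and `library_sizes` (named per-sample totals).
#' @export
read_abundance <- function(counts_file, metadata_file) {
  read_any <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
  }
  ctab <- read_any(counts_file)
  counts <- as.matrix(ctab[, -1L, drop = FALSE])
  rownames(counts) <- as.character(ctab[[1L]])
  storage.mode(counts) <- "double"
  meta <- read_any(metadata_file)
  rownames(meta) <- as.character(meta[[1L]])
  abundance_study(counts, meta)
}

#' Assemble an abundance study from in-memory objects
#'
#' @param counts taxa x samples non-negative count matrix with row and
#'   column names.
#' @param metadata per-sample data frame; either its row names or its first
#'   column must match `colnames(counts)`.
#' @return an `"abundance_study"` list; see [read_abundance()].
#' @export
abundance_study <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  ids <- colnames(counts)
  if (is.null(ids)) stop("counts must have sample (column) names")
  rn <- rownames(metadata)
  if (is.null(rn) || !all(ids %in% rn)) {
    if (all(ids %in% as.character(metadata[[1L]])))
      rownames(metadata) <- as.character(metadata[[1L]])
    else
      stop("sample identifiers in counts and metadata do not match")
  }
  metadata <- metadata[ids, , drop = FALSE]
  structure(
    list(counts = counts, metadata = metadata,
         library_sizes = colSums(counts)),
    class = "abundance_study"
  )
}

#' @export
print.abundance_study <- function(x, ...) {
  cat(sprintf("Abundance study: %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("Metadata columns:", paste(colnames(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Prevalence filter for taxa
#'
#' Keeps taxa whose prevalence — the fraction of samples with a nonzero
#' count — is at least `threshold` (typical choices: 0.05 or 0.10). Library
#' sizes computed from the unfiltered matrix are preserved so that
#' total-sum-scaling offsets stay faithful to the full sequencing depth.
#'
#' @param study an `"abundance_study"`, or a bare count matrix.
#' @param threshold minimum prevalence, in \[0, 1\].
#' @return for a study input, a filtered `"abundance_study"` with attributes
#'   `"dropped"` (dropped taxon names) and `"prevalence"` (per-taxon
#'   prevalences of the input); for a matrix input, the filtered matrix with
#'   the same attributes.
#' @export
prevalence_filter <- function(study, threshold = 0.05) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  counts <- if (inherits(study, "abundance_study")) study$counts else as.matrix(study)
  prevalence <- rowMeans(counts > 0)
  keep <- prevalence >= threshold
  dropped <- rownames(counts)[!keep]
  if (inherits(study, "abundance_study")) {
    out <- study
    out$counts <- counts[keep, , drop = FALSE]
    # library_sizes deliberately untouched: pre-filter totals
  } else {
    out <- counts[keep, , drop = FALSE]
  }
  attr(out, "dropped") <- dropped
  attr(out, "prevalence") <- prevalence
  out
}

#' Per-taxon differential abundance with robust standard errors
#'
#' For every retained taxon, fits a Poisson log-linear model of its counts on
#' the exposure and any adjustment covariates with a log-library-size offset
#' (total-sum scaling, using pre-filter library sizes), estimates the
#' coefficient covariance by the chosen method, Wald-tests the exposure
#' coefficient, and applies Benjamini-Hochberg adjustment across taxa.
#' Taxa whose fit fails or does not converge are reported with `NA`
#' statistics and excluded from the BH family.
#'
#' @param study an `"abundance_study"`.
#' @param exposure name of the metadata column to test.
#' @param adjust optional character vector of adjustment covariate names.
#' @param method covariance estimator, one of [benchmark_methods()].
#' @param prevalence minimum taxon prevalence (fraction of samples with a
#'   nonzero count); taxa below it are dropped before fitting.
#' @param B bootstrap resamples (used only when `method = "bootstrap"`).
#' @param seed integer seed for the bootstrap streams.
#' @param level confidence level for the per-taxon Wald intervals.
#' @return data frame of class `"taxon_results"`, one row per retained
#'   taxon: `taxon`, `prevalence`, `estimate` (log fold change per exposure
#'   unit), `se`, `statistic`, `p`, `p_bh`, `ci_lower`, `ci_upper`,
#'   `converged`, `method`.
#' @export
fit_all_taxa <- function(study, exposure, adjust = NULL,
                         method = "sandwich_hc3", prevalence = 0.05,
                         B = 1000L, seed = NULL, level = 0.95) {
  stopifnot(inherits(study, "abundance_study"))
  method <- match.arg(method, benchmark_methods())
  meta <- study$metadata
  vars <- c(exposure, adjust)
  missing_vars <- setdiff(vars, colnames(meta))
  if (length(missing_vars))
    stop("metadata lacks column(s): ", paste(missing_vars, collapse = ", "))
  if (length(unique(meta[[exposure]])) < 2L)
    stop("exposure '", exposure, "' is constant")

  filtered <- prevalence_filter(study, prevalence)
  counts <- filtered$counts
  prev <- attr(filtered, "prevalence")[rownames(counts)]
  offset <- log(study$library_sizes)
  X <- stats::model.matrix(stats::reformulate(vars), data = meta)
  exp_cols <- which(attr(X, "assign") == 1L)
  if (length(exp_cols) > 1L)
    warning("exposure has more than two levels; testing its first contrast column")
  exp_col <- exp_cols[1L]
  n <- nrow(X)
  p <- ncol(X)
  df <- if (method == "quasipoisson") n - p else Inf

  if (!is.null(seed)) set.seed(seed)
  taxa <- rownames(counts)
  res <- data.frame(
    taxon = taxa, prevalence = prev,
    estimate = NA_real_, se = NA_real_, statistic = NA_real_,
    p = NA_real_, p_bh = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
    converged = FALSE, method = method, row.names = NULL
  )
  for (t in seq_along(taxa)) {
    y <- counts[t, ]
    ans <- tryCatch(suppressWarnings({
      if (method == "negbin") {
        nb <- negbin_fit(y, X, offset = offset)
        if (!nb$converged) stop("no convergence")
        list(b = nb$fit$coefficients[exp_col], se = nb$vcov$se[exp_col])
      } else {
        fit <- irls_fit(y, X, offset = offset)
        if (!fit$converged) stop("no convergence")
        v <- switch(method,
          poisson_naive = vcov_naive(fit),
          sandwich_hc3 = vcov_hc3(fit),
          quasipoisson = vcov_quasipoisson(fit),
          bootstrap = vcov_bootstrap(y, X, offset = offset, B = B)
        )
        list(b = fit$coefficients[exp_col], se = v$se[exp_col])
      }
    }), error = function(e) NULL)
    if (is.null(ans) || !is.finite(ans$se) || ans$se <= 0) next
    w <- wald_test(ans$b, ans$se, level = level, df = df)
    res$estimate[t] <- ans$b
    res$se[t] <- ans$se
    res$statistic[t] <- w$statistic
    res$p[t] <- w$p_value
    res$ci_lower[t] <- w$ci_lower
    res$ci_upper[t] <- w$ci_upper
    res$converged[t] <- TRUE
  }
  res$p_bh <- bh_adjust(res$p)
  class(res) <- c("taxon_results", "data.frame")
  res
}

#' Write a taxon result table as TSV with a provenance header
#'
#' @param results a `"taxon_results"` data frame from [fit_all_taxa()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_taxon_results <- function(results, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# robustpois %s  method=%s  date=%s",
                     as.character(utils::packageVersion("robustpois")),
                     results$method[1L], format(Sys.Date())), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
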