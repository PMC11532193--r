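#' Covariance methods known to the benchmark
#' @return character vector of method names.
#' @export
benchmark_methods <- function() {
  c("poisson_naive", "sandwich_hc3", "bootstrap", "negbin", "quasipoisson")
}

# master seed -> stream of derived seeds, all below 2^31
derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, k)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Run one simulation cell
#'
#' One cell of the simulation study: `n_reps` replicates of a single
#' generator family and effect size, each fitted by Poisson IRLS, with the
#' coefficient covariance estimated by every requested method, Wald
#' intervals/tests formed, and the replicate batch summarised by
#' [summarize_replicates()]. All Poisson-based methods share the identical
#' point estimates within a replicate; the negative binomial baseline is
#' refitted by its own likelihood (on the balanced two-group design its
#' coefficient estimates coincide with the Poisson ones).
#'
#' Per-replicate seeds are derived deterministically from `seed`, so any
#' single replicate can be reproduced in isolation; the bootstrap resampling
#' of replicate `i` continues the RNG stream of that replicate.
#'
#' @param family generator family, one of [sim_families()].
#' @param beta0,beta1 true intercept and slope (effect sizes 0, 0.1 and 1.5
#'   are the three study settings).
#' @param methods character vector of covariance methods, from
#'   [benchmark_methods()].
#' @param n per-replicate sample size (study design: 200).
#' @param n_reps number of Monte-Carlo replicates (study design: 500).
#' @param B bootstrap resamples per replicate, if `"bootstrap"` is requested.
#' @param seed integer cell seed.
#' @param level confidence level (default 0.95; tests at `alpha = 0.05`).
#' @return data frame: the [summarize_replicates()] output stacked over
#'   methods, with a `method` column; attributes `n_failures` (replicates on
#'   which the base fit failed, excluded from all summaries) and `flagged`
#'   (`TRUE` if more than 5% of replicates failed).
#' @export
run_cell <- function(family, beta0, beta1, methods = "sandwich_hc3",
                     n = 200L, n_reps = 500L, B = 1000L, seed = 1L,
                     level = 0.95) {
  methods <- match.arg(methods, benchmark_methods(), several.ok = TRUE)
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("n_reps must be >= 2: SEE is undefined for fewer replicates")
  x <- sim_covariate(n)
  X <- cbind("(Intercept)" = 1, x = x)
  p <- ncol(X)
  truth <- c(beta0, beta1)

  rep_seeds <- derive_seeds(seed, n_reps)
  est <- lapply(methods, function(m)
    matrix(NA_real_, n_reps, p, dimnames = list(NULL, colnames(X))))
  ses <- lapply(methods, function(m)
    matrix(NA_real_, n_reps, p, dimnames = list(NULL, colnames(X))))
  names(est) <- names(ses) <- methods
  failures <- 0L

  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    y <- sim_response(x, beta0, beta1, family)
    fit <- tryCatch(suppressWarnings(irls_fit(y, X)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      failures <- failures + 1L
      next
    }
    for (m in methods) {
      res <- tryCatch(suppressWarnings(switch(m,
        poisson_naive = {
          v <- vcov_naive(fit)
          list(b = fit$coefficients, se = v$se)
        },
        sandwich_hc3 = {
          v <- vcov_hc3(fit)
          list(b = fit$coefficients, se = v$se)
        },
        quasipoisson = {
          v <- vcov_quasipoisson(fit)
          list(b = fit$coefficients, se = v$se)
        },
        bootstrap = {
          v <- vcov_bootstrap(y, X, B = B)
          list(b = fit$coefficients, se = v$se)
        },
        negbin = {
          nb <- negbin_fit(y, X)
          list(b = nb$fit$coefficients, se = nb$vcov$se)
        }
      )), error = function(e) NULL)
      if (!is.null(res)) {
        est[[m]][i, ] <- res$b
        ses[[m]][i, ] <- res$se
      }
    }
  }

  out <- do.call(rbind, lapply(methods, function(m) {
    keep <- stats::complete.cases(est[[m]]) & stats::complete.cases(ses[[m]])
    if (sum(keep) < 2L)
      stop("fewer than 2 successful replicates for method ", m)
    df <- if (m == "quasipoisson") n - p else Inf
    s <- summarize_replicates(
      est[[m]][keep, , drop = FALSE],
      ses[[m]][keep, , drop = FALSE],
      truth, level = level, df = df
    )
    cbind(method = m, s)
  }))
  attr(out, "n_failures") <- failures
  attr(out, "flagged") <- failures > 0.05 * n_reps
  attr(out, "settings") <- list(family = family, beta0 = beta0,
                                beta1 = beta1, n = n, n_reps = n_reps,
                                B = B, seed = seed)
  out
}

#' Run the full simulation benchmark
#'
#' Iterates [run_cell()] over every combination of effect settings and
#' generator families, producing one metric table per combination in the
#' layout of the study's result tables (rows: Bias/SEE/SEM/MSE/CP per
#' parameter plus a final "Type I error" or "power" row; columns: methods).
#'
#' @param settings list of `c(beta0, beta1)` pairs; the defaults are the
#'   three study settings (no, small, large effect at intercept 2).
#' @param families generator families to include.
#' @param methods covariance methods to include.
#' @param n,n_reps,B per-cell design sizes as in [run_cell()].
#' @param seed master seed; per-cell seeds are derived from it so cells are
#'   independent and individually reproducible.
#' @param out_dir optional directory; when given each table is written as a
#'   TSV via [write_benchmark_table()].
#' @return named list of table data frames (names like
#'   `"beta1_0_gamma_misspec"`), each with attribute `"metrics"` holding the
#'   raw [run_cell()] output.
#' @export
run_benchmark <- function(settings = list(c(2, 0), c(2, 0.1), c(2, 1.5)),
                          families = sim_families(),
                          methods = benchmark_methods(),
                          n = 200L, n_reps = 500L, B = 1000L, seed = 1L,
                          out_dir = NULL) {
  if (!length(settings) || !length(families) || !length(methods))
    stop("settings, families and methods must be non-empty")
  combos <- expand.grid(si = seq_along(settings), fi = seq_along(families))
  cell_seeds <- derive_seeds(seed, nrow(combos))
  tables <- list()
  for (k in seq_len(nrow(combos))) {
    bb <- settings[[combos$si[k]]]
    fam <- families[combos$fi[k]]
    message(sprintf("cell %d/%d: family=%s beta1=%g", k, nrow(combos), fam, bb[2]))
    cell <- run_cell(fam, bb[1], bb[2], methods = methods, n = n,
                     n_reps = n_reps, B = B, seed = cell_seeds[k])
    tab <- format_benchmark_table(cell)
    name <- sprintf("beta1_%s_%s", gsub("\\.", "p", format(bb[2])), fam)
    attr(tab, "metrics") <- cell
    tables[[name]] <- tab
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_benchmark_table(tab, file.path(out_dir, paste0(name, ".tsv")),
                            settings = attr(cell, "settings"))
    }
  }
  tables
}

# reshape run_cell output into the tables' layout:
# rows Bias/SEE/SEM/MSE/CP per parameter + Type I error or power; one column
# per method.
format_benchmark_table <- function(cell) {
  methods <- unique(cell$method)
  params <- unique(cell$parameter)
  truth <- cell$truth[match(params, cell$parameter)]
  slope_truth <- truth[length(truth)]
  rate_label <- if (slope_truth == 0) "Type I error" else "power"
  rows <- list()
  for (pm in params) {
    sub <- cell[cell$parameter == pm, ]
    for (metric in c("bias", "see", "sem", "mse", "cp")) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pm, metric = c(bias = "Bias", see = "SEE", sem = "SEM",
                                   mse = "MSE", cp = "CP")[[metric]],
        t(stats::setNames(sub[[metric]][match(methods, sub$method)], methods)),
        check.names = FALSE
      )
    }
  }
  slope <- params[length(params)]
  sub <- cell[cell$parameter == slope, ]
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = slope, metric = rate_label,
    t(stats::setNames(sub$rejection_rate[match(methods, sub$method)], methods)),
    check.names = FALSE
  )
  do.call(rbind, rows)
}

#' Write a benchmark table as TSV with a provenance header
#'
#' @param tab a table from [run_benchmark()].
#' @param file output path.
#' @param settings optional list of cell settings recorded as `#`-prefixed
#'   header lines.
#' @return `file`, invisibly.
#' @export
write_benchmark_table <- function(tab, file, settings = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# robustpois %s",
                     as.character(utils::packageVersion("robustpois"))), con)
  if (!is.null(settings))
    writeLines(sprintf("# %s", paste(names(settings),
                                     vapply(settings, format, ""),
                                     sep = "=", collapse = " ")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
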