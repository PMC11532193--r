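make_study <- function(n_samples = 100, n_taxa = 30, signal_fraction = 0,
                       seed = 1, ...) {
  s <- sim_multitaxon(n_samples = n_samples, n_taxa = n_taxa,
                      signal_fraction = signal_fraction, seed = seed, ...)
  list(study = abundance_study(s$counts, s$metadata), truth = s$truth,
       sim = s)
}

test_that("prevalence filter matches a brute-force counting oracle", {
  set.seed(2)
  n_s <- 20
  counts <- t(sapply(seq(0, 1, length.out = 100), function(pr) {
    pres <- as.integer(runif(n_s) < pr)
    pres * rpois(n_s, 5)
  }))
  rownames(counts) <- paste0("t", 1:100)
  colnames(counts) <- paste0("s", 1:n_s)

  filt <- prevalence_filter(counts, 0.25)
  brute_keep <- rownames(counts)[rowSums(counts > 0) / n_s >= 0.25]
  expect_identical(rownames(filt), brute_keep)
  expect_setequal(attr(filt, "dropped"), setdiff(rownames(counts), brute_keep))

  # threshold 0 is the identity; a 1-in-20 taxon is dropped at 0.10
  expect_identical(rownames(prevalence_filter(counts, 0)), rownames(counts))
  one_hit <- matrix(c(3, rep(0, 19)), 1, 20,
                    dimnames = list("rare", paste0("s", 1:20)))
  expect_equal(nrow(prevalence_filter(one_hit, 0.10)), 0)
  expect_error(prevalence_filter(counts, 1.5), "\\[0, 1\\]")
})

test_that("library sizes are preserved from the unfiltered matrix", {
  ms <- make_study(n_samples = 40, n_taxa = 20, seed = 3)
  counts <- ms$study$counts
  counts[1:5, 1:32] <- 0  # force 5 taxa below 25% prevalence
  counts[1:5, 33:40] <- 7 # but still contributing to some library sizes
  study <- abundance_study(counts, ms$study$metadata)
  pre_ls <- study$library_sizes
  filt <- prevalence_filter(study, 0.5)
  expect_lt(nrow(filt$counts), nrow(counts))
  expect_identical(filt$library_sizes, pre_ls)
  expect_false(isTRUE(all.equal(unname(colSums(filt$counts)), unname(pre_ls))))
})

test_that("doubling all counts leaves exposure estimates and p-values unchanged", {
  ms <- make_study(n_samples = 80, n_taxa = 15, signal_fraction = 0.2,
                   effect = 1, seed = 9)
  r1 <- fit_all_taxa(ms$study, "x", method = "sandwich_hc3")
  study2 <- abundance_study(2 * ms$study$counts, ms$study$metadata)
  r2 <- fit_all_taxa(study2, "x", method = "sandwich_hc3")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("results are invariant to taxon and sample ordering", {
  ms <- make_study(n_samples = 60, n_taxa = 12, signal_fraction = 0.25,
                   effect = 1, seed = 12)
  r1 <- fit_all_taxa(ms$study, "x", method = "sandwich_hc3")
  set.seed(1)
  tperm <- sample(nrow(ms$study$counts))
  sperm <- sample(ncol(ms$study$counts))
  study_p <- abundance_study(ms$study$counts[tperm, sperm],
                             ms$study$metadata[sperm, ])
  r2 <- fit_all_taxa(study_p, "x", method = "sandwich_hc3")
  r2 <- r2[match(r1$taxon, r2$taxon), ]
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
  expect_equal(r1$p_bh, r2$p_bh, tolerance = 1e-8)
})

test_that("under a global null the robust pipeline makes essentially no discoveries", {
  zero_disc <- vapply(1:10, function(s) {
    ms <- make_study(n_samples = 100, n_taxa = 50, signal_fraction = 0,
                     seed = 1000 + s)
    res <- fit_all_taxa(ms$study, "x", method = "sandwich_hc3",
                        prevalence = 0.05)
    sum(res$p_bh < 0.05, na.rm = TRUE) == 0
  }, logical(1))
  expect_gte(sum(zero_disc), 8)
})

test_that("robust and naive inference agree under equidispersion but the sandwich curbs false discoveries under overdispersion", {
  # near-Poisson counts: p-values from the two methods are rank-aligned
  ms <- make_study(n_samples = 400, n_taxa = 40, signal_fraction = 0.25,
                   effect = 0.8, dispersion = 1e6, depth_sdlog = 0, seed = 21)
  r_naive <- fit_all_taxa(ms$study, "x", method = "poisson_naive")
  r_sand <- fit_all_taxa(ms$study, "x", method = "sandwich_hc3")
  ok <- r_naive$converged & r_sand$converged
  expect_gt(cor(rank(r_naive$p[ok]), rank(r_sand$p[ok])), 0.99)

  # overdispersed counts: sandwich empirical FDR no worse than naive
  ms2 <- make_study(n_samples = 200, n_taxa = 100, signal_fraction = 0.3,
                    effect = 1.5, dispersion = 0.5, seed = 31)
  truth <- ms2$truth
  fdr_of <- function(res) {
    disc <- res$taxon[!is.na(res$p_bh) & res$p_bh < 0.05]
    is_sig <- truth[match(disc, rownames(ms2$study$counts))]
    if (!length(disc)) 0 else mean(!is_sig)
  }
  fdr_naive <- fdr_of(fit_all_taxa(ms2$study, "x", method = "poisson_naive"))
  fdr_sand <- fdr_of(fit_all_taxa(ms2$study, "x", method = "sandwich_hc3"))
  expect_lte(fdr_sand, fdr_naive)
})

test_that("input validation and file round-trips work", {
  ms <- make_study(n_samples = 30, n_taxa = 10, seed = 5)
  expect_error(fit_all_taxa(ms$study, "nope"), "lacks column")
  meta_const <- ms$study$metadata
  meta_const$g <- 1
  study_c <- abundance_study(ms$study$counts, meta_const)
  expect_error(fit_all_taxa(study_c, "g"), "constant")

  cf <- tempfile(fileext = ".tsv")
  mf <- tempfile(fileext = ".tsv")
  write.table(data.frame(taxon = rownames(ms$study$counts), ms$study$counts,
                         check.names = FALSE),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ms$study$metadata, mf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  study2 <- read_abundance(cf, mf)
  expect_equal(unname(study2$counts), unname(ms$study$counts))
  expect_equal(study2$library_sizes, ms$study$library_sizes)

  res <- fit_all_taxa(study2, "x", method = "poisson_naive")
  out <- tempfile(fileext = ".tsv")
  write_taxon_results(res, out)
  back <- read.delim(out, comment.char = "#")
  expect_equal(nrow(back), nrow(res))
  expect_true(all(back$p_bh >= back$p - 1e-12, na.rm = TRUE))
})

test_that("adjustment covariates enter the design and the exposure is still the tested term", {
  ms <- make_study(n_samples = 120, n_taxa = 8, signal_fraction = 0.5,
                   effect = 1, seed = 8)
  meta <- ms$study$metadata
  set.seed(2)
  meta$batch <- factor(sample(c("a", "b"), nrow(meta), replace = TRUE))
  study <- abundance_study(ms$study$counts, meta)
  res <- fit_all_taxa(study, "x", adjust = "batch", method = "sandwich_hc3")
  expect_equal(nrow(res), 8)
  expect_true(all(is.finite(res$estimate[res$converged])))
})
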