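test_that("genome simulation is deterministic and respects length requests", {
  p <- sim_params(seed = 7, n_genes = 60L)
  g1 <- simulate_genome(p)
  g2 <- simulate_genome(p)
  expect_identical(g1, g2)
  g3 <- simulate_genome(sim_params(seed = 8, n_genes = 60L))
  expect_false(identical(sort(g1$genes$tss), sort(g3$genes$tss)))

  # non-overlapping genes
  gr <- GenomicRanges::GRanges(g1$genes$chrom,
                               IRanges::IRanges(g1$genes$start + 1, g1$genes$end))
  expect_equal(max(GenomicRanges::countOverlaps(gr, gr)), 1L)
  # min gene length 25 kb -> nothing under the 20-kb classification cutoff
  expect_true(all(g1$genes$length > 20000))
  expect_setequal(unique(g1$genes$strand), c("+", "-"))

  expect_error(simulate_genome(sim_params(n_genes = 5000L)),
               "cannot place")
})

test_that("planted peak counts follow the declared negative-binomial model", {
  # dispersion -> 0 at high baseline: planted raw M concentrates at log2(0.5)
  p <- sim_params(seed = 3, nb_dispersion = 0, dic_fold_change = 0.5)
  genome <- simulate_genome(p)
  pk <- simulate_cohesin_peaks(p, genome)
  ma <- diff_peaks(pk$sites)
  m_dic <- ma$M_raw[pk$truth$is_planted_dic]
  expect_lt(abs(mean(m_dic) + 1), 0.1)
  expect_lt(stats::sd(m_dic), 0.25)

  # no planted fraction -> truth has no DICs
  p0 <- sim_params(seed = 3, n_planted_dic = 0L)
  pk0 <- simulate_cohesin_peaks(p0, simulate_genome(p0))
  expect_equal(sum(pk0$truth$is_planted_dic), 0L)

  # global factor s = 2 with no planted changes: median raw M ~ log2(2)
  ps <- sim_params(seed = 3, library_factor = 2, n_planted_dic = 0L)
  pks <- simulate_cohesin_peaks(ps, simulate_genome(ps))
  ma_s <- diff_peaks(pks$sites)
  expect_lt(abs(stats::median(ma_s$M_raw) - 1), 0.05)

  # infeasible planting is rejected
  expect_error(simulate_cohesin_peaks(
    sim_params(seed = 3, n_planted_dic = 2000L), genome), "cannot plant")
})

test_that("ground truth is consistent by construction", {
  sc <- default_scene()
  tr <- sc$truth
  # LC/HC only on planted DICs, mutually exclusive
  expect_true(all(tr$is_planted_dic[tr$is_HC | tr$is_LC]))
  expect_false(any(tr$is_HC & tr$is_LC))
  # every planted DIC summit lies inside a derived intragenic region of a
  # responsive gene
  reg <- derive_intragenic_regions(sc$genes)
  dic <- sc$sites[tr$is_planted_dic, ]
  s <- floor((dic$start + dic$end) / 2)
  host <- tr$host_gene[tr$is_planted_dic]
  expect_true(all(host %in% sc$responsive_genes))
  r <- reg[match(host, reg$gene_id), ]
  expect_true(all(s >= r$start & s < r$end))
})

test_that("cofactor signals reflect the planted CTCF mixture and TF classes", {
  sc <- default_scene()
  cof <- sc$cofactors
  expect_identical(cof, simulate_cofactor_signals(sc$params, sc$sites, sc$truth))
  hc <- sc$truth$is_HC; lc <- sc$truth$is_LC
  expect_gt(mean(log(cof$ctcf_density[hc])), mean(log(cof$ctcf_density[lc])) + 2)
  expect_gt(mean(cof$H3K27ac[lc]), mean(cof$H3K27ac[hc]))
  expect_true(all(unlist(cof[c("H3K27ac", "P300", "Med1", "ER", "CTCF_cobind")])
                  %in% c(0, 1)))

  pz <- sc$params
  pz$tf_cobind_probs <- lapply(pz$tf_cobind_probs, function(x) x * 0)
  cz <- simulate_cofactor_signals(pz, sc$sites, sc$truth)
  expect_true(all(cz$H3K27ac == 0) && all(cz$CTCF_cobind == 0))
})

test_that("elongation ratios separate responsive from other genes", {
  sc <- default_scene()
  resp <- sc$elongation$gene_id %in% sc$responsive_genes
  expect_gte(mean(sc$elongation$ratio[resp] > 1.2), 0.99)
  expect_lt(abs(stats::median(sc$elongation$ratio[!resp]) - 1), 0.05)
  expect_true(all(sc$expression$log2fc[resp] > 0))
})

test_that("contact maps carry the planted loops, boundaries and couplings", {
  # nothing planted -> the two conditions are the identical map
  p0 <- sim_params(seed = 5, n_loops = 0L, n_compaction_bins = 0L,
                   n_boundaries = 0L, chrom_length = 5e6)
  h0 <- simulate_contact_maps(p0, c(chr1 = 5e6, chr2 = 5e6))
  expect_identical(h0$map_a$records, h0$map_b$records)

  sc <- default_scene()
  hic <- sc$hic
  # planted loop pixels exceed local background in A
  m <- cis_dense_for_test(hic$map_a, "chr1")
  lp <- hic$loops[hic$loops$chrom1 == "chr1", ]
  res <- hic$map_a$resolution
  b1 <- lp$start1 / res + 1; b2 <- lp$start2 / res + 1
  loop_px <- m[cbind(b1, b2)]
  bg_px <- m[cbind(b1, b2 - 3)]  # same rows, off-loop pixels nearby
  expect_gt(mean(loop_px), 2 * mean(bg_px))

  # cross-boundary pixels are attenuated relative to within-block pixels at
  # the same distance (averaged over all boundaries to beat Poisson noise)
  bnd <- hic$boundaries[hic$boundaries$chrom == "chr1", "bin"] + 1
  bnd <- bnd[bnd > 12 & bnd < nrow(m) - 12]
  d <- 4
  cross_px <- m[cbind(bnd - 1, bnd + d - 1)]
  within_px <- m[cbind(bnd - d - 5, bnd - 5)]
  expect_lt(mean(cross_px), 0.3 * mean(within_px))
})

test_that("feature-matrix simulation plants recoverable structure", {
  fm <- simulate_feature_matrix(n_sites = 400, n_features = 30,
                                n_informative = 5, effect_size = 0,
                                k_nonzero = 4, snr = 0, seed = 2)
  # effect size 0: class-conditional means are indistinguishable
  d <- colMeans(fm$X[fm$y_class == 1, , drop = FALSE]) -
    colMeans(fm$X[fm$y_class == 0, , drop = FALSE])
  expect_lt(max(abs(d)), 0.5)
  # noiseless linear response: OLS recovers the planted coefficients exactly
  fm2 <- simulate_feature_matrix(n_sites = 300, n_features = 20,
                                 k_nonzero = 5, snr = 0, seed = 2)
  fit <- stats::lm.fit(cbind(1, fm2$X), fm2$y_linear)
  expect_lt(max(abs(fit$coefficients[-1] - fm2$beta)), 1e-8)
  # reproducibility
  expect_identical(fm, simulate_feature_matrix(n_sites = 400, n_features = 30,
                                               n_informative = 5,
                                               effect_size = 0, k_nonzero = 4,
                                               snr = 0, seed = 2))
  expect_error(simulate_feature_matrix(n_features = 10, k_nonzero = 11),
               "k_nonzero")
})
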