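test_that("intragenic regions exclude flanks and short genes", {
  genes <- validate_genes(data.frame(
    gene_id = c("plus", "short", "exact", "minus"),
    chrom = "chr1",
    strand = c("+", "+", "+", "-"),
    tss = c(0, 100000, 200000, 350000),
    tes = c(50000, 115000, 220000, 300000)))
  reg <- derive_intragenic_regions(genes)
  # + strand [0, 50000) -> [10000, 40000); 15-kb and exactly-20-kb genes drop
  expect_equal(reg$gene_id, c("plus", "minus"))
  expect_equal(reg$start[1], 10000)
  expect_equal(reg$end[1], 40000)
  expect_equal(c(reg$start[2], reg$end[2]), c(310000, 340000))
  expect_error(derive_intragenic_regions(genes, flank = -1), "flank")

  # extra exclusions are punched out of the region
  reg2 <- derive_intragenic_regions(
    genes, extra_exclusions = data.frame(chrom = "chr1", start = 20000,
                                         end = 25000))
  p <- reg2[reg2$gene_id == "plus", ]
  expect_equal(sort(p$start), c(10000, 25000))
  expect_equal(sort(p$end), c(20000, 40000))
})

test_that("site location classification follows the summit rules", {
  genes <- validate_genes(data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    tss = c(100000, 400000), tes = c(150000, 500000)))
  reg <- derive_intragenic_regions(genes)
  sites <- mk_sites("chr1",
                    c(100300, 125000, 700000) - 250,
                    c(100300, 125000, 700000) + 250)
  loc <- classify_site_location(sites, genes, reg)
  expect_equal(as.character(loc$location),
               c("aroundTSS", "intragenic", "intergenic"))
  expect_equal(loc$host_gene[1:2], c("g1", "g1"))
})

test_that("responsive gene calls require both the ratio and validation", {
  el <- data.frame(gene_id = c("a", "b", "c", "d"),
                   ratio = c(1.3, 1.2, 1.5, 2.0))
  ex <- data.frame(gene_id = c("a", "b", "c", "e"),
                   log2fc = c(1, 1, -1, 3))
  expect_warning(calls <- call_responsive_genes(el, ex), "excluded")
  expect_equal(calls$gene_id, c("a", "b", "c"))
  # r > 1.2 strict AND log2fc > 0
  expect_equal(calls$responsive, c(TRUE, FALSE, FALSE))
})

test_that("DIC extraction is the conjunction of its four predicates", {
  peaks <- data.frame(name = paste0("s", 1:5),
                      start = c(0, 0, 0, 0, 0),
                      end = c(3500, 1000, 1000, 1000, 2999),
                      M = c(-1, -0.6, -0.4, -0.6, -0.6))
  loc <- data.frame(name = peaks$name,
                    location = c("intragenic", "intragenic", "intragenic",
                                 "aroundTSS", "intragenic"),
                    host_gene = c("r", "r", "r", "r", "n"))
  resp <- data.frame(gene_id = c("r", "n"), responsive = c(TRUE, FALSE))
  d <- extract_dics(peaks, loc, resp)
  # width 3500 excluded; M=-0.4 not decreased; aroundTSS excluded;
  # non-responsive host excluded; only s2 qualifies
  expect_equal(d$is_dic, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_error(extract_dics(transform(peaks, M = c(NA, -1, -1, -1, -1)),
                            loc, resp), "M value")

  # removing any predicate only grows the set (synthetic scene)
  sc <- default_scene(); calls <- default_calls()
  base <- sum(calls$dics$is_dic)
  no_width <- extract_dics(calls$peaks, calls$locations, calls$responsive,
                           width_cap = Inf)
  all_resp <- calls$responsive; all_resp$responsive <- TRUE
  no_resp <- extract_dics(calls$peaks, calls$locations, all_resp)
  expect_gte(sum(no_width$is_dic), base)
  expect_gte(sum(no_resp$is_dic), base)
  # every DIC host is responsive and no DIC summit near a TSS/TES
  dn <- calls$dics[calls$dics$is_dic, ]
  expect_true(all(dn$host_gene %in%
                    calls$responsive$gene_id[calls$responsive$responsive]))
  g <- sc$genes[match(dn$host_gene, sc$genes$gene_id), ]
  s <- floor((sc$sites$start + sc$sites$end) / 2)[match(dn$name, sc$sites$name)]
  expect_true(all(abs(s - g$tss) > 10000 & abs(s - g$tes) > 10000))
})

test_that("density quantification is per-million window counting", {
  reads <- data.frame(chrom = "chr1", pos = c(seq(900, 1099, by = 2), 5000))
  sites <- mk_sites("chr1", 900, 1101)  # summit 1000
  expect_equal(quantify_density(reads, sites, window = 100, lib_size = 1e6),
               100)
  expect_equal(quantify_density(reads, sites, window = 100, lib_size = 2e6),
               50)
  far <- mk_sites("chr1", 99000, 101000)
  expect_equal(quantify_density(reads, far, window = 100, lib_size = 1e6), 0)
  expect_error(quantify_density(reads, sites, window = 0), "window")
  expect_error(quantify_density(reads, sites, window = 10, lib_size = 0),
               "library")
})

test_that("LC/HC split clusters log densities and honours overrides", {
  sc <- default_scene()
  pd <- which(sc$truth$is_planted_dic)
  cof <- sc$cofactors[pd, ]
  sp <- split_lc_hc(cof$name, cof$ctcf_density, cof$rad21_density)
  acc <- mean((sp$subtype == "HC") == sc$truth$is_HC[pd])
  expect_gte(acc, 0.95)
  # invariant to a uniform rescaling of the densities
  sp10 <- split_lc_hc(cof$name, cof$ctcf_density * 10, cof$rad21_density)
  expect_equal(as.character(sp10$subtype), as.character(sp$subtype))

  # explicit cutoff override
  o <- split_lc_hc(c("a", "b"), c(4.9, 5.1), cutoff = 5.0)
  expect_equal(as.character(o$subtype), c("LC", "HC"))
  # degenerate and undersized inputs
  expect_error(split_lc_hc(c("a", "b"), c(3, 3)), "identical")
  expect_error(split_lc_hc("a", 3), "fewer than 2")
  # Rad21 filter drops sites
  f <- split_lc_hc(c("a", "b", "c"), c(1, 50, 60), rad21_density = c(0.1, 9, 9),
                   min_rad21 = 1)
  expect_equal(as.character(f$subtype), c("none", "LC", "HC"))
})

test_that("aggregate profiles average, mirror and bound uncertainty", {
  track <- list(bin_size = 100,
                values = list(chr1 = rep(7, 100)))
  sites <- mk_sites("chr1", c(3000, 5000), c(3200, 5200), strand = "+")
  pr <- aggregate_profile(track, sites, flank = 500)
  expect_true(all(pr$mean == 7))
  expect_true(all(pr$ci_hi - pr$ci_lo == 0))

  # single site: zero-width CI with a warning
  expect_warning(p1 <- aggregate_profile(track, sites[1, ], flank = 500),
                 "single site")
  expect_true(all(p1$ci_hi == p1$mean))

  # minus-strand site reverses an asymmetric ramp
  ramp <- list(bin_size = 100, values = list(chr1 = seq_len(100)))
  plus <- suppressWarnings(aggregate_profile(ramp, sites[1, ], flank = 300))
  minus_site <- sites[1, ]; minus_site$strand <- "-"
  minus <- suppressWarnings(aggregate_profile(ramp, minus_site, flank = 300))
  expect_equal(minus$mean, rev(plus$mean))
  expect_error(aggregate_profile(track, sites[0, ], flank = 500), "empty")
  expect_error(aggregate_profile(track, sites, flank = 550), "multiple")
})

test_that("cross-sample presence matches brute-force overlap checks", {
  ref <- mk_sites("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  s1 <- mk_sites("chr1", c(0, 100), c(50, 150))
  s2 <- mk_sites("chr1", c(120, 340), c(160, 360))
  cp <- compare_presence(ref, list(a = s1, b = s2))
  # brute force: which ref intervals overlap each sample's intervals
  brute <- function(sample) {
    sapply(seq_len(nrow(ref)), function(i) any(
      pmax(ref$start[i], sample$start) < pmin(ref$end[i], sample$end)))
  }
  expect_equal(unname(cp$presence[, "a"]), brute(s1))
  expect_equal(unname(cp$presence[, "b"]), brute(s2))
  expect_equal(cp$absent_in_all_cases, "s3")

  same <- compare_presence(ref, list(a = ref, b = ref))
  expect_length(same$absent_in_all_cases, 0)
  none <- compare_presence(ref, list(a = mk_sites("chr2", 0, 10),
                                     b = mk_sites("chr2", 5, 15)))
  expect_equal(none$absent_in_all_cases, ref$name)
  expect_error(compare_presence(ref, list(a = s1)), "2 samples")
})

test_that("site-expression correlation is Spearman with guards", {
  x <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  y <- 1:10
  r <- correlate_site_expression(x, y)
  expect_equal(r$rho, -1)
  # hand-ranked oracle on 10 constructed pairs
  set.seed(42)
  a <- rnorm(10); b <- rnorm(10)
  r2 <- correlate_site_expression(a, b)
  expect_equal(r2$rho, stats::cor(rank(a), rank(b)))
  expect_error(correlate_site_expression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(correlate_site_expression(1:2, 2:1), "3 paired")
})
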