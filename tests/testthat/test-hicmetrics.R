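test_that("balancing equalizes covered-bin marginals and skips empty bins", {
  # 2x2 block with unequal raw marginals
  m <- contact_map(data.frame(chrom1 = "chr1", bin1 = c(0, 0, 1),
                              chrom2 = "chr1", bin2 = c(0, 1, 1),
                              count = c(1, 2, 4)),
                   10, c(chr1 = 20))
  b <- balance_map(m, tol = 1e-4)
  mb <- cis_dense_for_test(b, "chr1")
  rs <- rowSums(mb)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-3)

  # already-uniform matrix: weights equal
  u <- contact_map(data.frame(chrom1 = "chr1", bin1 = c(0, 0, 1),
                              chrom2 = "chr1", bin2 = c(0, 1, 1),
                              count = c(1, 1, 1)),
                   10, c(chr1 = 20))
  bu <- balance_map(u)
  w <- bu$weights[!is.na(bu$weights)]
  expect_lt(diff(range(w)), 1e-6)

  # an uncovered bin is excluded, not fatal
  z <- contact_map(data.frame(chrom1 = "chr1", bin1 = 0,
                              chrom2 = "chr1", bin2 = 1, count = 5),
                   10, c(chr1 = 30))
  bz <- balance_map(z)
  expect_true(is.na(bz$weights[["chr1:2"]]))
})

test_that("DLR arithmetic and self-comparison behave", {
  # constructed row: distal sum equals local sum -> DLR = 0
  res <- 10
  rec <- data.frame(chrom1 = "chr1", bin1 = c(5, 5), chrom2 = "chr1",
                    bin2 = c(6, 9), count = c(8, 8))
  m <- contact_map(rec, res, c(chr1 = 120))
  dlr <- compute_dlr(m, window = 0, local_cutoff = 20)
  expect_equal(dlr$dlr_a[dlr$bin == 5], 0)

  # identical maps: delta is exactly 0 everywhere it is defined
  sc <- default_scene()
  d0 <- compute_dlr(sc$hic$map_a, sc$hic$map_a, window = 10e3,
                    local_cutoff = 250e3)
  expect_true(all(d0$delta_dlr == 0, na.rm = TRUE))
  expect_error(compute_dlr(m, window = 30, local_cutoff = 20), "exceed")
})

test_that("ICF is the inter fraction with exact toy arithmetic", {
  rec <- data.frame(chrom1 = c("chr1", "chr1"), bin1 = c(0, 0),
                    chrom2 = c("chr1", "chr2"), bin2 = c(1, 0),
                    count = c(6, 2))
  m <- contact_map(rec, 10, c(chr1 = 20, chr2 = 10))
  icf <- compute_icf(m)
  expect_equal(icf$icf_a[icf$chrom == "chr1" & icf$bin == 0], 0.25)
  # no inter contacts -> ICF 0; zero-contact bin -> NA
  cis_only <- contact_map(rec[1, ], 10, c(chr1 = 20, chr2 = 10))
  icf0 <- compute_icf(cis_only)
  expect_equal(icf0$icf_a[icf0$chrom == "chr1" & icf0$bin == 0], 0)
  expect_true(is.na(icf0$icf_a[icf0$chrom == "chr2"]))
  # inter == intra -> 0.5
  rec2 <- data.frame(chrom1 = c("chr1", "chr1"), bin1 = c(0, 0),
                     chrom2 = c("chr1", "chr2"), bin2 = c(1, 0),
                     count = c(3, 3))
  expect_equal(compute_icf(contact_map(rec2, 10, c(chr1 = 20, chr2 = 10)))$
                 icf_a[1], 0.5)
  # delta of a map against itself is zero
  sc <- default_scene()
  di <- compute_icf(sc$hic$map_a, sc$hic$map_a)
  expect_true(all(di$delta_icf == 0, na.rm = TRUE))
})

test_that("insulation is ~0 on a noiseless decay map and dips at junctions", {
  m <- mk_decay_map(n_bins = 120)
  is0 <- compute_insulation(m, square_width = 4)
  expect_lt(max(abs(is0$profile$is), na.rm = TRUE), 0.05)

  # two-block map with 0.1x cross-block attenuation: minimum at the junction
  n <- 60; junction <- 30
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE))
  i <- ((ij - 1L) %% n) + 1L; j <- ((ij - 1L) %/% n) + 1L
  cnt <- 100 / (1 + abs(i - j))
  cross <- (i <= junction) != (j <= junction)
  cnt[cross] <- cnt[cross] * 0.1
  mb <- contact_map(data.frame(chrom1 = "chr1", bin1 = i - 1, chrom2 = "chr1",
                               bin2 = j - 1, count = cnt),
                    1e4, c(chr1 = n * 1e4))
  isb <- compute_insulation(mb, square_width = 4)
  expect_equal(isb$profile$bin[which.min(isb$profile$is)], junction - 1)
  expect_true((junction - 1) %in% isb$boundaries$bin)
  # short chromosome yields an empty profile
  tiny <- contact_map(data.frame(chrom1 = "chr1", bin1 = 0, chrom2 = "chr1",
                                 bin2 = 1, count = 3), 1e4, c(chr1 = 5e4))
  expect_equal(nrow(compute_insulation(tiny, square_width = 4)$profile), 0)
})

test_that("APA scores a hand-built submatrix exactly", {
  # uniform map: score ~ 1
  n <- 80
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE))
  i <- ((ij - 1L) %% n) + 1L; j <- ((ij - 1L) %/% n) + 1L
  u <- contact_map(data.frame(chrom1 = "chr1", bin1 = i - 1, chrom2 = "chr1",
                              bin2 = j - 1, count = 5),
                   1e4, c(chr1 = n * 1e4))
  pairs <- data.frame(chrom1 = "chr1", start1 = 20e4, end1 = 21e4,
                      chrom2 = "chr1", start2 = 50e4, end2 = 51e4)
  a_u <- run_apa(u, pairs, radius = 3, norm = "none")
  expect_equal(a_u$score, 1)

  # plant centre 10 vs corner 2: score 5 with norm = "none"
  cnt <- rep(2, length(ij))
  cnt[i == 21 & j == 51] <- 10
  h <- contact_map(data.frame(chrom1 = "chr1", bin1 = i - 1, chrom2 = "chr1",
                              bin2 = j - 1, count = cnt),
                   1e4, c(chr1 = n * 1e4))
  a_h <- run_apa(h, pairs, radius = 3, norm = "none")
  expect_equal(a_h$score, 5)

  # short-separation pairs are dropped and counted
  near <- data.frame(chrom1 = "chr1", start1 = 20e4, end1 = 21e4,
                     chrom2 = "chr1", start2 = 23e4, end2 = 24e4)
  expect_error(run_apa(u, near, radius = 3), "no usable pairs")
  both <- rbind(pairs, near)
  a_b <- run_apa(u, both, radius = 3, norm = "none")
  expect_equal(a_b$n_dropped, 1)

  # identical maps compare with statistic 0, p 1
  cmp <- compare_apa(u, u, pairs = rbind(pairs, pairs, pairs), radius = 3)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)
})

test_that("contact metrics are invariant to uniform count scaling", {
  sc <- default_scene()
  a <- sc$hic$map_a
  a10 <- a
  a10$records$count <- a10$records$count * 10
  d1 <- compute_dlr(a, window = 10e3, local_cutoff = 250e3)
  d2 <- compute_dlr(a10, window = 10e3, local_cutoff = 250e3)
  expect_equal(d1$dlr_a, d2$dlr_a)
  i1 <- compute_icf(a); i2 <- compute_icf(a10)
  expect_equal(i1$icf_a, i2$icf_a)
  s1 <- compute_insulation(a, square_width = 4)
  s2 <- compute_insulation(a10, square_width = 4)
  expect_equal(s1$profile$is, s2$profile$is)
  lp <- sc$hic$loops
  expect_equal(run_apa(a, lp, radius = 5)$score,
               run_apa(a10, lp, radius = 5)$score)
})
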