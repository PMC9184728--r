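# Shared fixtures: the default synthetic scene is expensive (~10 s), so it
# is simulated once per test run and reused, together with the downstream
# DIC-extraction cascade.

.fixture_cache <- new.env(parent = emptyenv())

default_scene <- function() {
  if (is.null(.fixture_cache$scene)) {
    .fixture_cache$scene <- simulate_scene(sim_params(seed = 1))
  }
  .fixture_cache$scene
}

default_calls <- function() {
  if (is.null(.fixture_cache$calls)) {
    sc <- default_scene()
    peaks <- diff_peaks(sc$sites)
    regions <- derive_intragenic_regions(sc$genes)
    locations <- classify_site_location(sc$sites, sc$genes, regions)
    responsive <- call_responsive_genes(sc$elongation, sc$expression)
    dics <- extract_dics(peaks, locations, responsive)
    .fixture_cache$calls <- list(peaks = peaks, regions = regions,
                                 locations = locations,
                                 responsive = responsive, dics = dics)
  }
  .fixture_cache$calls
}

# small site table constructor
mk_sites <- function(chrom, start, end, strand = ".", name = NULL, ...) {
  n <- length(start)
  df <- data.frame(chrom = rep_len(chrom, n), start = start, end = end,
                   name = if (is.null(name)) paste0("s", seq_len(n)) else name,
                   score = 0, strand = rep_len(strand, n),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# deterministic (noiseless) power-law decay contact map on one chromosome
mk_decay_map <- function(n_bins = 120, resolution = 1e4, base = 100,
                         exponent = 1, chrom = "chr1") {
  ij <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE))
  i <- ((ij - 1L) %% n_bins) + 1L
  j <- ((ij - 1L) %/% n_bins) + 1L
  contact_map(data.frame(chrom1 = chrom, bin1 = i - 1L, chrom2 = chrom,
                         bin2 = j - 1L,
                         count = base / (1 + abs(i - j))^exponent),
              resolution, stats::setNames(n_bins * resolution, chrom))
}

# Hubert-Arabie adjusted Rand index (independent of any clustering code)
adjusted_rand <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  sij <- sum(choose(ct, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# dense symmetric cis matrix rebuilt directly from the sparse records
# (independent of the package's internal accessor)
cis_dense_for_test <- function(map, chrom) {
  n <- ceiling(map$chrom_sizes[[chrom]] / map$resolution)
  r <- map$records
  r <- r[r$chrom1 == chrom & r$chrom2 == chrom, ]
  m <- matrix(0, n, n)
  m[cbind(r$bin1 + 1, r$bin2 + 1)] <- r$count
  m[cbind(r$bin2 + 1, r$bin1 + 1)] <- r$count
  m
}

# brute-force hypergeometric pmf for the Fisher enumeration oracle
hyper_pmf <- function(x, r1, r2, c1) {
  choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
}
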