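# DIC extraction cascade: intragenic regions, responsive-gene calling,
# decreased-intragenic-cohesin (DIC) selection, LC/HC subtype split,
# density quantification, metaprofiles and cross-sample presence analysis.

#' Derive intragenic regions from a gene table
#'
#' For each gene longer than \code{min_length} (strict), the intragenic
#' region is the gene body minus \code{flank} bp at each end (so nothing
#' within \code{flank} of the TSS or TES survives), minus any extra
#' exclusion intervals (e.g. alternative promoters).
#'
#' @param genes Gene table (see \code{\link{validate_genes}}).
#' @param flank Excluded flank around TSS and TES (bp, default 10 kb).
#' @param min_length Minimum gene length (bp, default 20 kb, strict >).
#' @param extra_exclusions Optional interval table (chrom, start, end) to
#'   subtract from the regions.
#' @return \code{data.frame(gene_id, chrom, start, end)}, 0-based half-open;
#'   provenance parameters attached as attribute \code{"params"}.
#' @export
derive_intragenic_regions <- function(genes, flank = 10000, min_length = 20000,
                                      extra_exclusions = NULL) {
  if (flank < 0) stop("flank must be >= 0")
  keep <- genes$length > min_length
  g <- genes[keep, , drop = FALSE]
  start <- g$start + flank
  end <- g$end - flank
  ok <- end > start
  out <- data.frame(gene_id = g$gene_id[ok], chrom = g$chrom[ok],
                    start = start[ok], end = end[ok],
                    stringsAsFactors = FALSE)
  if (!is.null(extra_exclusions) && nrow(out) > 0 && nrow(extra_exclusions) > 0) {
    reg <- GenomicRanges::GRanges(out$chrom,
                                  IRanges::IRanges(out$start + 1, out$end))
    S4Vectors::mcols(reg)$gene_id <- out$gene_id
    exc <- GenomicRanges::GRanges(
      extra_exclusions$chrom,
      IRanges::IRanges(extra_exclusions$start + 1, extra_exclusions$end))
    kept <- GenomicRanges::setdiff(reg, GenomicRanges::reduce(exc))
    hit <- GenomicRanges::findOverlaps(kept, reg, type = "within")
    out <- data.frame(
      gene_id = out$gene_id[S4Vectors::subjectHits(hit)],
      chrom = as.character(GenomicRanges::seqnames(kept))[S4Vectors::queryHits(hit)],
      start = GenomicRanges::start(kept)[S4Vectors::queryHits(hit)] - 1,
      end = GenomicRanges::end(kept)[S4Vectors::queryHits(hit)],
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "params") <- list(flank = flank, min_length = min_length,
                              n_extra_exclusions =
                                if (is.null(extra_exclusions)) 0L
                                else nrow(extra_exclusions))
  out
}

#' Classify each cohesin site by genomic location
#'
#' A site is \code{aroundTSS} if its summit lies within \code{tss_window} bp
#' of any TSS; otherwise \code{intragenic} if the summit falls inside an
#' intragenic region; otherwise \code{intergenic}. The host gene is the
#' region's gene (nearest TSS breaks ties between overlapping genes).
#'
#' @param sites Site table.
#' @param genes Gene table.
#' @param regions Intragenic regions from \code{\link{derive_intragenic_regions}}.
#' @param tss_window Promoter window around the TSS (bp, default 10 kb).
#' @return \code{data.frame(name, location, host_gene)}.
#' @export
classify_site_location <- function(sites, genes, regions, tss_window = 10000) {
  summit <- site_summits(sites)
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(summit + 1, summit + 1))
  tss_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$tss + 1, genes$tss + 1))
  near <- GenomicRanges::distanceToNearest(sgr, tss_gr)
  dist_tss <- rep(Inf, nrow(sites))
  nearest_gene <- rep(NA_character_, nrow(sites))
  dist_tss[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
  nearest_gene[S4Vectors::queryHits(near)] <-
    genes$gene_id[S4Vectors::subjectHits(near)]

  location <- rep("intergenic", nrow(sites))
  host <- rep(NA_character_, nrow(sites))

  around <- dist_tss <= tss_window
  location[around] <- "aroundTSS"
  host[around] <- nearest_gene[around]

  if (nrow(regions) > 0) {
    rgr <- GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(regions$start + 1, regions$end))
    hits <- GenomicRanges::findOverlaps(sgr, rgr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    # nearest-TSS tie-break when a summit sits in several genes' regions
    tss_of <- genes$tss[match(regions$gene_id[sh], genes$gene_id)]
    dd <- abs(summit[qh] - tss_of)
    ord <- order(qh, dd)
    first <- ord[!duplicated(qh[ord])]
    sel <- qh[first][!around[qh[first]]]
    location[sel] <- "intragenic"
    host[sel] <- regions$gene_id[sh[first]][!around[qh[first]]]
  }
  data.frame(name = sites$name, location =
               factor(location, levels = c("aroundTSS", "intragenic", "intergenic")),
             host_gene = host, stringsAsFactors = FALSE)
}

#' Call stimulus-responsive genes
#'
#' A gene is responsive iff its elongation-signal ratio (stimulated/control,
#' e.g. Pol2ser2 over the gene body) strictly exceeds \code{ratio_threshold}
#' and its expression change validates it (log2 fold change >
#' \code{lfc_threshold}).
#'
#' @param elongation \code{data.frame(gene_id, ratio)}.
#' @param expression Expression table with \code{gene_id}, \code{log2fc}.
#' @param ratio_threshold Elongation ratio cutoff (default 1.2, strict >).
#' @param lfc_threshold Expression log2FC validation cutoff (default 0).
#' @return \code{data.frame(gene_id, ratio, log2fc, expression_validated,
#'   responsive)}; genes present in only one table are dropped with a warning.
#' @export
call_responsive_genes <- function(elongation, expression,
                                  ratio_threshold = 1.2, lfc_threshold = 0) {
  common <- intersect(elongation$gene_id, expression$gene_id)
  n_drop <- length(union(elongation$gene_id, expression$gene_id)) - length(common)
  if (n_drop > 0) {
    warning(n_drop, " gene(s) present in only one table were excluded")
  }
  el <- elongation[match(common, elongation$gene_id), ]
  ex <- expression[match(common, expression$gene_id), ]
  validated <- ex$log2fc > lfc_threshold
  data.frame(gene_id = common, ratio = el$ratio, log2fc = ex$log2fc,
             expression_validated = validated,
             responsive = el$ratio > ratio_threshold & validated,
             stringsAsFactors = FALSE)
}

#' Extract decreased intragenic cohesin sites (DICs)
#'
#' A site is a DIC iff all four predicates hold: peak width <=
#' \code{width_cap}, normalized M < \code{-tau}, summit intragenic, and host
#' gene responsive.
#'
#' @param peaks Differential peak table (from \code{\link{diff_peaks}}) with
#'   \code{name, start, end, M}.
#' @param locations Location calls from \code{\link{classify_site_location}}.
#' @param responsive Responsive-gene calls from
#'   \code{\link{call_responsive_genes}}.
#' @param width_cap Maximum peak width (bp, default 3 kb; wider peaks are
#'   excluded).
#' @param tau Decrease threshold on normalized M (default 0.5: M < -0.5).
#' @return \code{data.frame(name, width, M, location, host_gene,
#'   host_responsive, is_dic)} in input row order.
#' @export
extract_dics <- function(peaks, locations, responsive, width_cap = 3000,
                         tau = 0.5) {
  if (!"M" %in% names(peaks) || any(is.na(peaks$M))) {
    stop("every site needs a normalized M value")
  }
  loc <- locations[match(peaks$name, locations$name), ]
  if (any(is.na(loc$location))) stop("location call missing for some sites")
  width <- peaks$end - peaks$start
  resp_ids <- responsive$gene_id[responsive$responsive]
  host_resp <- !is.na(loc$host_gene) & loc$host_gene %in% resp_ids
  is_dic <- width <= width_cap & peaks$M < -tau &
    loc$location == "intragenic" & host_resp
  data.frame(name = peaks$name, width = width, M = peaks$M,
             location = loc$location, host_gene = loc$host_gene,
             host_responsive = host_resp, is_dic = is_dic,
             stringsAsFactors = FALSE)
}

#' Quantify read density around site summits
#'
#' Density = reads with position in \code{[summit - window, summit + window)}
#' times 1e6 / library size (reads per million).
#'
#' @param reads \code{data.frame(chrom, pos)} of read positions (0-based).
#' @param sites Site table.
#' @param window Half-window around the summit (bp, > 0).
#' @param lib_size Library size (> 0); defaults to \code{nrow(reads)}.
#' @return Numeric density per site.
#' @export
quantify_density <- function(reads, sites, window, lib_size = nrow(reads)) {
  if (window <= 0) stop("window must be > 0")
  if (lib_size <= 0) stop("library size must be > 0")
  summit <- site_summits(sites)
  win <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(pmax(summit - window, 0) + 1, summit + window))
  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$pos + 1, reads$pos + 1))
  GenomicRanges::countOverlaps(win, rgr) * 1e6 / lib_size
}

#' Split DICs into low- and high-CTCF subtypes
#'
#' Sites with Rad21 density below \code{min_rad21} are dropped. The
#' remaining DICs are split by two-component 1-D clustering of
#' \code{log(ctcf_density + 1)} (the higher-mean component is HC), or by an
#' explicit density cutoff when supplied (\code{> cutoff} is HC).
#'
#' @param names Site identifiers of the DICs.
#' @param ctcf_density CTCF read density per DIC (same window for all).
#' @param rad21_density Optional Rad21 density per DIC.
#' @param min_rad21 Omission threshold for very low Rad21 signal.
#' @param cutoff Optional explicit CTCF density cutoff overriding clustering.
#' @return \code{data.frame(name, ctcf_density, kept, subtype)} with subtype
#'   in \{LC, HC, none\} (\code{none} for dropped sites).
#' @export
split_lc_hc <- function(names, ctcf_density, rad21_density = NULL,
                        min_rad21 = 0, cutoff = NULL) {
  stopifnot(length(names) == length(ctcf_density))
  kept <- if (is.null(rad21_density)) rep(TRUE, length(names)) else
    rad21_density >= min_rad21
  x <- ctcf_density[kept]
  if (length(x) < 2L) stop("fewer than 2 DICs after Rad21 filtering")
  if (is.null(cutoff)) {
    lx <- log(x + 1)
    if (max(lx) - min(lx) < 1e-12) {
      stop("all CTCF densities identical; no two-component split possible")
    }
    if (length(lx) == 2L) {
      hc <- lx == max(lx)   # two sites: the larger is the high component
    } else {
      km <- stats::kmeans(lx, centers = matrix(range(lx), ncol = 1))
      hc_cluster <- which.max(km$centers)
      hc <- km$cluster == hc_cluster
    }
  } else {
    hc <- x > cutoff
  }
  subtype <- rep("none", length(names))
  subtype[kept] <- ifelse(hc, "HC", "LC")
  data.frame(name = names, ctcf_density = ctcf_density, kept = kept,
             subtype = factor(subtype, levels = c("LC", "HC", "none")),
             stringsAsFactors = FALSE)
}

#' Aggregate signal profile around site summits
#'
#' Per-bin mean of per-million-normalized signal across site summits,
#' strand-oriented (minus-strand sites are mirrored), with a 95 % CI of
#' mean +/- 1.96 SE across sites.
#'
#' @param track Binned signal track: \code{list(bin_size, values)} where
#'   \code{values} is a named list of per-bin numeric vectors per chromosome
#'   (bin b covers \code{[(b-1)*bin_size, b*bin_size)}).
#' @param sites Site table (strand used for mirroring).
#' @param flank Half-width of the profile (bp, multiple of the bin size).
#' @param lib_size Library size for per-million scaling (default 1e6, i.e.
#'   track values already normalized).
#' @return \code{data.frame(offset, mean, ci_lo, ci_hi, n)}.
#' @export
aggregate_profile <- function(track, sites, flank, lib_size = 1e6) {
  if (nrow(sites) == 0L) stop("empty site set")
  bs <- track$bin_size
  if (flank %% bs != 0) stop("flank must be a multiple of the track bin size")
  nb <- flank / bs
  offsets <- seq(-nb, nb) * bs
  summit <- site_summits(sites)
  n <- nrow(sites)
  mat <- matrix(NA_real_, n, 2 * nb + 1)
  for (i in seq_len(n)) {
    v <- track$values[[sites$chrom[i]]]
    if (is.null(v)) next
    centre_bin <- floor(summit[i] / bs) + 1
    idx <- centre_bin + seq(-nb, nb)
    ok <- idx >= 1 & idx <= length(v)
    row <- rep(NA_real_, 2 * nb + 1)
    row[ok] <- v[idx[ok]]
    if (identical(sites$strand[i], "-")) row <- rev(row)
    mat[i, ] <- row
  }
  mat <- mat * 1e6 / lib_size
  mu <- colMeans(mat, na.rm = TRUE)
  n_eff <- colSums(!is.na(mat))
  if (n == 1L) {
    warning("single site: confidence interval undefined, reported zero-width")
    se <- rep(0, length(mu))
  } else {
    se <- apply(mat, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_eff, 1))
    se[n_eff < 2] <- 0
  }
  data.frame(offset = offsets, mean = mu,
             ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se, n = n_eff)
}

#' Cross-sample presence/absence of reference sites
#'
#' Marks each reference site present in a sample iff it overlaps one of the
#' sample's peaks by at least \code{min_overlap} bp, and reports the sites
#' absent from every listed case sample (e.g. reference sites lost in all
#' patient-derived cells).
#'
#' @param reference Reference site table.
#' @param samples Named list of site tables (>= 2).
#' @param case_samples Names of the "case" samples for the absent-in-all set
#'   (default: all samples).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List: \code{presence} (logical matrix, reference sites x samples)
#'   and \code{absent_in_all_cases} (reference site names).
#' @export
compare_presence <- function(reference, samples, case_samples = names(samples),
                             min_overlap = 1L) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  stopifnot(all(case_samples %in% names(samples)))
  ref_gr <- sites_granges(reference)
  presence <- vapply(samples, function(s) {
    suppressWarnings(  # disjoint chromosome sets simply mean "absent"
      IRanges::overlapsAny(ref_gr, sites_granges(s), minoverlap = min_overlap,
                           ignore.strand = TRUE))
  }, logical(nrow(reference)))
  rownames(presence) <- reference$name
  absent <- reference$name[rowSums(presence[, case_samples, drop = FALSE]) == 0]
  list(presence = presence, absent_in_all_cases = absent)
}

#' Correlate site density with host-gene expression
#'
#' Spearman rank correlation (two-sided) between per-site signal density and
#' the expression of the corresponding host genes.
#'
#' @param density Numeric vector of site densities.
#' @param expression Matched numeric vector of host-gene expression values.
#' @return \code{data.frame(rho, p, n)}.
#' @export
correlate_site_expression <- function(density, expression) {
  stopifnot(length(density) == length(expression))
  ok <- is.finite(density) & is.finite(expression)
  x <- density[ok]; y <- expression[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: Spearman correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
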