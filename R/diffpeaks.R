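# MA-based quantitative comparison of peak intensity between two conditions.
# M = log2 fold change of normalized read density, A = average log signal;
# the condition-wide M-vs-A trend fitted on common peaks is subtracted to
# give the normalized M value used for change classification.

#' Match peaks between two conditions
#'
#' Pairs peaks by interval overlap: each peak is matched to at most one
#' partner, the greatest-overlap partner winning (ties broken by leftmost
#' partner). Peaks with no partner are condition-unique.
#'
#' @param sites_a,sites_b Site tables (each with a \code{count} column).
#' @param min_overlap Minimum overlap (bp) to accept a pair.
#' @return List: \code{pairs} (\code{idx_a, idx_b, overlap}),
#'   \code{unique_a}, \code{unique_b} (row indices), and \code{union} — the
#'   combined peak table with \code{count_a}, \code{count_b} (0 for the
#'   missing condition of unique peaks) and a \code{common} flag.
#' @export
match_common_peaks <- function(sites_a, sites_b, min_overlap = 1L) {
  if (nrow(sites_a) == 0L || nrow(sites_b) == 0L) {
    stop("both peak sets must be non-empty")
  }
  gr_a <- sites_granges(sites_a)
  gr_b <- sites_granges(sites_b)
  hits <- suppressWarnings(  # disjoint chromosome sets are a valid no-match
    GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = min_overlap,
                                ignore.strand = TRUE))
  qa <- S4Vectors::queryHits(hits)
  sb <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_a)[qa],
                                           IRanges::ranges(gr_b)[sb]))
  # greedy one-to-one matching: largest overlap first, leftmost partner ties
  ord <- order(-ov, sites_b$start[sb], sb)
  used_a <- logical(nrow(sites_a)); used_b <- logical(nrow(sites_b))
  keep <- logical(length(ord))
  for (k in ord) {
    if (!used_a[qa[k]] && !used_b[sb[k]]) {
      used_a[qa[k]] <- TRUE; used_b[sb[k]] <- TRUE; keep[k] <- TRUE
    }
  }
  pairs <- data.frame(idx_a = qa[keep], idx_b = sb[keep], overlap = ov[keep])
  pairs <- pairs[order(pairs$idx_a), , drop = FALSE]
  unique_a <- which(!used_a); unique_b <- which(!used_b)

  union <- rbind(
    data.frame(chrom = sites_a$chrom[pairs$idx_a],
               start = sites_a$start[pairs$idx_a],
               end = sites_a$end[pairs$idx_a],
               name = sites_a$name[pairs$idx_a],
               count_a = sites_a$count[pairs$idx_a],
               count_b = sites_b$count[pairs$idx_b],
               common = rep(TRUE, nrow(pairs)), stringsAsFactors = FALSE),
    data.frame(chrom = sites_a$chrom[unique_a],
               start = sites_a$start[unique_a],
               end = sites_a$end[unique_a],
               name = sites_a$name[unique_a],
               count_a = sites_a$count[unique_a],
               count_b = rep(0, length(unique_a)),
               common = rep(FALSE, length(unique_a)),
               stringsAsFactors = FALSE),
    data.frame(chrom = sites_b$chrom[unique_b],
               start = sites_b$start[unique_b],
               end = sites_b$end[unique_b],
               name = sites_b$name[unique_b],
               count_a = rep(0, length(unique_b)),
               count_b = sites_b$count[unique_b],
               common = rep(FALSE, length(unique_b)),
               stringsAsFactors = FALSE))
  rownames(union) <- NULL
  list(pairs = pairs, unique_a = unique_a, unique_b = unique_b, union = union)
}

# M/A values from per-condition counts: densities scaled per million library
# reads, pseudocount added before log2
compute_ma <- function(count_a, count_b, lib_sizes = c(1e6, 1e6),
                       pseudocount = 1) {
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  d1 <- count_a * 1e6 / lib_sizes[1] + pseudocount
  d2 <- count_b * 1e6 / lib_sizes[2] + pseudocount
  if (any(d1 <= 0) || any(d2 <= 0)) stop("non-positive density; increase pseudocount")
  data.frame(A = 0.5 * (log2(d1) + log2(d2)), M_raw = log2(d2 / d1))
}

#' Fit the MA normalization line on common peaks
#'
#' Fits \code{M_raw = a + b * A} on common peaks with a robust Theil-Sen
#' (median-of-pairwise-slopes) regression, or ordinary least squares, then
#' defines normalized \code{M = M_raw - (a + b * A)} for every peak. After
#' normalization the median M over common peaks is ~0, removing global
#' library/efficiency trends so residual M reflects differential binding.
#'
#' @param A,M_raw M/A values of all peaks.
#' @param common Logical vector marking the matched common peaks used to fit.
#' @param method \code{"theilsen"} (default) or \code{"ols"}.
#' @param min_common Minimum common peaks required for a fit.
#' @return List of class \code{ma_fit}: \code{a}, \code{b}, \code{n_common},
#'   \code{method}, \code{M} (normalized M for all peaks).
#' @export
fit_ma_normalization <- function(A, M_raw, common = rep(TRUE, length(A)),
                                 method = c("theilsen", "ols"),
                                 min_common = 10L) {
  method <- match.arg(method)
  stopifnot(length(A) == length(M_raw), length(common) == length(A))
  Ac <- A[common]; Mc <- M_raw[common]
  n <- length(Ac)
  if (n < min_common) stop("only ", n, " common peaks; need >= ", min_common)
  if (max(Ac) - min(Ac) < 1e-12) {
    warning("degenerate A values (all equal); slope fixed at 0")
    b <- 0; a <- stats::median(Mc)
  } else if (method == "ols") {
    fit <- stats::lm.fit(cbind(1, Ac), Mc)
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
  } else {
    # Theil-Sen; deterministic A-rank subsample keeps all-pairs cost bounded
    if (n > 2000L) {
      idx <- order(Ac)[unique(round(seq(1, n, length.out = 2000L)))]
      Ac <- Ac[idx]; Mc <- Mc[idx]; n <- length(Ac)
    }
    dA <- outer(Ac, Ac, "-")
    dM <- outer(Mc, Mc, "-")
    lower <- lower.tri(dA)
    ok <- lower & abs(dA) > 1e-12
    b <- stats::median(dM[ok] / dA[ok])
    a <- stats::median(Mc - b * Ac)
  }
  structure(list(a = unname(a), b = unname(b), n_common = sum(common),
                 method = method, M = M_raw - (a + b * A)),
            class = "ma_fit")
}

#' Classify peak change from normalized M
#'
#' Strict thresholds: increased iff \code{M > tau}, decreased iff
#' \code{M < -tau}, otherwise unchanged.
#'
#' @param M Normalized M values (finite).
#' @param tau Positive threshold (default 0.5).
#' @return Factor with levels increased/decreased/unchanged.
#' @export
classify_change <- function(M, tau = 0.5) {
  if (tau <= 0) stop("tau must be > 0")
  if (any(!is.finite(M))) stop("M values must be finite")
  factor(ifelse(M > tau, "increased", ifelse(M < -tau, "decreased", "unchanged")),
         levels = c("increased", "decreased", "unchanged"))
}

#' Differential peak analysis on a matched peak table
#'
#' Computes M/A values from the two count columns, fits the MA normalization
#' on common peaks and classifies each peak as increased, decreased or
#' unchanged at threshold \code{tau}.
#'
#' @param sites Site table carrying both conditions' counts.
#' @param count_cols Names of the condition-1 and condition-2 count columns.
#' @param common Logical vector of peaks to use for the fit (default all).
#' @param lib_sizes Library sizes for per-million scaling (default 1e6 each,
#'   i.e. counts already are densities).
#' @param pseudocount Added to densities before log2.
#' @param tau Change-call threshold on normalized M.
#' @param method Robust fit method, see \code{\link{fit_ma_normalization}}.
#' @return The input table with \code{A}, \code{M_raw}, \code{M},
#'   \code{change} columns appended; the \code{ma_fit} is attached as
#'   attribute \code{"fit"}.
#' @export
diff_peaks <- function(sites, count_cols = c("count_ctrl", "count_e2"),
                       common = rep(TRUE, nrow(sites)),
                       lib_sizes = c(1e6, 1e6), pseudocount = 1, tau = 0.5,
                       method = "theilsen") {
  stopifnot(all(count_cols %in% names(sites)))
  ma <- compute_ma(sites[[count_cols[1]]], sites[[count_cols[2]]],
                   lib_sizes = lib_sizes, pseudocount = pseudocount)
  fit <- fit_ma_normalization(ma$A, ma$M_raw, common = common, method = method)
  out <- sites
  out$A <- ma$A
  out$M_raw <- ma$M_raw
  out$M <- fit$M
  out$change <- classify_change(fit$M, tau = tau)
  attr(out, "fit") <- fit
  out
}
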