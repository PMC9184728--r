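# Loop-occurrence and anchor-annotation statistics, plus thin wrappers
# around the generic tests used throughout the pipeline.

# GRanges of one loop anchor (0-based half-open -> 1-based closed)
anchor_granges <- function(loops, which = 1L) {
  GenomicRanges::GRanges(
    loops[[paste0("chrom", which)]],
    IRanges::IRanges(loops[[paste0("start", which)]] + 1,
                     loops[[paste0("end", which)]]))
}

#' Loop occurrence probability per site category
#'
#' A site "has a loop" iff its interval overlaps either anchor of any loop
#' by at least \code{min_overlap} bp. Occurrence probability = sites with a
#' loop / total sites per category; all pairwise category differences are
#' tested with a two-sided Fisher exact test.
#'
#' @param site_sets Named list of site tables (the categories).
#' @param loops Loop table (BEDPE columns).
#' @param min_overlap Minimum anchor overlap in bp (default 1).
#' @return List: \code{occurrence} \code{data.frame(category, hits, total,
#'   probability)} and \code{tests} \code{data.frame(category1, category2,
#'   p)}; empty categories are excluded with a warning.
#' @export
loop_occurrence <- function(site_sets, loops, min_overlap = 1L) {
  empty <- vapply(site_sets, function(s) nrow(s) == 0L, logical(1))
  if (any(empty)) {
    warning("excluding empty categories: ",
            paste(names(site_sets)[empty], collapse = ", "))
    site_sets <- site_sets[!empty]
  }
  if (length(site_sets) == 0L) stop("no non-empty categories")
  a1 <- anchor_granges(loops, 1L)
  a2 <- anchor_granges(loops, 2L)
  occ <- lapply(names(site_sets), function(nm) {
    gr <- sites_granges(site_sets[[nm]])
    hit <- IRanges::overlapsAny(gr, a1, minoverlap = min_overlap,
                                ignore.strand = TRUE) |
           IRanges::overlapsAny(gr, a2, minoverlap = min_overlap,
                                ignore.strand = TRUE)
    data.frame(category = nm, hits = sum(hit), total = length(hit),
               probability = mean(hit), stringsAsFactors = FALSE)
  })
  occurrence <- do.call(rbind, occ)
  tests <- NULL
  if (nrow(occurrence) >= 2L) {
    cmb <- utils::combn(nrow(occurrence), 2)
    tests <- data.frame(
      category1 = occurrence$category[cmb[1, ]],
      category2 = occurrence$category[cmb[2, ]],
      p = apply(cmb, 2, function(ij) {
        o <- occurrence[ij, ]
        fisher_exact(matrix(c(o$hits[1], o$total[1] - o$hits[1],
                              o$hits[2], o$total[2] - o$hits[2]),
                            2, byrow = TRUE))$p
      }),
      stringsAsFactors = FALSE)
  }
  list(occurrence = occurrence, tests = tests)
}

#' Annotate the distal ("other") anchor of DIC loops
#'
#' For each loop with exactly one anchor overlapping a DIC, classifies the
#' other anchor by priority promoter > enhancer > exon > intron > intergenic
#' (a loop with both anchors on DICs is counted once per DIC, the partner
#' anchor being "other"). Additionally flags contacts with the DIC's own
#' host-gene promoter.
#'
#' @param loops Loop table (BEDPE columns).
#' @param dics DIC site table; may carry a \code{host_gene} column.
#' @param promoters Interval table (chrom, start, end) with optional
#'   \code{gene_id} column for the host-gene flag.
#' @param enhancers Interval table (chrom, start, end).
#' @param genes Gene table (gene bodies stand in for exon/intron annotation:
#'   an anchor inside a gene body and in none of the above is "intragenic").
#' @return List: \code{annotations} per classified loop-DIC contact
#'   (\code{loop, dic, class, host_promoter}), \code{proportions} (summing
#'   to 1 over classified contacts) and \code{n_skipped} loops touching no DIC.
#' @export
annotate_other_anchor <- function(loops, dics, promoters, enhancers, genes) {
  dic_gr <- sites_granges(dics)
  prom_gr <- GenomicRanges::GRanges(promoters$chrom,
                                    IRanges::IRanges(promoters$start + 1,
                                                     promoters$end))
  enh_gr <- GenomicRanges::GRanges(enhancers$chrom,
                                   IRanges::IRanges(enhancers$start + 1,
                                                    enhancers$end))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1, genes$end))
  rows <- list()
  n_skipped <- 0L
  for (li in seq_len(nrow(loops))) {
    l <- loops[li, ]
    on1 <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(
      anchor_granges(l, 1L), dic_gr, ignore.strand = TRUE))
    on2 <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(
      anchor_granges(l, 2L), dic_gr, ignore.strand = TRUE))
    if (length(on1) == 0L && length(on2) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    sides <- rbind(
      if (length(on1) > 0) cbind(dic = on1, other = 2L),
      if (length(on2) > 0) cbind(dic = on2, other = 1L))
    for (k in seq_len(nrow(sides))) {
      other <- anchor_granges(l, sides[k, "other"])
      cls <- if (IRanges::overlapsAny(other, prom_gr)) "promoter"
        else if (IRanges::overlapsAny(other, enh_gr)) "enhancer"
        else if (IRanges::overlapsAny(other, gene_gr)) "intragenic"
        else "intergenic"
      host <- if ("host_gene" %in% names(dics))
        dics$host_gene[sides[k, "dic"]] else NA_character_
      host_prom <- FALSE
      if (!is.na(host) && "gene_id" %in% names(promoters)) {
        hp <- prom_gr[promoters$gene_id == host]
        host_prom <- length(hp) > 0 && IRanges::overlapsAny(other, hp)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        loop = l$name, dic = dics$name[sides[k, "dic"]], class = cls,
        host_promoter = host_prom, stringsAsFactors = FALSE)
    }
  }
  ann <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(loop = character(0), dic = character(0), class = character(0),
               host_promoter = logical(0))
  props <- if (nrow(ann) > 0) prop.table(table(factor(
    ann$class, levels = c("promoter", "enhancer", "intragenic", "intergenic"))))
    else NULL
  list(annotations = ann, proportions = props, n_skipped = n_skipped)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value is the probability-mass
#' rule (sum of all tables with fixed margins whose probability does not
#' exceed the observed table's).
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @param alternative \code{"two.sided"} (default), \code{"greater"},
#'   \code{"less"}.
#' @return \code{data.frame(test, statistic, p, n)}; a zero margin gives
#'   p = 1 with a warning.
#' @export
fisher_exact <- function(tab, alternative = "two.sided") {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: p = 1 by convention")
    return(data.frame(test = "fisher", statistic = NA_real_, p = 1,
                      n = sum(tab)))
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  data.frame(test = "fisher", statistic = unname(ft$estimate), p = ft$p.value,
             n = sum(tab))
}

#' Mann-Whitney U test
#'
#' Exact permutation distribution (tie-safe) when the combined sample has at
#' most \code{exact_max} observations; the tie-corrected normal approximation
#' of \code{wilcox.test} otherwise. The exact two-sided p-value is
#' P(|U - n_x n_y / 2| >= |U_obs - n_x n_y / 2|) over all group relabelings.
#'
#' @param x,y Numeric observation vectors (each non-empty).
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (x tends larger), \code{"less"}.
#' @param exact_max Largest combined sample size for the exact enumeration.
#' @return \code{data.frame(test, statistic, p, n_x, n_y)} with the U
#'   statistic of x.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided",
                           exact_max = 20L) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_max) {
    sets <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
      greater = mean(u_all >= u_obs - eps),
      less = mean(u_all <= u_obs + eps),
      stop("unknown alternative"))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
  }
  data.frame(test = "mann-whitney", statistic = u_obs, p = p,
             n_x = nx, n_y = ny)
}

#' Paired t test
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative \code{"two.sided"} (default), \code{"greater"},
#'   \code{"less"}.
#' @return \code{data.frame(test, statistic, p, n)}.
#' @export
paired_t <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(data.frame(test = "paired-t", statistic = 0, p = 1,
                        n = length(x)))
    }
    stop("zero variance of paired differences")
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  data.frame(test = "paired-t", statistic = unname(tt$statistic),
             p = tt$p.value, n = length(x))
}

#' Hypergeometric overlap enrichment test
#'
#' Upper-tail probability P(X >= k) of drawing at least \code{k} marked
#' elements when \code{n} are drawn from a universe of \code{N} containing
#' \code{K} marked elements.
#'
#' @param k Observed overlap.
#' @param K Marked elements in the universe.
#' @param n Drawn elements.
#' @param N Universe size.
#' @return \code{data.frame(test, statistic, p, n)}.
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  stopifnot(k <= min(K, n), K <= N, n <= N, k >= 0)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(test = "hypergeometric", statistic = k, p = p, n = N)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1.
#'
#' @param p Numeric p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
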