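# Contact-matrix analytics: matrix balancing, distal-to-local ratio (DLR),
# inter-chromosomal fraction (ICF), condition deltas, insulation score and
# aggregate peak analysis (APA).

# number of bins per chromosome
map_nbins <- function(map) {
  stats::setNames(floor(map$chrom_sizes / map$resolution) +
                    (map$chrom_sizes %% map$resolution > 0),
                  names(map$chrom_sizes))
}

# dense symmetric cis matrix for one chromosome (1-based bin indexing)
cis_dense <- function(map, chrom) {
  n <- map_nbins(map)[[chrom]]
  r <- map$records
  r <- r[r$chrom1 == chrom & r$chrom2 == chrom, , drop = FALSE]
  m <- matrix(0, n, n)
  if (nrow(r) > 0) {
    m[cbind(r$bin1 + 1L, r$bin2 + 1L)] <- r$count
    m[cbind(r$bin2 + 1L, r$bin1 + 1L)] <- r$count
  }
  m
}

# per-bin inter-chromosomal contact totals, named chrom:bin
inter_totals <- function(map) {
  nb <- map_nbins(map)
  tot <- stats::setNames(
    rep(0, sum(nb)),
    unlist(lapply(names(nb), function(ch) paste0(ch, ":", seq_len(nb[[ch]]) - 1L))))
  r <- map$records[map$records$chrom1 != map$records$chrom2, , drop = FALSE]
  if (nrow(r) > 0) {
    k1 <- paste0(r$chrom1, ":", r$bin1)
    k2 <- paste0(r$chrom2, ":", r$bin2)
    a1 <- rowsum(r$count, k1)
    a2 <- rowsum(r$count, k2)
    tot[rownames(a1)] <- tot[rownames(a1)] + a1[, 1]
    tot[rownames(a2)] <- tot[rownames(a2)] + a2[, 1]
  }
  tot
}

# mean contact per distance band (in bins) of a dense cis matrix
expected_by_distance <- function(m) {
  n <- nrow(m)
  dd <- abs(row(m) - col(m))
  as.vector(tapply(m, dd, mean))   # index d+1 = mean at distance d
}

#' Balance a contact map by iterative proportional scaling
#'
#' Finds per-bin weights so that every covered bin's genome-wide marginal is
#' equal (within \code{tol}, relative). Bins with zero raw marginal are
#' excluded from balancing and keep weight NA.
#'
#' @param map A \code{contact_map}.
#' @param max_iter Maximum iterations.
#' @param tol Relative tolerance on the covered-bin row sums.
#' @return The map with balanced counts in \code{records$count}, per-bin
#'   \code{weights} (named \code{chrom:bin}) and \code{balanced = TRUE}.
#' @export
balance_map <- function(map, max_iter = 200L, tol = 1e-3) {
  stopifnot(inherits(map, "contact_map"))
  nb <- map_nbins(map)
  offs <- stats::setNames(c(0, cumsum(nb))[seq_along(nb)], names(nb))
  nbin_total <- sum(nb)
  r <- map$records
  gi <- offs[r$chrom1] + r$bin1 + 1L
  gj <- offs[r$chrom2] + r$bin2 + 1L
  w <- rep(1, nbin_total)

  marg <- function(cnt) {
    s <- rep(0, nbin_total)
    a <- rowsum(cnt, gi); s[as.integer(rownames(a))] <- a[, 1]
    offd <- gi != gj
    if (any(offd)) {
      b <- rowsum(cnt[offd], gj[offd])
      s[as.integer(rownames(b))] <- s[as.integer(rownames(b))] + b[, 1]
    }
    s
  }
  covered <- marg(r$count) > 0
  if (!any(covered)) stop("no covered bins to balance")
  resid <- Inf
  for (it in seq_len(max_iter)) {
    cnt <- r$count * w[gi] * w[gj]
    s <- marg(cnt)
    sc <- s[covered]
    resid <- max(abs(sc / mean(sc) - 1))
    if (resid < tol) break
    w[covered] <- w[covered] / sqrt(sc / mean(sc))
  }
  if (resid >= tol) {
    stop("balancing did not converge in ", max_iter,
         " iterations (last residual ", signif(resid, 3), ")")
  }
  map$records$count <- r$count * w[gi] * w[gj]
  w[!covered] <- NA_real_
  names(w) <- unlist(lapply(names(nb), function(ch)
    paste0(ch, ":", seq_len(nb[[ch]]) - 1L)))
  map$weights <- w
  map$balanced <- TRUE
  map
}

# rolling sum over +/- wb bins (window aggregation of per-bin vectors)
roll_sum <- function(x, wb) {
  if (wb <= 0) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - wb, 1L)
  hi <- pmin(seq_len(n) + wb, n)
  cs[hi + 1L] - cs[lo]
}

# per-bin local/distal cis sums of one chromosome
dlr_sums <- function(m, res, local_cutoff) {
  n <- nrow(m)
  d <- abs(row(m) - col(m)) * res
  local <- m; local[!(d > 0 & d <= local_cutoff)] <- 0
  distal <- m; distal[d <= local_cutoff] <- 0
  list(local = rowSums(local), distal = rowSums(distal))
}

#' Distal-to-local ratio (DLR) and its condition delta
#'
#' DLR(bin) = log2(distal cis contacts / local cis contacts), with local =
#' cis contacts at distance <= \code{local_cutoff} and distal = the rest of
#' the chromosome, both aggregated over \code{window} bp around the anchor
#' bin. Delta DLR = DLR(B) - DLR(A); positive values mean de-compaction.
#'
#' @param map_a,map_b Contact maps (same resolution and chromosomes);
#'   \code{map_b = NULL} returns DLR of A alone.
#' @param window Aggregation window around each anchor bin (bp).
#' @param local_cutoff Local/distal distance threshold (bp, > window).
#' @return \code{data.frame(chrom, bin, dlr_a[, dlr_b, delta_dlr])}; DLR is
#'   NA when either sum is 0.
#' @export
compute_dlr <- function(map_a, map_b = NULL, window = 0, local_cutoff = 3e6) {
  if (local_cutoff <= window) stop("local_cutoff must exceed window")
  res <- map_a$resolution
  if (!is.null(map_b)) {
    stopifnot(map_b$resolution == res,
              identical(map_a$chrom_sizes, map_b$chrom_sizes))
  }
  wb <- floor(window / res)
  one <- function(map, ch) {
    s <- dlr_sums(cis_dense(map, ch), res, local_cutoff)
    loc <- roll_sum(s$local, wb); dis <- roll_sum(s$distal, wb)
    ifelse(loc > 0 & dis > 0, log2(dis / loc), NA_real_)
  }
  out <- lapply(names(map_a$chrom_sizes), function(ch) {
    da <- one(map_a, ch)
    df <- data.frame(chrom = ch, bin = seq_along(da) - 1L, dlr_a = da)
    if (!is.null(map_b)) {
      df$dlr_b <- one(map_b, ch)
      df$delta_dlr <- df$dlr_b - df$dlr_a
    }
    df
  })
  do.call(rbind, out)
}

#' Inter-chromosomal fraction (ICF) and its condition delta
#'
#' ICF(bin) = inter-chromosomal contacts / (inter + intra), aggregated over
#' \code{window} bp around the anchor bin. Delta ICF = ICF(B) - ICF(A).
#'
#' @param map_a,map_b Contact maps; \code{map_b = NULL} for a single map.
#' @param window Aggregation window (bp).
#' @return \code{data.frame(chrom, bin, icf_a[, icf_b, delta_icf])}; ICF is
#'   NA for bins with zero total contacts.
#' @export
compute_icf <- function(map_a, map_b = NULL, window = 0) {
  res <- map_a$resolution
  wb <- floor(window / res)
  one <- function(map) {
    inter <- inter_totals(map)
    out <- lapply(names(map$chrom_sizes), function(ch) {
      m <- cis_dense(map, ch)
      intra <- rowSums(m)
      key <- paste0(ch, ":", seq_along(intra) - 1L)
      iv <- roll_sum(unname(inter[key]), wb)
      av <- roll_sum(intra, wb)
      tot <- iv + av
      data.frame(chrom = ch, bin = seq_along(intra) - 1L,
                 icf = ifelse(tot > 0, iv / tot, NA_real_))
    })
    do.call(rbind, out)
  }
  a <- one(map_a)
  out <- data.frame(chrom = a$chrom, bin = a$bin, icf_a = a$icf)
  if (!is.null(map_b)) {
    stopifnot(map_b$resolution == res,
              identical(map_a$chrom_sizes, map_b$chrom_sizes))
    out$icf_b <- one(map_b)$icf
    out$delta_icf <- out$icf_b - out$icf_a
  }
  out
}

#' Insulation score profile and boundary detection
#'
#' IS(i) = log2( mean contacts in the off-diagonal square spanning bins
#' [i-w, i) x (i, i+w] / the chromosome-wide expected mean at the same
#' distance band ). Boundaries are local minima with IS below \code{-depth}.
#' Bins within \code{w} of a chromosome end are not scored.
#'
#' @param map A \code{contact_map}.
#' @param square_width Square width w in bins (>= 2).
#' @param depth Boundary depth: local minima with IS < -depth are boundaries.
#' @return List: \code{profile} \code{data.frame(chrom, bin, is)} and
#'   \code{boundaries} \code{data.frame(chrom, bin)}.
#' @export
compute_insulation <- function(map, square_width = 4L, depth = 0.5) {
  if (square_width < 2L) stop("square_width must be >= 2 bins")
  w <- square_width
  profs <- lapply(names(map$chrom_sizes), function(ch) {
    n <- map_nbins(map)[[ch]]
    if (n < 2L * w + 1L) {
      return(data.frame(chrom = character(0), bin = integer(0), is = numeric(0)))
    }
    m <- cis_dense(map, ch)
    exp_d <- expected_by_distance(m)
    isv <- rep(NA_real_, n)
    for (i in seq(w + 1L, n - w)) {
      rows <- seq(i - w, i - 1L); cols <- seq(i + 1L, i + w)
      obs <- mean(m[rows, cols])
      dmat <- abs(outer(rows, cols, "-"))
      expct <- mean(exp_d[dmat + 1L])
      isv[i] <- if (obs > 0 && expct > 0) log2(obs / expct) else NA_real_
    }
    data.frame(chrom = ch, bin = seq_len(n) - 1L, is = isv)
  })
  profile <- do.call(rbind, profs)
  bnd <- lapply(split(profile, profile$chrom), function(df) {
    v <- df$is
    n <- length(v)
    idx <- which(!is.na(v) & v < -depth)
    idx <- idx[idx > 1 & idx < n]
    loc_min <- idx[vapply(idx, function(i) {
      l <- v[i - 1L]; r <- v[i + 1L]
      (is.na(l) || v[i] <= l) && (is.na(r) || v[i] <= r)
    }, logical(1))]
    data.frame(chrom = df$chrom[loc_min], bin = df$bin[loc_min])
  })
  boundaries <- do.call(rbind, bnd)
  rownames(boundaries) <- NULL
  list(profile = profile, boundaries = boundaries)
}

# map loop anchors to pixel coordinates; drop short-range/out-of-range pairs
pairs_to_pixels <- function(map, pairs, radius) {
  res <- map$resolution
  nb <- map_nbins(map)
  cis <- pairs$chrom1 == pairs$chrom2
  p <- pairs[cis, , drop = FALSE]
  b1 <- floor((p$start1 + p$end1) / 2 / res)
  b2 <- floor((p$start2 + p$end2) / 2 / res)
  swap <- b1 > b2
  tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  n <- nb[p$chrom1]
  usable <- (b2 - b1) > 2L * radius &
    b1 - radius >= 0 & b2 + radius < n
  list(pixels = data.frame(chrom = p$chrom1[usable], bin1 = b1[usable],
                           bin2 = b2[usable], stringsAsFactors = FALSE),
       n_dropped = nrow(pairs) - sum(usable))
}

#' Aggregate peak analysis (APA)
#'
#' Sums the (2r+1) x (2r+1) submatrices centred on each anchor-pair pixel
#' (optionally dividing each cell by the chromosome's expected contact at
#' its distance) and scores enrichment as the centre value over the mean of
#' the r x r lower-left corner block. Pairs closer than 2r bins or too near
#' a chromosome end are dropped and counted.
#'
#' @param map A \code{contact_map}.
#' @param pairs Loop table (BEDPE-style columns chrom1,start1,end1,chrom2,
#'   start2,end2); inter-chromosomal pairs are ignored.
#' @param radius Submatrix radius r in pixels.
#' @param norm \code{"expected"} (distance-normalized, default) or
#'   \code{"none"}.
#' @return List of class \code{apa_result}: \code{matrix} (aggregate),
#'   \code{score}, \code{central} (per-pair central enrichment),
#'   \code{n_pairs}, \code{n_dropped}.
#' @export
run_apa <- function(map, pairs, radius = 5L, norm = c("expected", "none")) {
  norm <- match.arg(norm)
  px <- pairs_to_pixels(map, pairs, radius)
  if (nrow(px$pixels) == 0L) stop("no usable pairs for APA")
  size <- 2L * radius + 1L
  agg <- matrix(0, size, size)
  central <- numeric(nrow(px$pixels))
  for (ch in unique(px$pixels$chrom)) {
    m <- cis_dense(map, ch)
    exp_d <- if (norm == "expected") expected_by_distance(m) else NULL
    sel <- which(px$pixels$chrom == ch)
    for (k in sel) {
      i <- px$pixels$bin1[k] + 1L; j <- px$pixels$bin2[k] + 1L
      rows <- seq(i - radius, i + radius); cols <- seq(j - radius, j + radius)
      sub <- m[rows, cols]
      if (norm == "expected") {
        dmat <- abs(outer(rows, cols, "-"))
        ex <- matrix(exp_d[dmat + 1L], size, size)
        ex[ex <= 0 | is.na(ex)] <- NA_real_
        sub <- sub / ex
        sub[is.na(sub)] <- 0
      }
      agg <- agg + sub
      central[k] <- sub[radius + 1L, radius + 1L]
    }
  }
  corner <- agg[seq(radius + 2L, size), seq_len(radius)]
  score <- if (mean(corner) > 0) agg[radius + 1L, radius + 1L] / mean(corner)
           else NA_real_
  structure(list(matrix = agg, score = score, central = central,
                 n_pairs = nrow(px$pixels), n_dropped = px$n_dropped,
                 radius = radius, norm = norm),
            class = "apa_result")
}

#' Compare APA central enrichment between two conditions
#'
#' Runs APA with the same pair list on both maps and applies a paired
#' two-sided t test to the per-pair central enrichment values.
#'
#' @param map_a,map_b Contact maps.
#' @param pairs Loop table used for both maps.
#' @param radius Submatrix radius in pixels.
#' @param norm Normalization, see \code{\link{run_apa}}.
#' @return \code{data.frame(statistic, p, mean_diff, n)}; identical inputs
#'   give statistic 0 and p 1.
#' @export
compare_apa <- function(map_a, map_b, pairs, radius = 5L, norm = "expected") {
  apa_a <- run_apa(map_a, pairs, radius = radius, norm = norm)
  apa_b <- run_apa(map_b, pairs, radius = radius, norm = norm)
  if (apa_a$n_pairs != apa_b$n_pairs) stop("pair lists diverged between maps")
  if (apa_a$n_pairs < 3L) stop("need at least 3 usable pairs")
  d <- apa_b$central - apa_a$central
  if (all(d == 0)) {
    return(data.frame(statistic = 0, p = 1, mean_diff = 0, n = length(d)))
  }
  tt <- stats::t.test(apa_b$central, apa_a$central, paired = TRUE)
  data.frame(statistic = unname(tt$statistic), p = tt$p.value,
             mean_diff = mean(d), n = length(d))
}
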