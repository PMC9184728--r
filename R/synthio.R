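# Synthetic scenes with planted ground truth: genome, two-condition cohesin
# peaks, co-factor signals, expression/elongation summaries, contact maps and
# feature matrices. Every generator is a pure function of (params, seed).

#' Simulation parameters
#'
#' Bundles every knob of the synthetic-scene generators with desk-scale
#' defaults: 2 chromosomes x 20 Mb, 300 genes, ~3,000 cohesin sites, 100
#' planted DICs at fold change 0.5 under negative-binomial dispersion 0.1.
#'
#' @param seed Integer seed; every generator derives its randomness from it.
#' @param n_chroms,chrom_length Number of chromosomes and their length (bp).
#' @param n_genes Total genes to place (non-overlapping).
#' @param gene_length_range Min/max gene length (bp).
#' @param n_sites Named vector: cohesin sites per location class.
#' @param fraction_responsive Fraction of genes that respond to the stimulus.
#' @param n_planted_dic Number of planted decreased intragenic cohesin sites.
#' @param dic_fold_change Condition-B mean multiplier at planted DICs (in (0,1)).
#' @param nb_dispersion Negative-binomial dispersion of peak counts: the
#'   extra-Poisson variance fraction, variance = (1 + dispersion) * mu
#'   (0 gives Poisson counts).
#' @param library_factor Global condition-B scale factor s (all B means x s).
#' @param hc_fraction Fraction of planted DICs that are high-CTCF.
#' @param ctcf_mixture Two-component log-normal CTCF density mixture:
#'   \code{meanlog_low, meanlog_high, sdlog, weight_high} (weight used for
#'   non-DIC sites; planted DICs take the component given by their subtype).
#' @param tf_cobind_probs Named list of per-class Bernoulli probabilities for
#'   binary co-binding columns; each entry is \code{c(LC=, HC=, other=)}.
#' @param elongation_mean,elongation_sd Pol2ser2 stimulated/control ratio for
#'   responsive genes (non-responsive genes are centred at 1 with the same sd).
#' @param resolution Contact-map bin width (bp).
#' @param decay_exponent Power-law exponent of the contact distance decay.
#' @param base_contacts Poisson mean at distance 0 (per pixel).
#' @param inter_mean Poisson mean of inter-chromosomal background pixels.
#' @param n_loops Planted loops (split between DIC-anchored and background).
#' @param loop_enrichment_fold Pixel-mean multiplier at planted loop anchors.
#' @param loop_min_sep,loop_max_sep Anchor separation range for planted loops (bp).
#' @param n_boundaries Planted insulation boundaries across the genome.
#' @param boundary_attenuation Cross-boundary contact multiplier.
#' @param compaction_shift_fraction Fraction of local contact mass moved to
#'   distal positions (condition B) at planted de-compaction bins.
#' @param n_compaction_bins Planted de-compaction anchor bins.
#' @param local_cutoff Local/distal distance threshold (bp) used when planting
#'   de-compaction (scaled to the desk-size scene).
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 20e6,
                       n_genes = 300L,
                       gene_length_range = c(25e3, 120e3),
                       n_sites = c(aroundTSS = 1000L, intragenic = 1200L,
                                   intergenic = 800L),
                       fraction_responsive = 0.3,
                       n_planted_dic = 100L,
                       dic_fold_change = 0.5,
                       nb_dispersion = 0.1,
                       library_factor = 1,
                       hc_fraction = 141 / 558,
                       ctcf_mixture = list(meanlog_low = log(2),
                                           meanlog_high = log(32),
                                           sdlog = 0.4,
                                           weight_high = 0.25),
                       tf_cobind_probs = list(
                         H3K27ac = c(LC = 0.85, HC = 0.25, other = 0.25),
                         P300    = c(LC = 0.75, HC = 0.20, other = 0.20),
                         Med1    = c(LC = 0.70, HC = 0.20, other = 0.25),
                         ER      = c(LC = 0.60, HC = 0.15, other = 0.15),
                         CTCF_cobind = c(LC = 0.15, HC = 0.90, other = 0.50)),
                       elongation_mean = 1.5,
                       elongation_sd = 0.05,
                       resolution = 25e3,
                       decay_exponent = 1.0,
                       base_contacts = 100,
                       inter_mean = 0.02,
                       n_loops = 100L,
                       loop_enrichment_fold = 5,
                       loop_min_sep = 10L,
                       loop_max_sep = 60L,
                       n_boundaries = 100L,
                       boundary_attenuation = 0.1,
                       compaction_shift_fraction = 0.2,
                       n_compaction_bins = 40L,
                       local_cutoff = 250e3) {
  p <- as.list(environment())
  stopifnot(p$dic_fold_change > 0, p$dic_fold_change < 1,
            p$decay_exponent > 0,
            p$fraction_responsive >= 0, p$fraction_responsive <= 1,
            p$ctcf_mixture$weight_high >= 0, p$ctcf_mixture$weight_high <= 1,
            p$compaction_shift_fraction >= 0, p$compaction_shift_fraction <= 1)
  for (pr in p$tf_cobind_probs) stopifnot(all(pr >= 0 & pr <= 1))
  class(p) <- "sim_params"
  p
}

# run code under a derived seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# stable per-stage seed derivation, kept below 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(genome = 11L, peaks = 23L, cofactor = 37L, expression = 41L,
               contacts = 53L, features = 67L, split = 71L, smote = 83L)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% 2147483647L
}

#' Simulate a genome: chromosome sizes and non-overlapping genes
#'
#' Genes are placed sequentially per chromosome with random gaps (uniform
#' stick-breaking of the leftover space) and random strands.
#'
#' @param params A \code{sim_params} object.
#' @return List with \code{genes} (gene table) and \code{chrom_sizes}.
#' @export
simulate_genome <- function(params) {
  p <- params
  chroms <- paste0("chr", seq_len(p$n_chroms))
  chrom_sizes <- stats::setNames(rep(p$chrom_length, p$n_chroms), chroms)
  per_chrom <- diff(round(seq(0, p$n_genes, length.out = p$n_chroms + 1)))
  with_seed(derive_seed(p$seed, "genome"), {
    rows <- vector("list", p$n_chroms)
    for (ci in seq_len(p$n_chroms)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      lens <- round(stats::runif(ng, p$gene_length_range[1], p$gene_length_range[2]))
      margin <- 50e3  # keep gene deserts at both chromosome ends
      free <- p$chrom_length - 2 * margin - sum(lens) - (ng + 1) * 1000
      if (free < 0) {
        stop("cannot place ", ng, " genes of the requested lengths on a ",
             p$chrom_length, " bp chromosome; reduce n_genes or lengths")
      }
      # random gaps: stick-breaking of the free space across ng+1 slots
      cuts <- sort(stats::runif(ng))
      gaps <- (diff(c(0, cuts, 1)) * free + 1000)[seq_len(ng)]
      starts <- margin + cumsum(gaps) + cumsum(c(0, lens[-ng]))[seq_len(ng)]
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      rows[[ci]] <- data.frame(
        gene_id = sprintf("%s_g%04d", chroms[ci], seq_len(ng)),
        chrom = chroms[ci],
        strand = strand,
        tss = ifelse(strand == "+", starts, starts + lens),
        tes = ifelse(strand == "+", starts + lens, starts),
        stringsAsFactors = FALSE)
    }
    genes <- validate_genes(do.call(rbind, rows))
    list(genes = genes, chrom_sizes = chrom_sizes)
  })
}

#' Simulate two-condition cohesin peaks with planted DICs
#'
#' Places cohesin sites in three location classes (around TSSs, inside
#' intragenic regions, in gene deserts), draws per-condition read densities
#' from a negative binomial around a site-specific baseline, and plants
#' \code{n_planted_dic} decreased sites inside intragenic regions of
#' responsive genes (condition-B mean = baseline x \code{dic_fold_change}).
#' All condition-B means are additionally multiplied by
#' \code{library_factor}.
#'
#' @param params A \code{sim_params} object.
#' @param genome Output of \code{\link{simulate_genome}}.
#' @return List with \code{sites} (site table with \code{count_ctrl},
#'   \code{count_e2}) and \code{truth} (per-site planted labels plus the
#'   responsive gene ids).
#' @export
simulate_cohesin_peaks <- function(params, genome) {
  p <- params
  genes <- genome$genes
  flank <- 10e3
  with_seed(derive_seed(p$seed, "peaks"), {
    large <- genes[genes$length > 20e3 + 1e3, ]
    n_resp <- round(p$fraction_responsive * nrow(genes))
    responsive <- sample(large$gene_id, min(n_resp, nrow(large)))

    mk_widths <- function(n) round(stats::runif(n, 400, 1500))

    # aroundTSS sites: centred within +/-4 kb of a random TSS
    n1 <- p$n_sites[["aroundTSS"]]
    gi <- sample(nrow(genes), n1, replace = TRUE)
    w <- mk_widths(n1)
    centre <- genes$tss[gi] + round(stats::runif(n1, -4e3, 4e3))
    tss_sites <- data.frame(chrom = genes$chrom[gi],
                            start = pmax(0, centre - w %/% 2),
                            end = centre + w %/% 2 + 1,
                            planted_class = "aroundTSS",
                            host = genes$gene_id[gi],
                            stringsAsFactors = FALSE)

    # intragenic sites: inside gene body minus 10 kb flanks of large genes
    n2 <- p$n_sites[["intragenic"]]
    gi <- sample(which(genes$length > 2 * flank + 5e3), n2, replace = TRUE)
    lo <- genes$start[gi] + flank + 1e3
    hi <- genes$end[gi] - flank - 1e3
    centre <- round(lo + stats::runif(n2) * (hi - lo))
    w <- mk_widths(n2)
    intra_sites <- data.frame(chrom = genes$chrom[gi],
                              start = centre - w %/% 2,
                              end = centre + w %/% 2 + 1,
                              planted_class = "intragenic",
                              host = genes$gene_id[gi],
                              stringsAsFactors = FALSE)

    # intergenic sites: rejection-sample gene-desert positions
    n3 <- p$n_sites[["intergenic"]]
    inter <- matrix(NA_real_, 0, 2)
    chrom3 <- character(0)
    gene_gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(genes$start - flank + 1, genes$end + flank))
    while (length(chrom3) < n3) {
      m <- 2L * (n3 - length(chrom3))
      cc <- sample(names(genome$chrom_sizes), m, replace = TRUE)
      pos <- round(stats::runif(m, 5e3, genome$chrom_sizes[cc] - 5e3))
      cand <- GenomicRanges::GRanges(cc, IRanges::IRanges(pos, pos))
      keep <- !IRanges::overlapsAny(cand, gene_gr)
      chrom3 <- c(chrom3, cc[keep])
      inter <- rbind(inter, cbind(pos[keep], pos[keep]))
    }
    chrom3 <- chrom3[seq_len(n3)]
    pos3 <- inter[seq_len(n3), 1]
    w <- mk_widths(n3)
    inter_sites <- data.frame(chrom = chrom3,
                              start = pos3 - w %/% 2,
                              end = pos3 + w %/% 2 + 1,
                              planted_class = "intergenic",
                              host = NA_character_,
                              stringsAsFactors = FALSE)

    sites <- rbind(tss_sites, intra_sites, inter_sites)
    sites$name <- sprintf("site_%05d", seq_len(nrow(sites)))
    sites$score <- 0
    sites$strand <- "."

    # plant DICs among intragenic sites hosted by responsive genes
    cand <- which(sites$planted_class == "intragenic" &
                    sites$host %in% responsive)
    if (length(cand) < p$n_planted_dic) {
      stop("only ", length(cand), " intragenic sites in responsive genes; ",
           "cannot plant ", p$n_planted_dic, " DICs")
    }
    dic_idx <- sort(sample(cand, p$n_planted_dic))
    is_dic <- seq_len(nrow(sites)) %in% dic_idx
    is_hc <- rep(FALSE, nrow(sites))
    if (p$n_planted_dic > 0) {
      n_hc <- round(p$hc_fraction * p$n_planted_dic)
      is_hc[sample(dic_idx, n_hc)] <- TRUE
    }

    # negative-binomial densities: var = (1 + dispersion) * mu, so the
    # dispersion is the extra-Poisson variance fraction (0 -> Poisson)
    baseline <- stats::rlnorm(nrow(sites), meanlog = log(200), sdlog = 0.5)
    mu_a <- baseline
    mu_b <- baseline * ifelse(is_dic, p$dic_fold_change, 1) * p$library_factor
    draw <- function(mu) {
      if (p$nb_dispersion <= 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = mu / p$nb_dispersion)
    }
    sites$count_ctrl <- draw(mu_a)
    sites$count_e2 <- draw(mu_b)

    truth <- data.frame(name = sites$name,
                        location_class = sites$planted_class,
                        host_gene = sites$host,
                        is_planted_dic = is_dic,
                        is_HC = is_hc,
                        is_LC = is_dic & !is_hc,
                        stringsAsFactors = FALSE)
    sites$planted_class <- NULL
    sites$host <- NULL
    sites <- sites[, c("chrom", "start", "end", "name", "score", "strand",
                       "count_ctrl", "count_e2")]
    list(sites = sites, truth = truth, responsive_genes = sort(responsive))
  })
}

#' Simulate co-factor signals at cohesin sites
#'
#' CTCF density is drawn from a two-component log-normal mixture whose
#' component is fixed by the planted subtype for DICs (high for HC, low for
#' LC) and mixed by \code{weight_high} elsewhere. Binary TF co-binding
#' columns are Bernoulli with class-dependent probabilities, and a Rad21
#' density column is drawn well above typical omission thresholds.
#'
#' @param params A \code{sim_params} object.
#' @param sites Site table from \code{\link{simulate_cohesin_peaks}}.
#' @param truth Matching truth table.
#' @return \code{data.frame}: name, ctcf_density, rad21_density, one 0/1
#'   column per TF in \code{tf_cobind_probs}.
#' @export
simulate_cofactor_signals <- function(params, sites, truth) {
  p <- params
  mx <- p$ctcf_mixture
  stopifnot(nrow(sites) == nrow(truth), all(sites$name == truth$name))
  with_seed(derive_seed(p$seed, "cofactor"), {
    n <- nrow(sites)
    high <- ifelse(truth$is_planted_dic, truth$is_HC,
                   stats::runif(n) < mx$weight_high)
    ctcf <- stats::rlnorm(n,
                          meanlog = ifelse(high, mx$meanlog_high, mx$meanlog_low),
                          sdlog = mx$sdlog)
    rad21 <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.4)
    cls <- ifelse(truth$is_LC, "LC", ifelse(truth$is_HC, "HC", "other"))
    out <- data.frame(name = sites$name, ctcf_density = ctcf,
                      rad21_density = rad21, stringsAsFactors = FALSE)
    for (tf in names(p$tf_cobind_probs)) {
      pr <- p$tf_cobind_probs[[tf]][cls]
      out[[tf]] <- as.integer(stats::runif(n) < pr)
    }
    out
  })
}

#' Simulate expression and elongation summaries per gene
#'
#' Responsive genes draw a Pol2ser2 stimulated/control elongation ratio from
#' Normal(\code{elongation_mean}, \code{elongation_sd}) and a positive
#' expression log2 fold change; other genes are centred at ratio 1 and
#' log2fc 0.
#'
#' @param params A \code{sim_params} object.
#' @param genes Gene table.
#' @param responsive_genes Character vector of responsive gene ids.
#' @return List with \code{elongation} (gene_id, ratio) and
#'   \code{expression} (gene_id, mean_ctrl, mean_e2, log2fc, significant).
#' @export
simulate_expression_elongation <- function(params, genes, responsive_genes) {
  p <- params
  with_seed(derive_seed(p$seed, "expression"), {
    n <- nrow(genes)
    resp <- genes$gene_id %in% responsive_genes
    ratio <- stats::rnorm(n, mean = ifelse(resp, p$elongation_mean, 1),
                          sd = p$elongation_sd)
    ratio <- pmax(ratio, 0.01)
    log2fc <- ifelse(resp,
                     abs(stats::rnorm(n, 1.5, 0.5)) + 0.1,
                     stats::rnorm(n, 0, 0.3))
    mean_ctrl <- stats::rlnorm(n, log(100), 1)
    mean_e2 <- mean_ctrl * 2^log2fc
    list(elongation = data.frame(gene_id = genes$gene_id, ratio = ratio,
                                 stringsAsFactors = FALSE),
         expression = data.frame(gene_id = genes$gene_id,
                                 mean_ctrl = mean_ctrl, mean_e2 = mean_e2,
                                 log2fc = log2fc,
                                 significant = resp,
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate a pair of contact maps with planted structure
#'
#' Background counts are Poisson with mean
#' \code{base_contacts / (1 + d)^decay_exponent} for bin distance \code{d}.
#' Planted loops multiply their anchor-pair pixel mean by
#' \code{loop_enrichment_fold} in condition A; loops anchored at planted DIC
#' summits are removed in condition B. At planted de-compaction bins,
#' \code{compaction_shift_fraction} of the local contact mass (distance <=
#' \code{local_cutoff}) is moved to distal positions in condition B.
#' Insulation boundaries attenuate pixel means once for any pair separated
#' by a boundary. A uniform inter-chromosomal Poisson background is added.
#' Condition B shares condition A's counts through exact Poisson coupling,
#' so pixels whose mean is unchanged are identical between conditions (and
#' with nothing planted the two maps are equal).
#'
#' @param params A \code{sim_params} object.
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param dic_summits Optional \code{data.frame(chrom, pos)} of planted DIC
#'   summits; when given, half of the planted loops are anchored there and
#'   those loops are removed in condition B.
#' @return List: \code{map_a}, \code{map_b} (contact_map), \code{loops}
#'   (BEDPE-style table with \code{at_dic} flag), \code{boundaries}
#'   (chrom, bin), \code{compaction_bins} (chrom, bin).
#' @export
simulate_contact_maps <- function(params, chrom_sizes, dic_summits = NULL) {
  p <- params
  res <- p$resolution
  nbins <- floor(chrom_sizes / res)
  with_seed(derive_seed(p$seed, "contacts"), {
    chroms <- names(chrom_sizes)

    # plan boundaries, compaction bins and loops per chromosome
    per <- function(n_total) {
      k <- length(chroms)
      diff(round(seq(0, n_total, length.out = k + 1)))
    }
    nb <- per(p$n_boundaries); nc <- per(p$n_compaction_bins)
    nl <- per(p$n_loops)

    boundaries <- compaction <- loops <- NULL
    recs_a <- recs_b <- vector("list", length(chroms) + 1L)

    loc_bins <- max(1L, floor(p$local_cutoff / res))

    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      n <- nbins[[ch]]
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      mu <- p$base_contacts / (1 + d)^p$decay_exponent

      # boundaries: evenly spaced candidates, jittered, min separation
      kb <- nb[ci]
      if (kb > 0) {
        spacing <- n / (kb + 1)
        bpos <- round(spacing * seq_len(kb) + stats::runif(kb, -spacing / 4, spacing / 4))
        bpos <- sort(unique(pmin(pmax(bpos, 10L), n - 10L)))
        block <- findInterval(seq_len(n), bpos + 0.5)  # block id per bin
        cross <- pmin(abs(outer(block, block, "-")), 1L)  # attenuate once
        mu <- mu * p$boundary_attenuation^cross
        boundaries <- rbind(boundaries,
                            data.frame(chrom = ch, bin = bpos - 1L))
      }

      # loops: pairs away from boundaries; first chromosome hosts DIC loops
      kl <- nl[ci]
      lp <- NULL
      if (kl > 0) {
        a1 <- sort(sample(seq(5L, n - 5L - p$loop_min_sep), kl, replace = FALSE))
        sep <- sample(seq(p$loop_min_sep, p$loop_max_sep), kl, replace = TRUE)
        a2 <- pmin(a1 + sep, n - 2L)
        at_dic <- rep(FALSE, kl)
        if (!is.null(dic_summits)) {
          ds <- dic_summits[dic_summits$chrom == ch, , drop = FALSE]
          if (nrow(ds) > 0) {
            k_dic <- min(nrow(ds), ceiling(kl / 2))
            pick <- sample(nrow(ds), k_dic)
            a1[seq_len(k_dic)] <- pmin(pmax(floor(ds$pos[pick] / res) + 1L, 3L),
                                       n - p$loop_min_sep - 2L)
            a2[seq_len(k_dic)] <- pmin(a1[seq_len(k_dic)] +
                                         sample(seq(p$loop_min_sep, p$loop_max_sep),
                                                k_dic, replace = TRUE), n - 2L)
            at_dic[seq_len(k_dic)] <- TRUE
          }
        }
        lp <- data.frame(chrom = ch, bin1 = a1 - 1L, bin2 = a2 - 1L,
                         at_dic = at_dic)
        # drop accidental duplicates of the same pixel
        lp <- lp[!duplicated(lp[, c("bin1", "bin2")]), , drop = FALSE]
      }

      mu_a <- mu
      if (!is.null(lp) && nrow(lp) > 0) {
        ij <- cbind(lp$bin1 + 1L, lp$bin2 + 1L)
        mu_a[ij] <- mu[ij] * p$loop_enrichment_fold
        mu_a[ij[, c(2, 1), drop = FALSE]] <- mu_a[ij]
      }
      mu_b <- mu_a
      if (!is.null(lp) && any(lp$at_dic)) {
        ij <- cbind(lp$bin1[lp$at_dic] + 1L, lp$bin2[lp$at_dic] + 1L)
        mu_b[ij] <- mu[ij]               # loop removed: back to background
        mu_b[ij[, c(2, 1), drop = FALSE]] <- mu_b[ij]
      }

      # de-compaction in B: shift local mass of planted rows to distal
      kc <- nc[ci]
      if (kc > 0) {
        cand <- setdiff(seq(loc_bins + 2L, n - loc_bins - 2L),
                        unlist(lapply(if (is.null(lp)) NULL else
                          c(lp$bin1, lp$bin2), function(x) x)))
        cbins <- sort(sample(cand, kc))
        for (b in cbins) {
          row_d <- abs(seq_len(n) - b)
          local <- which(row_d > 0 & row_d <= loc_bins)
          distal <- which(row_d > loc_bins)
          L <- sum(mu_b[b, local]); D <- sum(mu_b[b, distal])
          f <- p$compaction_shift_fraction
          mu_b[b, local] <- mu_b[b, local] * (1 - f)
          mu_b[b, distal] <- mu_b[b, distal] * (1 + f * L / D)
          mu_b[local, b] <- mu_b[b, local]
          mu_b[distal, b] <- mu_b[b, distal]
        }
        compaction <- rbind(compaction, data.frame(chrom = ch, bin = cbins - 1L))
      }

      # sample upper triangle (diagonal included); condition B shares A's
      # counts via exact Poisson coupling (thinning where the mean drops,
      # additional draws where it rises), so unchanged pixels are identical
      ut <- which(upper.tri(mu, diag = TRUE))
      ma <- mu_a[ut]; mb <- mu_b[ut]
      ca <- stats::rpois(length(ut), ma)
      cb <- ca
      dn <- which(mb < ma)
      if (length(dn) > 0) {
        cb[dn] <- stats::rbinom(length(dn), ca[dn], mb[dn] / ma[dn])
      }
      up <- which(mb > ma)
      if (length(up) > 0) {
        cb[up] <- ca[up] + stats::rpois(length(up), mb[up] - ma[up])
      }
      rowi <- ((ut - 1L) %% n) + 1L
      colj <- ((ut - 1L) %/% n) + 1L
      keep <- ca > 0 | cb > 0
      recs <- data.frame(chrom1 = ch, bin1 = rowi[keep] - 1L,
                         chrom2 = ch, bin2 = colj[keep] - 1L)
      recs_a[[ci]] <- cbind(recs, count = ca[keep])[ca[keep] > 0, ]
      recs_b[[ci]] <- cbind(recs, count = cb[keep])[cb[keep] > 0, ]
      if (!is.null(lp) && nrow(lp) > 0) {
        loops <- rbind(loops, lp)
      }
    }

    # inter-chromosomal background (identical process both conditions)
    if (length(chroms) >= 2 && p$inter_mean > 0) {
      inter_list_a <- inter_list_b <- list()
      idx <- 1L
      for (i in seq_len(length(chroms) - 1L)) {
        for (j in seq((i + 1L), length(chroms))) {
          ni <- nbins[[chroms[i]]]; nj <- nbins[[chroms[j]]]
          m <- ni * nj
          ka <- stats::rpois(m, p$inter_mean)
          kb2 <- ka  # inter-chromosomal background identical in B
          w <- which(ka > 0 | kb2 > 0)
          base <- data.frame(chrom1 = chroms[i], bin1 = ((w - 1L) %% ni),
                             chrom2 = chroms[j], bin2 = ((w - 1L) %/% ni))
          inter_list_a[[idx]] <- cbind(base, count = ka[w])[ka[w] > 0, ]
          inter_list_b[[idx]] <- cbind(base, count = kb2[w])[kb2[w] > 0, ]
          idx <- idx + 1L
        }
      }
      recs_a[[length(chroms) + 1L]] <- do.call(rbind, inter_list_a)
      recs_b[[length(chroms) + 1L]] <- do.call(rbind, inter_list_b)
    }

    map_a <- contact_map(do.call(rbind, recs_a), res, chrom_sizes)
    map_b <- contact_map(do.call(rbind, recs_b), res, chrom_sizes)

    loops_bedpe <- NULL
    if (!is.null(loops)) {
      loops_bedpe <- data.frame(
        chrom1 = loops$chrom, start1 = loops$bin1 * res,
        end1 = (loops$bin1 + 1) * res,
        chrom2 = loops$chrom, start2 = loops$bin2 * res,
        end2 = (loops$bin2 + 1) * res,
        name = sprintf("loop_%04d", seq_len(nrow(loops))),
        score = 0, at_dic = loops$at_dic,
        stringsAsFactors = FALSE)
    }
    list(map_a = map_a, map_b = map_b, loops = loops_bedpe,
         boundaries = boundaries, compaction_bins = compaction)
  })
}

#' Simulate a labelled feature matrix with planted structure
#'
#' Continuous features are standard normal; informative features are shifted
#' by \code{effect_size} (in SDs) for class-1 rows. A sparse linear response
#' (\code{k_nonzero} coefficients, Gaussian noise at the stated
#' signal-to-noise ratio) is attached for regression-selection tests, and
#' each row carries a chromosome label for held-out splits.
#'
#' @param n_sites,n_features Matrix dimensions.
#' @param n_informative Number of class-informative features.
#' @param effect_size Class-1 mean shift (SD units) of informative features.
#' @param minority_fraction Fraction of class-1 rows.
#' @param k_nonzero Nonzero coefficients of the planted linear model.
#' @param snr Signal-to-noise ratio (var(X beta)/var(noise)) of the linear
#'   response.
#' @param n_chrom_labels Rows are assigned uniformly to chr1..chrN labels.
#' @param seed Integer seed.
#' @return List: \code{X} (matrix, named columns), \code{y_class} (0/1),
#'   \code{y_linear}, \code{chrom}, \code{informative_idx}, \code{beta}.
#' @export
simulate_feature_matrix <- function(n_sites = 2000L, n_features = 50L,
                                    n_informative = 10L, effect_size = 2,
                                    minority_fraction = 0.1,
                                    k_nonzero = 5L, snr = 3,
                                    n_chrom_labels = 22L, seed = 1L) {
  stopifnot(k_nonzero <= n_features, n_informative <= n_features)
  with_seed(derive_seed(seed, "features"), {
    X <- matrix(stats::rnorm(n_sites * n_features), n_sites, n_features)
    colnames(X) <- sprintf("feat_%03d", seq_len(n_features))
    y <- as.integer(stats::runif(n_sites) < minority_fraction)
    info <- sort(sample(n_features, n_informative))
    X[y == 1, info] <- X[y == 1, info] + effect_size

    beta <- numeric(n_features)
    nz <- sort(sample(n_features, k_nonzero))
    beta[nz] <- sample(c(-1, 1), k_nonzero, replace = TRUE) *
      stats::runif(k_nonzero, 1, 2)
    signal <- as.vector(X %*% beta)
    sd_noise <- if (snr > 0) stats::sd(signal) / sqrt(snr) else 0
    y_lin <- signal + stats::rnorm(n_sites, 0, sd_noise)

    chrom <- paste0("chr", sample(n_chrom_labels, n_sites, replace = TRUE))
    list(X = X, y_class = y, y_linear = y_lin, chrom = chrom,
         informative_idx = info, beta = beta)
  })
}

#' Simulate a complete scene
#'
#' Convenience wrapper running genome, peaks, co-factor, expression and
#' contact-map generators under one parameter set.
#'
#' @param params A \code{sim_params} object.
#' @param contacts Set \code{FALSE} to skip the (slower) contact maps.
#' @return List with genes, chrom_sizes, sites, truth, cofactors,
#'   elongation, expression, responsive_genes and (optionally) hic.
#' @export
simulate_scene <- function(params = sim_params(), contacts = TRUE) {
  genome <- simulate_genome(params)
  pk <- simulate_cohesin_peaks(params, genome)
  cof <- simulate_cofactor_signals(params, pk$sites, pk$truth)
  ee <- simulate_expression_elongation(params, genome$genes, pk$responsive_genes)
  out <- list(params = params, genes = genome$genes,
              chrom_sizes = genome$chrom_sizes,
              sites = pk$sites, truth = pk$truth,
              responsive_genes = pk$responsive_genes,
              cofactors = cof,
              elongation = ee$elongation, expression = ee$expression)
  if (contacts) {
    dic <- pk$truth$is_planted_dic
    summits <- data.frame(chrom = pk$sites$chrom[dic],
                          pos = site_summits(pk$sites[dic, ]))
    out$hic <- simulate_contact_maps(params, genome$chrom_sizes, summits)
  }
  out
}
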