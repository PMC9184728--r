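# Readers/writers for the genomic formats the pipeline exchanges.
# All coordinates are BED-style 0-based half-open internally.

#' Read a BED-like site table
#'
#' Reads a tab-separated BED3/BED6 file, optionally carrying per-condition
#' read-count columns after the standard fields. Coordinates are 0-based
#' half-open and are kept that way internally.
#'
#' @param path Path to a tab-separated file with at least 3 columns
#'   (chrom, start, end). Columns 4-6, when present, are taken as
#'   name, score and strand.
#' @param count_names Character vector naming extra numeric columns that
#'   follow the positional fields (e.g. \code{c("count_a","count_b")}).
#'   \code{NULL} means no extra columns are expected.
#' @return A \code{data.frame} with columns \code{chrom, start, end, name,
#'   score, strand} plus any declared count columns, rows in input order.
#' @export
read_bed <- function(path, count_names = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- 3L + length(count_names)
  nf <- lengths(fields)
  bad <- which(nf < ncol_min)
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], ": expected >= ", ncol_min,
         " tab-separated fields, got ", nf[bad[1L]])
  }
  n_pos <- min(nf) - length(count_names)   # positional BED fields present
  n_pos <- min(n_pos, 6L)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) stop("malformed BED line ", bad[1L], ": non-numeric coordinates")
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0L) {
    stop("invalid interval at line ", bad[1L], ": end <= start or start < 0")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  df$name <- if (n_pos >= 4L) vapply(fields, `[[`, "", 4L) else
    paste0("site_", seq_along(fields))
  df$score <- if (n_pos >= 5L) suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))) else 0
  df$strand <- if (n_pos >= 6L) vapply(fields, `[[`, "", 6L) else "."
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  if (!is.null(count_names)) {
    for (k in seq_along(count_names)) {
      v <- suppressWarnings(as.numeric(vapply(fields, function(f) f[[n_pos + k]], "")))
      if (anyNA(v)) stop("non-numeric value in count column '", count_names[k], "'")
      df[[count_names[k]]] <- v
    }
  }
  df
}

#' Write a site table as BED(+counts)
#'
#' Inverse of \code{\link{read_bed}}: writes chrom, start, end, name, score,
#' strand and any extra columns named in \code{count_names}, tab-separated,
#' so that canonical files round-trip byte-identically.
#'
#' @param sites Site table as returned by \code{read_bed}.
#' @param path Output path.
#' @param count_names Extra numeric columns to append after strand.
#' @export
write_bed <- function(sites, path, count_names = NULL) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", count_names)
  stopifnot(all(cols %in% names(sites)))
  m <- sites[, cols, drop = FALSE]
  lines <- do.call(paste, c(lapply(m, format_plain), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# plain decimal formatting (no scientific notation) for text output
format_plain <- function(x) {
  if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE) else as.character(x)
}

#' Read a BEDPE loop list
#'
#' Reads paired-anchor records (chrom1, start1, end1, chrom2, start2, end2
#' [, name, score]). Intra-chromosomal loops are canonicalized so that
#' anchor1 starts before anchor2.
#'
#' @param path Path to a BEDPE file (>= 6 tab-separated columns).
#' @return A \code{data.frame} with columns \code{chrom1, start1, end1,
#'   chrom2, start2, end2, name, score}.
#' @export
read_bedpe <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad) > 0L) stop("malformed BEDPE line ", bad[1L], ": fewer than 6 fields")
  num <- function(k) suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
  df <- data.frame(chrom1 = vapply(fields, `[[`, "", 1L),
                   start1 = num(2L), end1 = num(3L),
                   chrom2 = vapply(fields, `[[`, "", 4L),
                   start2 = num(5L), end2 = num(6L),
                   stringsAsFactors = FALSE)
  if (any(df$end1 <= df$start1) || any(df$end2 <= df$start2)) {
    bad <- which(df$end1 <= df$start1 | df$end2 <= df$start2)[1L]
    stop("invalid anchor at BEDPE line ", bad, ": end <= start")
  }
  df$name <- if (min(nf) >= 7L) vapply(fields, `[[`, "", 7L) else
    paste0("loop_", seq_along(fields))
  df$score <- if (min(nf) >= 8L) num(8L) else 0
  canonicalize_loops(df)
}

# order intra-chromosomal anchors so anchor1 is genomically first
canonicalize_loops <- function(df) {
  swap <- df$chrom1 == df$chrom2 & df$start1 > df$start2
  if (any(swap)) {
    tmp <- df[swap, c("start1", "end1")]
    df[swap, c("start1", "end1")] <- df[swap, c("start2", "end2")]
    df[swap, c("start2", "end2")] <- tmp
  }
  df
}

#' Write a loop list as BEDPE
#' @param loops Loop table as returned by \code{\link{read_bedpe}}.
#' @param path Output path.
#' @export
write_bedpe <- function(loops, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name", "score")
  stopifnot(all(cols %in% names(loops)))
  m <- loops[, cols, drop = FALSE]
  writeLines(do.call(paste, c(lapply(m, format_plain), sep = "\t")), path)
  invisible(path)
}

#' Construct a binned contact map
#'
#' A contact map stores symmetric binned contact counts in canonical sparse
#' triple form: each record is (chrom1, bin1, chrom2, bin2, count) with the
#' pair ordered so that chrom1 precedes chrom2 in \code{names(chrom_sizes)}
#' (and bin1 <= bin2 within a chromosome). Bin indices are 0-based and count
#' positions \code{[bin*resolution, (bin+1)*resolution)}.
#'
#' @param records \code{data.frame} with columns \code{chrom1, bin1, chrom2,
#'   bin2, count}.
#' @param resolution Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return An object of class \code{contact_map}.
#' @export
contact_map <- function(records, resolution, chrom_sizes) {
  stopifnot(resolution > 0, length(chrom_sizes) > 0, !is.null(names(chrom_sizes)))
  req <- c("chrom1", "bin1", "chrom2", "bin2", "count")
  stopifnot(all(req %in% names(records)))
  records <- records[, req, drop = FALSE]
  if (any(!is.finite(records$count)) || any(records$count < 0)) {
    stop("contact counts must be finite and >= 0")
  }
  if (!all(records$chrom1 %in% names(chrom_sizes)) ||
      !all(records$chrom2 %in% names(chrom_sizes))) {
    stop("records reference undeclared chromosomes")
  }
  nbins <- ceiling(chrom_sizes / resolution)
  if (any(records$bin1 < 0) || any(records$bin2 < 0) ||
      any(records$bin1 >= nbins[records$chrom1]) ||
      any(records$bin2 >= nbins[records$chrom2])) {
    stop("bin index out of chromosome extent")
  }
  records <- canonicalize_records(records, names(chrom_sizes))
  # merge duplicate pairs
  key <- paste(records$chrom1, records$bin1, records$chrom2, records$bin2)
  if (anyDuplicated(key)) {
    agg <- rowsum(records$count, key, reorder = FALSE)
    keep <- !duplicated(key)
    records <- records[keep, , drop = FALSE]
    records$count <- agg[match(key[keep], rownames(agg)), 1L]
  }
  records <- records[records$count > 0, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(resolution = resolution,
                 chrom_sizes = chrom_sizes,
                 records = records,
                 balanced = FALSE,
                 weights = NULL),
            class = "contact_map")
}

canonicalize_records <- function(records, chrom_order) {
  i1 <- match(records$chrom1, chrom_order)
  i2 <- match(records$chrom2, chrom_order)
  swap <- i1 > i2 | (i1 == i2 & records$bin1 > records$bin2)
  if (any(swap)) {
    tmp_c <- records$chrom1[swap]; tmp_b <- records$bin1[swap]
    records$chrom1[swap] <- records$chrom2[swap]
    records$bin1[swap] <- records$bin2[swap]
    records$chrom2[swap] <- tmp_c
    records$bin2[swap] <- tmp_b
  }
  records
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", length(x$chrom_sizes), "chromosomes, resolution",
      x$resolution, "bp,", nrow(x$records), "nonzero pairs",
      if (isTRUE(x$balanced)) "(balanced)" else "(raw)", "\n")
  invisible(x)
}

#' Read a contact map from sparse triple text
#'
#' Expects a header line \code{chrom1 bin1 chrom2 bin2 count} preceded by
#' comment lines \code{#resolution <bp>} and one \code{#chrom <name> <length>}
#' per chromosome (the format \code{\link{write_contact_map}} emits).
#'
#' @param path Path to the sparse triple TSV.
#' @param resolution Optional resolution override; defaults to the value in
#'   the file header.
#' @return A \code{contact_map}.
#' @export
read_contact_map <- function(path, resolution = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  res_line <- grep("^#resolution\t", hdr, value = TRUE)
  if (is.null(resolution)) {
    if (length(res_line) != 1L) stop("file lacks a #resolution header; pass resolution=")
    resolution <- as.numeric(strsplit(res_line, "\t")[[1L]][2L])
  }
  cs_lines <- grep("^#chrom\t", hdr, value = TRUE)
  if (length(cs_lines) == 0L) stop("file lacks #chrom headers")
  cs_parts <- strsplit(cs_lines, "\t")
  chrom_sizes <- stats::setNames(as.numeric(vapply(cs_parts, `[[`, "", 3L)),
                                 vapply(cs_parts, `[[`, "", 2L))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) < 1L) stop("no records in contact map file")
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  contact_map(tab, resolution = resolution, chrom_sizes = chrom_sizes)
}

#' Write a contact map as sparse triple text
#' @param map A \code{contact_map}.
#' @param path Output path.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#resolution\t", format_plain(map$resolution)), con)
  writeLines(paste0("#chrom\t", names(map$chrom_sizes), "\t",
                    format_plain(unname(map$chrom_sizes))), con)
  writeLines("chrom1\tbin1\tchrom2\tbin2\tcount", con)
  r <- map$records
  writeLines(paste(r$chrom1, format_plain(r$bin1), r$chrom2,
                   format_plain(r$bin2), format_plain(r$count), sep = "\t"), con)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with header columns \code{gene_id, chrom, strand, tss, tes}.
#' TSS/TES are 0-based positions; on the + strand tss < tes, on the - strand
#' tss > tes. Gene length is |tes - tss|.
#'
#' @param path Path to the TSV.
#' @return \code{data.frame} with the five key columns plus \code{length},
#'   \code{start}, \code{end} (BED-style gene body bounds).
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(req %in% names(df))) {
    stop("gene table must have header columns: ", paste(req, collapse = ", "))
  }
  validate_genes(df[, req, drop = FALSE])
}

#' Validate and complete a gene table
#' @param genes \code{data.frame} with gene_id, chrom, strand, tss, tes.
#' @return The table with \code{length}, \code{start}, \code{end} added.
#' @export
validate_genes <- function(genes) {
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  bad <- (genes$strand == "+" & genes$tss >= genes$tes) |
         (genes$strand == "-" & genes$tss <= genes$tes)
  if (any(bad)) {
    stop("gene ", genes$gene_id[which(bad)[1L]],
         ": tss/tes inconsistent with strand")
  }
  genes$length <- abs(genes$tes - genes$tss)
  genes$start <- pmin(genes$tss, genes$tes)
  genes$end <- pmax(genes$tss, genes$tes)
  genes
}

#' Write a gene table
#' @param genes Gene table.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss", "tes")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated with header; requires \code{gene_id} and \code{log2fc}
#' columns, keeps any per-condition mean-expression columns, and an optional
#' \code{significant} flag.
#'
#' @param path Path to the TSV.
#' @return \code{data.frame} keyed by gene_id.
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(df))) {
    stop("expression table must have gene_id and log2fc columns")
  }
  if (any(!is.finite(df$log2fc))) stop("log2fc must be finite")
  expr_cols <- setdiff(names(df), c("gene_id", "log2fc", "significant"))
  for (cc in expr_cols) {
    if (is.numeric(df[[cc]]) && any(df[[cc]] < 0)) {
      stop("expression values must be >= 0 (column ", cc, ")")
    }
  }
  df
}

#' Write an expression table
#' @param expr Expression table.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GRanges view of a site table (internal; 0-based half-open -> 1-based closed)
sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = ifelse(sites$strand %in% c("+", "-"), sites$strand, "*"))
}

# summit of a site: midpoint unless a 'summit' column is present
site_summits <- function(sites) {
  if ("summit" %in% names(sites)) return(sites$summit)
  floor((sites$start + sites$end) / 2)
}
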