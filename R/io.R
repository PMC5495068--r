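#' Read a BED file into an interval data.frame
#'
#' BED3/BED6, tab-separated, 0-based half-open. Columns beyond the sixth are
#' ignored. When a `layout` is supplied, every interval is validated against
#' the chromosome lengths.
#'
#' @param path path to a BED file
#' @param layout optional `genome_layout` for coordinate validation
#' @return data.frame with `chrom`, `start`, `end` and, when present in the
#'   file, `name`, `score`, `strand`
#' @export
read_bed <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("invalid interval at BED line ", bad[1],
         ": need 0 <= start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  ncol_min <- min(nf)
  if (ncol_min >= 4) df$name <- vapply(fields, `[[`, character(1), 4)
  if (ncol_min >= 5)
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5)))
  if (ncol_min >= 6) {
    s <- vapply(fields, `[[`, character(1), 6)
    if (!all(s %in% c("+", "-", ".")))
      stop("invalid strand at BED line ", which(!s %in% c("+", "-", "."))[1])
    df$strand <- s
  }
  if (!is.null(layout)) {
    len <- chrom_lengths(layout)
    unknown <- which(!df$chrom %in% names(len))
    if (length(unknown))
      stop("interval on unknown chromosome at BED line ", unknown[1])
    over <- which(df$end > len[df$chrom])
    if (length(over))
      stop("interval beyond chromosome end at BED line ", over[1])
  }
  df
}

#' Write intervals as BED
#'
#' Writes BED3 when only coordinates are present, BED6 when `name`, `score`
#' and `strand` columns exist (missing ones are filled with `.`/`0` only if a
#' later column is present, so `read_bed(write_bed(x))` round-trips).
#' @param df interval data.frame
#' @param path output path
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE))
  have <- c("name", "score", "strand") %in% names(df)
  upto <- if (any(have)) max(which(have)) else 0
  if (upto >= 1) cols <- c(cols, list(if (have[1]) df$name else "."))
  if (upto >= 2) cols <- c(cols, list(if (have[2])
    format(df$score, scientific = FALSE, trim = TRUE) else "0"))
  if (upto >= 3) cols <- c(cols, list(if (have[3]) df$strand else "."))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Keeps `gene` features (plus `transposable_element_gene` and `pseudogene`
#' typed features), mapping the `biotype` attribute onto the closed set
#' `protein_coding` / `TE_gene` / `pseudogene`. Coordinates are converted from
#' GFF3 1-based closed to 0-based half-open. Unknown biotypes are recorded as
#' `protein_coding` with a warning; a gene without an ID is an error.
#'
#' @param path path to a GFF3 file
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`, in file order
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("gene", "transposable_element_gene", "pseudogene")
  gr <- gr[keep]
  type <- type[keep]
  if (length(gr) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      biotype = character(), stringsAsFactors = FALSE))
  id <- gr$ID
  if (is.null(id) || anyNA(id))
    stop("gene feature without an ID attribute")
  biotype <- if (!is.null(gr$biotype)) as.character(gr$biotype) else rep(NA, length(gr))
  # feature type itself carries the biotype for Ensembl-style TE/pseudogene rows
  biotype[is.na(biotype) & type == "transposable_element_gene"] <- "transposable_element"
  biotype[is.na(biotype) & type == "pseudogene"] <- "pseudogene"
  mapped <- c(protein_coding = "protein_coding",
              transposable_element = "TE_gene",
              transposable_element_gene = "TE_gene",
              TE_gene = "TE_gene",
              pseudogene = "pseudogene")[biotype]
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warning(sum(unknown), " gene(s) with unknown biotype recorded as protein_coding")
    mapped[unknown] <- "protein_coding"
  }
  df <- granges_to_df(gr, strand = TRUE)
  data.frame(gene_id = as.character(id), chrom = df$chrom, start = df$start,
             end = df$end, strand = df$strand, biotype = unname(mapped),
             stringsAsFactors = FALSE)
}

#' Fraction of a query interval covered by a set of target intervals
#'
#' Computes |query intersect union(targets)| / |query| per query, the quantity
#' behind the ">80% of the transcribed region" gene-enrichment rule. Targets
#' are unioned first so overlapping targets are not double counted; strand is
#' ignored.
#'
#' @param query interval data.frame (one or more rows)
#' @param targets interval data.frame
#' @return numeric vector in \[0, 1\], one value per query row
#' @export
overlap_fraction <- function(query, targets) {
  width <- query$end - query$start
  if (any(width <= 0)) stop("zero-length query interval")
  out <- numeric(nrow(query))
  if (nrow(targets) == 0 || nrow(query) == 0) return(out)
  # per chromosome: merge targets, then read coverage off a cumulative map
  # (performance matters: this sits under the permutation-test loop)
  q_idx <- split(seq_len(nrow(query)), query$chrom)
  t_idx <- split(seq_len(nrow(targets)), targets$chrom)
  for (ch in intersect(names(q_idx), names(t_idx))) {
    ti <- t_idx[[ch]]
    o <- ti[order(targets$start[ti])]
    s <- targets$start[o]
    e <- targets$end[o]
    if (length(s) > 1) {
      top <- cummax(c(e[1], e[-length(e)]))
      grp <- cumsum(c(TRUE, s[-1] > top[-1]))
      s <- as.numeric(tapply(s, grp, min))
      e <- as.numeric(tapply(e, grp, max))
    }
    cum <- c(0, cumsum(e - s))
    cov_at <- function(x) {
      i <- findInterval(x, s)
      ifelse(i == 0, 0, cum[pmax(i, 1)] +
               pmin(pmax(x - s[pmax(i, 1)], 0), (e - s)[pmax(i, 1)]))
    }
    qi <- q_idx[[ch]]
    out[qi] <- (cov_at(query$end[qi]) - cov_at(query$start[qi])) / width[qi]
  }
  out
}

#' Read a dense, square Hi-C contact matrix from TSV
#'
#' One header-free whitespace-separated square matrix per chromosome. The
#' matrix is checked for symmetry and symmetrised by averaging with its
#' transpose (with a warning) when the maximum asymmetry exceeds `tol`.
#' `NA`/`NaN` cells are allowed and propagate as masked bins.
#'
#' @param path path to the matrix TSV
#' @param binsize bin size in bp, stored as an attribute (default 20000)
#' @param tol symmetry tolerance (default 1e-9)
#' @return numeric matrix with attribute `binsize`
#' @export
read_dense_matrix <- function(path, binsize = 20000, tol = 1e-9) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stop("matrix is not square: ", nrow(m), " x ", ncol(m))
  d <- abs(m - t(m))
  if (any(d[!is.na(d)] > tol)) {
    warning("asymmetric matrix symmetrized by averaging (max |A - t(A)| = ",
            format(max(d, na.rm = TRUE)), ")")
    m <- (m + t(m)) / 2
  }
  attr(m, "binsize") <- binsize
  m
}

#' Write a dense matrix as TSV
#' @param m numeric matrix
#' @param path output path
#' @export
write_dense_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin loops from BEDPE
#'
#' First six columns are the two anchors (0-based half-open); extra columns
#' are ignored. Anchor order within a row is preserved.
#' @param path path to a BEDPE file
#' @return data.frame with `chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2`
#' @export
read_bedpe <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 6) stop("BEDPE needs at least 6 columns")
  df <- x[, 1:6]
  names(df) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (any(df$start1 >= df$end1) || any(df$start2 >= df$end2))
    stop("invalid anchor interval in BEDPE")
  df
}

#' @rdname read_bedpe
#' @param loops BEDPE data.frame as returned by `read_bedpe`
#' @export
write_bedpe <- function(loops, path) {
  utils::write.table(loops, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write bedGraph (4-column) tracks
#'
#' @param path file path
#' @return data.frame with `chrom`, `start`, `end`, `value`
#' @export
read_bedgraph <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(x) < 4) stop("bedGraph needs 4 columns")
  df <- x[, 1:4]
  names(df) <- c("chrom", "start", "end", "value")
  if (any(df$start >= df$end)) stop("invalid interval in bedGraph")
  df
}

#' @rdname read_bedgraph
#' @param df bedGraph data.frame (`chrom`, `start`, `end`, `value`)
#' @export
write_bedgraph <- function(df, path) {
  out <- data.frame(df$chrom,
                    format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    df$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a two-column gene expression table
#'
#' TSV with a header line; columns `gene_id` and `expression` (nonnegative,
#' arbitrary units).
#' @param path file path
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "expression") %in% names(x)))
    stop("expression table needs columns gene_id and expression")
  if (any(x$expression < 0)) stop("negative expression value")
  x[, c("gene_id", "expression")]
}

#' @rdname read_expression
#' @param df data.frame with `gene_id` and `expression`
#' @export
write_expression <- function(df, path) {
  utils::write.table(df[, c("gene_id", "expression")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene annotations as GFF3
#'
#' Inverse of [read_gff3_genes()]: emits `gene` features with `ID` and
#' `biotype` attributes, converting back to 1-based closed coordinates.
#' @param genes annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`)
#' @param path output path
#' @export
write_gff3_genes <- function(genes, path) {
  rev_bio <- c(protein_coding = "protein_coding",
               TE_gene = "transposable_element",
               pseudogene = "pseudogene")[genes$biotype]
  lines <- sprintf("%s\tplads\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                   genes$chrom, as.integer(genes$start + 1),
                   as.integer(genes$end), genes$strand, genes$gene_id,
                   rev_bio)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
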