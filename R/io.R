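#' Read genotypes from VCF or dosage TSV
#'
#' VCF 4.x reading (GT field only, via the vcfR package) or the package's
#' dosage TSV dialect. Dosage is the count of the ALT allele; missing
#' calls ("./." or ".") become NA. Multi-allelic VCF records are skipped
#' with a warning carrying the skip count. VCF positions (1-based) are
#' converted to the internal 0-based convention on read.
#'
#' @param path input file.
#' @param format "vcf" or "dosage-tsv". The dosage dialect is a pair of
#'   files: `<path>` with samples in rows and SNPs in columns (first
#'   column sample_id) and `<path>.map` with the SNP map.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage-tsv")) {
  format <- match.arg(format)
  if (format == "dosage-tsv") return(read_dosage_tsv(path))
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  dosage <- t(dos)
  map <- data.frame(
    snp_id = fix$ID, chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,  # to 0-based
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  colnames(dosage) <- map$snp_id
  genotype_matrix(dosage, map)
}

gt_to_dosage <- function(g) {
  if (is.na(g)) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

#' Write genotypes to a VCF file
#'
#' Minimal VCF 4.2 with a GT field and one ALT allele per record.
#' Internal 0-based positions are written 1-based.
#'
#' @param geno a [genotype_matrix].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage; map <- geno$map
  gt_strings <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  ), con)
  if (ncol(d) > 0) {
    body <- vapply(seq_len(ncol(d)), function(j) {
      g <- gt_strings[as.character(d[, j])]
      g[is.na(g)] <- "./."
      paste(c(map$chrom[j], map$pos[j] + 1L, map$snp_id[j], map$ref[j],
              map$alt[j], ".", "PASS", ".", "GT", g), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write or read the dosage TSV dialect
#'
#' Samples in rows (first column `sample_id`), SNPs in columns; the SNP
#' map is stored alongside in `<path>.map`.
#'
#' @param geno a [genotype_matrix].
#' @param path TSV path.
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv`
#'   a [genotype_matrix].
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dt <- data.table::data.table(sample_id = rownames(geno$dosage))
  for (j in seq_len(ncol(geno$dosage))) {
    dt[[colnames(geno$dosage)[j]]] <- geno$dosage[, j]
  }
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(geno$map, paste0(path, ".map"), sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  map <- as.data.frame(data.table::fread(paste0(path, ".map"), sep = "\t"))
  dosage <- as.matrix(dt[, -1])
  rownames(dosage) <- dt[[1]]
  genotype_matrix(dosage, map)
}

#' Write or read an expression (or trait) matrix as TSV
#'
#' Samples in rows, first column `sample_id`, one column per probe or
#' trait.
#'
#' @param mat samples x columns numeric matrix with dimnames.
#' @param path TSV path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  dt <- data.table::data.table(sample_id = rownames(mat))
  for (j in seq_len(ncol(mat))) dt[[colnames(mat)[j]]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Read a probe annotation table
#'
#' BED-like TSV with columns chrom, start, end, probe_id, gene, strand
#' (0-based half-open intervals, BED-native). Rows with start >= end are
#' rejected with an error naming the probe; duplicate probe ids are an
#' error; a missing gene field leaves the gene empty but keeps the probe
#' (probes need not map to an annotated gene).
#'
#' @param path TSV path, with or without a header row.
#' @return data.frame with probe_id, gene, chrom, tx_start, tx_end, strand.
#' @export
read_probe_annotation <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = "auto"))
  if (!all(c("chrom", "start", "end", "probe_id") %in% names(dt))) {
    if (ncol(dt) < 4) stop("annotation needs columns chrom, start, end, probe_id")
    names(dt)[1:4] <- c("chrom", "start", "end", "probe_id")
    if (ncol(dt) >= 5) names(dt)[5] <- "gene"
    if (ncol(dt) >= 6) names(dt)[6] <- "strand"
  }
  if (!"gene" %in% names(dt)) dt$gene <- ""
  if (!"strand" %in% names(dt)) dt$strand <- "*"
  dt$gene[is.na(dt$gene)] <- ""
  bad <- dt$start >= dt$end
  if (any(bad)) {
    stop("invalid interval (start >= end) for probe(s): ",
         paste(dt$probe_id[bad], collapse = ", "))
  }
  if (anyDuplicated(dt$probe_id)) {
    stop("duplicate probe_id: ",
         paste(unique(dt$probe_id[duplicated(dt$probe_id)]), collapse = ", "))
  }
  data.frame(probe_id = as.character(dt$probe_id), gene = as.character(dt$gene),
             chrom = as.character(dt$chrom), tx_start = as.integer(dt$start),
             tx_end = as.integer(dt$end), strand = as.character(dt$strand),
             stringsAsFactors = FALSE)
}

#' Write a probe annotation table
#'
#' @param annotation data.frame as returned by [read_probe_annotation].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  out <- data.frame(chrom = annotation$chrom, start = annotation$tx_start,
                    end = annotation$tx_end, probe_id = annotation$probe_id,
                    gene = annotation$gene, strand = annotation$strand)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

RESULT_COLUMNS <- c("snp_id", "snp_chrom", "probe_id", "gene", "probe_chrom",
                    "class", "n", "beta", "se", "p", "locus_id")

#' Write association/call records to TSV
#'
#' Normalizes records to the standard result column set (snp_id,
#' snp_chrom, probe_id, gene, probe_chrom, class, n, beta, se, p,
#' locus_id; absent fields become NA) and writes them ordered by p
#' ascending with snp_id as the tie-break, so output is deterministic.
#'
#' @param records data.frame of association results or calls.
#' @param path output TSV path.
#' @param snp_map,annotation optional tables used to fill in chromosome
#'   columns when absent from `records`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, snp_map = NULL, annotation = NULL) {
  r <- as.data.frame(records)
  if (!"snp_chrom" %in% names(r)) {
    r$snp_chrom <- if (is.null(snp_map)) rep(NA_character_, nrow(r)) else
      snp_map$chrom[match(r$snp_id, snp_map$snp_id)]
  }
  if (!"probe_chrom" %in% names(r)) {
    r$probe_chrom <- if (is.null(annotation)) rep(NA_character_, nrow(r)) else
      annotation$chrom[match(r$probe_id, annotation$probe_id)]
  }
  if (!"gene" %in% names(r) && !is.null(annotation)) {
    r$gene <- annotation$gene[match(r$probe_id, annotation$probe_id)]
  }
  for (col in RESULT_COLUMNS) if (!col %in% names(r)) r[[col]] <- rep(NA, nrow(r))
  r <- r[order(r$p, r$snp_id), RESULT_COLUMNS, drop = FALSE]
  data.table::fwrite(r, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}
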