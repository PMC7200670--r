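# Numbers are serialized with %.17g so every write/read cycle restores the
# exact double; all writers here are paired with readers that round-trip.
.fmt_num <- function(x) sprintf("%.17g", x)

.read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' Plain TSV with a `gene_id` first column and one column per sample.
#'
#' @param x Genes x samples numeric matrix.
#' @param path File path.
#' @return The path (writer) or the matrix (reader).
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene_id") stop("malformed expression header in ", path)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id: ", df$gene_id[duplicated(df$gene_id)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))[1]
    stop("non-numeric expression value near data line ",
         (bad - 1) %% nrow(m) + 2)
  }
  rownames(m) <- df$gene_id
  m
}

#' Write / read an expression matrix in GCT format
#'
#' The two-line-header GCT dialect: a `#1.2` version line, a dimensions
#' line, then `Name`/`Description` columns ahead of the samples.
#'
#' @param x Genes x samples numeric matrix.
#' @param path File path.
#' @return The path (writer) or the matrix (reader).
#' @export
write_gct <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(x)), collapse = "\t"), con)
  body <- cbind(rownames(x), "na", matrix(.fmt_num(x), nrow(x)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_gct
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "#1.2") stop("malformed GCT header (line 1) in ", path)
  dims <- as.integer(strsplit(lines[2], "\t")[[1]])
  header <- strsplit(lines[3], "\t")[[1]]
  if (!identical(header[1:2], c("Name", "Description")))
    stop("malformed GCT column header (line 3) in ", path)
  df <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) != dims[1] || ncol(df) - 2 != dims[2])
    stop("GCT dimension line disagrees with the body in ", path)
  if (anyDuplicated(df$Name))
    stop("duplicate gene id: ", df$Name[duplicated(df$Name)][1])
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$Name
  m
}

#' Write / read genotype dosages as TSV
#'
#' Variants in rows (`variant_id`, `chrom`, `pos`, then one column per
#' donor); missing genotypes as NA. Reading recomputes the per-variant
#' metadata from the dosages.
#'
#' @param genotypes An `iqtl_genotypes` object.
#' @param path File path.
#' @return The path (writer) or an `iqtl_genotypes` (reader).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  dos <- t(genotypes$dosage)
  df <- data.frame(variant_id = genotypes$variants$variant_id,
                   chrom = genotypes$variants$chrom,
                   pos = genotypes$variants$pos,
                   dos, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- .read_tsv(path)
  need <- c("variant_id", "chrom", "pos")
  if (!identical(names(df)[1:3], need))
    stop("malformed dosage header in ", path)
  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup)) stop("duplicated variant id: ", dup[1])
  dos <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  if (!all(dos %in% c(0L, 1L, 2L) | is.na(dos)))
    stop("dosage values outside {0, 1, 2, NA} in ", path)
  storage.mode(dos) <- "integer"
  colnames(dos) <- df$variant_id
  meta <- variant_metadata(dos)
  meta$chrom <- as.character(df$chrom)
  meta$pos <- df$pos
  meta <- meta[, c("variant_id", "chrom", "pos", "maf", "missing_rate",
                   "hwe_p", "ld_partner_count")]
  structure(list(dosage = dos, variants = meta), class = "iqtl_genotypes")
}

#' Write / read genotypes as minimal VCFv4.2
#'
#' GT-only records (`0/0`, `0/1`, `1/1`, `./.`) with placeholder alleles.
#' Reading goes through vcfR and accepts both `/` and `|` separators;
#' dosage is the ALT allele count.
#'
#' @param genotypes An `iqtl_genotypes` object.
#' @param path File path.
#' @return The path (writer) or an `iqtl_genotypes` (reader).
#' @export
write_vcf <- function(genotypes, path) {
  dos <- genotypes$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos), ncol(dos))
  gt[is.na(dos)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t")),
             con)
  body <- cbind(genotypes$variants$chrom, genotypes$variants$pos,
                genotypes$variants$variant_id, "A", "G", ".", "PASS", ".",
                "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  known <- !is.na(alleles) & alleles != "./."
  dos[known] <- vapply(strsplit(alleles[known], "/"),
                       function(a) sum(a == "1"), integer(1))
  dos <- t(dos)
  meta <- variant_metadata(dos)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  meta$chrom <- unname(fix[, "CHROM"])
  meta$pos <- as.integer(fix[, "POS"])
  meta <- meta[, c("variant_id", "chrom", "pos", "maf", "missing_rate",
                   "hwe_p", "ld_partner_count")]
  structure(list(dosage = dos, variants = meta), class = "iqtl_genotypes")
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param gene_sets Named list of character vectors.
#' @param path File path.
#' @return The path (writer) or a named list (reader).
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed GMT record at line ", bad[1])
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' Write / read a score set as TSV
#'
#' Columns: `sample_id`, `tissue`, one per cell type, then
#' `scaling_factor` and `presence_p` where the method defines them.
#'
#' @param scores An `iqtl_scores` object.
#' @param path File path.
#' @return The path (writer) or an `iqtl_scores` (reader).
#' @export
write_scores_tsv <- function(scores, path) {
  df <- data.frame(sample_id = rownames(scores$scores),
                   method = scores$method,
                   tissue = unname(scores$tissue[rownames(scores$scores)]),
                   scores$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(scores$scaling_factor))
    df$scaling_factor <- unname(scores$scaling_factor)
  if (!is.null(scores$presence_p))
    df$presence_p <- unname(scores$presence_p)
  .write_tsv(df, path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  df <- .read_tsv(path)
  fixed <- c("sample_id", "method", "tissue", "scaling_factor", "presence_p")
  ct <- setdiff(names(df), fixed)
  sc <- as.matrix(df[, ct, drop = FALSE])
  rownames(sc) <- df$sample_id
  structure(list(
    method = df$method[1], scores = sc,
    tissue = stats::setNames(df$tissue, df$sample_id),
    scaling_factor = if ("scaling_factor" %in% names(df))
      stats::setNames(df$scaling_factor, df$sample_id) else NULL,
    presence_p = if ("presence_p" %in% names(df))
      stats::setNames(df$presence_p, df$sample_id) else NULL
  ), class = "iqtl_scores")
}

#' Write / read a donor covariate table as TSV
#' @param donors Donor data.frame.
#' @param path File path.
#' @return The path (writer) or the data.frame (reader).
#' @export
write_covariates_tsv <- function(donors, path) .write_tsv(donors, path)

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) .read_tsv(path)

#' Write / read a variant annotation table as TSV
#' @param annotation Annotation data.frame (`eqtl_*` and `catalog_flag`
#'   columns are restored as logicals).
#' @param path File path.
#' @return The path (writer) or the data.frame (reader).
#' @export
write_annotation_tsv <- function(annotation, path) .write_tsv(annotation, path)

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  df <- .read_tsv(path)
  flag_cols <- grep("^eqtl_|^catalog_flag$", names(df))
  df[flag_cols] <- lapply(df[flag_cols], as.logical)
  df
}

#' Read a supported artifact by kind
#'
#' Dispatches to the matching reader; expression files are sniffed for
#' the GCT header and otherwise read as plain TSV.
#'
#' @param path File path.
#' @param kind One of `"expression"`, `"genotypes"`, `"vcf"`, `"scores"`,
#'   `"gene_sets"`, `"covariates"`, `"annotation"`, `"results"`.
#' @return The parsed object.
#' @export
io_read <- function(path, kind = c("expression", "genotypes", "vcf",
                                   "scores", "gene_sets", "covariates",
                                   "annotation", "results")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(kind,
         expression = if (identical(readLines(path, n = 1), "#1.2"))
           read_gct(path) else read_expression_tsv(path),
         genotypes = read_dosage_tsv(path),
         vcf = read_vcf(path),
         scores = read_scores_tsv(path),
         gene_sets = read_gmt(path),
         covariates = read_covariates_tsv(path),
         annotation = read_annotation_tsv(path),
         results = .read_tsv(path))
}
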