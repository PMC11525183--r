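# Readers and writers for the package's tabular interchange formats.
# TSV dialect: tab-separated, mandatory header, UTF-8, '.' for missing.

tsv_write <- function(df, path) {
  df[] <- lapply(df, function(col) {
    col[is.na(col)] <- NA
    col
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

tsv_read <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

# Map caller/VEP consequence vocabulary onto the internal enum.
map_consequence <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[grepl("stop_gained|nonsense", x)] <- "stop_gained"
  out[grepl("missense", x)] <- "missense"
  out[grepl("synonymous", x)] <- "synonymous"
  out[grepl("frameshift|inframe|insertion|deletion|indel", x)] <- "indel"
  out[grepl("splice", x)] <- "splice"
  out
}

#' Read a variant table (TSV dialect)
#'
#' Mandatory columns: `sample_id`, `gene`, `codon`, `consequence`, `depth`,
#' `alt_reads`, `n_amplicons`; optional `vaf` (recomputed as
#' `alt_reads/depth` when absent or missing) and `aa_change`. Consequence
#' terms are normalised to the internal vocabulary (`stop_gained`,
#' `missense`, `synonymous`, `indel`, `splice`, `other`). Records violating
#' the invariants are reported with their line number.
#'
#' @param path file path.
#' @return data.frame of normalised variant calls.
#' @export
read_variant_table <- function(path) {
  df <- tsv_read(path)
  need_cols(df, c("sample_id", "gene", "codon", "consequence", "depth",
                  "alt_reads", "n_amplicons"), paste("variant table", path))
  if (!"vaf" %in% names(df)) df$vaf <- NA_real_
  if (!"aa_change" %in% names(df)) df$aa_change <- NA_character_
  df$consequence <- map_consequence(df$consequence)
  miss <- is.na(df$vaf)
  df$vaf[miss] <- df$alt_reads[miss] / df$depth[miss]
  bad <- which(df$alt_reads > df$depth | df$vaf < 0 | df$vaf > 1 |
                 df$n_amplicons < 1 | df$depth < 1)
  abort_if(length(bad) > 0,
           sprintf("malformed variant record at line %d of %s",
                   bad[1] + 1L, path))
  df[c("sample_id", "gene", "codon", "aa_change", "consequence", "vaf",
       "depth", "alt_reads", "n_amplicons")]
}

#' Write a variant table (TSV dialect)
#'
#' @param calls variant call data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  validate_variant_calls(calls)
  tsv_write(calls, path)
}

#' Write variant calls as a minimal VCF
#'
#' One record per call, protein-space coordinates: the contig is the gene
#' symbol and POS the codon. INFO carries `SAMPLE`, `VAF`, `DP`, `ALTREADS`,
#' `NAMP`, `CSQ` and optionally `AACHANGE`.
#'
#' @param calls variant call data.frame.
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  validate_variant_calls(calls)
  header <- c(
    "##fileformat=VCFv4.3",
    "##source=polyclone",
    paste0("##contig=<ID=", unique(calls$gene), ">"),
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=ALTREADS,Number=1,Type=Integer,Description=\"Mutant read count\">",
    "##INFO=<ID=NAMP,Number=1,Type=Integer,Description=\"Supporting amplicon count\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=AACHANGE,Number=1,Type=String,Description=\"Amino acid change\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  aach <- if ("aa_change" %in% names(calls)) calls$aa_change else NA
  info <- sprintf("SAMPLE=%s;VAF=%.6g;DP=%d;ALTREADS=%d;NAMP=%d;CSQ=%s",
                  calls$sample_id, calls$vaf, as.integer(calls$depth),
                  as.integer(calls$alt_reads), as.integer(calls$n_amplicons),
                  calls$consequence)
  has_aa <- !is.na(aach)
  info[has_aa] <- paste0(info[has_aa], ";AACHANGE=", aach[has_aa])
  body <- sprintf("%s\t%d\t.\tN\tA\t.\tPASS\t%s",
                  calls$gene, as.integer(calls$codon), info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variant calls from a VCF
#'
#' Reads either the minimal protein-space VCF written by
#' [write_variant_vcf()] or any VCF carrying the same INFO keys. `VAF` is
#' recomputed from `ALTREADS/DP` when absent.
#'
#' @param path VCF path.
#' @param amplicon_key INFO key holding the supporting-amplicon count.
#' @return data.frame of normalised variant calls.
#' @export
read_variant_vcf <- function(path, amplicon_key = "NAMP") {
  abort_if(!file.exists(path), "file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  info_chr <- function(key) vcfR::extract.info(v, element = key)
  depth <- info_num("DP")
  alt <- info_num("ALTREADS")
  vaf <- info_num("VAF")
  vaf[is.na(vaf)] <- (alt / depth)[is.na(vaf)]
  df <- data.frame(
    sample_id = info_chr("SAMPLE"),
    gene = fix$CHROM,
    codon = as.integer(fix$POS),
    aa_change = info_chr("AACHANGE"),
    consequence = map_consequence(info_chr("CSQ")),
    vaf = vaf,
    depth = as.integer(depth),
    alt_reads = as.integer(alt),
    n_amplicons = as.integer(info_num(amplicon_key)),
    stringsAsFactors = FALSE)
  validate_variant_calls(df)
  df
}

#' Read a variant file of either dialect
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @param ... passed to the dialect reader.
#' @return data.frame of normalised variant calls.
#' @export
read_variant_file <- function(path, dialect = NULL, ...) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  switch(match.arg(dialect, c("tsv", "vcf")),
         tsv = read_variant_table(path),
         vcf = read_variant_vcf(path, ...))
}

#' Write / read a tumour table
#'
#' Columns: `tumour_id`, `mouse_id`, `segment_id`, `x_mm`, `y_mm`,
#' `diameter_mm`, `confetti_status`, `day`.
#'
#' @param tumours tumour data.frame.
#' @param path file path.
#' @return The path (writer, invisibly) or the tumour data.frame (reader).
#' @export
write_tumour_table <- function(tumours, path) {
  need_cols(tumours, c("tumour_id", "mouse_id", "segment_id", "x_mm", "y_mm",
                       "diameter_mm", "confetti_status", "day"),
            "tumour table")
  tsv_write(tumours, path)
}

#' @rdname write_tumour_table
#' @export
read_tumour_table <- function(path) {
  df <- tsv_read(path)
  need_cols(df, c("tumour_id", "mouse_id", "segment_id", "x_mm", "y_mm",
                  "diameter_mm", "confetti_status", "day"),
            paste("tumour table", path))
  df
}

#' Write / read a growth series table
#'
#' @param series growth series data.frame (`tumour_id`, `group`, `mouse_id`,
#'   `day`, `size`).
#' @param path file path.
#' @return The path (writer, invisibly) or the series data.frame (reader).
#' @export
write_growth_series <- function(series, path) {
  need_cols(series, c("tumour_id", "group", "mouse_id", "day", "size"),
            "growth series")
  tsv_write(series, path)
}

#' @rdname write_growth_series
#' @export
read_growth_series <- function(path) {
  df <- tsv_read(path)
  need_cols(df, c("tumour_id", "group", "mouse_id", "day", "size"),
            paste("growth series", path))
  df
}

#' Write / read a count matrix as MatrixMarket triplets
#'
#' Writes `<prefix>.mtx` (MatrixMarket), `<prefix>.genes.tsv` and
#' `<prefix>.samples.tsv`.
#'
#' @param mat gene-by-sample count matrix.
#' @param prefix path prefix.
#' @return The prefix (writer, invisibly) or the matrix (reader).
#' @export
write_count_matrix <- function(mat, prefix) {
  abort_if(!is.matrix(mat) || is.null(dimnames(mat)),
           "mat must be a matrix with dimnames")
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(mat), paste0(prefix, ".genes.tsv"))
  writeLines(colnames(mat), paste0(prefix, ".samples.tsv"))
  invisible(prefix)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  dimnames(m) <- list(readLines(paste0(prefix, ".genes.tsv")),
                      readLines(paste0(prefix, ".samples.tsv")))
  storage.mode(m) <- "integer"
  m
}

#' Write cohort ground truth as a JSON sidecar
#'
#' @param truth ground truth from [gen_tumour_field()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(tumours = truth$tumours,
                            founders = truth$founders,
                            apc_bin_probs = as.list(truth$apc_bin_probs)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a crypt grid / read it back
#'
#' @param grid character label matrix from [simulate_labelling()].
#' @param path file path (TSV of labels, no header).
#' @return The path (writer, invisibly) or the grid matrix (reader).
#' @export
write_crypt_grid <- function(grid, path) {
  abort_if(!is.matrix(grid), "grid must be a matrix")
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_crypt_grid
#' @export
read_crypt_grid <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                                   colClasses = "character"))
  dimnames(m) <- NULL
  m
}
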