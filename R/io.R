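#' Write a cohort table to TSV
#'
#' One row per individual, header row, `NA` for missing cells, and the
#' `"PNS"` sentinel for prefer-not-to-say item responses (stored
#' in-memory as -1).
#'
#' @param data Cohort data frame.
#' @param path Output file.
#' @export
write_cohort_tsv <- function(data, path) {
  out <- data
  for (v in grep("^item_", names(out), value = TRUE)) {
    x <- as.character(out[[v]])
    x[!is.na(out[[v]]) & out[[v]] == -1L] <- "PNS"
    out[[v]] <- x
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Read a cohort table from TSV
#'
#' Inverse of [write_cohort_tsv()]: `"PNS"` item responses come back as
#' the -1 sentinel; character covariates are left as read.
#'
#' @param path Input file.
#' @return Data frame.
#' @export
read_cohort_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "NA")
  for (v in grep("^item_", names(d), value = TRUE)) {
    x <- d[[v]]
    x[!is.na(x) & x == "PNS"] <- "-1"
    d[[v]] <- as.integer(x)
  }
  d
}

#' Write GWAS summary statistics to TSV
#'
#' Columns `SNP, CHR, POS, A1, A2, BETA, SE, P, MAF, INFO, HWE_P`.
#'
#' @param summary Summary-statistics data frame (internal column names).
#' @param path Output file.
#' @export
write_sumstats_tsv <- function(summary, path) {
  out <- data.frame(SNP = summary$snp, CHR = summary$chr, POS = summary$pos,
                    A1 = summary$a1, A2 = summary$a2, BETA = summary$beta,
                    SE = summary$se, P = summary$p, MAF = summary$maf,
                    INFO = summary$info, HWE_P = summary$hwe_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read GWAS summary statistics from TSV
#' @param path Input file.
#' @return `summary_stats` data frame with internal column names.
#' @export
read_sumstats_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(snp = d$SNP, chr = d$CHR, pos = d$POS, a1 = d$A1,
                    a2 = d$A2, beta = d$BETA, se = d$SE, p = d$P,
                    maf = d$MAF, info = d$INFO, hwe_p = d$HWE_P,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write a dosage matrix to TSV
#'
#' First column `id`, then one column per variant.
#'
#' @param dosages Matrix with variant ids as column names.
#' @param ids Individual identifiers.
#' @param path Output file.
#' @export
write_dosages_tsv <- function(dosages, ids, path) {
  out <- data.frame(id = ids, dosages, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a dosage matrix from TSV
#' @param path Input file.
#' @return List with `dosages` (matrix) and `ids`.
#' @export
read_dosages_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  list(dosages = as.matrix(d[, -1, drop = FALSE]), ids = d$id)
}

#' Write genotypes as a minimal VCF with DS and GT fields
#'
#' 1-based positions; the panel's counted allele is written as ALT so
#' that the DS field equals the stored dosage. Integer dosages map to
#' unphased GT calls.
#'
#' @param panel A `genotype_panel`.
#' @param ids Individual identifiers.
#' @param path Output file (plain text .vcf).
#' @export
write_vcf <- function(panel, ids, path) {
  v <- panel$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    d <- panel$dosages[, j]
    cells <- paste0(gt_of[d + 1L], ":", d)
    writeLines(paste(c(v$chr[j], v$pos[j], v$snp[j], v$a2[j], v$a1[j], ".",
                       "PASS", ".", "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Uses the DS field when present, otherwise counts ALT alleles in GT.
#'
#' @param path VCF file (plain text).
#' @return List with `dosages` (individuals x variants), `ids`, and
#'   `variants` (snp, chr, pos, a1 = ALT/counted, a2 = REF).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(lines[1], "\t")[[1]]
  ids <- header[-(1:9)]
  body <- lines[-1]
  fields <- strsplit(body, "\t")
  m <- length(fields)
  dos <- matrix(NA_real_, length(ids), m)
  variants <- data.frame(snp = character(m), chr = integer(m),
                         pos = integer(m), a1 = character(m),
                         a2 = character(m), stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- fields[[j]]
    variants$snp[j] <- f[3]
    variants$chr[j] <- as.integer(f[1])
    variants$pos[j] <- as.integer(f[2])
    variants$a2[j] <- f[4]  # REF
    variants$a1[j] <- f[5]  # ALT = counted allele
    fmt <- strsplit(f[9], ":")[[1]]
    cells <- strsplit(f[-(1:9)], ":")
    ds_i <- match("DS", fmt)
    gt_i <- match("GT", fmt)
    if (!is.na(ds_i)) {
      dos[, j] <- as.numeric(vapply(cells, `[[`, character(1), ds_i))
    } else if (!is.na(gt_i)) {
      gt <- vapply(cells, `[[`, character(1), gt_i)
      dos[, j] <- vapply(strsplit(gt, "[/|]"), function(a) {
        sum(a == "1")
      }, numeric(1))
    } else {
      stop("VCF has neither DS nor GT fields", call. = FALSE)
    }
  }
  colnames(dos) <- variants$snp
  list(dosages = dos, ids = ids, variants = variants)
}

#' Write an analysis results table to TSV
#' @param results Fit-record data frame.
#' @param path Output file.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}
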