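#' Export one sample's genotype calls as VCF 4.2
#'
#' Writes a single-sample VCF with GT:DP:AD format fields (AD holds
#' reference- and alt-supporting read counts). A sample with no records
#' yields a header-only file.
#'
#' @param fact Fact data.frame.
#' @param samples Sample registry (used to validate `sample_id`).
#' @param sample_id Sample to export.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_vcf <- function(fact, samples, sample_id, path) {
  if (!sample_id %in% samples$sample_id) {
    stop("unknown sample: ", sample_id)
  }
  rec <- fact[fact$sample_id == sample_id, , drop = FALSE]
  rec <- rec[order(chrom_rank(rec$chrom), rec$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varwarehouse",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS",
           sample_id)
  )
  body <- character(0)
  if (nrow(rec) > 0L) {
    gt <- ifelse(rec$genotype == "HET", "0/1", "1/1")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:DP:AD\t%s:%d:%d,%d",
                    rec$chrom, rec$pos, rec$ref, rec$alt, gt, rec$dp,
                    rec$dp - rec$ad_alt, rec$ad_alt)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Import a single-sample VCF written by [export_vcf()]
#'
#' Parses the file with `vcfR` and maps GT/DP/AD back to the fact-record
#' representation, so that `import_vcf(export_vcf(x))` equals `x` on
#' (chrom, pos, ref, alt, genotype, dp, ad_alt).
#'
#' @param path VCF file path.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, `dp`, `ad_alt`.
#' @export
import_vcf <- function(path) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), dp = integer(0),
                      ad_alt = integer(0), stringsAsFactors = FALSE)
  n_data <- sum(!startsWith(readLines(path), "#"))
  if (n_data == 0L) return(empty)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  dp <- as.integer(vcfR::extract.gt(v, element = "DP")[, 1])
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  ad_alt <- as.integer(vapply(strsplit(ad, ","), `[`, character(1), 2))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    genotype = ifelse(gt == "0/1", "HET", "HOM_ALT"),
    dp = dp, ad_alt = ad_alt,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
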