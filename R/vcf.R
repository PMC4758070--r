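#' Extract allele counts from the AD field of a VCF
#'
#' Convenience helper turning the per-sample allelic depths (FORMAT/AD,
#' "ref,alt") of a VCF 4.x file into rows of the static count schema.
#' Multi-allelic records keep only the first alternative allele. Gene
#' assignment is annotation-dependent and out of scope here, so the
#' `gene_id` column is left `NA` for the caller to fill. Requires the
#' \pkg{vcfR} package.
#'
#' @param path Path to a VCF (plain or bgzipped) with an AD FORMAT
#'   field.
#' @return A `data.frame` with columns `sample_id`, `variant_id`
#'   (ID or chrom:pos), `gene_id` (`NA`), `ref_count`, `alt_count`.
#' @export
vcfAlleleCounts <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcfAlleleCounts() requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  out <- do.call(rbind, lapply(colnames(ad), function(s) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    data.frame(sample_id = s, variant_id = ids, gene_id = NA_character_,
               ref_count = as.integer(vapply(parts, `[`, "", 1L)),
               alt_count = as.integer(vapply(parts, function(x)
                 if (length(x) >= 2L) x[2L] else NA_character_, "")),
               stringsAsFactors = FALSE)
  }))
  out[!is.na(out$ref_count) & !is.na(out$alt_count), , drop = FALSE]
}
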