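#' Read an allele-count table
#'
#' Reads a tab-separated allele-count table with a header row. The
#' static schema requires columns `sample_id`, `variant_id`, `gene_id`,
#' `ref_count`, `alt_count`; the icd schema requires `sample_id`,
#' `variant_id`, `gene_id`, `ref_count_U`, `alt_count_U`, `ref_count_T`,
#' `alt_count_T`. Optional columns `in_dbsnp` (logical) and, for static
#' data, `null_ratio` are honoured; missing ones default to `TRUE` and
#' 0.5. Counts must parse as non-negative integers and a variant may
#' appear at most once per sample.
#'
#' @param path Path to a TSV file.
#' @param mode `"static"` or `"icd"`.
#' @return An [AseCountTable-class].
#' @seealso [writeAseResults()], [vcfAlleleCounts()]
#' @export
readAseCounts <- function(path, mode = c("static", "icd")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- if (mode == "static") .STATIC_COLS else .ICD_COLS
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("input lacks required ", mode, " column(s): ",
         paste(missing, collapse = ", "))
  for (cc in .countCols(mode)) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("column '", cc, "': invalid count at data row ", bad[1L],
           " (value '", df[[cc]][bad[1L]], "')")
    df[[cc]] <- as.integer(v)
  }
  if (!is.null(df$in_dbsnp)) df$in_dbsnp <- as.logical(df$in_dbsnp)
  AseCountTable(df, mode)
}

#' Read DNA allele counts for null-model fitting
#'
#' Reads a two-or-more-column TSV of reference/alternative allele counts
#' at heterozygous DNA sites (columns `ref_count` and `alt_count`, or the
#' first two columns if unnamed). Sites with total depth below
#' `minDepth` are retained but flagged, so the caller can see what the
#' fit will exclude.
#'
#' @param path Path to a TSV file with a header row.
#' @param minDepth Depth floor used to flag sites (default 10).
#' @return A `data.frame` with columns `ref_count`, `alt_count`, `depth`
#'   and logical `excluded` (depth < `minDepth`).
#' @export
readDnaCounts <- function(path, minDepth = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("no DNA sites in ", path, ": the null model cannot be fit")
  if (is.null(df$ref_count) || is.null(df$alt_count)) {
    if (ncol(df) < 2L) stop("expected two count columns in ", path)
    names(df)[1:2] <- c("ref_count", "alt_count")
  }
  for (cc in c("ref_count", "alt_count")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("column '", cc, "': invalid count at data row ", bad[1L])
    df[[cc]] <- as.integer(v)
  }
  out <- df[, c("ref_count", "alt_count")]
  out$depth <- out$ref_count + out$alt_count
  out$excluded <- out$depth < minDepth
  out
}

#' Filter variants by read depth
#'
#' `scope = "per_sample"` keeps variants whose depth in the sample meets
#' `minDepth` (for icd data, each condition's depth must meet it);
#' `scope = "summed_conditions"` (icd only) keeps variants whose total
#' depth summed over both conditions and both alleles meets `minDepth`.
#' Both filters are idempotent and commute with each other.
#'
#' @param x An [AseCountTable-class].
#' @param minDepth Non-negative depth threshold.
#' @param scope `"per_sample"` or `"summed_conditions"`.
#' @return A filtered [AseCountTable-class].
#' @examples
#' df <- data.frame(sample_id = "s", variant_id = c("v1", "v2"),
#'                  gene_id = "g", ref_count = c(6L, 30L),
#'                  alt_count = c(3L, 20L))
#' x <- AseCountTable(df, "static")
#' length(filterByDepth(x, 10))  # v1 (depth 9) removed
#' @export
filterByDepth <- function(x, minDepth,
                          scope = c("per_sample", "summed_conditions")) {
  stopifnot(is(x, "AseCountTable"))
  scope <- match.arg(scope)
  if (minDepth < 0) stop("minDepth must be >= 0")
  df <- aseCounts(x)
  if (aseMode(x) == "static") {
    if (scope == "summed_conditions")
      stop("summed_conditions scope requires icd data")
    keep <- df$ref_count + df$alt_count >= minDepth
  } else {
    dU <- df$ref_count_U + df$alt_count_U
    dT <- df$ref_count_T + df$alt_count_T
    keep <- if (scope == "per_sample") dU >= minDepth & dT >= minDepth
            else dU + dT >= minDepth
  }
  AseCountTable(df[keep, , drop = FALSE], aseMode(x))
}

.resultColumns <- list(
  snv  = c("sample_id", "variant_id", "gene_id", "effect_size", "p_value",
           "p_adjusted"),
  gene = c("sample_id", "gene_id", "k", "statistic", "p_value", "p_adjusted"),
  meta = c("gene_id", "m", "chi2", "p_meta", "p_meta_adjusted", "evidence",
           "sample_ids")
)

#' Write ASE results as a TSV
#'
#' Writes a deterministic tab-separated table: a fixed column order per
#' result level, floats at 6 significant digits, rows sorted by adjusted
#' p-value then by gene id (ties broken on `gene_id`, then `variant_id`
#' where present). An empty result writes the header line only.
#'
#' @param results A [GeneAseResult-class], a `data.frame`, or the output
#'   of [metaAnalysis()].
#' @param path Output file path.
#' @param level `"snv"`, `"gene"` or `"meta"`; defaults to `"gene"` for
#'   `GeneAseResult` input.
#' @return Invisibly, the written `data.frame`.
#' @export
writeAseResults <- function(results, path, level = c("gene", "snv", "meta")) {
  level <- match.arg(level)
  df <- if (is(results, "GeneAseResult")) geneResults(results)
        else as.data.frame(results)
  cols <- .resultColumns[[level]]
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("results lack column(s) for level '", level, "': ",
         paste(missing, collapse = ", "))
  df <- df[, cols, drop = FALSE]
  if (nrow(df)) {
    adjCol <- intersect(c("p_adjusted", "p_meta_adjusted"), cols)[1L]
    ord <- do.call(order, c(list(df[[adjCol]], df$gene_id),
                            if (!is.null(df$variant_id)) list(df$variant_id)))
    df <- df[ord, , drop = FALSE]
  }
  fmt <- df
  for (cc in names(fmt))
    if (is.double(fmt[[cc]])) fmt[[cc]] <- formatC(fmt[[cc]], digits = 6,
                                                   format = "g")
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e)))
  invisible(df)
}
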