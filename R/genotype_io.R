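#' Read a VCF into a genotype matrix
#'
#' Keeps bi-allelic SNP records only (multi-allelic records are skipped with
#' a message and counted). GT fields are mapped `0/0 -> 0`, `0/1`/`1/0` ->
#' 1, `1/1 -> 2`, missing (`./.` or `.`) -> `NA`; phased separators are
#' accepted. MAF (folded) and missingness are computed per marker over the
#' non-missing calls.
#'
#' @param path Path to a VCF (v4.x) file with GT genotypes.
#' @return A [genotype_matrix()] (trees = samples). The number of skipped
#'   multi-allelic/non-SNP records is attached as attribute
#'   `"n_skipped_multiallelic"`.
#' @export
read_vcf <- function(path) {
  # validate the column header up front (malformed files otherwise crash
  # deep inside the parser with no usable message)
  head_lines <- readLines(path, n = 1000L, warn = FALSE)
  chrom_at <- grep("^#CHROM\t", head_lines)
  if (!length(chrom_at))
    stop("failed to parse VCF '", path, "': no #CHROM header line",
         call. = FALSE)
  hdr <- strsplit(head_lines[chrom_at[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10)
    stop("VCF has no sample genotype columns")
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse VCF '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2)
    stop("VCF has no sample genotype columns")
  snp <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "ALT"] != "."
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " multi-allelic/non-SNP record(s) skipped")
  if (!any(snp)) stop("no bi-allelic SNP records in VCF")
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, -1, drop = FALSE]   # drop FORMAT column
  # GT is the first colon-separated field
  gtf <- sub(":.*", "", gt)
  gtf <- gsub("\\|", "/", gtf)
  code <- matrix(NA_integer_, nrow(gtf), ncol(gtf))
  code[gtf == "0/0"] <- 0L
  code[gtf %in% c("0/1", "1/0")] <- 1L
  code[gtf == "1/1"] <- 2L
  unknown <- !is.na(gtf) & !(gtf %in% c("0/0", "0/1", "1/0", "1/1",
                                        "./.", ".", "./0", "0/."))
  if (any(unknown))
    stop("unrecognized GT value(s), e.g. '", gtf[which(unknown)[1]], "'")
  codes <- t(code)
  rownames(codes) <- colnames(gt)
  geno <- genotype_matrix(codes, contig = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"], alt = fix[, "ALT"])
  attr(geno, "n_skipped_multiallelic") <- n_skip
  geno
}

#' Write a genotype matrix as VCF v4.2
#'
#' @param geno A [genotype_matrix()] with integer codes.
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  meta <- geno$marker_meta
  gt_str <- c("0/0", "0/1", "1/1")
  codes <- geno$codes
  body <- vapply(seq_len(ncol(codes)), function(j) {
    g <- codes[, j]
    s <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(meta$contig[j], meta$pos[j], meta$marker_id[j], meta$ref[j],
            meta$alt[j], ".", "PASS", ".", "GT", s), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(codes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter markers on MAF and missingness
#'
#' Retains markers with folded MAF at or above `maf_min` **and** missingness
#' at or below `miss_max`; markers exactly at either boundary are kept (the
#' removal rule is MAF strictly below 0.05 or missingness strictly above
#' 20%). Marker order is preserved and the operation is idempotent.
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min Minimum folded MAF (default 0.05).
#' @param miss_max Maximum missingness fraction (default 0.20).
#' @return The filtered [genotype_matrix()]; the per-marker report
#'   (`marker_id`, `maf`, `missingness`, `kept`) is attached as attribute
#'   `"filter_report"`. An empty result triggers a warning, not an error.
#' @export
filter_markers <- function(geno, maf_min = 0.05, miss_max = 0.20) {
  stopifnot(inherits(geno, "genotype_matrix"),
            maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  meta <- geno$marker_meta
  kept <- !is.na(meta$maf) & meta$maf >= maf_min &
    meta$missingness <= miss_max
  report <- data.frame(marker_id = meta$marker_id, maf = meta$maf,
                       missingness = meta$missingness, kept = kept,
                       stringsAsFactors = FALSE)
  if (!any(kept)) {
    warning("no markers pass the MAF/missingness filter")
    out <- geno
    out$codes <- geno$codes[, 0, drop = FALSE]
    out$marker_meta <- meta[0, , drop = FALSE]
  } else {
    out <- subset_markers(geno, markers = which(kept))
  }
  attr(out, "filter_report") <- report
  out
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing call by its marker's mean genotype (a real value in
#' `[0, 2]`). The original missing mask is kept for reporting. Downstream
#' LASSO fits standardize the columns, so the constant shift introduced by
#' mean imputation is immaterial there.
#'
#' @param geno A [genotype_matrix()] (normally post-filter).
#' @return The imputed object: `codes` becomes a numeric matrix with no
#'   missing values and a logical `missing_mask` element is added.
#' @export
impute_missing <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  codes <- geno$codes
  storage.mode(codes) <- "double"
  mask <- is.na(codes)
  if (any(colSums(!mask) == 0))
    stop("marker(s) with all calls missing cannot be imputed")
  if (any(mask)) {
    mu <- colMeans(codes, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    codes[idx] <- mu[idx[, 2]]
  }
  geno$codes <- codes
  geno$missing_mask <- mask
  geno
}

#' Read / write the supporting delimited tables
#'
#' Ring phenotypes travel as CSV with columns `tree_id`, `trait`,
#' `cambial_age`, `value`; the field design as CSV with `tree_id`, `site`,
#' `block`, `family`.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return The data frame (readers) or `path` invisibly (writers).
#' @name tables_io
NULL

#' @rdname tables_io
#' @export
read_rings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "trait", "cambial_age", "value")
  if (!all(need %in% names(df)))
    stop("ring CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname tables_io
#' @export
write_rings_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tables_io
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "site", "block", "family")
  if (!all(need %in% names(df)))
    stop("design CSV must have columns: ", paste(need, collapse = ", "))
  validate_design(df)
  df
}

#' @rdname tables_io
#' @export
write_design_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# every block label must sit inside exactly one site; every tree labelled
validate_design <- function(design) {
  need <- c("tree_id", "site", "block", "family")
  stopifnot(all(need %in% names(design)))
  if (anyDuplicated(design$tree_id)) stop("duplicate tree_id in design")
  if (any(!stats::complete.cases(design[need])))
    stop("design has missing labels")
  sites_per_block <- tapply(design$site, design$block,
                            function(s) length(unique(s)))
  if (any(sites_per_block > 1))
    stop("block label(s) span multiple sites: ",
         paste(names(sites_per_block)[sites_per_block > 1], collapse = ", "))
  invisible(design)
}
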