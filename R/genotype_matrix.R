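#' Genotype matrix container
#'
#' Trees-by-markers integer genotype codes (0 = AA, 1 = AB, 2 = BB, `NA` =
#' missing call) together with per-marker metadata. Marker ids follow the
#' `contig_position` convention common in conifer exome-capture catalogues.
#'
#' @param codes Integer matrix, trees in rows, markers in columns. Values in
#'   `{0, 1, 2, NA}`.
#' @param contig Character vector of contig ids, one per marker.
#' @param pos Integer vector of 1-based positions on the contig.
#' @param ref,alt Reference / alternate allele characters (single bases).
#' @param tree_ids Character vector of unique tree labels; defaults to
#'   rownames of `codes` or `T1..Tn`.
#'
#' @return An object of class `genotype_matrix`: a list with `codes`
#'   (integer matrix with dimnames), and `marker_meta` (data.frame with
#'   columns `marker_id`, `contig`, `pos`, `ref`, `alt`, `maf`,
#'   `missingness`). MAF is folded (always in `[0, 0.5]`) and both MAF and
#'   missingness are computed ignoring missing calls.
#' @export
genotype_matrix <- function(codes, contig, pos, ref = NULL, alt = NULL,
                            tree_ids = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  p <- ncol(codes)
  stopifnot(length(contig) == p, length(pos) == p)
  if (is.null(ref)) ref <- rep("A", p)
  if (is.null(alt)) alt <- rep("G", p)
  if (is.null(tree_ids)) {
    tree_ids <- rownames(codes)
    if (is.null(tree_ids)) tree_ids <- paste0("T", seq_len(nrow(codes)))
  }
  if (anyDuplicated(tree_ids)) stop("tree_ids must be unique")
  bad <- codes[!is.na(codes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  marker_id <- paste(contig, pos, sep = "_")
  if (anyDuplicated(marker_id)) stop("duplicate marker ids (contig_position)")
  rownames(codes) <- tree_ids
  colnames(codes) <- marker_id
  meta <- data.frame(
    marker_id = marker_id, contig = as.character(contig),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    maf = marker_maf(codes), missingness = colMeans(is.na(codes)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(codes = codes, marker_meta = meta),
            class = "genotype_matrix")
}

#' Folded minor-allele frequency per marker
#'
#' @param codes Integer 0/1/2 matrix (NA = missing).
#' @return Numeric vector in `[0, 0.5]`; `NA` for all-missing markers.
#' @export
marker_maf <- function(codes) {
  n_called <- colSums(!is.na(codes))
  alt_freq <- colSums(codes, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(alt_freq, 1 - alt_freq)
  maf[n_called == 0] <- NA_real_
  unname(maf)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d trees x %d markers\n",
              nrow(x$codes), ncol(x$codes)))
  cat(sprintf("  missing calls: %.2f%%; MAF range: [%.3f, %.3f]\n",
              100 * mean(is.na(x$codes)),
              suppressWarnings(min(x$marker_meta$maf, na.rm = TRUE)),
              suppressWarnings(max(x$marker_meta$maf, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix by marker and/or tree
#'
#' @param geno A [genotype_matrix()].
#' @param markers Logical, integer or character index over markers.
#' @param trees Logical, integer or character index over trees.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_markers <- function(geno, markers = NULL, trees = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  codes <- geno$codes
  meta <- geno$marker_meta
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, meta$marker_id)
    codes <- codes[, markers, drop = FALSE]
    meta <- meta[markers, , drop = FALSE]
  }
  if (!is.null(trees)) codes <- codes[trees, , drop = FALSE]
  genotype_matrix(codes, meta$contig, meta$pos, meta$ref, meta$alt,
                  tree_ids = rownames(codes))
}
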