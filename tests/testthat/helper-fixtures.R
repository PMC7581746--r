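# Small in-code fixtures shared across test files.

# Desk-scale configuration: fast but structurally complete.
tiny_config <- function(seed = 1, ...) {
  sim_config(n_families = 40, trees_per_family = 3, n_sites = 2,
             n_blocks_per_site = 2, n_markers = 120, n_qtl = 3,
             n_rings = 12, knots = c(4, 9), seed = seed, ...)
}

# A hand-built VCF: 4 samples, 3 bi-allelic SNPs (one with a missing call)
# and 1 tri-allelic record that readers must skip.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("ctg1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/0", sep = "\t"),
    paste("ctg1", "200", ".", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "./.", "0/1", "1/1", sep = "\t"),
    paste("ctg2", "50", ".", "G", "A,T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "2/2", "0/0", sep = "\t"),
    paste("ctg2", "75", ".", "T", "C", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/1", "0/1", sep = "\t"))
  writeLines(lines, path)
  path
}

# Balanced one-site, one-block, equal-family design (closed-form BLUP case).
one_way_design <- function(K = 25, n_per_family = 8) {
  data.frame(tree_id = sprintf("T%04d", seq_len(K * n_per_family)),
             site = "S1", block = "S1_B1",
             family = rep(sprintf("F%03d", seq_len(K)), each = n_per_family),
             stringsAsFactors = FALSE)
}
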