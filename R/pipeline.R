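#' Run the full functional-mapping association pipeline for one trait
#'
#' Chains the four stages on a ring-resolved trait: (1) per-age joint-site
#' mixed models refine the trajectories to family breeding values with the
#' per-age adjusted mean added back; (2) a shared two-knot linear spline
#' turns each refined family trajectory into four latent traits
#' `beta0..beta3`; (3) each latent trait is scanned with the
#' stability-selection LASSO, genotypes aggregated to family level (family
#' mean genotype) and the first `n_pcs` genotype principal components
#' included as unpenalised covariates; (4) selected markers are
#' characterised (adaptive-LASSO PVE, class means, `2a`, `d`, `d/a`, mode,
#' Kruskal-Wallis).
#'
#' @param rings Ring phenotype table (`tree_id`, `trait`, `cambial_age`,
#'   `value`).
#' @param design Design table (`tree_id`, `site`, `block`, `family`).
#' @param geno [genotype_matrix()] for the trees (missing calls allowed:
#'   markers are filtered and mean-imputed internally).
#' @param trait Trait to analyse.
#' @param knots `"auto"` or a fixed `(K1, K2)` pair.
#' @param latent Which latent traits to scan (default all four).
#' @param maf_min,miss_max Marker filter thresholds.
#' @param n_pcs Number of population-structure PCs (default 5).
#' @param pi_thr,ev_max,n_subsamples Stability-selection settings.
#' @param seed Seed for the subsampling.
#' @return List of class `tracheid_gwas`: `refined`, `latents` (family-level
#'   latent traits with the knots as attribute), `stability` (one
#'   `stability_result` per latent trait), `associations` (combined
#'   association records), `geno_family` (family-mean genotype matrix),
#'   `pcs`.
#' @export
run_tracheid_gwas <- function(rings, design, geno, trait = NULL,
                              knots = "auto", latent = paste0("beta", 0:3),
                              maf_min = 0.05, miss_max = 0.20, n_pcs = 5,
                              pi_thr = 0.52, ev_max = 1, n_subsamples = 100,
                              seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"))
  geno_f <- filter_markers(geno, maf_min, miss_max)
  geno_i <- impute_missing(geno_f)

  refined <- refine_trajectories(rings, design, trait = trait)
  traj <- refined$trajectories
  traj_in <- data.frame(id = traj$family, cambial_age = traj$cambial_age,
                        value = traj$value, stringsAsFactors = FALSE)
  latents <- fit_latent_traits(traj_in, knots = knots)

  # family-mean genotypes aligned with the latent-trait rows
  fam <- design$family[match(rownames(geno_i$codes), design$tree_id)]
  Xfam <- apply(geno_i$codes, 2, function(col) tapply(col, fam, mean))
  Xfam <- Xfam[latents$id, , drop = FALSE]
  pcs <- if (n_pcs > 0) genotype_pcs(Xfam, k = n_pcs) else NULL

  stability <- list()
  assoc <- list()
  for (lt in latent) {
    y <- latents[[lt]]
    ss <- stability_selection(y, Xfam, C = pcs,
                              n_subsamples = n_subsamples, pi_thr = pi_thr,
                              ev_max = ev_max, seed = seed)
    stability[[lt]] <- ss
    if (length(ss$selected)) {
      gf <- geno_i
      gf$codes <- Xfam
      gf$missing_mask <- NULL
      assoc[[lt]] <- characterize_associations(
        y, gf, ss, C = pcs, trait = paste(refined$trait, lt, sep = "."))
    }
  }
  associations <- if (length(assoc)) do.call(rbind, assoc) else
    empty_association_frame()
  rownames(associations) <- NULL
  structure(list(refined = refined, latents = latents,
                 stability = stability, associations = associations,
                 geno_family = Xfam, pcs = pcs),
            class = "tracheid_gwas")
}

#' @export
print.tracheid_gwas <- function(x, ...) {
  cat("functional-mapping LASSO GWAS\n")
  cat(sprintf("  %d families, %d markers, knots K=(%s)\n",
              nrow(x$latents), ncol(x$geno_family),
              paste(attr(x$latents, "knots"), collapse = ", ")))
  cat(sprintf("  %d association record(s) at pi >= %.2f\n",
              nrow(x$associations),
              if (length(x$stability)) x$stability[[1]]$pi_thr else NA))
  invisible(x)
}
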