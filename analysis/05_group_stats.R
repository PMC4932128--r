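#!/usr/bin/env Rscript
# Group-level statistics on the quantified cohort: per-ROI AUC for
# patients-vs-controls, Kruskal-Wallis + Mann-Whitney composite-ROI tests
# at the Bonferroni-corrected alpha, z-score abnormality count maps,
# the voxel-wise permutation contrast with FDR control, and DVR-vs-SUVR
# correlation (ROI matrix and voxel-wise with cluster extents).
# Reads results/cohort + results/quant, writes results/group_stats/.

suppressPackageStartupMessages(library(taupet))

indir <- "results/cohort"; qdir <- "results/quant"; out <- "results/group_stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
man <- read.delim(file.path(indir, "manifest.tsv"))
gm <- read_volume(file.path(indir, "gm.nii.gz"))
gm_mask <- gm >= 0.5
tab <- read.delim(file.path(qdir, "roi_values.tsv"))
grp <- setNames(man$group, man$subject_id)

## ROI-level discrimination and rank tests on the composites
comp <- tab[tab$quantification == "dvr" &
              tab$roi_name %in% c("limbic", "isocortical"), ]
comp$group <- grp[comp$subject_id]
auc <- do.call(rbind, lapply(split(comp, comp$roi_name), function(cc)
  data.frame(roi_name = cc$roi_name[1],
             auc = roc_auc(cc$value, cc$group != "HC"))))
write.table(auc, file.path(out, "auc.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
kw <- kruskal_mannwhitney(comp$value, comp$group, comp$roi_name)
write.table(kw$pairwise, file.path(out, "pairwise_tests.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("Patients-vs-controls AUC: limbic %.3f, isocortical %.3f",
                auc$auc[auc$roi_name == "limbic"],
                auc$auc[auc$roi_name == "isocortical"]))
sig <- kw$pairwise[kw$pairwise$significant, ]
message("Significant pairwise contrasts at corrected alpha ",
        signif(kw$pairwise$alpha_corrected[1], 2), ": ",
        paste(sprintf("%s %s-vs-%s", sig$roi, sig$group1, sig$group2),
              collapse = "; "))

## smoothed DVR maps for voxel-level analyses
maps <- lapply(man$subject_id, function(sid) {
  m <- read_volume(file.path(qdir, paste0(sid, "_dvr.nii.gz")))
  m <- array(m, dim(gm)); m[!is.finite(m)] <- 1
  smooth_image(m, 8, c(2, 2, 2))
})
names(maps) <- man$subject_id

## z-score abnormality counts per patient group vs controls
ctrl <- simplify2array(maps[man$group == "HC"])
mu <- apply(ctrl, 1:3, mean); sdv <- apply(ctrl, 1:3, sd)
for (g in c("prodromal_AD", "AD_dementia")) {
  bins <- lapply(maps[man$group == g], function(m)
    zscore_map(m, mu, sdv, 1.96)$abnormal & gm_mask)
  counts <- abnormality_count_map(bins)
  write_volume(counts, file.path(out, paste0("abnormal_count_", g, ".nii.gz")),
               c(2, 2, 2))
  message(sprintf("%s: max abnormality count %d of %d subjects",
                  g, max(counts), sum(man$group == g)))
}

## voxel-wise permutation contrast, HC vs AD dementia
pt <- permutation_twosample(maps[man$group == "AD_dementia"],
                            maps[man$group == "HC"],
                            n_permutations = 10000, seed = 99,
                            fdr_q = 0.05, mask = gm_mask)
write_volume(pt$t, file.path(out, "hc_vs_ad_t.nii.gz"), c(2, 2, 2))
write_volume(pt$p_fdr, file.path(out, "hc_vs_ad_p_fdr.nii.gz"), c(2, 2, 2))
message(sprintf("HC vs AD dementia: %d of %d GM voxels significant at FDR q=0.05 (%s null, %d relabelings)",
                sum(pt$significant, na.rm = TRUE), sum(gm_mask),
                if (pt$exhaustive) "exhaustive" else "sampled", pt$n_null))

## cross-quantification correlation (DVR vs SUVR), patients only
pat <- man$subject_id[man$group != "HC"]
dvr_tab <- tab[tab$quantification == "dvr" & tab$subject_id %in% pat &
                 !tab$roi_name %in% c("limbic", "isocortical", "cerebellum_gm"), ]
suvr_tab <- tab[tab$quantification == "suvr" & tab$subject_id %in% pat &
                  !tab$roi_name %in% c("limbic", "isocortical", "cerebellum_gm"), ]
cm <- roi_correlation_matrix(dvr_tab, suvr_tab)
write.table(round(cm$r, 4), file.path(out, "dvr_suvr_roi_correlation.tsv"),
            sep = "\t", quote = FALSE)
message(sprintf("ROI-level DVR~SUVR correlation (n=%d patients): median r on the diagonal %.3f",
                cm$n, median(diag(cm$r))))
suvr_maps <- lapply(pat, function(sid) {
  dyn <- read_dynamic_image(file.path(indir, paste0(sid, "_dyn.nii.gz")))
  ref <- read_volume(file.path(indir, "atlas.nii.gz"))
  s <- suvr_image(frame_average(dyn, c(40, 60)),
                  array(round(ref) == 1, dim(gm)))
  smooth_image(array(s, dim(gm)), 8, c(2, 2, 2))
})
vc <- voxelwise_correlation(maps[pat], suvr_maps,
                            p_thresholds = c(0.001, 0.01, 0.05),
                            cluster_extent = 20, mask = gm_mask)
write.table(vc$clusters, file.path(out, "dvr_suvr_clusters.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("Voxel-wise DVR~SUVR: %d clusters of >= 20 voxels at p<0.001",
                sum(vc$clusters$threshold == 0.001)))
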