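#!/usr/bin/env Rscript
# Stage 5 — family-level community comparison: Bray-Curtis dissimilarity,
# NMDS ordination, Spearman/UPGMA clustering of gut samples, shared-family
# (Venn) accounting, the >1% & >2-fold heatmap family selection, and the
# within-group dispersion contrast between native and exchanged groups.

suppressPackageStartupMessages(library(gutswap))

run_dir <- "scratch/run"
fx <- readRDS(file.path(run_dir, "01_fixture.rds"))
otus <- readRDS(file.path(run_dir, "03_otus.rds"))

fam <- aggregate_to_rank(otus$table, "family")
props <- relative_abundance(fam)
bc <- bray_curtis(props)
saveRDS(list(fam = fam, props = props, bray = bc),
        file.path(run_dir, "05_compare.rds"))

ord <- nmds(bc, k = 2)
coords <- data.frame(sample_id = rownames(ord$points), ord$points)
names(coords) <- c("sample_id", "axis1", "axis2")
write.table(coords, "results/05_nmds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sheet <- fx$sample_sheet
gut_ids <- sheet$sample_id[sheet$type == "gut"]
write_dendrogram(correlation_dendrogram(props[, gut_ids]),
                 "results/05_gut_dendrogram.nwk")

groups <- stats::setNames(sheet$group, sheet$sample_id)
disp <- within_group_dispersion(bc, groups)
write.table(disp, "results/05_dispersion.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fam_sets <- lapply(split(gut_ids, sheet$group[sheet$type == "gut"]),
                   function(ids) rownames(props)[rowSums(props[, ids]) > 0])
venn <- shared_membership(fam_sets)
write.table(venn, "results/05_venn_gut_families.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

gm <- gutswap:::group_mean_props(props, data.frame(sample_id = sheet$sample_id,
                                                   group = sheet$group))
hm <- heatmap_select(gm)
write.table(hm$selected, "results/05_heatmap_families.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("NMDS stress: %.4f (%s)\n", ord$stress,
            if (ord$converged) "converged" else "max iterations"))
cat("mean within-group Bray-Curtis dispersion:\n")
print(disp, digits = 3)
d <- stats::setNames(disp$mean_within_bc, disp$group)
cat(sprintf("lake-to-river vs native lake: %.3f vs %.3f (%s)\n",
            d["CK"], d["C"], if (d["CK"] > d["C"]) "diverging" else "converging"))
cat(sprintf("river-to-lake vs native river: %.3f vs %.3f (%s)\n",
            d["KC"], d["K"], if (d["KC"] < d["K"]) "converging" else "diverging"))
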