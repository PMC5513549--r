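#!/usr/bin/env Rscript
# Stage 4 — alpha diversity per sample (observed richness, Chao1, Shannon),
# analytic rarefaction, and Welch comparisons of native vs exchanged groups.

suppressPackageStartupMessages(library(gutswap))

run_dir <- "scratch/run"
fx <- readRDS(file.path(run_dir, "01_fixture.rds"))
otus <- readRDS(file.path(run_dir, "03_otus.rds"))
tbl <- otus$table

alpha <- alpha_diversity(tbl)
write.table(alpha, "results/04_alpha.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

depths <- unique(round(seq(1, min(colSums(tbl$counts)), length.out = 10)))
rare <- do.call(rbind, lapply(colnames(tbl$counts), function(s)
  cbind(sample_id = s, rarefaction_curve(tbl$counts[, s], depths))))
write.table(rare, "results/04_rarefaction.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sheet <- fx$sample_sheet
tests <- do.call(rbind, lapply(list(c("C", "CK"), c("K", "KC")), function(p) {
  do.call(rbind, lapply(c("chao1", "shannon"), function(metric) {
    va <- alpha[[metric]][alpha$sample_id %in%
                            sheet$sample_id[sheet$group == p[1]]]
    vb <- alpha[[metric]][alpha$sample_id %in%
                            sheet$sample_id[sheet$group == p[2]]]
    w <- compare_alpha(va, vb)
    data.frame(native = p[1], exchanged = p[2], metric = metric,
               statistic = w$statistic, p_value = w$p_value)
  }))
}))
write.table(tests, "results/04_alpha_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("group means:\n")
print(aggregate(cbind(chao1, shannon) ~ sheet$group[match(alpha$sample_id,
                                                          sheet$sample_id)],
                data = alpha, FUN = mean))
cat("Welch tests (native vs exchanged):\n")
print(tests, digits = 3)
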