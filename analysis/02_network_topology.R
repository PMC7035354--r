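#!/usr/bin/env Rscript
# Stage 2: group networks and threshold-free topology.
#
# Per (group, age) cell: positive-correlation network, distance matrix
# d = sqrt(1 - r), graph filtration (beta0-curve, GCC threshold, Newick
# dendrogram, single-linkage matrix) and the MST with modularization scores
# of the memory and reward-motivation systems. Also writes the
# developmental SLM contrasts (wk6 - wk4 within each group).

suppressPackageStartupMessages(library(metanet))
out <- "results"
schema <- read_roi_schema(file.path(out, "roi_schema.csv"))
cells <- c("control.wk4", "control.wk6", "adhd.wk4", "adhd.wk6")

slms <- list()
feat <- NULL
for (cell in cells) {
  m <- read_subject_matrix(file.path(out, paste0("activity_", cell, ".csv")),
                           schema)
  d <- distance_matrix(m)
  dend <- single_linkage_merges(d)
  t <- minimum_spanning_tree(d)
  slms[[cell]] <- single_linkage_matrix(dend)
  write_beta0_curve(beta0_curve(dend),
                    file.path(out, paste0("beta0_", cell, ".csv")))
  dendrogram_to_newick(dend, file.path(out,
                                       paste0("dendrogram_", cell, ".nwk")))
  write_mst(t, file.path(out, paste0("mst_", cell, ".tsv")))
  feat <- rbind(feat, data.frame(
    cell = cell,
    gcc_threshold = gcc_threshold(dend),
    memory_score = modularization_score(t, "memory", schema,
                                        warn_ties = FALSE),
    reward_score = modularization_score(t, "reward_motivation", schema,
                                        warn_ties = FALSE)))
}
write.csv(feat, file.path(out, "topology_features.csv"), row.names = FALSE)

cat("Graph filtration and MST modularization per group x age:\n")
print(feat, row.names = FALSE, digits = 4)
delta <- function(col, g) feat[[col]][feat$cell == paste0(g, ".wk6")] -
  feat[[col]][feat$cell == paste0(g, ".wk4")]
cat(sprintf("\nGCC threshold change with age: control %+0.3f, ADHD %+0.3f\n",
            delta("gcc_threshold", "control"), delta("gcc_threshold", "adhd")))
cat(sprintf("memory-system score change:    control %+d, ADHD %+d\n",
            delta("memory_score", "control"), delta("memory_score", "adhd")))

for (g in c("control", "adhd")) {
  ct <- sld_contrast(slms[[paste0(g, ".wk6")]], slms[[paste0(g, ".wk4")]])
  write_square_matrix(ct, file.path(out, paste0("slm_contrast_", g, ".csv")))
  cat(sprintf("SLM contrast %s (wk6 - wk4): mean %.4f, %d%% of pairs closer\n",
              g, mean(ct[upper.tri(ct)]),
              round(100 * mean(ct[upper.tri(ct)] < 0))))
}
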