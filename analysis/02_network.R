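#!/usr/bin/env Rscript
# Stage 2 — build the topological patient-similarity network.
#
# 16 pre-upgrade features -> mean imputation -> Z-scores ->
# normalized-correlation distance -> two classical-MDS lenses ->
# equalized cover (resolution 25, gain 2.1) -> per-cell single-linkage
# clustering -> shared-member edges -> outlier-component removal.

library(crtphenomap)

out_dir <- "results/analysis"
cohort <- read_cohort_csv(file.path(out_dir, "cohort.csv"))

features <- fit_feature_pipeline(cohort)
graph <- mapper_network(features, cover = cover_config(25, 2.1, TRUE),
                        event = cohort$event)
print(graph)

export_mapper_graphml(graph, file.path(out_dir, "graph.graphml"))
export_mapper_json(graph, file.path(out_dir, "graph.json"))

# static network plot in lens coordinates, colored by node event rate
png(file.path(out_dir, "network.png"), 900, 700)
node_xy <- t(vapply(graph$members, function(m) {
  colMeans(graph$lens[m, , drop = FALSE])
}, numeric(2)))
plot(node_xy, type = "n", xlab = "MDS lens 1", ylab = "MDS lens 2",
     main = "Topological patient-similarity network")
segments(node_xy[graph$edges[, 1], 1], node_xy[graph$edges[, 1], 2],
         node_xy[graph$edges[, 2], 1], node_xy[graph$edges[, 2], 2],
         col = "grey80")
pal <- colorRampPalette(c("steelblue", "gold", "firebrick"))(101)
points(node_xy, pch = 19,
       cex = 0.5 + sqrt(graph$node_info$size) / 2,
       col = pal[1 + round(100 * graph$node_stats$event_rate)])
dev.off()

message(length(graph$members), " nodes, ", nrow(graph$edges), " edges, ",
        length(graph$outliers), " outlier patients removed")
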