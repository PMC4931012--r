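#!/usr/bin/env Rscript

# Step 5 — co-occurrence network and taxa-environment correlations.
#
# Builds the Spearman co-occurrence network among families above 1% mean
# abundance (edges: |rho| > 0.3 and p < 0.05) and the full taxa x
# environment correlation table; exports GraphML and edge/heatmap TSVs.

library(infantgut)

tab <- read_abundance_table("results/data/abundance.tsv")
env <- read_sample_table("results/data/environment.tsv")

net <- build_network(tab, rho_min = 0.3, p_max = 0.05, min_mean = 0.01)
export_graph(net, "results/cooccurrence.graphml", format = "graphml")
export_graph(net, "results/cooccurrence_edges.tsv", format = "edge_tsv")
cat(sprintf("network: %d nodes, %d edges (%d negative)\n",
            nrow(net$nodes), nrow(net$edges), sum(net$edges$sign == "-")))
print(net$edges[, c("from", "to", "rho", "p", "sign")])

hm <- correlation_heatmap_table(tab, env)
write_heatmap_table(hm, "results/env_correlations.tsv")
cat("\nBifidobacteriaceae vs gut-environment Spearman rho:\n")
print(round(hm$rho["Bifidobacteriaceae", ], 3))
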