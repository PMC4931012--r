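#!/usr/bin/env Rscript

# Step 2 — community-state typing.
#
# Computes sqrt Jensen-Shannon distances between the simulated samples,
# selects the cluster number by 1000 trials of subsampled PAM +
# Calinski-Harabasz voting (80% subsamples, k = 2..10), fits the final PAM
# partition and a PCoA ordination, and orders samples by complete-linkage
# clustering for heatmap display.

library(infantgut)

seed <- 20160624
dir.create("results", showWarnings = FALSE)

tab <- read_abundance_table("results/data/abundance.tsv")
d <- jsd_matrix(tab)
write_dist_matrix(d, "results/jsd_distances.tsv")

vote <- estimate_k(d, k_range = 2:10, trials = 1000,
                   subsample_fraction = 0.8, seed = seed)
write_cluster_json(vote, "results/k_voting.json")
cat("CH-vote histogram over", vote$trials, "trials:\n")
print(vote$votes)
cat(sprintf("optimal number of community states: k = %d\n", vote$optimal_k))

sol <- pam_cluster(d, vote$optimal_k)
write_cluster_json(sol, "results/pam_solution.json")
cat(sprintf("PAM partition: total cost %.3f, cluster sizes %s\n",
            sol$total_cost,
            paste(table(sol$assignment), collapse = "/")))

ord <- pcoa(d, n_axes = 2)
coords <- data.frame(sample_id = rownames(ord$coordinates), ord$coordinates)
write.table(coords, "results/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA: PC1/PC2 explain %.1f%% / %.1f%% of positive inertia\n",
            100 * ord$proportion_explained[1],
            100 * ord$proportion_explained[2]))

hc <- hclust_complete(d)
writeLines(hc$labels[hc$order], "results/heatmap_sample_order.txt")
cat("wrote distance matrix, voting result, PAM solution, PCoA, leaf order\n")
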