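#!/usr/bin/env Rscript
# Stage 6: exhaustive shortest-path analytics — totals and per-edge usage,
# rich-club path participation, degree profiles along paths, directional
# flow into/out of the club (200 degree-preserving nulls), cross-module
# involvement and Euclidean communication cost.

library(richclubnet)

net <- prune_to_connected(load_network("results/data/network_edges.tsv",
                                       "results/data/network_labels.txt"))
truth <- jsonlite::read_json("results/data/planted_truth.json",
                             simplifyVector = TRUE)
coords <- read.csv("results/data/coordinates.csv")
club <- intersect(truth$rc_nodes, net$labels)
shell <- intersect(truth$rc2_nodes, net$labels)
modules <- unlist(truth$module_of)[net$labels]

ps <- count_shortest_paths(net)
cat(sprintf("%d shortest paths over %d connected pairs (diameter %d)\n",
            ps$total_paths, ps$n_connected_pairs, ps$diameter))

part <- rc_participation(net, club)
cat(sprintf("paths between non-club regions: %.1f%% touch a club node, %.1f%% travel a club edge\n",
            100 * part$frac_touch_node, 100 * part$frac_travel_edge))
cross <- cross_module_paths(net, modules, club)
cat(sprintf("module-crossing paths involving the club: %.0f%% (max pair %.0f%%)\n",
            100 * cross$frac_overall, 100 * max(cross$per_pair$frac_rc, na.rm = TRUE)))

prof <- degree_profile_along_paths(net, shell)
write.csv(prof$median_degree, "results/degree_profile.csv", row.names = FALSE)
write.csv(prof$touch_prob, "results/touch_prob.csv", row.names = FALSE)
md3 <- prof$median_degree[prof$median_degree$length == 3, ]
cat("median degree along length-3 paths:",
    paste(md3$median_degree[order(md3$position)], collapse = " -> "), "\n")

flow_ens <- build_ensemble(net, "randomized", 200, seed = 808)
flow <- flow_asymmetry(net, shell, flow_ens)
write.csv(flow, "results/flow_asymmetry.csv", row.names = FALSE)
sig <- flow$label[which(flow$significant)]
cat(sprintf("flow-asymmetric club/shell nodes at p < 0.01: %d%s\n", length(sig),
            if (length(sig)) paste0(" (", paste(sig, collapse = " "), ")") else ""))

cost <- communication_cost(net, coords, club)
print(cost$shares)
write.csv(cost$edges, "results/edge_cost.csv", row.names = FALSE)
write.csv(cost$shares, "results/cost_shares.csv", row.names = FALSE)
cat(sprintf("club edges carry %.2fx their density share of communication cost\n",
            cost$shares$cost_to_density[cost$shares$class == "rich_club"]))
write.csv(merge(classify_edges(net, club)$edges, ps$edge_usage,
                by = c("source", "target")),
          "results/edge_usage.csv", row.names = FALSE)
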