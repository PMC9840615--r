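# Shared column vocabularies: the 12 geometric ratio indices, the 3 hash
# Hamming distances, and the per-stimulus feature schema built from them.
.visual_indices <- c("perim_total", "perim_mean", "perim_sd",
                     "area_total", "area_mean", "area_sd",
                     "convex_hull", "ch_per_dot", "ch_per_area",
                     "dist_total", "dist_mean", "dist_sd")
.hash_indices <- c("hash_avg", "hash_perc", "hash_wav")
.feature_columns <- c("dot_ratio", .visual_indices, .hash_indices)
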