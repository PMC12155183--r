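# Shared settings for the analysis scripts: the three state points
# (ambient water at 26 and 34 C, pressurized water at 103 C represented by
# its density), the workstation-scale system size, and a run cache so the
# simulation stage is computed once and reused by the later scripts.
#
# Scale: 64 molecules with 10 ps of production at a 0.1 fs step. The box is
# small enough to run in minutes yet large enough to show the percolating
# hydrogen-bond network and the temperature ordering of its statistics.

library(hydropatch)

STATE_POINTS <- data.frame(
  label = c("26C", "34C", "103C"),
  temperature = c(299, 307, 376),
  density = c(0.997, 0.994, 0.969))

N_MOLECULES <- 64
N_PRODUCTION <- 100000   # 10 ps at 0.1 fs
ANNEAL_STAGE <- 4000     # per stage; final stage holds 4x longer
GLOBAL_SEED <- 20

RESULTS_DIR <- "results"
CACHE_DIR <- file.path(RESULTS_DIR, "cache")
dir.create(CACHE_DIR, showWarnings = FALSE, recursive = TRUE)

# run (or reload) one state point; the cache avoids re-simulating when the
# later scripts are run in sequence
get_state_run <- function(i) {
  sp <- STATE_POINTS[i, ]
  cache <- file.path(CACHE_DIR, paste0("run_", sp$label, ".rds"))
  if (file.exists(cache)) return(readRDS(cache))
  message(sprintf("simulating %s (T = %g K, rho = %g g/cm^3)...",
                  sp$label, sp$temperature, sp$density))
  cfg <- md_config(
    N_MOLECULES, density = sp$density, target_temperature = sp$temperature,
    n_production_steps = N_PRODUCTION, annealing_stage_steps = ANNEAL_STAGE,
    store_interval = 1, seed = GLOBAL_SEED + 1000 * i)
  out <- run_nve(cfg)
  saveRDS(out, cache)
  out
}
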