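# Stage 5: IR band-shape analysis on a synthetic temperature series.
#
# A 5-80 C series of absorption spectra is generated with the trends the
# measured mid-IR spectra of water show: a two-state OH-stretch envelope
# whose cold component gives way to the hot one (exact isosbestic point), a
# bending band that narrows and gains integral intensity on heating, and an
# association (combination) band. The full band-shape toolkit then runs on
# it: area normalization, difference spectra, smoothed second derivatives,
# isosbestic location, mirror-FWHM statistics, and combination-mode
# arithmetic.

source("analysis/00_common.R")

labels <- seq(5, 80, by = 5)
series <- generate_spectrum_series(spectrum_series_spec(
  labels = labels, grid = c(1000, 4000, 1),
  # rows: the bending band (narrows and intensifies on heating, slight red
  # shift) and the association band near 2125 cm^-1 (weakens, red-shifts)
  components = data.frame(
    position = c(1645, 2130), position_slope = c(-0.10, -0.60),
    sigma_left = c(42, 95), sigma_left_slope = c(-0.05, 0),
    sigma_right = c(62, 95), sigma_right_slope = c(-0.15, 0),
    amplitude = c(1, 0.18), amplitude_slope = c(0.004, -0.0008)),
  two_state = list(position_a = 3330, sigma_a = 150, position_b = 3580,
                   sigma_b = 130, amplitude = 2.2),
  noise_sd = 0.0015, seed = GLOBAL_SEED))
spectra <- lapply(series$spectra, normalize_total_area)

# difference spectra relative to the coldest temperature
ref <- spectra[[1]]
diffs <- lapply(spectra[-1], difference_spectrum, reference = ref)
write_spectrum(diffs[[length(diffs)]],
               file.path(RESULTS_DIR, "ir_difference_80C_minus_5C.csv"))

# isosbestic point of the stretch envelope
iso <- find_isosbestic(spectra, c(3200, 3700))
cat(sprintf("Isosbestic point of the OH-stretch envelope: %.0f cm^-1 (construction: %.1f), clear = %s\n",
            iso$wavenumber, series$crossing, iso$clear))

# second-derivative components of the stretch region at 5 C
cmp <- second_derivative_components(spectrum_window(spectra[[1]], c(3100, 3750)))
cat("Second-derivative components in the stretch region at 5 C (cm^-1):",
    paste(round(cmp$position), collapse = ", "), "\n")

# mirror-FWHM series of the bending band
tab <- band_temperature_series(spectra, c(1400, 2000))
write.csv(tab$stats, file.path(RESULTS_DIR, "ir_bending_series.csv"),
          row.names = FALSE)
cat("\nBending-band mirror-FWHM series (first and last rows):\n")
print(tab$stats[c(1, nrow(tab$stats)), ], row.names = FALSE)
fwhm_fit <- lm(fwhm_total ~ as.numeric(label), data = tab$stats)
int_fit <- lm(integral_intensity ~ as.numeric(label), data = tab$stats)
cat(sprintf("\nTotal FWHM narrows at %.3f cm^-1 per degree; integral intensity grows at %.2e per degree.\n",
            coef(fwhm_fit)[2], coef(int_fit)[2]))
cat(sprintf("FWHM-skewness correlation across the series: r = %.3f\n",
            cor(tab$stats$fwhm_total, tab$stats$skewness)))

# combination-mode arithmetic with the reference fundamentals
cm <- combination_mode_positions(mode_fundamentals())
cat("\nCombination-mode positions (cm^-1):\n")
print(cm)
write.csv(data.frame(assignment = names(cm), position_cm1 = unname(cm)),
          file.path(RESULTS_DIR, "combination_modes.csv"), row.names = FALSE)
cat("\nThe delta+L2 assignment (2325 cm^-1) sits closest to the observed",
    "\nassociation band; with the bending and minor-libration fundamentals",
    "\nnearly temperature-independent, the band's temperature sensitivity",
    "\ntracks the major libration L2.\n")
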