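#!/usr/bin/env Rscript
# Stage 4 — growth-factor loading and 21-day release accounting.
#
# Applies the loading arithmetic (reservoir mass, supernatant-depletion
# efficacy, leaching), generates synthetic 21-day release series at the
# observed per-film totals, and fits the delayed-release law — contrasting
# a free film with a 2-zone film whose lower-zone factor is suppressed.

suppressMessages(library(periomorph))
dir.create("results", showWarnings = FALSE)

# loading: in vivo reservoirs are 80 uL at 75 ug/mL per disc (both faces)
applied <- applied_mass(0.080, 75)
eff <- loading_efficacy(applied_ug = applied, remaining_ug = 1.9,
                        area_cm2 = 0.70)
cat(sprintf("Applied %.1f ug; loaded %.1f ug = %.1f ug/cm2 (both faces)\n",
            applied, eff$loaded_ug, eff$loaded_ug_per_cm2))
cat(sprintf("Leaching during second loading: %.2f%% of the first factor\n",
            leach_fraction(0.0036, eff$loaded_ug)))

# release: single-loaded film vs lower-zone factor of a 2-zone film
scenarios <- data.frame(
  label = c("PEM20_BMP2_alone", "two_zone_lower_BMP2"),
  total_ug = c(2.59, 2.59),
  delay_days = c(0, 30))     # lower-zone release suppressed beyond day 21
out <- list()
for (i in seq_len(nrow(scenarios))) {
  s <- gen_release_series(scenarios$total_ug[i], burst_fraction = 0.3,
                          rate_per_day = 0.2,
                          delay_days = scenarios$delay_days[i],
                          noise_sd = 0.05, seed = 40 + i)
  cr <- cumulative_release(s$interval_ug, s$timepoint_days, area_cm2 = 0.35)
  cr$label <- scenarios$label[i]
  out[[i]] <- cr
  fit <- fit_release_model(s)
  cat(sprintf("%s: released %.2f ug by day 21 (%.2f ug/cm2); ",
              scenarios$label[i], max(cr$cumulative_ug),
              max(cr$cumulative_ug_per_cm2)))
  if (!fit$identifiable) {
    cat("fit: non-identifiable (no release observed)\n")
  } else if (max(cr$cumulative_ug) < 10 * 0.05) {
    # released total at the assay noise floor: the law is unconstrained
    cat(sprintf("fit: release at noise floor (%.2f ug), parameters not interpretable\n",
                max(cr$cumulative_ug)))
  } else {
    cat(sprintf("fit: total %.2f ug, burst %.2f, rate %.2f /d, delay %.1f d\n",
                fit$total_ug, fit$burst_fraction, fit$rate_per_day,
                fit$delay_days))
  }
}
write.csv(do.call(rbind, out), "results/release_curves.csv",
          row.names = FALSE)
cat("Wrote results/release_curves.csv\n")
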