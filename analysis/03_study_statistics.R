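#!/usr/bin/env Rscript
# Stage 3 — the statistical battery on a synthetic multi-animal study.
#
# Simulates the full design (10 surface conditions x 12 animals x 2 healing
# timepoints, one lost disc) with a planted immediate-layer effect for one
# 2-zone film at 13 weeks, then runs the analysis exactly as a study would:
# Shapiro-Wilk gate, Friedman with Dunn/Bonferroni post hoc per timepoint,
# Mann-Whitney across timepoints, and a Spearman correlation grid.

suppressMessages(library(periomorph))
dir.create("results", showWarnings = FALSE)

eff_cond <- "PEM10_VEGF+PEM10_BMP2"   # early-BMP2 2-zone film
design <- study_design(
  planted_effects = data.frame(condition = eff_cond, timepoint = 13,
                               shift = 0.3),
  lost_discs = data.frame(animal = 7, condition = "PEM20_VEGF",
                          timepoint = 13))
spec <- section_spec(scale = 12, growth_steps = 2000, seed = 1)

study <- gen_study(design, spec, seed = 20260925 %% 100000)
cat("Simulated", nrow(study$discs), "discs (one lost)\n")
dm <- study_disc_means(study)
write.csv(dm, "results/study_disc_means.csv", row.names = FALSE)

# per-disc immediate-layer BD (mean over the six immediate regions)
imm <- dm[dm$metric == "BD" & grepl("immediate", dm$region), ]
imm_disc <- aggregate(value ~ disc_id + animal + condition + timepoint,
                      imm, mean)

# 1. normality gate
gate <- shapiro_gate(split(imm_disc$value, imm_disc$condition))
write.csv(gate$table, "results/stats_shapiro.csv", row.names = FALSE)
cat("Shapiro-Wilk gate -> nonparametric branch:", gate$nonparametric, "\n")

# 2. Friedman + post hoc per timepoint
for (tp in design$timepoints) {
  sub <- imm_disc[imm_disc$timepoint == tp, ]
  m <- with(sub, tapply(value, list(animal, condition), mean))
  fb <- friedman_bonferroni(m, control = "Ti_control")
  cat(sprintf("Week %d: Friedman chi2 = %.2f, p = %.4g; %d/%d post hoc significant\n",
              tp, fb$statistic, fb$p, sum(fb$posthoc$significant),
              nrow(fb$posthoc)))
  write.csv(fb$posthoc, sprintf("results/stats_posthoc_w%d.csv", tp),
            row.names = FALSE)
  hit <- fb$posthoc[(fb$posthoc$a == eff_cond | fb$posthoc$b == eff_cond) &
                      (fb$posthoc$a == "Ti_control" |
                         fb$posthoc$b == "Ti_control"), ]
  cat(sprintf("  %s vs Ti_control: z = %.2f, adjusted p = %.4g (%s)\n",
              eff_cond, hit$statistic, hit$p_adj,
              if (hit$significant) "significant" else "ns"))
}

# 3. healing-time effect per condition (Mann-Whitney)
mw <- do.call(rbind, lapply(design$conditions, function(cc) {
  x4 <- imm_disc$value[imm_disc$condition == cc & imm_disc$timepoint == 4]
  x13 <- imm_disc$value[imm_disc$condition == cc & imm_disc$timepoint == 13]
  cbind(condition = cc, mannwhitney_timepoints(x4, x13))
}))
write.csv(mw, "results/stats_mannwhitney.csv", row.names = FALSE)
cat("Mann-Whitney 4 vs 13 weeks: significant in",
    sum(mw$p <= 0.05, na.rm = TRUE), "of", nrow(mw), "conditions\n")

# 4. Spearman grid: whole-defect BF vs BIC per condition and timepoint
wide <- merge(
  setNames(aggregate(value ~ disc_id + animal + condition + timepoint,
                     dm[dm$metric == "BF" & dm$region == "whole_defect", ],
                     mean), c("disc_id", "animal", "condition", "timepoint",
                              "BF")),
  setNames(dm[dm$metric == "BIC", c("disc_id", "value")],
           c("disc_id", "BIC")), by = "disc_id")
sg <- spearman_grid(wide, list(c("BF", "BIC")))
write.csv(sg, "results/stats_spearman.csv", row.names = FALSE)
cat("Spearman BF~BIC: median rho =", round(median(sg$rho, na.rm = TRUE), 2),
    "across", nrow(sg), "condition-timepoint cells\n")

# design-stage alpha arithmetic, for reference alongside the 5% test level
cat(sprintf("Design-stage per-comparison alpha: %.2f%% (5%% FWER / 14)\n",
            100 * bonferroni_alpha(0.05, 14)))
cat("Wrote results/study_disc_means.csv and stats_*.csv\n")
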