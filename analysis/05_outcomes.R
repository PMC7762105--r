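#!/usr/bin/env Rscript
# Stage 5: outcome and biology associations of the q-delta class.
#
# Uses the model-predicted q-delta class from stage 3 for every patient:
# Kaplan-Meier medians and log-rank for OS and DMFS, a Cox model adjusted
# for margin / nodal stage / adjuvant chemotherapy, the one-year survival
# contingency analysis (Fisher exact + likelihood ratio, relative risk),
# Spearman correlation of NE with nAUC, and Welch t-tests of stromal area
# and cellularity between the classes.

suppressPackageStartupMessages(library(qdelta))

outdir <- "results"
cohort <- read.csv(file.path(outdir, "cohort.csv"), stringsAsFactors = FALSE)
pred <- read.csv(file.path(outdir, "predictions.csv"),
                 stringsAsFactors = FALSE)
cohort$qdelta <- factor(pred$qdelta_class, levels = c("low", "high"))

km_os <- km_fit(cohort$os_months, cohort$os_event, cohort$qdelta)
message("Overall survival by q-delta class:")
print(km_os)
km_dmfs <- km_fit(cohort$dmfs_months, cohort$dmfs_event, cohort$qdelta)
message("Distant-metastasis-free survival by q-delta class:")
print(km_dmfs)

cox <- cox_fit(cohort, c("qdelta", "margin", "n_stage", "adjuvant_chemo"))
print(cox)

oy <- one_year_table(cohort$os_months, cohort$os_event,
                     as.character(cohort$qdelta))
fr <- fisher_rr(oy)
message(sprintf(
  "One-year OS: RR (low vs high) %.2f (%.2f-%.2f), Fisher p = %.3g, LR p = %.3g",
  fr$relative_risk, fr$rr_ci_low, fr$rr_ci_high, fr$fisher_p, fr$lr_p))

sp <- spearman(cohort$ne_ar_npp, cohort$nauc)
message(sprintf("Spearman NE(AR-NPP) vs nAUC: rho = %.2f, p = %.3g",
                sp$rho, sp$p_value))

st <- ttest_groups(cohort$stroma_area_pct, cohort$qdelta)
de <- ttest_groups(cohort$cell_density, cohort$qdelta)
message(sprintf(
  "Stroma area %%: low %.1f vs high %.1f, Welch p = %.3g",
  st$group_means[["low"]], st$group_means[["high"]], st$p_value))
message(sprintf(
  "Cell density: low %.0f vs high %.0f, Welch p = %.3g",
  de$group_means[["low"]], de$group_means[["high"]], de$p_value))

hr_row <- grep("^qdelta", cox$table$term)[1]
report <- list(
  os = list(median_low = unname(km_os$medians["low"]),
            median_high = unname(km_os$medians["high"]),
            logrank_p = km_os$logrank_p),
  dmfs = list(median_low = unname(km_dmfs$medians["low"]),
              median_high = unname(km_dmfs$medians["high"]),
              logrank_p = km_dmfs$logrank_p),
  cox = cox$table,
  cox_hr_qdelta = cox$table$hr[hr_row],
  one_year = list(table = as.vector(oy), fisher_p = fr$fisher_p,
                  lr_p = fr$lr_p, rr = fr$relative_risk,
                  rr_ci = c(fr$rr_ci_low, fr$rr_ci_high)),
  spearman_ne_nauc = list(rho = sp$rho, p = sp$p_value),
  stroma_ttest = list(mean_low = st$group_means[["low"]],
                      mean_high = st$group_means[["high"]],
                      p = st$p_value),
  density_ttest = list(mean_low = de$group_means[["low"]],
                       mean_high = de$group_means[["high"]],
                       p = de$p_value))
jsonlite::write_json(report, file.path(outdir, "outcomes.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Wrote ", outdir, "/outcomes.json")
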