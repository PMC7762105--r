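#!/usr/bin/env Rscript
# Stage 3: build and validate the q-delta classifier.
#
# On the 101-patient training split: univariate logistic screens of the four
# NE features, backward elimination at alpha = 0.05, and the multivariate
# q-delta fit on the retained features. The 90-patient holdout split is then
# scored with the frozen model and its ROC reported.

suppressPackageStartupMessages(library(qdelta))

outdir <- "results"
cohort <- read.csv(file.path(outdir, "cohort.csv"), stringsAsFactors = FALSE)
feature_cols <- c("ne_ar_npp", "ne_pv_npp", "ne_ar_aaf", "ne_pv_aaf")
train <- cohort[1:101, ]
holdout <- cohort[102:191, ]

message("Univariate logistic screens (training split):")
uni <- do.call(rbind, lapply(feature_cols, function(fc) {
  f <- fit_univariate(train[[fc]], train$delta_label)
  data.frame(feature = fc, p_value = f$wald_p, auc = f$roc$auc,
             auc_ci_low = f$roc$ci_low, auc_ci_high = f$roc$ci_high,
             sensitivity_pct = f$roc$sensitivity,
             specificity_pct = f$roc$specificity,
             accuracy_pct = f$roc$accuracy,
             misclassification_pct = f$roc$misclassification)
}))
print(uni, digits = 3)

elim <- backward_eliminate(train[, feature_cols], train$delta_label,
                           alpha = 0.05)
message("Backward elimination retained: ",
        paste(elim$selected, collapse = ", "))
if (nrow(elim$removed) > 0) {
  message("  removed in order: ",
          paste(sprintf("%s (p=%.2f)", elim$removed$feature,
                        elim$removed$p_value), collapse = ", "))
}

model <- fit_qdelta(train[, elim$selected, drop = FALSE], train$delta_label)
print(model)
write_qdelta_model(model, file.path(outdir, "qdelta_model.json"))

pred <- predict_qdelta(model, holdout)
roc_h <- roc_analysis(pred$prob_high, holdout$delta_label,
                      threshold = model$decision_threshold)
message("Holdout (n = 90) performance at the 0.5 decision threshold:")
print(roc_h)

write.csv(rbind(uni,
                data.frame(feature = "qdelta_holdout", p_value = roc_h$p_value,
                           auc = roc_h$auc, auc_ci_low = roc_h$ci_low,
                           auc_ci_high = roc_h$ci_high,
                           sensitivity_pct = roc_h$sensitivity,
                           specificity_pct = roc_h$specificity,
                           accuracy_pct = roc_h$accuracy,
                           misclassification_pct = roc_h$misclassification)),
          file.path(outdir, "classifier_metrics.csv"), row.names = FALSE)
write.csv(data.frame(patient_id = cohort$patient_id,
                     predict_qdelta(model, cohort)),
          file.path(outdir, "predictions.csv"), row.names = FALSE)
message("Wrote ", outdir,
        "/classifier_metrics.csv, qdelta_model.json, predictions.csv")
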