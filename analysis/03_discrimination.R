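#!/usr/bin/env Rscript
# Step 3: discrimination of fallers from non-fallers.
#
# ROC analysis of the fitted model's predicted probabilities: apparent AUC
# with a DeLong 95% interval, the sensitivity+specificity-maximizing
# probability cutoff, and the 10-fold cross-validated AUC from pooled
# out-of-fold probabilities (internal validation).

suppressPackageStartupMessages(library(fallstrat))
cohort <- load_cohort("results/cohort.csv")
fit <- fit_logistic(cohort)
p <- predict_probability(fit, cohort)

roc <- roc_curve(p, cohort$faller)
ci <- auc_ci(p, cohort$faller)
yj <- youden_cutoff(p, cohort$faller)
cv <- crossval_auc(cohort, k = 10, seed = 20240503)

cat(sprintf("Apparent AUC: %.3f (95%% CI %.3f-%.3f)\n",
            ci$auc, ci$lower, ci$upper))
cat(sprintf("Youden cutoff: pi = %.5f (sens %.1f%%, spec %.1f%%)\n",
            yj$cutoff, 100 * yj$sensitivity, 100 * yj$specificity))
cat(sprintf("Cross-validated AUC: %.3f (95%% CI %.3f-%.3f)\n",
            cv$auc, cv$lower, cv$upper))
cat(sprintf("Optimism (apparent - cross-validated): %.3f\n",
            ci$auc - cv$auc))

write.csv(data.frame(threshold = roc$thresholds,
                     sensitivity = roc$sensitivity,
                     specificity = roc$specificity),
          "results/roc_points.csv", row.names = FALSE)
jsonlite::write_json(
  list(auc = ci$auc, auc_ci = c(ci$lower, ci$upper),
       youden_cutoff = yj$cutoff, sensitivity = yj$sensitivity,
       specificity = yj$specificity,
       cv_auc = cv$auc, cv_auc_ci = c(cv$lower, cv$upper)),
  "results/discrimination.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/roc_points.csv, results/discrimination.json\n")
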