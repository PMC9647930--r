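#!/usr/bin/env Rscript
# Full-scale experiment: 228 subjects (76 per class), 200-neuron networks,
# 1 s of activity each, 30 serialized train/evaluate runs per classifier and
# the ensemble rule. This is a long run (several hours on one CPU); the
# reduced-scale counterpart used by tests and scripts/acceptance.R finishes
# in minutes.
#
# Usage: Rscript scripts/full_experiment.R --seed 1 --out results/full

suppressPackageStartupMessages(library(epinetml))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(getArg("--seed", "1"))
outDir <- getArg("--out", "results/full")
dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

spec <- cohortSpec(masterSeed = seed)
cohort <- runCohort(spec, verbose = TRUE)
writeFeatureCsv(cohort, file.path(outDir, "features.csv"))

exp <- runExperiment(cohort, nRuns = 30, trainPerClass = 50, seed = seed)
write.csv(exp$metrics, file.path(outDir, "metrics.csv"), row.names = FALSE)

m <- exp$metrics
overall <- m[m$class == "overall" & m$metric == "accuracy", ]
cat("\nOverall accuracy, mean (sd) - max, by model:\n")
for (k in seq_len(nrow(overall)))
  cat(sprintf("  %-5s %.2f (%.2f) - %.2f\n", overall$method[k],
              100 * overall$mean[k], 100 * overall$sd[k],
              100 * overall$max[k]))
cat(sprintf("\nEnsemble overall accuracy: %.2f%%\n",
            100 * exp$ensemble$overall))
cat(sprintf("Selected features: %d of 92\n", sum(exp$selection$included)))

rocDump <- do.call(rbind, lapply(names(exp$runs), function(m) {
  do.call(rbind, lapply(diseaseClasses(), function(cl) {
    pts <- exp$runs[[m]]$rocPoints[[cl]]
    data.frame(method = m, class = cl, pts)
  }))
}))
write.csv(rocDump, file.path(outDir, "roc_points.csv"), row.names = FALSE)

aucs <- sapply(exp$roc, function(r) sapply(r, `[[`, "auc"))
cat("\nAUC by class (rows) and model (columns):\n")
print(round(aucs, 3))

runManifest(defaultConfig(), seeds = seed,
            extra = list(nSelected = sum(exp$selection$included),
                         selectedFeatures =
                           names(which(exp$selection$included)),
                         ensembleOverall = exp$ensemble$overall),
            path = file.path(outDir, "manifest.json"))
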