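#!/usr/bin/env Rscript
# Score the pipeline's output against the simulator's ground truth:
# pair detection, geography (location + orientation), structural class,
# mechanism, Ks error and span error. Writes results/recovery.tsv.

library(dupliscan)

truth <- read.delim("scratch/simulation/truth.tsv")
events <- read.delim("results/pipeline/events.tsv")

key_t <- paste(pmin(truth$donor, truth$copy), pmax(truth$donor, truth$copy))
key_e <- paste(pmin(events$gene1, events$gene2),
               pmax(events$gene1, events$gene2))
m <- match(key_t, key_e)
ok <- !is.na(m)
ori <- ok & !is.na(truth$orientation) & truth$orientation != ""

scores <- data.frame(
  metric = c("pair_detection", "location_accuracy", "orientation_accuracy",
             "class_accuracy", "mechanism_accuracy", "ks_mae",
             "span_median_abs_err"),
  value = c(
    mean(ok),
    mean(truth$location[ok] == events$location[m[ok]]),
    mean(truth$orientation[ori] == events$orientation[m[ori]]),
    mean(truth$class[ok] == events$class[m[ok]]),
    mean(truth$mechanism[ok] == events$mechanism[m[ok]]),
    mean(abs(truth$ks[ok] - events$ks[m[ok]])),
    median(abs(truth$span[ok] - events$span[m[ok]]))))

dir.create("results", showWarnings = FALSE)
write.table(scores, "results/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(scores, row.names = FALSE)
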