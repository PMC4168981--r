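#!/usr/bin/env Rscript
# Step 1 -- simulate the study cohort.
# Generates the packaged toy metabolic model plus paired cancer/normal
# expression, somatic mutation calls and the compound library, all with
# planted ground truth, and summarizes the mutation burden per sample and
# per class (the cohort-level statistics the screen starts from).

suppressMessages(library(oncoflux))

seed <- 1L
scenario <- synthetic_scenario(seed)
dir.create("results", showWarnings = FALSE)
paths <- write_scenario(scenario, file.path("results", "scenario"))
cat("cohort artifacts written to results/scenario/\n")

model <- generate_toy_model(scenario)
muts <- generate_mutations(scenario, model)
summ <- mutation_summary(muts)

cat(sprintf("mutated genes per sample: median %.1f, mean %.2f (n = %d samples)\n",
            summ$median, summ$mean, nrow(summ$per_sample)))
cat("mutation class percentages:\n")
print(round(summ$per_class, 1))
dominant <- names(which.max(summ$per_class))
cat(sprintf("dominant class: %s (as in real tumor cohorts, missense-rich)\n",
            dominant))

utils::write.table(summ$per_sample, "results/01_mutations_per_sample.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(class = names(summ$per_class),
                              percent = as.numeric(summ$per_class)),
                   "results/01_mutation_class_percent.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("tables: results/01_mutations_per_sample.tsv, results/01_mutation_class_percent.tsv\n")
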