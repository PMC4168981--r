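#!/usr/bin/env Rscript
# Step 2 -- gene-selection funnel.
# Recurrence (>= 5% of samples, transporters removed), LoF/GoF arm
# classification by mutation class, isoenzyme-redundancy filter,
# functional-impact filter, and pathway enrichment of the selected genes.

suppressMessages(library(oncoflux))

scenario <- synthetic_scenario(1L)
model <- generate_toy_model(scenario)
muts <- generate_mutations(scenario, model)

scr <- mutation_screen(muts, scenario$n_samples_cancer, model)
dir.create("results", showWarnings = FALSE)
utils::write.table(scr, "results/02_screen_funnel.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("recurrent genes (>=5%% of %d samples, transporters removed): %d\n",
            scenario$n_samples_cancer, nrow(scr)))
cat(sprintf("selected after isoenzyme + FIS filters: %s\n",
            paste(scr$gene[scr$selected], collapse = ", ")))
cat(sprintf("LoF arm: %s | GoF arm: %s\n",
            paste(scr$gene[scr$selected & grepl("LoF", scr$arm)], collapse = ","),
            paste(scr$gene[scr$selected & grepl("GoF", scr$arm)], collapse = ",")))

enr <- pathway_enrichment(scr$gene[scr$selected], model)
utils::write.table(enr, "results/02_pathway_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("pathway enrichment (hypergeometric):\n")
print(enr[, c("subsystem", "overlap", "size", "p_value", "enriched")],
      row.names = FALSE, digits = 3)
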