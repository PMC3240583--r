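#!/usr/bin/env Rscript
# ESE scan and mutation design: scan an exon with a fabricated octamer
# z-score table, call enhancer/silencer regions, and search for single-base
# substitutions that abolish the strongest ESE without creating a silencer.

library(tra2clip)

set.seed(1)
# fabricated score table over purine-rich octamers plus a planted strong ESE
octs <- Biostrings::mkAllStrings(c("A", "G"), 8)
scores <- setNames(rnorm(length(octs), 0, 2), octs)
exon <- paste(sample(c("A", "G", "C", "T"), 150,
                     prob = c(0.35, 0.35, 0.15, 0.15), TRUE), collapse = "")
ese_site <- "AGAAGAAG"
substr(exon, 61, 68) <- ese_site
scores[ese_site] <- 6.5
tab <- octamer_score_table(scores, ese_threshold = 4, ess_threshold = -4)

prof <- zscore_profile(exon, tab)
calls <- call_regions(prof)

dir.create("results", showWarnings = FALSE)
write.table(data.frame(position = as.integer(names(prof$values)),
                       z = unname(prof$values)),
            "results/ese_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(calls, "results/ese_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("windows scanned: %d (%d without a table entry, scored 0)\n",
            length(prof$values), prof$n_unknown))
print(calls)

ese <- calls[calls$type == "ESE", ][which.max(calls$peak[calls$type == "ESE"]), ]
plans <- design_disrupting_mutation(exon, ese, tab)
plans_flat <- plans[, setdiff(names(plans), "after_scores")]
write.table(plans_flat, "results/mutation_plans.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("substitutions searched in the top ESE: %d; valid: %d\n",
            nrow(plans), sum(plans$valid)))
if (any(plans$valid)) {
  best <- plans[plans$valid, ][1, ]
  cat(sprintf("best disrupting mutation: position %d %s>%s (peak %.2f -> %.2f)\n",
              best$position, best$ref_base, best$alt_base,
              best$peak_before, best$peak_after))
}
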