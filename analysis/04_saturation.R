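#!/usr/bin/env Rscript
# Saturation under a tight mass cap: (a) the chain-growth toy, whose
# closed-form answer validates the fixed point, and (b) the iron-containing
# formose network at an 80 AMU cap run until no new species or reactions
# appear. Writes results/saturation/.

suppressMessages(library(feronet))

dir.create(file.path("results", "saturation"), recursive = TRUE,
           showWarnings = FALSE)

toy <- make_toy_system("chain_growth", cap = 100L)
net <- expand(toy$config)
cat(sprintf("chain toy (cap 100): %d species, saturation at G%d (expected %d/%d)\n",
            sum(!net$species$ubiquitous), saturation_generation(net),
            toy$expected$n_species, toy$expected$saturation))

formose <- expand(preset_config("formose", TRUE, generations = 20L,
                                mass_cap = 80L))
nc <- novel_counts(formose)
write.csv(nc, file.path("results", "saturation", "formose_cap80.csv"),
          row.names = FALSE)
write_manifest(formose, file.path("results", "saturation",
                                  "formose_cap80_manifest.json"))
cat(sprintf("formose (iron, cap 80): %d species, %d events, saturates at G%d\n",
            sum(!formose$species$ubiquitous), length(formose$events),
            saturation_generation(formose)))
cat("\nUnder a tight cap the discoverable chemical space is finite: novelty\n")
cat("per generation rises, peaks, and falls to zero once every sub-cap\n")
cat("product is reachable; extrapolating the early exponential phase beyond\n")
cat("that point overestimates the true saturated count.\n")

fit <- growth_fit(cumulative_species(formose)[2:5, c("generation", "species")],
                  project = saturation_generation(formose))
cat(sprintf("log-linear fit of G1-G4 projects %.0f species at G%d vs %d actual.\n",
            fit$projection$projected, saturation_generation(formose),
            sum(!formose$species$ubiquitous)))
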