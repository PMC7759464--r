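#!/usr/bin/env Rscript
# Simulate the labelled training/test loci for the classifier under the
# desk-scale colonization-split model: equal numbers of neutral, shared-
# sweep and divergent-sweep loci with parameters drawn from the profile
# distributions, masked to mirror the fixture accessibility mask.
# Takes roughly ten minutes on one CPU at the default 400/200 per class.

library(diverscan)

dir.create("results", showWarnings = FALSE)
mask <- read_mask_bed("results/fixtures/mask_chr1.bed", "chr1", 2e6)

model <- desk_model()
profile <- desk_profile()
t0 <- Sys.time()
ts <- make_training_set(model, profile, pair_sizes = c(40L, 40L),
                        mask = mask, seed = 714L)
cat(sprintf("simulated %d train + %d test loci in %.1f min\n",
            length(ts$train), length(ts$test),
            as.numeric(Sys.time() - t0, units = "mins")))

saveRDS(ts, "results/training_set.rds")

# per-class diversity summary at the central subwindow
tab <- do.call(rbind, lapply(split(ts$train,
                                   sapply(ts$train, `[[`, "label")),
  function(insts) {
    v <- t(sapply(insts, function(i) {
      fm <- build_features(i$hap, i$mask, c(0, i$params$locus_bp))
      c(pi_center = fm$raw["pi_a", 11], fst_center = fm$raw["fst", 11],
        ssh12_center = fm$raw["ssh12", 11])
    }))
    colMeans(v, na.rm = TRUE)
  }))
cat("class means at the central subwindow:\n")
print(round(tab, 4))
write.csv(tab, "results/training_class_summary.csv")
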