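#!/usr/bin/env Rscript
# Spatial organization of the contact: center/periphery CTCF comparison of
# connexin vs glutamate-receptor fluorescence, and labeling-occupancy
# fractions of the contact surface.

library(cequant)

dir.create("results", showWarnings = FALSE)
n_scenes <- 8L

set.seed(23)
contacts <- list(); occ_rows <- list()
for (i in seq_len(n_scenes)) {
  sc <- apply_expansion(sample_contact())
  st <- render(sc, channels = c("Cx35.5", "GluR2", "NCad"))
  p <- sum_project(st)
  # outline on the total labeling: the connexin channel alone stops short of
  # the rim, where the receptor patches live
  total <- p$channels[["Cx35.5"]] + p$channels[["GluR2"]] + p$channels[["NCad"]]
  fit <- fit_contact_outline(total, p$pixel_size_xy)
  part <- partition_center_periphery(fit$mask, fit$measure)
  contacts[[i]] <- list(chA = p$channels[["Cx35.5"]],
                        chB = p$channels[["GluR2"]],
                        partition = part,
                        background_roi = default_background_roi(
                          p$channels[["Cx35.5"]], fit$mask))
  oc <- occupancy(p$channels[c("Cx35.5", "GluR2", "NCad")], fit$mask)
  occ_rows[[i]] <- data.frame(scene = i, t(oc$fractions),
                              unlabeled = oc$unlabeled)
}

cp <- center_periphery_analysis(contacts)
tb <- cp$table
cat("normalized fluorescence/area (mean over contacts):\n")
cat(sprintf("  center:    Cx35.5 %.2f, GluR2 %.2f (t-test p = %.2g)\n",
            mean(tb$Cx35.5_center), mean(tb$GluR2_center),
            cp$tests$center$p_value))
cat(sprintf("  periphery: Cx35.5 %.2f, GluR2 %.2f (p = %.2g)\n",
            mean(tb$Cx35.5_periphery), mean(tb$GluR2_periphery),
            cp$tests$periphery$p_value))

occ <- do.call(rbind, occ_rows)
cat(sprintf("occupancy of the contact (mean): GJ %.1f%%, AJ %.1f%%, GluR2 %.1f%%, unlabeled %.1f%%\n",
            100 * mean(occ$Cx35.5), 100 * mean(occ$NCad),
            100 * mean(occ$GluR2), 100 * mean(occ$unlabeled)))

write_table(cp$table, "results/center_periphery.csv")
write_table(result_table(occ, units = setNames(rep("", ncol(occ)), names(occ))),
            "results/occupancy.csv")
cat("written: results/center_periphery.csv, results/occupancy.csv\n")
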