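#!/usr/bin/env Rscript
# Binding-site orientation analysis: the alpha angle (eye vector vs smallest
# principal axis, flipped into [90, 180]) of the refined representative
# models from 03_refine_oligomers.R, next to the designed truth values and
# the alpha of the truth models themselves. The expectation is a monotone
# decrease of alpha with oligomer order: the larger the ring, the more the
# binding sites rotate into the ring plane.

library(ringfit)

stopifnot(file.exists("results/refinement/recovery.tsv"))
rec <- read.delim("results/refinement/recovery.tsv")

rows <- NULL
for (i in seq_len(nrow(rec))) {
  nm <- rec$preset[i]
  truth <- make_oligomer(synthetic_preset(nm, eye_beads = 24,
                                          arm_cluster_beads = 6))
  a_truth <- alpha_angle(truth$model)
  body <- read_body_pdb(file.path("results/refinement",
                                  paste0(nm, "_representative.pdb")))
  # the PDB stores one chain per protomer; alpha was computed at refinement
  # time, recovery.tsv carries it — here we add the truth-model statistic
  rows <- rbind(rows, data.frame(
    preset = nm, alpha_designed = truth$spec$alpha_true,
    alpha_truth_model = round(a_truth$mean_alpha, 1),
    alpha_refined = rec$alpha[i],
    flipped = a_truth$flipped))
  message(sprintf("%s: designed %g, truth model %.1f, refined %.1f", nm,
                  truth$spec$alpha_true, a_truth$mean_alpha, rec$alpha[i]))
}
ok <- all(diff(rows$alpha_refined) < 0)
message("alpha decreases with oligomer order: ", ok)
write.table(rows, "results/alpha.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message("wrote results/alpha.tsv")
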