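#!/usr/bin/env Rscript
# Regenerates inst/extdata/synthetic_sbs96_catalog.tsv: ten synthetic
# row-stochastic SBS96 signatures (sparse Dirichlet-style profiles with a
# few dominant peaks, mimicking the shape of real consensus signatures).
# Deterministic; rerun only if the fixture ever needs to change.
set.seed(20240901)

subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
base <- c("A", "C", "G", "T")
types <- unlist(lapply(subs, function(s) {
  paste0(rep(base, each = 4), "[", s, "]", rep(base, times = 4))
}))

K <- 10
H <- matrix(rgamma(K * 96, shape = 0.15), K, 96)
# give each signature a handful of strong peaks in one substitution class
for (k in seq_len(K)) {
  cls <- ((k - 1) %% 6)
  idx <- cls * 16 + sample(1:16, 4)
  H[k, idx] <- H[k, idx] + rgamma(4, shape = 4)
}
H <- H / rowSums(H)
# floor: real consensus signatures are never exactly zero in any context;
# keeps simulated cohorts free of structurally empty mutation-type columns
H <- 0.97 * H + 0.03 / 96
H <- H / rowSums(H)
rownames(H) <- paste0("SBS", seq_len(K))
colnames(H) <- types

out <- rbind(c("Type", rownames(H)),
             cbind(types, t(formatC(H, digits = 15, format = "g"))))
writeLines(apply(out, 1, paste, collapse = "\t"),
           "inst/extdata/synthetic_sbs96_catalog.tsv")
cat("wrote inst/extdata/synthetic_sbs96_catalog.tsv\n")
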