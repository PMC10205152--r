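#!/usr/bin/env Rscript
# Stage 4 — group statistics on the stage-3 results.
#
# One-sample cluster-mass permutation tests ask where the signal predictors'
# unique contribution (delta-z) is above zero (expected: a positive cluster)
# and whether the null predictor shows any effect (expected: none). A paired
# cluster test over lags compares the word-onset TRF GFP between the full-
# and half-amplitude conditions. With six subjects the 2^6 = 64 sign flips
# are enumerated completely, so p values are exact multiples of 1/64.
#
# Outputs under results/stats/.

suppressPackageStartupMessages(library(speechtrf))

fd <- "results/fit"
if (!file.exists(file.path(fd, "delta_z_signal.tsv"))) {
  stop("missing stage-3 outputs; run analysis/03_fit_trf.R first",
       call. = FALSE)
}
verify_manifest(file.path(fd, "manifest.json"))
cfg <- pipeline_config(seed = 20260927L)
out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_mat <- function(f) as.matrix(read.table(file.path(fd, f),
                                             header = TRUE)[, -1])
dz_signal <- read_mat("delta_z_signal.tsv")
dz_null <- read_mat("delta_z_null.tsv")
gfp_a <- read_mat("gfp_condA.tsv")
gfp_b <- read_mat("gfp_condB.tsv")

# 2 x 2 channel montage: all four channels mutually adjacent via grid edges
coords <- data.frame(channel = sprintf("ch%02d", 1:4),
                     x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
adj <- montage_adjacency(coords, threshold = 1.01)

report <- function(res, label, f) {
  tb <- cluster_table(res)
  write.table(tb, file.path(out, f), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(tb)) {
    for (i in seq_len(nrow(tb))) {
      message(sprintf("%s: cluster {%s}, mass = %.2f, t_max = %.2f, p = %.4g",
                      label, tb$members[i], tb$mass[i], tb$t_max[i], tb$p[i]))
    }
  } else {
    message(sprintf("%s: no supra-threshold clusters", label))
  }
  res
}

res_sig <- report(cluster_test_one_sample(dz_signal, adj, seed = cfg$seed),
                  "delta-z signal > 0", "clusters_delta_z_signal.tsv")
res_nul <- report(cluster_test_one_sample(dz_null, adj, seed = cfg$seed),
                  "delta-z null > 0", "clusters_delta_z_null.tsv")
res_gfp <- report(cluster_test_paired(gfp_a, gfp_b, seed = cfg$seed),
                  "GFP cond A vs B", "clusters_gfp.tsv")

summary <- data.frame(
  test = c("delta_z_signal", "delta_z_null", "gfp_paired"),
  n_clusters = c(length(res_sig$clusters), length(res_nul$clusters),
                 length(res_gfp$clusters)),
  min_p = vapply(list(res_sig, res_nul, res_gfp), function(r)
    if (length(r$clusters)) min(vapply(r$clusters, `[[`, 0, "p")) else NA_real_,
    numeric(1)),
  complete_enumeration = c(res_sig$complete_enumeration,
                           res_nul$complete_enumeration,
                           res_gfp$complete_enumeration))
write.table(summary, file.path(out, "summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write_manifest(file.path(out, "manifest.json"), stage = "stats",
               inputs = file.path(fd, c("delta_z_signal.tsv",
                                        "delta_z_null.tsv", "gfp_condA.tsv",
                                        "gfp_condB.tsv")),
               outputs = file.path(out, c("clusters_delta_z_signal.tsv",
                                          "clusters_delta_z_null.tsv",
                                          "clusters_gfp.tsv", "summary.tsv")),
               config = cfg, seed = cfg$seed)
message("stage 4 complete: results/stats/")
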