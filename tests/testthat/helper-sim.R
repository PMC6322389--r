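# Count-level site-signal matrix straight from the generator's sampling
# model (no coverage tracks), used for the statistical recovery tests.
sim_counts_matrix <- function(cfg, truth, condition, reps = NULL,
                              cell_line = NULL) {
  if (is.null(reps)) reps <- seq_len(cfg$n_replicates)
  out <- NULL
  for (assay in c("alpha1", "alpha2", "beta")) {
    for (rp in reps) {
      sc <- simulate_site_counts(cfg, truth, assay, condition, rp, cell_line)
      if (is.null(out))
        out <- data.frame(site_id = sc$site_id, stringsAsFactors = FALSE)
      out[[sprintf("%s_r%d", assay, rp)]] <- sc$cpm
    }
  }
  as_site_signal_matrix(out)
}
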