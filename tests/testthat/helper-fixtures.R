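# Shared synthetic fixtures for the hybrid / acceptance tests.

hybrid_fixture <- function(n = 160, seed = 1) {
  cfg <- synth_config(n_genes = 80, n_signature_genes = 30, n_tumor = n,
                      n_normal = 10, n_demisg = 20, n_subtype_genes = 15,
                      seed = seed)
  d <- generate_dataset(cfg)
  annT <- d$ann[d$ann$group == "tumor", ]
  list(x = t(d$expr[d$truth$demisg, annT$sample_id]), y = annT$grade,
       subtype = annT$subtype_truth)
}

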