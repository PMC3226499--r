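# Shared fixture loaders and small random-data builders.

fixture_matrix <- function() {
  read_potency_matrix(pvdc_extdata("vascular_targets_ac50.csv"),
                      fixture_annotations())
}

fixture_annotations <- function() {
  read_annotations(pvdc_extdata("vascular_targets_annotations.csv"))
}

fixture_vbs <- function() {
  read.csv(pvdc_extdata("vascular_targets_vbs.csv"),
           stringsAsFactors = FALSE)
}

# Random sparse potency matrix: hits log10-uniform on [0.1, 50] uM.
random_pm <- function(n_chem = 10, n_assay = 10, hit_rate = 0.3) {
  vals <- matrix(inactive_sentinel(), n_chem, n_assay,
                 dimnames = list(sprintf("c%02d", seq_len(n_chem)),
                                 sprintf("a%02d", seq_len(n_assay))))
  hit <- matrix(runif(n_chem * n_assay) < hit_rate, n_chem, n_assay)
  vals[hit] <- 10^runif(sum(hit), -1, log10(50))
  potency_matrix(vals)
}

# Annotation table mapping assays round-robin onto target features.
round_robin_annotations <- function(assays, targets) {
  data.frame(assay_id = assays, platform = "X", cell_system = "X",
             gene_symbol = paste0("G_", assays),
             target_feature = rep_len(targets, length(assays)),
             direction = "na", measure = "AC50", stringsAsFactors = FALSE)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
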