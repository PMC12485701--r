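# Small in-code fixtures shared across test files.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# Tiny expression SummarizedExperiment with explicit values.
tinySE <- function(values, gene_id = rownames(values),
                   chromosome = rep("1", nrow(values))) {
  rd <- DataFrame(gene_id = gene_id, symbol = gene_id,
                  chromosome = chromosome, row.names = gene_id)
  SummarizedExperiment(assays = list(tpm = values), rowData = rd)
}

# Marker TPM vector for the default Y panel, all at `base` except overrides.
yMarkers <- function(base = 0.1, ...) {
  genes <- c("DDX3Y", "EIF1AY", "KDM5D", "RPS4Y1", "USP9Y", "ZFY", "UTY")
  v <- setNames(rep(base, length(genes)), genes)
  over <- c(...)
  v[names(over)] <- over
  v
}

# Hand-built 4-sample cohort covering XaXi / X0_LOX / XY / X0_LOY.
handCohort <- function() {
  genes <- c("XIST", names(yMarkers()), "GENE1")
  values <- cbind(
    s_xaxi = c(55, rep(0.2, 7), 12),
    s_lox  = c(0.3, rep(0.2, 7), 10),
    s_xy   = c(0.4, rep(30, 7), 9),
    s_loy  = c(0.2, rep(0.3, 7), 11))
  rownames(values) <- genes
  se <- tinySE(values, chromosome = c("X", rep("Y", 7), "1"))
  ann <- DataFrame(
    sample_id = colnames(values),
    subject_id = colnames(values),
    tissue = "T1",
    reported_sex = c("female", "female", "male", "male"),
    age_years = c(60, 65, 58, 63),
    sample_type = "primary_tumor",
    x_ploidy = c("2", "1", "unknown", "unknown"),
    survival_days = c(100, 200, 300, 400),
    event = c(1L, 1L, 0L, 1L),
    row.names = colnames(values))
  alignSamples(se, ann)
}

# Write a small GCT v1.2 file; returns the path.
writeGCTFixture <- function(path, values, ids = rownames(values),
                            declared_dims = dim(values)) {
  lines <- c("#1.2", paste(declared_dims[1], declared_dims[2], sep = "\t"),
             paste(c("Name", "Description", colnames(values)), collapse = "\t"))
  for (i in seq_len(nrow(values)))
    lines <- c(lines, paste(c(ids[i], ids[i], values[i, ]), collapse = "\t"))
  writeLines(lines, path)
  path
}
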