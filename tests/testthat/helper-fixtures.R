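# Shared fixtures, built in code and memoised for the session.

.fx <- new.env(parent = emptyenv())

# Small annotated genome reused by classification / simulation tests.
fx_genome <- function() {
  if (is.null(.fx$gen)) {
    .fx$gen <- generate_genome(synthetic_genome_config(
      length = 3e5, n_genes = 30, n_simple_repeats = 20,
      n_sines = 12, n_lines = 2, seed = 5))
  }
  .fx$gen
}

fx_donors <- function() {
  if (is.null(.fx$donors)) .fx$donors <- donor_pool(n = 120, seed = 12)
  .fx$donors
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# One insertion record row.
rec_row <- function(id, pos, len, filter = "PASS", chrom = "chr1", info = ".",
                    geno = "1/1", resolved = TRUE, seq = NULL) {
  if (is.null(seq)) seq <- if (resolved) strrep("A", len) else ""
  data.frame(record_id = id, chrom = chrom, pos = pos,
             inserted_seq = if (resolved) seq else "",
             size = if (resolved) nchar(seq) else 0L,
             filter = filter, info = info, genotype = geno,
             resolved = resolved, stringsAsFactors = FALSE)
}

# Write a VCF with the given body lines and a minimal header.
write_toy_vcf <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=UNION,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=ExactMatchID,Number=1,Type=String,Description=\"t\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"t\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    body), path)
  path
}
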