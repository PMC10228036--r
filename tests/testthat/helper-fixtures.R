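# Shared fixtures, generated in code at test time.

# deterministic 200-bp amplicon used across end-to-end tests
fixture_reference <- function(name = "amp1", length = 200L, seed = 42L,
                              cut_site = NULL) {
  withr::with_seed(seed, aq_reference(name, random_dna(length), cut_site))
}

# spectrum entry: one deletion at position 8, length 3
del8_spectrum <- function(fraction = 0.30) {
  list(list(signature = parse_signature_key("8:D:3"), fraction = fraction))
}

write_temp_fastq <- function(reads, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "reads.fastq")
  write_fastq(reads, path)
  path
}
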