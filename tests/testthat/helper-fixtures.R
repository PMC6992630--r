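# Shared fixtures built in code.

AA20_test <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# a tcr_sample from a named count vector (all productive unless stated)
make_sample <- function(counts, sample_id = "S1", patient_id = "P1",
                        compartment = "TUMOR", usable_input = NA_real_,
                        productive = TRUE) {
  nm <- names(counts)
  if (is.null(nm)) nm <- paste0("CASS", toupper(letters[seq_along(counts)]), "EQYF")
  cl <- data.frame(cdr3_aa = nm, cdr3_nt = NA_character_,
                   v_gene = "TRBV9", j_gene = "TRBJ2-7",
                   templates = as.integer(counts),
                   productive = rep_len(productive, length(counts)),
                   stringsAsFactors = FALSE)
  cl$cdr3_aa[!cl$productive] <- paste0("CASS*", seq_len(sum(!cl$productive)), "F")
  tcr_sample(cl, sample_id = sample_id, patient_id = patient_id,
             compartment = compartment, usable_input = usable_input)
}

# write a toy immunoSEQ-dialect TSV; rows = list of c(nt, aa, count, v, j, status)
write_toy_immunoseq <- function(rows, path = tempfile(fileext = ".tsv")) {
  hdr <- c("nucleotide", "aminoAcid", "count (templates)", "vGeneName",
           "jGeneName", "sequenceStatus")
  lines <- c(paste(hdr, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

# small default simulation used by several tests
small_sim_config <- function(seed = 1, n_patients = 6, ...) {
  sim_config(n_patients = n_patients, seed = seed,
             clones_per_compartment = c(PBMC = 150, ADJACENT_LUNG = 120,
                                        TUMOR = 140),
             depth = c(PBMC = 4000, ADJACENT_LUNG = 3000, TUMOR = 3500),
             viral_reference_size = 300, ...)
}

# all integer partitions of n (independent enumeration helper)
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part)))
    for (tail in integer_partitions(n - k, k))
      out[[length(out) + 1]] <- c(k, tail)
  out
}

# brute-force expected unique clones in a size-t subsample, by enumerating
# every t-subset of the n labeled templates
enum_expected_richness <- function(counts, t) {
  ids <- rep(seq_along(counts), counts)
  combs <- utils::combn(length(ids), t)
  mean(apply(combs, 2, function(ix) length(unique(ids[ix]))))
}
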