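# Shared fixtures built in code at test time.

# tiny FASTA/label files written into a temp dir
write_tiny_fasta <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tiny.fasta")
  writeLines(lines, path)
  path
}

write_tiny_labels <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tiny.labels")
  writeLines(lines, path)
  path
}

# random amino-acid sequences under a fixed RNG state
random_sequences <- function(n, len_range = c(10L, 30L), seed = 1L) {
  set.seed(seed)
  aa <- aa_alphabet(with_x = FALSE)
  seqs <- vapply(seq_len(n), function(i) {
    L <- sample(seq.int(len_range[1], len_range[2]), 1L)
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("seq%03d", seq_len(n))
  seqs
}

# small labeled dataset with embeddings for trainer tests
tiny_training_problem <- function(n = 8L, dim = 6L, seed = 3L) {
  seqs <- random_sequences(n, c(12L, 20L), seed = seed)
  set.seed(seed + 1L)
  labels <- lapply(seqs, function(s) {
    L <- nchar(s)
    y <- integer(L)
    start <- sample(seq_len(max(1L, L - 4L)), 1L)
    y[start:min(L, start + 2L)] <- 1L
    y
  })
  ds <- labeled_dataset(seqs, labels)
  # embeddings that carry the labels (signal along first coordinate)
  embs <- lapply(names(seqs), function(id) {
    L <- nchar(seqs[[id]])
    mu <- outer(2 * labels[[id]] - 1, c(1.5, rep(0, dim - 1L)))
    mu + matrix(stats::rnorm(L * dim, sd = 0.5), nrow = L)
  })
  names(embs) <- names(seqs)
  list(ds = ds, embeddings = embs)
}

# small backbone configuration used across tests
tiny_backbone <- function(input_dim = 6L, dropout = 0.2) {
  backbone_config(input_dim = input_dim,
                  layer_dims = c(8L, 6L, 4L, 2L),
                  kernel_sizes = c(3L, 3L, 3L, 1L),
                  dropout = dropout)
}

# hand-built toy protein-DNA complex: protein chain A (CA atoms only),
# one nucleic chain B with a phosphorus atom at the origin
toy_complex <- function(ca_dists, extra_nuc = NULL) {
  r <- vdw_radii()
  prot <- data.frame(chain = "A", resno = seq_along(ca_dists), resid = "ALA",
                     element = "C", x = ca_dists, y = 0, z = 0,
                     class = "protein", stringsAsFactors = FALSE)
  nuc <- data.frame(chain = "B", resno = 1L, resid = "DA", element = "P",
                    x = 0, y = 0, z = 0, class = "nucleic",
                    stringsAsFactors = FALSE)
  if (!is.null(extra_nuc)) nuc <- rbind(nuc, extra_nuc)
  complex_structure(rbind(prot, nuc))
}
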