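# Binding-site labeling against an all-pairs brute-force oracle.

brute_force_labels <- function(struct, radii, tol) {
  at <- struct$atoms
  at <- at[at$element != "H", ]
  prot <- at[at$class == "protein", ]
  nuc <- at[at$class == "nucleic", ]
  out <- list()
  for (ch in unique(prot$chain)) {
    resnos <- sort(unique(prot$resno[prot$chain == ch]))
    labels <- integer(length(resnos))
    for (k in seq_along(resnos)) {
      rows <- which(prot$chain == ch & prot$resno == resnos[k])
      hit <- FALSE
      for (i in rows) {
        for (j in seq_len(nrow(nuc))) {
          d <- sqrt((prot$x[i] - nuc$x[j])^2 + (prot$y[i] - nuc$y[j])^2 +
                      (prot$z[i] - nuc$z[j])^2)
          if (d - radii[prot$element[i]] - radii[nuc$element[j]] < tol) {
            hit <- TRUE
          }
        }
      }
      labels[k] <- as.integer(hit)
    }
    out[[ch]] <- labels
  }
  out
}

test_that("distance rule is applied with a strict inequality at the boundary", {
  r <- vdw_radii()
  inside <- unname(r["C"] + r["P"] + 0.4)
  boundary <- unname(r["C"] + r["P"] + 0.5)
  res <- label_binding_sites(toy_complex(c(inside, boundary)))
  expect_equal(res$A$labels, c(1L, 0L))
  # shrinking the tolerance never adds labels
  res_tight <- label_binding_sites(toy_complex(c(inside, boundary)),
                                   tol = 0.2)
  expect_true(all(res_tight$A$labels <= res$A$labels))
})

test_that("labels match the all-pairs brute-force oracle on a toy complex", {
  set.seed(40)
  # 5 protein residues x 3 atoms at random positions near a 2-atom nucleic
  # chain
  prot <- data.frame(
    chain = "A",
    resno = rep(1:5, each = 3),
    resid = rep(c("ARG", "GLY", "LYS", "TYR", "ALA"), each = 3),
    element = rep(c("N", "C", "O"), times = 5),
    x = rnorm(15, sd = 4), y = rnorm(15, sd = 4), z = rnorm(15, sd = 4),
    class = "protein", stringsAsFactors = FALSE)
  nuc <- data.frame(chain = "B", resno = c(1L, 1L), resid = "DG",
                    element = c("P", "N"),
                    x = c(0, 1), y = c(0, 0.5), z = c(0, -0.5),
                    class = "nucleic", stringsAsFactors = FALSE)
  struct <- complex_structure(rbind(prot, nuc))
  got <- label_binding_sites(struct)
  oracle <- brute_force_labels(struct, vdw_radii(), 0.5)
  expect_equal(got$A$labels, oracle$A)
  expect_equal(got$A$sequence, "RGKYA")
})

test_that("labeling is invariant under rigid-body transforms", {
  set.seed(41)
  prot <- data.frame(chain = "A", resno = rep(1:6, each = 2), resid = "SER",
                     element = "C", x = rnorm(12, sd = 5), y = rnorm(12, sd = 5),
                     z = rnorm(12, sd = 5), class = "protein",
                     stringsAsFactors = FALSE)
  nuc <- data.frame(chain = "B", resno = 1L, resid = "DA", element = "P",
                    x = 0, y = 0, z = 0, class = "nucleic",
                    stringsAsFactors = FALSE)
  atoms <- rbind(prot, nuc)
  base <- label_binding_sites(complex_structure(atoms))
  for (rep in 1:5) {
    # random rotation (QR of a Gaussian matrix) plus translation
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    t_ <- rnorm(3, sd = 20)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
    moved <- atoms
    moved$x <- xyz[, 1] + t_[1]
    moved$y <- xyz[, 2] + t_[2]
    moved$z <- xyz[, 3] + t_[3]
    expect_equal(label_binding_sites(complex_structure(moved))$A$labels,
                 base$A$labels)
  }
})

test_that("structures without the required chains or radii are rejected", {
  prot_only <- data.frame(chain = "A", resno = 1L, resid = "ALA",
                          element = "C", x = 0, y = 0, z = 0,
                          class = "protein", stringsAsFactors = FALSE)
  nuc <- data.frame(chain = "B", resno = 1L, resid = "DA", element = "P",
                    x = 3, y = 0, z = 0, class = "nucleic",
                    stringsAsFactors = FALSE)
  expect_error(label_binding_sites(complex_structure(prot_only)),
               "no nucleic")
  weird <- rbind(prot_only, nuc)
  weird$element[1] <- "ZZ"
  expect_error(label_binding_sites(complex_structure(weird)), "ZZ")
})

test_that("the shipped example complex labels residues near the nucleic chain", {
  path <- system.file("extdata", "toy_complex.pdb", package = "resibind")
  struct <- read_structure(path)
  expect_false(any(struct$atoms$resid == "HOH"))
  res <- label_binding_sites(struct)
  expect_equal(res$A$sequence, "RGKAY")
  expect_equal(res$A$labels, brute_force_labels(struct, vdw_radii(), 0.5)$A)
  # residues with atoms a few Angstrom from the DNA phosphate bind; the
  # far-away ALA and GLY do not
  expect_equal(res$A$labels[c(2, 4)], c(0L, 0L))
  expect_equal(res$A$labels[c(1, 3)], c(1L, 1L))
})

test_that("PDB files are parsed, waters dropped, chains classified", {
  pdb_lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1L, 1L, 3.0, 0, 0),
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            2L, 2L, 20.0, 0, 0),
    sprintf("ATOM  %5d  P    DA B%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
            3L, 1L, 0.0, 0, 0),
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            4L, 90L, 1.0, 1, 1),
    "END")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.pdb")
  writeLines(pdb_lines, path)
  struct <- read_structure(path)
  expect_s3_class(struct, "complex_structure")
  expect_equal(nrow(struct$atoms), 3L)  # water excluded
  expect_setequal(unique(struct$atoms$class), c("protein", "nucleic"))
  res <- label_binding_sites(struct)
  # CA at 3.0 A from P: gap 3.0 - 1.7 - 1.8 = -0.5 < 0.5 -> binding;
  # CA at 20 A is not
  expect_equal(res$A$labels, c(1L, 0L))
  expect_equal(res$A$sequence, "AG")
})
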