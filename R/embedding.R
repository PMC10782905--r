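# Per-residue embedding: pluggable embedder contract, deterministic fallback,
# and an on-disk cache keyed by sequence id.

# run code under a temporary RNG state so embedders never disturb the
# caller's random stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe an embedder
#'
#' @param name \code{"fallback"} (deterministic windowed one-hot random
#'   projection, no external model needed) or \code{"protbert"} (adapter for a
#'   frozen transformer protein language model, 1024-dim).
#' @param dim Embedding dimension; fixed at 1024 for \code{"protbert"}.
#' @param window Odd context-window width used by the fallback embedder.
#' @param seed Integer seed fixing the fallback projection matrix.
#' @return An \code{embedder_spec} list.
#' @export
embedder_spec <- function(name = c("fallback", "protbert"), dim = 16L,
                          window = 5L, seed = 0L) {
  name <- match.arg(name)
  dim <- as.integer(dim)
  window <- as.integer(window)
  if (name == "protbert") dim <- 1024L
  if (dim <= 0L) stop("dim must be positive")
  if (window <= 0L || window %% 2L == 0L) stop("window must be odd and positive")
  structure(list(name = name, dim = dim, deterministic = TRUE,
                 window = window, seed = as.integer(seed)),
            class = "embedder_spec")
}

#' Preprocess a sequence for a transformer protein language model
#'
#' Residues are uppercased, non-canonical letters are mapped to \code{'X'},
#' and letters are space-separated, the input convention of ProtBert-style
#' encoders.
#'
#' @param sequence Amino-acid string.
#' @return Single space-separated string.
#' @export
protbert_preprocess <- function(sequence) {
  cleaned <- clean_sequence(sequence)$sequence
  paste(strsplit(cleaned, "")[[1]], collapse = " ")
}

#' Embed one sequence with a frozen transformer encoder
#'
#' Adapter contract for ProtBert-style encoders: the sequence is preprocessed
#' with [protbert_preprocess()], passed to \code{encoder}, and the first and
#' last rows of the returned matrix (the begin/end special tokens) are
#' stripped, leaving an L x 1024 matrix. The encoder is used purely as a
#' feature extractor; nothing in this package ever updates its parameters.
#'
#' @param sequence Amino-acid string of length L >= 1.
#' @param encoder Function taking the preprocessed string and returning an
#'   (L+2) x dim numeric matrix including special-token rows. When \code{NULL}
#'   (the default) no encoder is available and an error directs the user to
#'   the fallback embedder.
#' @param dim Expected embedding dimension (1024 for ProtBert).
#' @param max_len Longest residue stretch passed to the encoder in one call.
#'   Longer sequences are embedded in overlapping chunks and stitched back
#'   together, each residue taking its row from the chunk in which it sits
#'   most interior (cuts fall mid-overlap), so every kept row has at least
#'   \code{overlap / 2} residues of context on each side.
#' @param overlap Residues of overlap between consecutive chunks.
#' @return L x dim numeric matrix.
#' @export
embed_protbert <- function(sequence, encoder = NULL, dim = 1024L,
                           max_len = 1022L, overlap = 64L) {
  if (!nzchar(sequence)) stop("cannot embed an empty sequence")
  if (is.null(encoder)) {
    stop("no transformer encoder is available in this installation; ",
         "use the deterministic fallback embedder instead: ",
         "embed_fallback(sequence, embedder_spec('fallback'))")
  }
  stopifnot(max_len > overlap, overlap >= 2L)
  L <- nchar(sequence)

  encode_span <- function(subseq) {
    n <- nchar(subseq)
    raw <- encoder(protbert_preprocess(subseq))
    if (!is.matrix(raw) || ncol(raw) != dim) {
      stop("encoder returned a matrix with ", ncol(raw),
           " columns; expected ", dim)
    }
    if (nrow(raw) != n + 2L) {
      stop("encoder returned ", nrow(raw), " rows for a sequence of length ",
           n, "; expected ", n + 2L, " (sequence plus begin/end tokens)")
    }
    raw[seq.int(2L, n + 1L), , drop = FALSE]
  }

  if (L <= max_len) {
    emb <- encode_span(sequence)
  } else {
    step <- max_len - overlap
    starts <- seq.int(1L, L - max_len, by = step)
    starts <- unique(c(starts, L - max_len + 1L))
    emb <- matrix(NA_real_, L, dim)
    half <- overlap %/% 2L
    for (i in seq_along(starts)) {
      s <- starts[i]
      e <- s + max_len - 1L
      take_from <- if (i == 1L) 1L else s + half
      take_to <- if (i == length(starts)) L else starts[i + 1L] + half - 1L
      chunk <- encode_span(substr(sequence, s, e))
      emb[take_from:take_to, ] <- chunk[(take_from:take_to) - s + 1L, ,
                                        drop = FALSE]
    }
  }
  if (!all(is.finite(emb))) stop("encoder produced non-finite values")
  emb
}

# deterministic projection matrix for the fallback embedder:
# (21 * window) one-hot inputs -> dim outputs
fallback_projection <- function(spec) {
  n_in <- 21L * spec$window
  with_local_seed(spec$seed,
    matrix(stats::rnorm(n_in * spec$dim, sd = 1 / sqrt(spec$window)),
           nrow = n_in, ncol = spec$dim))
}

#' Deterministic fallback embedder
#'
#' Each residue's row is a fixed seeded random projection of the one-hot
#' encodings of the residues in a centered window (zero-padded at the
#' sequence ends). Fully reproducible from (sequence, seed, dim, window) and
#' shift-equivariant away from the ends, giving the downstream convolutional
#' network local-context structure to learn from without any external model.
#'
#' @param sequence Amino-acid string.
#' @param spec An [embedder_spec()] with \code{name = "fallback"}.
#' @return L x dim numeric matrix.
#' @export
embed_fallback <- function(sequence, spec = embedder_spec("fallback")) {
  stopifnot(inherits(spec, "embedder_spec"))
  if (spec$name != "fallback") stop("spec is not a fallback embedder spec")
  if (!nzchar(sequence)) stop("cannot embed an empty sequence")
  alpha <- aa_alphabet()
  chars <- strsplit(clean_sequence(sequence)$sequence, "")[[1]]
  L <- length(chars)
  code <- match(chars, alpha)  # 1..21, never NA after cleaning
  P <- fallback_projection(spec)
  w <- spec$window
  h <- (w - 1L) %/% 2L
  # one-hot window design matrix, L x (21*w), then a single projection
  X <- matrix(0, nrow = L, ncol = 21L * w)
  for (j in seq_len(w)) {
    off <- j - 1L - h
    pos <- seq_len(L) + off
    ok <- pos >= 1L & pos <= L
    rows <- which(ok)
    X[cbind(rows, (j - 1L) * 21L + code[pos[ok]])] <- 1
  }
  emb <- X %*% P
  rownames(emb) <- NULL
  emb
}

#' Embed every sequence of a dataset
#'
#' @param sequences Named character vector of sequences.
#' @param spec An [embedder_spec()]; the \code{"protbert"} spec requires an
#'   \code{encoder}.
#' @param encoder Optional encoder function for the \code{"protbert"} spec.
#' @return Named list of L x dim matrices.
#' @export
embed_dataset <- function(sequences, spec = embedder_spec("fallback"),
                          encoder = NULL) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  out <- if (spec$name == "fallback") {
    lapply(sequences, embed_fallback, spec = spec)
  } else {
    lapply(sequences, embed_protbert, encoder = encoder, dim = spec$dim)
  }
  names(out) <- names(sequences)
  out
}

#' Save per-residue embeddings to a cache file
#'
#' The cache is a versioned RDS container holding the embedder name, the
#' embedding dimension and a named list of matrices keyed by sequence id.
#' Embeddings are computed once and cached; training never updates them.
#'
#' @param embeddings Named list of L x dim matrices.
#' @param path Output path.
#' @param embedder Name of the embedder that produced the matrices.
#' @return Invisibly, \code{path}.
#' @export
cache_embeddings <- function(embeddings, path, embedder = "fallback") {
  stopifnot(length(embeddings) > 0, !is.null(names(embeddings)))
  if (anyDuplicated(names(embeddings))) {
    stop("duplicate ids in embeddings: ",
         paste(unique(names(embeddings)[duplicated(names(embeddings))]),
               collapse = ", "))
  }
  dims <- unique(vapply(embeddings, ncol, integer(1)))
  if (length(dims) != 1L) stop("embeddings have inconsistent dimensions: ",
                               paste(dims, collapse = ", "))
  saveRDS(list(version = 1L, embedder = embedder, dim = dims,
               matrices = embeddings), path)
  invisible(path)
}

#' Load per-residue embeddings from a cache file
#'
#' @param path Cache file written by [cache_embeddings()].
#' @param expected_dim Optional; error if the cached dimension differs.
#' @return Named list of L x dim matrices.
#' @export
load_embeddings <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) stop("embedding cache not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$version) || obj$version != 1L) {
    stop("not a recognized embedding cache: ", path)
  }
  if (!is.null(expected_dim) && obj$dim != expected_dim) {
    stop("embedding cache dimension ", obj$dim,
         " does not match expected dimension ", expected_dim)
  }
  obj$matrices
}
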