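# Text encoder contract and the deterministic reference encoder.
#
# An encoder is a list with fields:
#   id     - configuration string
#   dim    - width of the pooled representation
#   encode - function(segments_matrix) -> numeric matrix [n x dim]
# The classifier head consumes the pooled vector (the analogue of a
# transformer's classification-token representation). The shipped
# "reference" encoder is a deterministic, dependency-free hashed
# bag-of-tokens embedder: each token is hashed (salted by its segment role,
# so target and neighbour occurrences are distinct features) into two
# signed buckets (double hashing, so a single collision never destroys a
# feature), and the pooled vector is the signed token-count vector. The
# classification head standardizes pooled features on the training set.
# The reference encoder exists so the entire pipeline is trainable and
# testable offline; a pretrained biomedical transformer adapter can be
# plugged in through the same contract for production use.


#' Resolve a text encoder by id
#'
#' @param encoder_id `"reference"` for the deterministic hashed
#'   bag-of-tokens encoder, or a custom encoder object (list with `id`,
#'   `dim`, `encode`). Other ids raise a configuration error; adapters for
#'   pretrained transformers are supplied by passing the encoder object
#'   itself.
#' @param dim Representation width of the reference encoder.
#' @return An encoder object.
#' @export
resolve_encoder <- function(encoder_id = "reference", dim = 1024L) {
  if (is.list(encoder_id)) {
    enc <- encoder_id
    if (!all(c("id", "dim", "encode") %in% names(enc)) ||
        !is.function(enc$encode)) {
      stopf("custom encoder must be a list with fields id, dim, encode")
    }
    return(enc)
  }
  if (!identical(encoder_id, "reference")) {
    stopf(paste0("encoder '%s' is not resolvable in this installation; ",
                 "use encoder_id = \"reference\" or pass an encoder object"),
          encoder_id)
  }
  reference_encoder(dim)
}

#' The deterministic reference encoder
#'
#' @param dim Representation width (number of hash buckets).
#' @return An encoder object (see [resolve_encoder()]).
#' @export
reference_encoder <- function(dim = 1024L) {
  dim <- as.integer(dim)
  list(id = "reference", dim = dim,
       encode = function(segments) encode_hashed(segments, dim))
}

# Tokenize: lowercase, split on non-alphanumerics.
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Polynomial string hashes (Horner, mod 2^26), in double arithmetic:
# intermediate values stay far below 2^53, so they are exact. Each token is
# mapped to two independent (bucket, sign) pairs; writing every token into
# two buckets keeps single collisions from destroying a feature.
.hash_cache <- new.env(parent = emptyenv())
hash_token <- function(token) {
  cached <- get0(token, .hash_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  h1 <- 7; h2 <- 5381
  for (b in utf8ToInt(token)) {
    h1 <- (h1 * 131 + b) %% 67108864
    h2 <- (h2 * 137 + b) %% 67108864
  }
  out <- c(h1, h2)
  assign(token, out, .hash_cache)
  out
}

# segments: character matrix [n x nseg]; returns [n x dim] pooled matrix.
encode_hashed <- function(segments, dim) {
  n <- nrow(segments)
  nseg <- ncol(segments)
  roles <- if (nseg == 3L) c("prev", "tgt", "next") else "tgt"
  out <- matrix(0, nrow = n, ncol = dim)
  for (i in seq_len(n)) {
    v <- numeric(dim)
    for (s in seq_len(nseg)) {
      toks <- tokenize(segments[i, s])
      for (t in toks) {
        h <- hash_token(paste0(roles[s], ":", t))
        for (k in 1:2) {
          bucket <- (h[k] %% dim) + 1
          sign <- if ((h[k] %/% dim) %% 2 == 0) 1 else -1
          v[bucket] <- v[bucket] + sign
        }
      }
    }
    out[i, ] <- v
  }
  out
}
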