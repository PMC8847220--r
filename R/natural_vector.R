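#' Natural vector of nucleotide sequences
#'
#' The natural vector is a 12-number alignment-free descriptor of a DNA
#' sequence: for each base k in (A, C, G, T) it records the count `n_k`, the
#' mean position `mu_k` (0-based offset from the first residue), and the
#' normalized second central moment
#' `D2_k = sum_i (s_ki - mu_k)^2 / (n_k * n)`, where `s_ki` are the offsets of
#' the occurrences of base k and `n` is the total sequence length. Distinct
#' sequences map to distinct vectors (the mapping is injective when all
#' central moments are retained; in practice the first 12 dimensions are
#' used), and similarity between sequences is measured as Euclidean distance
#' between their vectors.
#'
#' Ambiguous symbols (N and other IUPAC codes) belong to no base class but
#' still occupy positions: they shift the offsets of later residues and count
#' toward `n`. Bases absent from the sequence get `mu_k = D2_k = 0` by
#' convention.
#'
#' @param seqs A tibble with columns `id` and `seq` (as from [read_fasta()]),
#'   or a named character vector of sequences.
#' @return A tibble with column `id` followed by the 12 components in fixed
#'   order: `n_A, n_C, n_G, n_T, mu_A, mu_C, mu_G, mu_T, D2_A, D2_C, D2_G,
#'   D2_T`.
#' @seealso [divided_natural_vector()], [nv_vec()]
#' @export
#' @examples
#' natural_vector(tibble::tibble(id = "s1", seq = "ACGT"))
natural_vector <- function(seqs) {
  seqs <- as_seq_tbl(seqs)
  validate_sequences(seqs)
  mat <- t(vapply(seqs$seq, nv_vec, numeric(12), USE.NAMES = FALSE))
  colnames(mat) <- nv_component_names()
  dplyr::bind_cols(tibble(id = seqs$id), as_tibble(mat))
}

#' Divided natural vector of nucleotide sequences
#'
#' The divided natural vector (DNV) splits each sequence into `k` contiguous
#' segments left-to-right and concatenates the 12-dimensional natural vectors
#' of the segments into a single vector of length `12 * k`, blending local
#' composition signal with the global statistics. Segment offsets restart at
#' 0 within each segment. When the sequence length is `q * k + r`, the first
#' `r` segments have length `q + 1` and the rest length `q`. With `k = 1` the
#' DNV equals the plain natural vector.
#'
#' @inheritParams natural_vector
#' @param k Number of segments (positive integer, at most the shortest
#'   sequence length). Default 4, the setting used throughout the pipeline.
#' @return A tibble with column `id` followed by `12 * k` components named
#'   `s<j>_<component>` in segment-major order.
#' @export
#' @examples
#' divided_natural_vector(tibble::tibble(id = "s1", seq = "AACCGGTT"), k = 2)
divided_natural_vector <- function(seqs, k = 4) {
  seqs <- as_seq_tbl(seqs)
  validate_sequences(seqs)
  check_segment_count(k, min(nchar(seqs$seq)))
  mat <- t(vapply(seqs$seq, dnv_vec, numeric(12 * k), k = k,
                  USE.NAMES = FALSE))
  colnames(mat) <- dnv_component_names(k)
  dplyr::bind_cols(tibble(id = seqs$id), as_tibble(mat))
}

#' Natural vector of a single sequence string
#'
#' Low-level worker behind [natural_vector()].
#'
#' @param x A single nucleotide sequence string (uppercase A/C/G/T plus
#'   IUPAC ambiguity codes).
#' @return A named numeric vector of length 12.
#' @export
nv_vec <- function(x) {
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    abort("sequence must be a single nonempty string")
  }
  nv_from_chars(strsplit(x, "", fixed = TRUE)[[1]])
}

nv_from_chars <- function(s) {
  n <- length(s)
  out <- numeric(12)
  for (i in 1:4) {
    idx <- which(s == DNA_BASES[i]) - 1  # 0-based offsets from the origin
    nk <- length(idx)
    if (nk > 0) {
      mu <- sum(idx) / nk
      out[i] <- nk
      out[4 + i] <- mu
      out[8 + i] <- sum((idx - mu)^2) / (nk * n)
    }
  }
  names(out) <- nv_component_names()
  out
}

#' Divided natural vector of a single sequence string
#'
#' Low-level worker behind [divided_natural_vector()].
#'
#' @inheritParams nv_vec
#' @param k Number of segments.
#' @return A named numeric vector of length `12 * k`.
#' @export
dnv_vec <- function(x, k = 4) {
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    abort("sequence must be a single nonempty string")
  }
  s <- strsplit(x, "", fixed = TRUE)[[1]]
  check_segment_count(k, length(s))
  bounds <- segment_bounds(length(s), k)
  out <- unlist(lapply(seq_len(k), function(j) {
    nv_from_chars(s[bounds$from[j]:bounds$to[j]])
  }), use.names = FALSE)
  names(out) <- dnv_component_names(k)
  out
}

#' Segment boundaries for the divided natural vector
#'
#' For a sequence of length `n = q * k + r`, the first `r` segments have
#' length `q + 1` and the remaining `k - r` have length `q`, contiguous
#' left-to-right.
#'
#' @param n Sequence length.
#' @param k Number of segments.
#' @return A tibble with columns `segment`, `from`, `to` (1-based inclusive).
#' @export
segment_bounds <- function(n, k) {
  check_segment_count(k, n)
  q <- n %/% k
  r <- n %% k
  len <- c(rep(q + 1L, r), rep(q, k - r))
  to <- cumsum(len)
  tibble(segment = seq_len(k), from = to - len + 1L, to = to)
}

check_segment_count <- function(k, n) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != floor(k)) {
    abort("segment count k must be a positive integer")
  }
  if (k > n) {
    abort(paste0("segment count k = ", k,
                 " exceeds sequence length ", n))
  }
  invisible(k)
}

nv_component_names <- function() {
  c(paste0("n_", DNA_BASES), paste0("mu_", DNA_BASES), paste0("D2_", DNA_BASES))
}

dnv_component_names <- function(k) {
  as.vector(vapply(seq_len(k), function(j) {
    paste0("s", j, "_", nv_component_names())
  }, character(12)))
}

#' Coordinate-wise mean of a list of vectors
#'
#' Averaging is how a pair of haplotype vectors collapses to one personal
#' vector and how personal vectors collapse to a population centroid: the two
#' haplotypes of a diploid pair carry equal weight, so their average position
#' in vector space represents the pair.
#'
#' @param vectors A nonempty list of equal-length numeric vectors, or a
#'   numeric matrix whose rows are the vectors.
#' @return The coordinate-wise arithmetic mean as a numeric vector.
#' @export
#' @examples
#' average_vectors(list(c(0, 2), c(2, 4)))
average_vectors <- function(vectors) {
  if (is.matrix(vectors)) {
    vectors <- lapply(seq_len(nrow(vectors)), function(i) vectors[i, ])
  }
  if (!is.list(vectors) || length(vectors) == 0) {
    abort("`vectors` must be a nonempty list of numeric vectors")
  }
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1) {
    abort("all vectors must have the same length")
  }
  colMeans(do.call(rbind, vectors))
}

#' Euclidean distance between two vectors
#'
#' @param u,v Equal-length numeric vectors.
#' @return The L2 norm of `u - v`.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) {
    abort("vectors must have the same length")
  }
  sqrt(sum((u - v)^2))
}
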