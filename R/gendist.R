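# Pairwise sequence identity from FASTA input, similarity/distance
# conversion, and the Jukes-Cantor distance correction.

#' Construct a sequence set
#'
#' @param seqs named character vector of nucleotide sequences
#'   (A, C, G, T; N allowed as an ambiguity code). Lowercase is
#'   normalized to uppercase.
#' @return a named character vector of class `sequence_set`.
#' @export
sequence_set <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    gv_stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    gv_stop("duplicate sequence names: ",
            paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  nms <- names(seqs)
  seqs <- stats::setNames(toupper(as.character(seqs)), nms)
  if (any(!nzchar(seqs))) {
    gv_stop("empty sequence(s): ",
            paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    off <- regmatches(seqs[bad][1], regexpr("[^ACGTN]", seqs[bad][1]))
    gv_stop("non-nucleotide character '", off, "' in sequence '",
            names(seqs)[bad][1], "' (alphabet is ACGT plus N)")
  }
  structure(seqs, class = "sequence_set")
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) gv_stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  sequence_set(stats::setNames(as.character(ss), names(ss)))
}

#' Write a sequence set to FASTA
#' @param seqs a [sequence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Alignment scoring parameters
#'
#' Defaults (+1 match, -1 mismatch, -2 gap open, -0.5 gap extend, free
#' end gaps) are conventional for rRNA-scale identity computation and a
#' gap run of length L costs `gap_open + (L - 1) * gap_extend`. With
#' `end_gaps = "free"`, terminal overhangs are unpenalized and excluded
#' from the identity denominator, i.e. identity is reported over the
#' aligned region, the usual convention in the 16S species-threshold
#' literature. `N` never counts as a match.
#'
#' @param match positive match score.
#' @param mismatch,gap_open,gap_extend non-positive penalties.
#' @param end_gaps `"free"` (default) or `"penalized"`.
#' @return a list of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = -2,
                             gap_extend = -0.5,
                             end_gaps = c("free", "penalized")) {
  end_gaps <- match.arg(end_gaps)
  if (match <= 0) gv_stop("match score must be positive")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    gv_stop("mismatch and gap penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, end_gaps = end_gaps),
            class = "alignment_params")
}

check_seq <- function(s, what = "sequence") {
  if (length(s) != 1 || is.na(s)) gv_stop(what, " must be a single string")
  s <- toupper(s)
  if (!nzchar(s)) gv_stop(what, " is empty")
  if (grepl("[^ACGTN]", s))
    gv_stop("non-nucleotide character '",
            regmatches(s, regexpr("[^ACGTN]", s)), "' in ", what)
  s
}

#' Globally align two sequences (affine gaps)
#'
#' Needleman-Wunsch/Gotoh dynamic programming with affine gap costs and,
#' by default, free end gaps. Co-optimal alignments are resolved by a
#' deterministic traceback preference (diagonal over up over left), so
#' the reported identity is reproducible.
#'
#' @param a,b nucleotide strings.
#' @param params an [alignment_params()].
#' @return a list with `score`, `matches`, `columns` (aligned columns,
#'   terminal overhangs excluded under free end gaps), `identity` (%),
#'   and the two gapped alignment strings.
#' @export
pairwise_alignment <- function(a, b, params = alignment_params()) {
  a <- check_seq(a, "sequence 'a'")
  b <- check_seq(b, "sequence 'b'")
  # canonical argument order: the traceback preference picks one
  # co-optimal alignment, and aligning in a fixed orientation makes the
  # reported identity exactly symmetric in (a, b)
  swapped <- (a > b)
  res <- if (swapped) {
    align_affine_cpp(b, a, params$match, params$mismatch, params$gap_open,
                     params$gap_extend, params$end_gaps == "free")
  } else {
    align_affine_cpp(a, b, params$match, params$mismatch, params$gap_open,
                     params$gap_extend, params$end_gaps == "free")
  }
  if (swapped) {
    tmp <- res$aligned_a
    res$aligned_a <- res$aligned_b
    res$aligned_b <- tmp
  }
  res
}

#' Percent identity between two sequences
#'
#' `100 * matches / aligned columns` from the optimal global alignment of
#' [pairwise_alignment()]; symmetric and in \[0, 100\].
#'
#' @inheritParams pairwise_alignment
#' @return percent identity.
#' @export
pairwise_identity <- function(a, b, params = alignment_params()) {
  pairwise_alignment(a, b, params)$identity
}

#' Pairwise identity matrix for a sequence set
#'
#' @param seqs a [sequence_set()] with at least two sequences.
#' @param params an [alignment_params()].
#' @return a [labeled_matrix()] of kind `similarity_percent` (diagonal
#'   100).
#' @export
identity_matrix <- function(seqs, params = alignment_params()) {
  seqs <- sequence_set(seqs)
  n <- length(seqs)
  if (n < 2) gv_stop("need at least 2 sequences")
  labs <- names(seqs)
  v <- matrix(100, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pid <- tryCatch(
      pairwise_identity(seqs[[i]], seqs[[j]], params),
      geovar_error = function(e)
        gv_stop("pair (", labs[i], ", ", labs[j], "): ", conditionMessage(e))
    )
    v[i, j] <- pid
    v[j, i] <- pid
  }
  labeled_matrix(v, kind = "similarity_percent")
}

#' Proportion-of-differing-sites matrix for equal-length sequences
#'
#' For sequences that are positionally homologous by construction (e.g.
#' simulator output, or a pre-aligned marker without indels) the
#' p-distance is a direct per-site comparison; no alignment is performed.
#'
#' @param seqs a [sequence_set()] of equal-length sequences.
#' @return a [labeled_matrix()] of kind `distance_percent` holding
#'   100 * p (percent differing sites).
#' @export
p_distance_matrix <- function(seqs) {
  seqs <- sequence_set(seqs)
  if (length(seqs) < 2) gv_stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1)
    gv_stop("p_distance_matrix requires equal-length sequences")
  v <- p_distance_cpp(unclass(seqs)) * 100
  dimnames(v) <- list(names(seqs), names(seqs))
  labeled_matrix(v, kind = "distance_percent")
}

#' Convert a percent-similarity matrix to a percent-distance matrix
#'
#' `D = 100 - S` elementwise, the convention used to treat genomic
#' similarity (DDH %, identity %) as a genetic "distance" before matrix
#' correlation.
#'
#' @param m a [labeled_matrix()] of kind `similarity_percent`.
#' @return a [labeled_matrix()] of kind `distance_percent`.
#' @export
similarity_to_distance <- function(m) {
  if (m$kind != "similarity_percent")
    gv_stop("expected a similarity_percent matrix, got ", m$kind)
  labeled_matrix(100 - m$values, kind = "distance_percent")
}

#' Convert a percent-distance matrix back to percent similarity
#' @param m a [labeled_matrix()] of kind `distance_percent`.
#' @return a [labeled_matrix()] of kind `similarity_percent`.
#' @export
distance_to_similarity <- function(m) {
  if (m$kind != "distance_percent")
    gv_stop("expected a distance_percent matrix, got ", m$kind)
  labeled_matrix(100 - m$values, kind = "similarity_percent")
}

#' Jukes-Cantor (JC69) distance from an observed difference proportion
#'
#' `d = -(3/4) * log(1 - 4p/3)` substitutions per site. Saturates as p
#' approaches 0.75 (the expected difference between unrelated random
#' sequences under JC69); values at or beyond 0.75 raise an error.
#'
#' @param p proportion(s) of differing sites, in \[0, 0.75).
#' @return substitutions per site (vectorized).
#' @export
#' @examples
#' jc69_distance(0.1)
jc69_distance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0))
    gv_stop("p must be finite and non-negative")
  if (any(p >= 0.75))
    gv_stop("JC69 saturation: p >= 0.75 (observed ", max(p),
            "); distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}
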