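# Combinatorial hexapeptide beta-sheet breaker (BSB) library.
#
# The reference inhibitor is LPFFFD (iAb6): two N-terminal hydrophobic
# residues, three consecutive aromatic residues, and an acidic C-terminus.
# The library explores conservative substitutions at each position.

#' Reference beta-sheet breaker hexapeptide
#' @return The string \code{"LPFFFD"}.
#' @export
bsb_reference <- function() "LPFFFD"

#' Per-position substitution scheme for the BSB library
#'
#' Position 1 (Leu) may become A, G, I, M, P or V; position 2 (Pro) may
#' become A, G, I, L, M or V; positions 3-5 (Phe) may become W or Y; and
#' position 6 (Asp) may become E. Substitution sets never contain the
#' reference residue at that position.
#'
#' @return A list of six character vectors, one per position.
#' @export
bsb_mutation_scheme <- function() {
  list(
    c("A", "G", "I", "M", "P", "V"),
    c("A", "G", "I", "L", "M", "V"),
    c("W", "Y"),
    c("W", "Y"),
    c("W", "Y"),
    "E"
  )
}

.validate_scheme <- function(reference, scheme) {
  ref <- strsplit(reference, "")[[1]]
  if (length(ref) != 6L) .stopf("reference peptide must have 6 residues")
  if (length(scheme) != 6L) .stopf("scheme must list 6 positions")
  for (p in 1:6) {
    if (ref[p] %in% scheme[[p]])
      .stopf("scheme at position %d contains the reference residue %s", p, ref[p])
  }
  ref
}

#' Count sequence variants with exactly k substituted positions
#'
#' The number of distinct sequences at Hamming distance \code{k} from the
#' reference under a per-position substitution scheme is the k-th elementary
#' symmetric polynomial of the per-position alternative counts, i.e. the
#' coefficient of \eqn{x^k} in \eqn{\prod_p (1 + n_p x)}.
#'
#' @param scheme Substitution scheme as from \code{\link{bsb_mutation_scheme}}.
#' @param k Number of substituted positions, 0..6.
#' @return Integer count.
#' @export
count_variants <- function(scheme = bsb_mutation_scheme(), k) {
  if (k < 0 || k > length(scheme)) .stopf("k must be between 0 and %d", length(scheme))
  counts <- lengths(scheme)
  poly <- 1
  for (n in counts) poly <- c(poly, 0) + c(0, poly * n)
  as.integer(poly[k + 1])
}

#' Generate the virtual BSB hexapeptide library
#'
#' Enumerates all distinct sequences whose set of substituted positions has
#' size in \code{mutation_counts}, each substituted position drawing from its
#' scheme set. With the default scheme and \code{mutation_counts = c(0, 2, 3)}
#' this yields the 627-member library (reference + all double and triple
#' mutants); \code{c(0, 1, 2, 3)} yields 646.
#'
#' @param reference Reference hexapeptide (default \code{\link{bsb_reference}}).
#' @param scheme Per-position substitution sets.
#' @param mutation_counts Set of allowed substitution counts, a subset of 0:3.
#' @return Data frame with columns \code{sequence} (lexicographically sorted)
#'   and \code{n_mutations} (Hamming distance to the reference).
#' @export
generate_library <- function(reference = bsb_reference(),
                             scheme = bsb_mutation_scheme(),
                             mutation_counts = c(0, 2, 3)) {
  if (length(mutation_counts) == 0) .stopf("mutation_counts must be non-empty")
  if (!all(mutation_counts %in% 0:3))
    .stopf("mutation_counts must be a subset of {0,1,2,3}")
  ref <- .validate_scheme(reference, scheme)
  seqs <- character(0)
  nmut <- integer(0)
  for (k in sort(unique(mutation_counts))) {
    if (k == 0) {
      seqs <- c(seqs, reference)
      nmut <- c(nmut, 0L)
      next
    }
    pos_sets <- utils::combn(6, k, simplify = FALSE)
    for (pos in pos_sets) {
      grid <- expand.grid(scheme[pos], stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        s <- ref
        s[pos] <- unlist(grid[r, ], use.names = FALSE)
        seqs <- c(seqs, paste(s, collapse = ""))
        nmut <- c(nmut, k)
      }
    }
  }
  keep <- !duplicated(seqs)
  out <- data.frame(sequence = seqs[keep], n_mutations = nmut[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a peptide library as FASTA and/or a plain list
#'
#' FASTA record ids are \code{<sequence>_k<n_mutations>}.
#'
#' @param library Data frame as returned by \code{\link{generate_library}}.
#' @param fasta Optional path for a FASTA file.
#' @param txt Optional path for a plain one-sequence-per-line file.
#' @return Invisibly, the library.
#' @export
write_library <- function(library, fasta = NULL, txt = NULL) {
  if (!is.null(fasta)) {
    aa <- Biostrings::AAStringSet(library$sequence)
    names(aa) <- sprintf("%s_k%d", library$sequence, library$n_mutations)
    Biostrings::writeXStringSet(aa, fasta)
  }
  if (!is.null(txt)) writeLines(library$sequence, txt)
  invisible(library)
}
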