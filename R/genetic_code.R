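#' Standard genetic code for codon models
#'
#' Builds the standard (universal) genetic code in the fixed base order
#' T, C, A, G, the convention used throughout the codon-model literature so
#' that sense-codon matrix indices are stable and comparable across tools.
#'
#' @return An object of class \code{genetic_code}: a list with
#'   \item{codons}{all 64 triplets in lexicographic T<C<A<G order}
#'   \item{aa}{amino-acid one-letter symbol per triplet, \code{"*"} for stop}
#'   \item{sense_codons}{the 61 non-stop triplets, in the same order}
#'   \item{sense_aa}{amino acid per sense codon}
#'   \item{stop_codons}{the 3 stop triplets}
#'   \item{pairs}{single-nucleotide-difference sense-codon pairs with their
#'     substitution type, used to fill rate matrices (see
#'     \code{\link{build_rate_matrix}})}
#' @export
standard_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(vapply(bases, function(b1)
    vapply(bases, function(b2)
      paste0(b1, b2, bases), character(4)), character(16)))
  # standard code, rows follow the T<C<A<G nesting above
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  names(aa) <- codons
  sense <- codons[aa != "*"]
  stopifnot(length(sense) == 61L)

  code <- list(
    codons = codons,
    aa = aa,
    sense_codons = sense,
    sense_aa = unname(aa[sense]),
    stop_codons = codons[aa == "*"]
  )
  code$pairs <- .codon_pairs(code)
  class(code) <- "genetic_code"
  code
}

# Enumerate ordered sense-codon pairs differing at exactly one position.
# type: 0 = synonymous transversion, 1 = synonymous transition,
#       2 = nonsynonymous transversion, 3 = nonsynonymous transition.
.codon_pairs <- function(code) {
  sense <- code$sense_codons
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  purines <- c("A", "G")
  is_transition <- function(a, b)
    (a %in% purines) == (b %in% purines)
  ii <- jj <- tt <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(mat[i, ] != mat[j, ])
      if (length(diff) != 1L) next
      syn <- code$sense_aa[i] == code$sense_aa[j]
      ts <- is_transition(mat[i, diff], mat[j, diff])
      ii <- c(ii, i); jj <- c(jj, j)
      tt <- c(tt, 2L * as.integer(!syn) + as.integer(ts))
    }
  }
  list(i = ii, j = jj, type = tt)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons (order T<C<A<G)\n")
  invisible(x)
}
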