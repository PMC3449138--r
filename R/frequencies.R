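#' Equilibrium codon frequencies (F3x4 and F61)
#'
#' \code{f3x4_frequencies} estimates sense-codon equilibrium frequencies from
#' position-specific nucleotide frequencies: the frequency of codon
#' \eqn{b_1 b_2 b_3} is the product of the per-codon-position frequencies of
#' \eqn{b_1, b_2, b_3}, with stop codons removed and the 61 sense entries
#' renormalised to sum to 1. \code{f61_frequencies} uses empirical sense-codon
#' counts with a pseudocount.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @param pseudocount added to every sense codon count (F61 only), default 1.
#' @return An object of class \code{codon_frequencies}: numeric 61-vector
#'   named by sense codon, nonnegative, summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  if (aln$n_codon_sites == 0L) stop("empty alignment", call. = FALSE)
  code <- aln$code
  sense <- code$sense_codons
  bases <- c("T", "C", "A", "G")
  # observed nucleotide counts per codon position over non-missing cells
  obs <- aln$sites[!is.na(aln$sites)]
  if (length(obs) == 0L) stop("alignment has no unambiguous codons", call. = FALSE)
  trip <- do.call(rbind, strsplit(sense[obs], ""))
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, bases))
  for (p in 1:3) {
    tab <- table(factor(trip[, p], levels = bases))
    if (sum(tab) == 0L)
      stop("codon position ", p, " has no observed unambiguous nucleotides",
           call. = FALSE)
    pos_freq[p, ] <- tab / sum(tab)
  }
  cm <- do.call(rbind, strsplit(sense, ""))
  pi <- pos_freq[1, cm[, 1]] * pos_freq[2, cm[, 2]] * pos_freq[3, cm[, 3]]
  pi <- pi / sum(pi)
  structure(stats::setNames(as.numeric(pi), sense),
            class = "codon_frequencies", model = "F3x4")
}

#' @rdname f3x4_frequencies
#' @export
f61_frequencies <- function(aln, pseudocount = 1) {
  if (aln$n_codon_sites == 0L) stop("empty alignment", call. = FALSE)
  sense <- aln$code$sense_codons
  obs <- aln$sites[!is.na(aln$sites)]
  cnt <- tabulate(obs, nbins = length(sense)) + pseudocount
  pi <- cnt / sum(cnt)
  structure(stats::setNames(as.numeric(pi), sense),
            class = "codon_frequencies", model = "F61")
}

#' Uniform codon frequencies (1/61 each); mostly for tests and symmetry checks
#' @param code a \code{genetic_code}.
#' @return A \code{codon_frequencies} vector.
#' @export
uniform_frequencies <- function(code = standard_genetic_code()) {
  n <- length(code$sense_codons)
  structure(stats::setNames(rep(1 / n, n), code$sense_codons),
            class = "codon_frequencies", model = "uniform")
}
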