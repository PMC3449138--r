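#' GY94-style codon rate matrix
#'
#' Builds the 61x61 instantaneous rate matrix of the Goldman-Yang codon model:
#' substitutions altering more than one nucleotide have rate 0; a single-
#' nucleotide change i -> j has rate \eqn{\pi_j} (synonymous transversion),
#' \eqn{\kappa \pi_j} (synonymous transition), \eqn{\omega \pi_j}
#' (nonsynonymous transversion) or \eqn{\omega \kappa \pi_j} (nonsynonymous
#' transition). The diagonal makes rows sum to zero and the matrix is rescaled
#' to unit mean rate, \eqn{-\sum_i \pi_i Q_{ii} = 1}, so branch lengths are
#' expected substitutions per codon.
#'
#' @param freqs \code{codon_frequencies} (61-vector).
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega dN/dS ratio, >= 0.
#' @param code a \code{genetic_code}.
#' @param normalize rescale to unit mean rate (default TRUE). With
#'   \code{FALSE} the raw matrix is returned together with its mean rate in
#'   \code{attr(,"mean_rate")}, which mixture models use to apply one shared
#'   scale across site classes.
#' @return 61x61 matrix of class \code{codon_rate_matrix}.
#' @export
build_rate_matrix <- function(freqs, kappa, omega,
                              code = standard_genetic_code(),
                              normalize = TRUE) {
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  n <- length(code$sense_codons)
  Q <- matrix(0, n, n, dimnames = list(code$sense_codons, code$sense_codons))
  p <- code$pairs
  mult <- c(1, kappa, omega, omega * kappa)[p$type + 1L]
  Q[cbind(p$i, p$j)] <- mult * freqs[p$j]
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(freqs * diag(Q))
  if (normalize) {
    if (mean_rate <= 0) stop("degenerate rate matrix (zero mean rate)",
                             call. = FALSE)
    Q <- Q / mean_rate
    mean_rate <- 1
  }
  structure(Q, class = c("codon_rate_matrix", "matrix"),
            mean_rate = mean_rate, kappa = kappa, omega = omega)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Uses the symmetric eigendecomposition available for reversible Q
#' (\eqn{\Pi^{1/2} Q \Pi^{-1/2}} is symmetric). Tiny negative entries from
#' round-off are clipped at 0 and rows renormalised; clipping beyond 1e-8
#' triggers a warning.
#'
#' @param Q a \code{codon_rate_matrix}.
#' @param freqs the equilibrium frequencies Q was built with.
#' @param t branch length, >= 0.
#' @return 61x61 row-stochastic matrix.
#' @export
transition_matrix <- function(Q, freqs, t) {
  if (t < 0) stop("branch length must be >= 0", call. = FALSE)
  sq <- sqrt(as.numeric(freqs))
  S <- (sq * Q) %*% diag(1 / sq)      # symmetric for reversible Q
  S <- (S + t(S)) / 2                 # symmetrise round-off
  e <- eigen(S, symmetric = TRUE)
  P <- (e$vectors * rep(exp(e$values * t), each = nrow(S))) %*% t(e$vectors)
  P <- diag(1 / sq) %*% P %*% diag(sq)
  neg <- P < 0
  if (any(neg)) {
    if (max(-P[neg]) > 1e-8)
      warning("clipped negative transition probability of magnitude ",
              format(max(-P[neg])), call. = FALSE)
    P[neg] <- 0
  }
  P / rowSums(P)
}
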