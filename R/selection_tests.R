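#' Two-LRT positive-selection protocol (M7 vs M8, M8a vs M8)
#'
#' Runs the site-model decision rule: a gene is called under
#' \emph{positive selection} only if M8 beats both M7 and M8a at level
#' \code{alpha}; if M8 beats M7 but not M8a the signal is attributed to
#' \emph{relaxation} of purifying selection; otherwise \emph{none}. Branch
#' lengths and kappa are estimated once under M0 and fixed; M8a is
#' warm-started from M7 and M8 from both, which enforces the nested-model
#' likelihood ordering. On a positive verdict, BEB site posteriors from the
#' M8 fit are attached.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @param tree \code{ape::phylo}.
#' @param freqs codon frequencies; default F3x4.
#' @param alpha significance level in (0,1), default 0.05.
#' @param options passed to \code{\link{fit_model}} (n_restarts, tol, seed,
#'   n_categories, grid_resolution for BEB).
#' @return A \code{selection_call}: verdict ("positive_selection",
#'   "relaxation", "none" or "withheld"), the two \code{lrt_result}s, alpha,
#'   all three fits, and \code{beb} when positive.
#' @export
positive_selection_test <- function(aln, tree, freqs = NULL, alpha = 0.05,
                                    options = list()) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  freqs <- freqs %||% f3x4_frequencies(aln)
  o <- utils::modifyList(list(n_restarts = 3L, tol = 1e-8, seed = 1L,
                              n_categories = 10L, grid_resolution = 10L),
                         options)
  m0 <- fit_m0(aln, tree, freqs, tol = o$tol)
  base <- list(n_restarts = o$n_restarts, tol = o$tol, seed = o$seed,
               n_categories = o$n_categories, m0 = m0)

  f_m7 <- fit_model(aln, tree, "M7", freqs, base)
  # share the column cache across the three fits
  base$m0 <- m0

  init8a <- f_m7$model; init8a$name <- "M8a"
  init8a$p0 <- 0.95; init8a$omega_s <- 1
  f_m8a <- fit_model(aln, tree, "M8a", freqs,
                     c(base, list(init = init8a)))

  init8_from_8a <- f_m8a$model; init8_from_8a$name <- "M8"
  init8_from_8a$omega_s <- 1 + 1.5e-9
  init8_from_7 <- f_m7$model; init8_from_7$name <- "M8"
  init8_from_7$p0 <- 0.95; init8_from_7$omega_s <- 2
  f_m8 <- fit_model(aln, tree, "M8", freqs,
                    c(base, list(init = init8_from_8a,
                                 extra_inits = list(init8_from_7))))

  fits <- list(M0 = m0, M7 = f_m7, M8a = f_m8a, M8 = f_m8)
  if (!all(f_m7$converged, f_m8a$converged, f_m8$converged)) {
    return(structure(list(verdict = "withheld",
                          lrt_m7_m8 = NULL, lrt_m8a_m8 = NULL,
                          alpha = alpha, fits = fits,
                          diagnostics = "one or more fits failed to converge"),
                     class = "selection_call"))
  }
  l78 <- lrt(f_m7, f_m8)
  l8a8 <- lrt(f_m8a, f_m8)
  verdict <- if (l78$p_value < alpha && l8a8$p_value < alpha) {
    "positive_selection"
  } else if (l78$p_value < alpha) "relaxation" else "none"
  out <- structure(list(verdict = verdict, lrt_m7_m8 = l78,
                        lrt_m8a_m8 = l8a8, alpha = alpha, fits = fits),
                   class = "selection_call")
  if (verdict == "positive_selection")
    out$beb <- beb_posteriors(f_m8, o$grid_resolution)
  out
}

#' Branch-site test of lineage-specific positive selection
#'
#' Fits branch-site model A with omega2 free (alternative) versus fixed at 1
#' (null) on the flagged foreground branches and compares them by an LRT
#' with 1 degree of freedom. Where significant at \code{alpha}, BEB
#' posteriors for the foreground omega > 1 classes are attached.
#'
#' @inheritParams positive_selection_test
#' @return list with \code{lrt} (an \code{lrt_result}), \code{significant},
#'   \code{posterior} (BEB \code{site_posterior} or NULL), and both fits.
#' @export
branch_site_test <- function(aln, tree, freqs = NULL, alpha = 0.05,
                             options = list()) {
  if (!any(tree$foreground %||% FALSE))
    stop("branch-site test needs a tree with >= 1 foreground (#1) branch",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  freqs <- freqs %||% f3x4_frequencies(aln)
  o <- utils::modifyList(list(n_restarts = 3L, tol = 1e-8, seed = 1L,
                              grid_resolution = 10L), options)
  # Branch lengths are estimated jointly under the branch-site NULL model
  # and then fixed for both fits. Fixing lengths from any simpler stage
  # (M0, branch models) lets omega2 compensate branch-length misfit and
  # breaks the chi-square(1) calibration of the LRT; lengths from the null
  # keep the test conservative. A two-ratio branch fit provides kappa and
  # starting lengths.
  m0 <- fit_m0(aln, tree, freqs, tol = o$tol, two_ratio = TRUE)
  f_null <- fit_model(aln, tree, "BSA_null", freqs,
                      list(n_restarts = o$n_restarts, tol = o$tol,
                           seed = o$seed, m0 = m0,
                           fix_branch_lengths = FALSE))
  base <- list(n_restarts = o$n_restarts, tol = o$tol, seed = o$seed,
               m0 = list(kappa = m0$kappa, omega = m0$omega,
                         branch_lengths = f_null$branch_lengths))
  # warm-start the alternative both at the null boundary and away from it
  # (the boundary point has a near-zero omega2 gradient and can trap the
  # optimiser)
  init_alt <- f_null$model; init_alt$name <- "BSA_alt"
  init_alt$bs_omega2 <- 1 + 1.5e-9
  init_alt2 <- f_null$model; init_alt2$name <- "BSA_alt"
  init_alt2$bs_omega2 <- 3
  f_alt <- fit_model(aln, tree, "BSA_alt", freqs,
                     c(base, list(init = init_alt,
                                  extra_inits = list(init_alt2))))

  if (!f_null$converged || !f_alt$converged)
    return(list(lrt = NULL, significant = NA, posterior = NULL,
                fits = list(null = f_null, alt = f_alt),
                diagnostics = "branch-site fit failed to converge"))
  l <- lrt(f_null, f_alt)
  sig <- l$p_value < alpha
  list(lrt = l, significant = sig,
       posterior = if (sig) beb_posteriors(f_alt, o$grid_resolution) else NULL,
       fits = list(null = f_null, alt = f_alt))
}

#' @export
print.selection_call <- function(x, ...) {
  cat("selection_call:", x$verdict, "\n")
  if (!is.null(x$lrt_m7_m8)) print(x$lrt_m7_m8)
  if (!is.null(x$lrt_m8a_m8)) print(x$lrt_m8a_m8)
  invisible(x)
}
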