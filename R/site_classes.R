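#' Site-class omega-mixture model specification
#'
#' Constructs a named codon site-model specification of the family used for
#' positive-selection scans:
#' \itemize{
#'   \item \code{M0}: one ratio omega for all sites.
#'   \item \code{M7}: omega ~ Beta(p, q) on (0,1), discretised into K
#'     equal-probability categories (quantile midpoints).
#'   \item \code{M8}: with probability p0 the M7 beta mixture, with
#'     probability 1-p0 an extra class at omega_s >= 1.
#'   \item \code{M8a}: M8 with omega_s frozen at 1 (relaxation null).
#'   \item \code{BSA_alt}/\code{BSA_null}: branch-site model A with classes
#'     0 (omega0 < 1 everywhere), 1 (neutral everywhere), 2a and 2b
#'     (omega0 / 1 on background, omega2 on foreground branches);
#'     \code{BSA_null} freezes omega2 = 1.
#' }
#'
#' @param name one of "M0","M7","M8","M8a","BSA_null","BSA_alt".
#' @param kappa transition/transversion ratio, > 0.
#' @param omega M0 omega, >= 0.
#' @param beta_p,beta_q beta shape parameters, > 0 (M7/M8/M8a).
#' @param p0 proportion of beta-distributed sites in [0,1] (M8/M8a).
#' @param omega_s omega of the extra class, >= 1 (M8; forced to 1 for M8a).
#' @param n_categories number of beta discretisation categories K (default 10).
#' @param bs_p0,bs_p1 branch-site class-0 and class-1 proportions (>= 0,
#'   bs_p0 + bs_p1 <= 1, bs_p0 + bs_p1 > 0).
#' @param bs_omega0 background purifying omega in (0,1).
#' @param bs_omega2 foreground omega, >= 1 (forced to 1 for BSA_null).
#' @return An object of class \code{site_class_model}.
#' @export
site_class_model <- function(name, kappa = 2,
                             omega = NULL,
                             beta_p = NULL, beta_q = NULL,
                             p0 = NULL, omega_s = NULL,
                             n_categories = 10L,
                             bs_p0 = NULL, bs_p1 = NULL,
                             bs_omega0 = NULL, bs_omega2 = NULL) {
  name <- match.arg(name, c("M0", "M7", "M8", "M8a", "BSA_null", "BSA_alt"))
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  m <- list(name = name, kappa = kappa, n_categories = as.integer(n_categories))
  if (name == "M0") {
    omega <- omega %||% 0.5
    if (omega < 0) stop("omega must be >= 0", call. = FALSE)
    m$omega <- omega
  } else if (name %in% c("M7", "M8", "M8a")) {
    m$beta_p <- beta_p %||% 1; m$beta_q <- beta_q %||% 2
    if (m$beta_p <= 0 || m$beta_q <= 0)
      stop("beta shape parameters must be > 0", call. = FALSE)
    if (name != "M7") {
      m$p0 <- p0 %||% 0.9
      if (m$p0 < 0 || m$p0 > 1) stop("p0 must be in [0,1]", call. = FALSE)
      m$omega_s <- if (name == "M8a") 1 else (omega_s %||% 2)
      if (m$omega_s < 1) stop("omega_s must be >= 1", call. = FALSE)
    }
  } else { # branch-site A
    m$bs_p0 <- bs_p0 %||% 0.7; m$bs_p1 <- bs_p1 %||% 0.2
    if (m$bs_p0 < 0 || m$bs_p1 < 0 || m$bs_p0 + m$bs_p1 > 1 + 1e-12)
      stop("need bs_p0, bs_p1 >= 0 with bs_p0 + bs_p1 <= 1", call. = FALSE)
    if (m$bs_p0 + m$bs_p1 == 0)
      stop("degenerate branch-site model: bs_p0 + bs_p1 = 0", call. = FALSE)
    m$bs_omega0 <- bs_omega0 %||% 0.1
    if (m$bs_omega0 <= 0 || m$bs_omega0 >= 1)
      stop("bs_omega0 must be in (0,1)", call. = FALSE)
    m$bs_omega2 <- if (name == "BSA_null") 1 else (bs_omega2 %||% 2)
    if (m$bs_omega2 < 1) stop("bs_omega2 must be >= 1", call. = FALSE)
  }
  class(m) <- "site_class_model"
  m
}

#' Realised site-class table of a mixture model
#'
#' Expands a \code{\link{site_class_model}} into its realised mixture: one
#' row per class with (proportion, omega_background, omega_foreground).
#' Beta mixtures use K equal-probability categories represented by the beta
#' quantiles at \eqn{(2k-1)/(2K)}. For branch-site model A the class-2
#' proportions follow the model's proportionality rule
#' \eqn{p_{2a} = (1-p_0-p_1) p_0/(p_0+p_1)},
#' \eqn{p_{2b} = (1-p_0-p_1) p_1/(p_0+p_1)}.
#'
#' @param model a \code{site_class_model}.
#' @return data.frame with columns proportion, omega_background,
#'   omega_foreground; proportions sum to 1.
#' @export
build_site_classes <- function(model) {
  stopifnot(inherits(model, "site_class_model"))
  K <- model$n_categories
  beta_cats <- function() {
    # qbeta can warn about ~1e-3 inversion accuracy at extreme shapes;
    # immaterial for quantile-midpoint category representatives
    w <- suppressWarnings(
      stats::qbeta((2 * seq_len(K) - 1) / (2 * K), model$beta_p, model$beta_q))
    # floor keeps every class able to explain nonsynonymous variation, so
    # mixture likelihoods stay finite across the whole parameter space
    data.frame(proportion = rep(1 / K, K), omega = pmax(w, 1e-6))
  }
  tab <- switch(model$name,
    M0 = data.frame(proportion = 1, omega = model$omega),
    M7 = beta_cats(),
    M8 = , M8a = {
      b <- beta_cats()
      rbind(data.frame(proportion = model$p0 * b$proportion, omega = b$omega),
            data.frame(proportion = 1 - model$p0, omega = model$omega_s))
    },
    BSA_null = , BSA_alt = {
      p0 <- model$bs_p0; p1 <- model$bs_p1
      p2 <- 1 - p0 - p1
      prop <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
      return(data.frame(
        proportion = prop,
        omega_background = c(model$bs_omega0, 1, model$bs_omega0, 1),
        omega_foreground = c(model$bs_omega0, 1, model$bs_omega2,
                             model$bs_omega2)))
    })
  data.frame(proportion = tab$proportion,
             omega_background = tab$omega,
             omega_foreground = tab$omega)
}

#' Free-parameter count of each model (branch lengths excluded)
#'
#' The counts behind LRT degrees of freedom: M0 2 (kappa, omega); M7 3
#' (kappa, p, q); M8a 4 (adds p0); M8 5 (adds omega_s); branch-site A null
#' 4 (kappa, p0, p1, omega0); branch-site A alternative 5 (adds omega2).
#'
#' @param model a \code{site_class_model} or model name.
#' @return integer count.
#' @export
n_free_params <- function(model) {
  name <- if (inherits(model, "site_class_model")) model$name else model
  c(M0 = 2L, M7 = 3L, M8 = 5L, M8a = 4L, BSA_null = 4L, BSA_alt = 5L)[[name]]
}

#' @export
print.site_class_model <- function(x, ...) {
  ps <- setdiff(names(x), c("name", "class"))
  cat("site_class_model", x$name, ":",
      paste(ps, vapply(x[ps], function(v) format(v, digits = 4), ""),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
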