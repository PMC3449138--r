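#' Naive Empirical Bayes site posteriors
#'
#' Class posteriors at the maximum-likelihood estimates:
#' \eqn{P(k \mid h) = p_k L_{h|k} / \sum_j p_j L_{h|j}}. \code{p_positive}
#' is the posterior mass on classes with foreground omega > 1;
#' \code{posterior_mean_omega} averages the class omegas (foreground side,
#' which equals the background side for non-branch-site models).
#'
#' @param fit a converged \code{fit_result}.
#' @return A \code{site_posterior} (method "NEB"): class-posterior matrix
#'   (rows sum to 1), p_positive and posterior_mean_omega per site.
#' @export
neb_posteriors <- function(fit) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  tab <- fit$class_table
  ll <- fit$site_class_loglik
  # same arithmetic path as the BEB grid points, so a one-point BEB grid
  # reproduces NEB bit for bit
  mx <- mix_loglik(ll, tab$proportion, rep(1, nrow(ll)), want_post = TRUE)
  if (any(!is.finite(mx$site)))
    stop("zero total likelihood at site ", which(!is.finite(mx$site))[1],
         call. = FALSE)
  .site_posterior(mx$post, tab, "NEB")
}

.site_posterior <- function(post, tab, method) {
  pos_class <- tab$omega_foreground > 1
  structure(list(
    post = post,
    p_positive = as.numeric(post[, pos_class, drop = FALSE] %*%
                              rep(1, sum(pos_class))),
    posterior_mean_omega = as.numeric(post %*% tab$omega_foreground),
    class_table = tab,
    method = method), class = "site_posterior")
}

#' Bayes Empirical Bayes site posteriors
#'
#' Averages the class posteriors over a uniform prior grid on the mixture
#' parameters that govern the positively selected class, weighting each grid
#' point by its marginal data likelihood; the remaining parameters (kappa,
#' beta shapes / background omega, branch lengths) stay at their MLEs. Grids
#' (\code{grid_resolution} midpoints per axis): M8, p0 on (0,1) and omega_s
#' on (1,11); branch-site A, p0+p1 and p0/(p0+p1) on (0,1) and omega2 on
#' (1,11). \code{grid_resolution = 1} collapses the grid to the MLE point,
#' reproducing \code{\link{neb_posteriors}} exactly. Sites with p_positive
#' > 0.9 are reported "positive", > 0.8 "suggestive".
#'
#' @param fit converged \code{fit_result} for M8 or BSA_alt.
#' @param grid_resolution points per grid axis (default 10).
#' @return A \code{site_posterior} (method "BEB") with a \code{report}
#'   data.frame of sites passing the 0.8/0.9 thresholds.
#' @export
beb_posteriors <- function(fit, grid_resolution = 10L) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  model <- fit$model
  if (!model$name %in% c("M8", "BSA_alt"))
    stop("BEB is defined for M8 and BSA_alt fits only", call. = FALSE)
  G <- as.integer(grid_resolution)
  dat <- fit$dat
  mid <- function(G) (2 * seq_len(G) - 1) / (2 * G)

  if (model$name == "M8") {
    grid <- if (G == 1L) {
      data.frame(p0 = model$p0, ws = model$omega_s)
    } else {
      expand.grid(p0 = mid(G), ws = 1 + 10 * mid(G))
    }
    mk <- function(i) {
      m <- model; m$p0 <- grid$p0[i]; m$omega_s <- grid$ws[i]
      m
    }
  } else {
    grid <- if (G == 1L) {
      data.frame(a = model$bs_p0 + model$bs_p1,
                 r = model$bs_p0 / (model$bs_p0 + model$bs_p1),
                 w2 = model$bs_omega2)
    } else {
      expand.grid(a = mid(G), r = mid(G), w2 = 1 + 10 * mid(G))
    }
    mk <- function(i) {
      m <- model
      m$bs_p0 <- grid$a[i] * grid$r[i]
      m$bs_p1 <- grid$a[i] * (1 - grid$r[i])
      m$bs_omega2 <- grid$w2[i]
      m
    }
  }

  n_grid <- nrow(grid)
  lnl_g <- numeric(n_grid)
  post_acc <- NULL
  posts <- vector("list", n_grid)
  for (i in seq_len(n_grid)) {
    tab <- build_site_classes(mk(i))
    cols <- class_cols(dat, model$kappa, tab)
    mx <- mix_loglik(cols, tab$proportion, dat$weights, want_post = TRUE)
    lnl_g[i] <- mx$lnl
    posts[[i]] <- mx$post
  }
  wlog <- lnl_g - logsumexp(lnl_g)
  w <- exp(wlog)
  post_acc <- if (n_grid == 1L) posts[[1]] else
    Reduce(`+`, Map(function(p, wi) p * wi, posts, w))
  post_full <- post_acc[dat$pattern_of_site, , drop = FALSE]
  # renormalise away round-off accumulated over grid points
  if (n_grid > 1L) post_full <- post_full / rowSums(post_full)
  sp <- .site_posterior(post_full, fit$class_table, "BEB")
  pp <- sp$p_positive
  rep_idx <- which(pp > 0.8)
  sp$report <- data.frame(
    site = rep_idx,
    p_positive = pp[rep_idx],
    level = ifelse(pp[rep_idx] > 0.9, "positive", "suggestive"))
  sp$grid_weights <- w
  sp
}

#' Classify sites and build a selection profile
#'
#' A site is \emph{positive} if its posterior probability of the omega > 1
#' class(es) exceeds \code{p_pos}; otherwise \emph{neutral} if its posterior
#' mean omega lies in [omega_low, omega_high]; otherwise \emph{purifying}.
#' The profile is the frequency of each label, the per-gene coordinate
#' compared across ligand-receptor pairs.
#'
#' @param post a \code{site_posterior}.
#' @param omega_low,omega_high neutral band (defaults 0.9, 1.1).
#' @param p_pos posterior threshold for calling a site positive (default 0.5).
#' @param gene optional gene name attached to the profile.
#' @return list with \code{labels} (factor per site) and \code{profile}
#'   (a \code{\link{selection_profile}}).
#' @export
classify_sites <- function(post, omega_low = 0.9, omega_high = 1.1,
                           p_pos = 0.5, gene = NA_character_) {
  if (!omega_low < omega_high)
    stop("need omega_low < omega_high", call. = FALSE)
  lab <- ifelse(post$p_positive > p_pos, "positive",
                ifelse(post$posterior_mean_omega >= omega_low &
                         post$posterior_mean_omega <= omega_high,
                       "neutral", "purifying"))
  lab <- factor(lab, levels = c("purifying", "neutral", "positive"))
  prof <- selection_profile(
    p_purifying = mean(lab == "purifying"),
    p_neutral = mean(lab == "neutral"),
    p_positive = mean(lab == "positive"),
    gene = gene)
  list(labels = lab, profile = prof)
}

#' Per-gene selection profile
#'
#' Proportions of sites under purifying, neutral and positive selection;
#' must sum to 1.
#'
#' @param p_purifying,p_neutral,p_positive proportions in [0,1].
#' @param gene gene name.
#' @return A \code{selection_profile}.
#' @export
selection_profile <- function(p_purifying, p_neutral, p_positive,
                              gene = NA_character_) {
  v <- c(p_purifying, p_neutral, p_positive)
  if (any(v < -1e-12) || abs(sum(v) - 1) > 1e-9)
    stop("profile proportions must be in [0,1] and sum to 1", call. = FALSE)
  structure(list(gene = gene, p_purifying = p_purifying,
                 p_neutral = p_neutral, p_positive = p_positive),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("selection_profile %s: purifying %.3f, neutral %.3f, positive %.3f\n",
              x$gene, x$p_purifying, x$p_neutral, x$p_positive))
  invisible(x)
}

#' @export
print.site_posterior <- function(x, ...) {
  cat("site_posterior (", x$method, "): ", length(x$p_positive), " sites, ",
      sum(x$p_positive > 0.9), " with p_positive > 0.9\n", sep = "")
  invisible(x)
}
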