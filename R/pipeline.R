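# Orchestration: the full analysis over a set of genes (selection tests ->
# profiles -> coevolution report -> expression integration), driven either
# by in-memory objects (as the analysis/ scripts and tests do) or by a YAML
# config of file paths.

#' Simulate the packaged toy ligand-receptor study
#'
#' Three ligand-receptor pairs on one tree: the first truly coevolving
#' (shared selection profile, jitter 0), the other two with discordant
#' profiles; plus a qPCR Ct table in which each ligand co-expresses with its
#' receptor, most strongly for the coevolving pair. The default scale
#' (6 taxa, 150 codons per gene) keeps a full run to minutes on one CPU.
#'
#' @param seed integer seed.
#' @param n_taxa,n_codons tree and gene size.
#' @param noise_sd Ct noise (cycles).
#' @return list: \code{genes} (named list of \code{codon_alignment}s),
#'   \code{tree}, \code{true_profiles}, \code{hypotheses} (data.frame
#'   ligand, receptor), \code{coevolving_pair}, \code{expression}
#'   (an \code{expression_table}).
#' @export
simulate_toy_study <- function(seed = 1L, n_taxa = 6L, n_codons = 150L,
                               noise_sd = 0.2) {
  profs <- list(
    rln3  = c(0.75, 0.20, 0.05), rxfp3 = c(0.75, 0.20, 0.05), # coevolving
    insl5 = c(0.50, 0.45, 0.05), rxfp4 = c(0.92, 0.06, 0.02),
    rln   = c(0.70, 0.12, 0.18), rxfp1 = c(0.88, 0.10, 0.02))
  hyp <- data.frame(ligand = c("rln3", "insl5", "rln"),
                    receptor = c("rxfp3", "rxfp4", "rxfp1"))
  with_seed(seed, {
    tree <- sample_tree(n_taxa, mean_branch_length = 0.25)
    freqs <- uniform_frequencies()
    genes <- lapply(names(profs), function(g) {
      tab <- data.frame(proportion = profs[[g]],
                        omega_background = c(0.1, 1, 3),
                        omega_foreground = c(0.1, 1, 3))
      attr(tab, "kappa") <- 2
      simulate_alignment(tree, tab, freqs, n_codons)$alignment
    })
    names(genes) <- names(profs)

    tissues <- c("heart", "intestine", "gonad", "muscle", "gill", "brain",
                 "eye")
    base_expr <- function() 2^stats::runif(length(tissues), -2, 4)
    expr <- matrix(NA_real_, length(profs), length(tissues),
                   dimnames = list(names(profs), tissues))
    for (i in seq_len(nrow(hyp))) {
      lig <- base_expr()
      # receptor tracks its ligand across tissues, tightly for the
      # coevolving pair, loosely otherwise
      wob <- if (i == 1L) 0.3 else 1.5
      rec <- lig * 2^stats::rnorm(length(tissues), 0, wob)
      expr[hyp$ligand[i], ] <- lig
      expr[hyp$receptor[i], ] <- rec
    }
    ct <- simulate_ct_table(expr, noise_sd)
    list(genes = genes, tree = tree,
         true_profiles = lapply(stats::setNames(names(profs), names(profs)),
           function(g) selection_profile(profs[[g]][1], profs[[g]][2],
                                         profs[[g]][3], g)),
         hypotheses = hyp, coevolving_pair = hyp[1, ],
         expression = ct)
  })
}

#' Run the selection scan over a set of genes
#'
#' For each gene: the M7/M8/M8a positive-selection protocol
#' (\code{\link{positive_selection_test}}), a branch-site test when the
#' gene's tree carries foreground tags, and a selection profile classified
#' from the gene's site posteriors (BEB when the verdict is positive, NEB of
#' the M8 fit otherwise).
#'
#' @param genes named list of \code{codon_alignment}s, or of lists with
#'   elements \code{aln} and \code{tree}.
#' @param tree default tree for genes given as bare alignments.
#' @param alpha significance level.
#' @param options fit options (n_restarts, tol, seed, n_categories,
#'   grid_resolution).
#' @param thresholds list(omega_low, omega_high, p_pos) for site
#'   classification.
#' @param out_dir optional directory; tables are written there via
#'   \code{\link{write_report}}.
#' @return list: \code{calls} (per-gene \code{selection_call}s),
#'   \code{profiles} (named \code{selection_profile}s), \code{posteriors},
#'   \code{tables} (fits, lrts, profiles, sites data.frames).
#' @export
run_selection <- function(genes, tree = NULL, alpha = 0.05, options = list(),
                          thresholds = list(), out_dir = NULL) {
  th <- utils::modifyList(list(omega_low = 0.9, omega_high = 1.1,
                               p_pos = 0.5), thresholds)
  calls <- list(); profiles <- list(); posteriors <- list()
  fit_rows <- list(); lrt_rows <- list(); site_rows <- list()
  skipped <- character(0)
  for (g in names(genes)) {
    item <- genes[[g]]
    aln <- if (inherits(item, "codon_alignment")) item else item$aln
    tr <- if (inherits(item, "codon_alignment")) tree else
      (item$tree %||% tree)
    res <- tryCatch({
      call <- positive_selection_test(aln, tr, alpha = alpha,
                                      options = options)
      post <- call$beb %||% neb_posteriors(call$fits$M8)
      cl <- classify_sites(post, th$omega_low, th$omega_high, th$p_pos,
                           gene = g)
      list(call = call, post = post, cl = cl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, g)
      message("gene '", g, "' skipped: ", conditionMessage(res))
      next
    }
    calls[[g]] <- res$call
    posteriors[[g]] <- res$post
    profiles[[g]] <- res$cl$profile
    for (mn in c("M7", "M8a", "M8")) {
      f <- res$call$fits[[mn]]
      fit_rows[[paste(g, mn)]] <- data.frame(
        gene = g, model = mn, lnL = f$lnL,
        n_free_params = f$n_free_params, converged = f$converged,
        n_restarts_used = f$n_restarts_used,
        params = paste(sprintf("%s=%.4g",
          setdiff(names(f$model), c("name", "n_categories")),
          unlist(f$model[setdiff(names(f$model),
                                 c("name", "n_categories"))])),
          collapse = ";"))
    }
    if (!is.null(res$call$lrt_m7_m8)) {
      for (l in list(res$call$lrt_m7_m8, res$call$lrt_m8a_m8))
        lrt_rows[[paste(g, l$null_model)]] <- data.frame(
          gene = g, null_model = l$null_model, alt_model = l$alt_model,
          stat = l$stat, df = l$df, p_value = l$p_value,
          verdict = res$call$verdict)
    }
    site_rows[[g]] <- data.frame(
      gene = g, site = seq_along(res$post$p_positive),
      p_positive = res$post$p_positive,
      mean_omega = res$post$posterior_mean_omega,
      label = as.character(res$cl$labels), method = res$post$method)
  }
  prof_tab <- do.call(rbind, lapply(names(profiles), function(g)
    data.frame(gene = g, p_purifying = profiles[[g]]$p_purifying,
               p_neutral = profiles[[g]]$p_neutral,
               p_positive = profiles[[g]]$p_positive,
               verdict = calls[[g]]$verdict)))
  tables <- list(fits = do.call(rbind, unname(fit_rows)),
                 lrts = do.call(rbind, unname(lrt_rows)),
                 selection_profiles = prof_tab,
                 sites = do.call(rbind, unname(site_rows)))
  if (!is.null(out_dir)) write_report(tables, out_dir)
  list(calls = calls, profiles = profiles, posteriors = posteriors,
       tables = tables, skipped = skipped)
}

#' Build the coevolution / pairing report
#'
#' For each hypothesised (ligand, receptor) pair: profile-concordance
#' distance, optional coexpression score, and combined score
#' \code{w1 (1 - distance) + w2 coexpression}; per-ligand candidate rankings
#' via \code{\link{rank_candidate_receptors}}; region summaries for genes
#' with domain annotations. Hypotheses naming unknown genes are listed under
#' \code{unresolved}, not fatal.
#'
#' @param selection result of \code{\link{run_selection}} (or a named list
#'   of \code{selection_profile}s via \code{profiles =}).
#' @param hypotheses data.frame(ligand, receptor).
#' @param expression optional \code{relative_expression} data.frame (from
#'   \code{\link{delta_delta_ct}}) for coexpression scoring.
#' @param annotations optional \code{domain_annotation}; regions are
#'   summarised for annotated genes present in the posteriors.
#' @param weights c(w1, w2) for the combined score.
#' @param p_threshold selected-site threshold for region mapping.
#' @param out_dir optional report directory.
#' @return list: \code{pairs} (scored pair table, best first),
#'   \code{rankings} (per-ligand), \code{regions}, \code{unresolved}.
#' @export
run_coevolution <- function(selection, hypotheses, expression = NULL,
                            annotations = NULL, weights = c(1, 1),
                            p_threshold = 0.5, out_dir = NULL) {
  profiles <- if (!is.null(selection$profiles)) selection$profiles
              else selection
  known <- names(profiles)
  ok <- hypotheses$ligand %in% known & hypotheses$receptor %in% known
  unresolved <- hypotheses[!ok, , drop = FALSE]
  hyp <- hypotheses[ok, , drop = FALSE]

  coex <- function(lig, rec) {
    if (is.null(expression)) return(NA_real_)
    tryCatch(as.numeric(coexpression_score(
      expression[expression$gene == lig, ],
      expression[expression$gene == rec, ])), error = function(e) NA_real_)
  }
  pairs <- do.call(rbind, lapply(seq_len(nrow(hyp)), function(i) {
    d <- pair_concordance(profiles[[hyp$ligand[i]]],
                          profiles[[hyp$receptor[i]]])
    cx <- coex(hyp$ligand[i], hyp$receptor[i])
    data.frame(ligand = hyp$ligand[i], receptor = hyp$receptor[i],
               concordance_distance = d, coexpression = cx,
               score = weights[1] * (1 - d) +
                 (if (is.na(cx)) 0 else weights[2] * cx))
  }))
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$score, pairs$ligand), ]
    rownames(pairs) <- NULL
  }

  rankings <- lapply(stats::setNames(unique(hyp$ligand), unique(hyp$ligand)),
    function(lig) {
      recs <- hyp$receptor[hyp$ligand == lig]
      cx <- if (is.null(expression)) NULL else
        stats::setNames(vapply(recs, coex, 0, lig = lig), recs)
      if (!is.null(cx)) cx[is.na(cx)] <- 0
      rank_candidate_receptors(profiles[[lig]], profiles[recs],
                               coexpr = cx, weights = weights)
    })

  regions <- NULL
  if (!is.null(annotations) && !is.null(selection$posteriors)) {
    gs <- intersect(unique(annotations$gene), names(selection$posteriors))
    regions <- do.call(rbind, lapply(gs, function(g)
      region_selection_fraction(selection$posteriors[[g]],
                                annotations[annotations$gene == g, ],
                                p_threshold)))
  }
  out <- list(pairs = pairs, rankings = rankings, regions = regions,
              unresolved = unresolved)
  if (!is.null(out_dir)) {
    tabs <- list(pair_concordance = pairs %||% data.frame())
    if (!is.null(regions)) tabs$region_summary <- regions
    write_report(tabs, out_dir)
  }
  out
}

#' Read and validate a YAML run configuration
#'
#' Fields: \code{genes} (list of name/alignment/tree paths), optional
#' \code{annotations}, \code{ct}, \code{reference}, \code{rna_yield} paths,
#' \code{pairs} (ligand/receptor hypotheses), \code{out_dir}, and
#' \code{options}/\code{thresholds} overriding the fitting and
#' classification defaults. All referenced files must exist.
#'
#' @param path YAML file.
#' @return validated config list with loaded objects under \code{objects}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  for (g in cfg$genes) {
    for (f in c(g$alignment, g$tree))
      if (!file.exists(resolve(f)))
        stop("config references missing file: ", f, call. = FALSE)
  }
  th <- cfg$thresholds %||% list()
  for (t in c("alpha", "p_pos", "p_threshold"))
    if (!is.null(th[[t]]) && (th[[t]] <= 0 || th[[t]] >= 1))
      stop("threshold ", t, " must be in (0,1)", call. = FALSE)
  objects <- list()
  for (g in cfg$genes) {
    objects[[g$name]] <- list(
      aln = read_codon_alignment(resolve(g$alignment)),
      tree = read_newick(resolve(g$tree)))
  }
  ann <- NULL
  if (!is.null(cfg$annotations))
    ann <- read_domain_annotation(resolve(cfg$annotations))
  cfg$objects <- list(genes = objects, annotations = ann)
  cfg
}
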