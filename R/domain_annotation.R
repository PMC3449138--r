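#' Read a receptor-domain annotation table
#'
#' Reads a TSV with columns \code{gene, region, start, end} giving 1-based
#' inclusive codon coordinates of receptor regions (LDLa, LRR, TM1..TM7,
#' ICL1..ICL3, ECL1..ECL3, other). Intervals must be non-overlapping within a
#' gene; regions are returned sorted by start.
#'
#' @param path TSV file.
#' @return A \code{domain_annotation}: data.frame with the four columns,
#'   sorted by (gene, start).
#' @export
read_domain_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  domain_annotation(d)
}

#' Validate a domain annotation data.frame
#'
#' @param d data.frame with columns gene, region, start, end.
#' @return The validated, sorted \code{domain_annotation}.
#' @export
domain_annotation <- function(d) {
  need <- c("gene", "region", "start", "end")
  if (!all(need %in% names(d)))
    stop("annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  if (any(d$start < 1L)) stop("codon coordinates are 1-based", call. = FALSE)
  if (any(d$end < d$start))
    stop("end < start in region '", d$region[which(d$end < d$start)[1]], "'",
         call. = FALSE)
  d <- d[order(d$gene, d$start), , drop = FALSE]
  for (g in unique(d$gene)) {
    dg <- d[d$gene == g, ]
    if (nrow(dg) > 1L && any(dg$start[-1] <= dg$end[-nrow(dg)]))
      stop("overlapping regions in gene '", g, "'", call. = FALSE)
  }
  rownames(d) <- NULL
  class(d) <- c("domain_annotation", "data.frame")
  d
}
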