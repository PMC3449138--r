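#' Codon alignment container
#'
#' A \code{codon_alignment} stores an in-frame coding-sequence alignment as a
#' taxa x codon-site matrix of sense-codon indices (1..61, in T<C<A<G order;
#' see \code{\link{standard_genetic_code}}). Gapped or ambiguous triplets are
#' stored as \code{NA} (missing) and are marginalised over all sense codons
#' during likelihood computation, so site indexing is preserved for site
#' posteriors and domain mapping.
#'
#' @param sites integer matrix [n_taxa x n_codon_sites] of 1-based sense-codon
#'   indices, \code{NA} for missing.
#' @param taxon_names character vector of unique row names.
#' @param code a \code{genetic_code}.
#' @return A validated \code{codon_alignment}.
#' @export
codon_alignment <- function(sites, taxon_names, code = standard_genetic_code()) {
  sites <- as.matrix(sites)
  storage.mode(sites) <- "integer"
  if (nrow(sites) < 2L)
    stop("a codon alignment needs at least 2 taxa", call. = FALSE)
  if (anyDuplicated(taxon_names))
    stop("duplicate taxon name: ",
         paste(unique(taxon_names[duplicated(taxon_names)]), collapse = ", "),
         call. = FALSE)
  if (length(taxon_names) != nrow(sites))
    stop("taxon_names length must match number of rows", call. = FALSE)
  ok <- is.na(sites) | (sites >= 1L & sites <= length(code$sense_codons))
  if (!all(ok))
    stop("codon indices must be in 1..", length(code$sense_codons),
         " or NA", call. = FALSE)
  rownames(sites) <- taxon_names
  structure(list(sites = sites, taxon_names = taxon_names,
                 n_codon_sites = ncol(sites),
                 source_nucleotide_length = 3L * ncol(sites),
                 code = code),
            class = "codon_alignment")
}

#' Read a codon-aligned FASTA file
#'
#' Parses an aligned CDS FASTA into a \code{\link{codon_alignment}}. Triplets
#' containing \code{-} or any non-ACGT character become missing cells; an
#' internal stop codon is an error (it would have zero likelihood under any
#' sense-codon model), except that a terminal stop shared at the last site is
#' also rejected -- strip stop codons before aligning.
#'
#' @param path FASTA file of equal-length, in-frame coding sequences.
#' @param code a \code{genetic_code}.
#' @return A \code{codon_alignment}.
#' @export
read_codon_alignment <- function(path, code = standard_genetic_code()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- .read_fasta(path)
  if (length(seqs) < 2L)
    stop("alignment must contain at least 2 sequences", call. = FALSE)
  codon_alignment_from_strings(seqs, code)
}

#' Build a codon alignment from named character strings
#'
#' @param seqs named character vector of aligned nucleotide sequences.
#' @param code a \code{genetic_code}.
#' @return A \code{codon_alignment}.
#' @export
codon_alignment_from_strings <- function(seqs, code = standard_genetic_code()) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: unequal lengths (",
         paste(range(lens), collapse = "-"), ")", call. = FALSE)
  if (lens[1] %% 3L != 0L)
    stop("alignment length ", lens[1], " is not divisible by 3 (frame error)",
         call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon name: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  n_sites <- lens[1] %/% 3L
  sense_idx <- stats::setNames(seq_along(code$sense_codons), code$sense_codons)
  sites <- matrix(NA_integer_, length(seqs), n_sites)
  for (k in seq_along(seqs)) {
    s <- toupper(chartr("U", "T", seqs[[k]]))
    trip <- substring(s, 3L * seq_len(n_sites) - 2L, 3L * seq_len(n_sites))
    clean <- grepl("^[ACGT]{3}$", trip)
    stop_hit <- clean & trip %in% code$stop_codons
    if (any(stop_hit))
      stop("stop codon ", trip[which(stop_hit)[1]], " in taxon '",
           names(seqs)[k], "' at codon position ", which(stop_hit)[1],
           call. = FALSE)
    sites[k, clean] <- sense_idx[trip[clean]]
  }
  codon_alignment(sites, names(seqs), code)
}

#' Write a codon alignment to FASTA
#'
#' Missing cells are written as \code{---}, so write/read round-trips
#' reproduce the in-memory object exactly.
#'
#' @param aln a \code{codon_alignment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  sense <- aln$code$sense_codons
  lines <- character(0)
  for (k in seq_len(nrow(aln$sites))) {
    trip <- ifelse(is.na(aln$sites[k, ]), "---", sense[aln$sites[k, ]])
    lines <- c(lines, paste0(">", aln$taxon_names[k]),
               paste(trip, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

# minimal FASTA reader (multi-line records, no dependencies on sequence class)
.read_fasta <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  hdr <- grepl("^>", raw)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  id <- cumsum(hdr)
  nm <- sub("^>\\s*", "", raw[hdr])
  nm <- sub("\\s.*$", "", nm)
  seqs <- vapply(split(raw[!hdr], id[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  stats::setNames(unname(seqs), nm)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", nrow(x$sites), "taxa x", x$n_codon_sites,
      "codon sites;", sum(is.na(x$sites)), "missing cells\n")
  invisible(x)
}
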