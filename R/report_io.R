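#' Write named result tables to a report directory
#'
#' Writes each table as a tab-separated file \code{<name>.tsv} under
#' \code{out_dir} and returns a manifest of file names and row counts.
#' Output is deterministic: the same tables always produce byte-identical
#' files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a manifest data.frame (file, n_rows). Also written as
#'   \code{manifest.tsv}.
#' @export
write_report <- function(tables, out_dir) {
  if (length(tables) == 0L || is.null(names(tables)) ||
      any(!nzchar(names(tables))))
    stop("tables must be a nonempty named list", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create: ", out_dir, call. = FALSE)
  files <- character(0); rows <- integer(0)
  for (nm in sort(names(tables))) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, basename(f)); rows <- c(rows, nrow(tables[[nm]]))
  }
  manifest <- data.frame(file = files, n_rows = rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
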