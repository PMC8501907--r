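# Figure export: write a list of ggplots either as one JPEG per figure or
# compiled into a single multi-page PDF.

#' Export a list of graphs
#'
#' @param figures non-empty (optionally named) list of ggplot objects, e.g.
#'   from `compile_data(fits, "graphs")`.
#' @param format `"jpeg"` (one file per figure) or `"pdf"` (one multi-page
#'   document).
#' @param destination existing writable directory for the output files.
#' @param base_name file-name stem; figure names (or indices) are appended
#'   for JPEG output.
#' @param width,height,dpi device settings (inches / dots per inch).
#' @return Character vector of the files written, invisibly.
#' @export
print_graphs <- function(figures, format = c("jpeg", "pdf"), destination,
                         base_name = "graph", width = 6, height = 4,
                         dpi = 150) {
  format <- match.arg(format)
  if (length(figures) == 0) abort("empty figure collection")
  if (inherits(figures, "ggplot")) figures <- list(figures)
  if (!dir.exists(destination) ||
        file.access(destination, mode = 2) != 0) {
    abort(paste0("destination is not a writable directory: ", destination))
  }
  nms <- names(figures)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- paste0(base_name, "_", seq_along(figures))
  }
  if (format == "jpeg") {
    paths <- file.path(destination, paste0(nms, ".jpeg"))
    for (i in seq_along(figures)) {
      ggsave(paths[i], figures[[i]], width = width, height = height,
             dpi = dpi)
    }
    invisible(paths)
  } else {
    path <- file.path(destination, paste0(base_name, ".pdf"))
    grDevices::pdf(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    for (fig in figures) print(fig)
    invisible(path)
  }
}
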