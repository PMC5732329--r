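`%||%` <- function(a, b) if (is.null(a)) b else a

#' Atomic file write
#'
#' Writes through a temporary file in the destination directory and renames it
#' into place, so an interrupted run never leaves a truncated output file.
#'
#' @param path destination path.
#' @param writer function of one argument (a path) that performs the write.
#' @return `path`, invisibly.
#' @export
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file into place at ", path)
  }
  invisible(path)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

stop_unknown_ui <- function(ui) {
  stop("unknown descriptor ui: ", paste(ui, collapse = ", "), call. = FALSE)
}
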