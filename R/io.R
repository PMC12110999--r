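# Reading and writing IBD segment sets and packaged fixtures.

#' Read / write IBD segment sets
#'
#' Tab-delimited text with header columns `chromosome`, `start_cM`,
#' `end_cM`, `ibd_state`; one row per constant-state segment. Reading
#' validates tiling and alternation; writing rounds coordinates to two
#' decimals by default (full precision with `digits = NA`). A written and
#' re-read full-precision set is structurally identical.
#'
#' @param path file path.
#' @param map optional [genetic_map()] to validate against; default
#'   chromosome lengths are taken from the last segment end.
#' @return an [ibd_segments()] object; an empty file (header only) gives
#'   an empty set.
#' @export
read_segments <- function(path, map = NULL) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) validation_error(paste0("cannot parse '", path,
                                                "': ", conditionMessage(e))))
  need <- c("chromosome", "start_cM", "end_cM", "ibd_state")
  if (!all(need %in% names(tab))) {
    validation_error(paste0("'", path, "' lacks required columns: ",
                            paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  for (col in c("start_cM", "end_cM", "ibd_state")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v) && nrow(tab)) {
      validation_error(sprintf("malformed value in column %s, line %d of %s",
                               col, which(is.na(v))[1] + 1L, path))
    }
    tab[[col]] <- v
  }
  tab$ibd_state <- as.integer(tab$ibd_state)
  ibd_segments(tab, map = map)
}

#' @param segs an [ibd_segments()] object.
#' @param digits decimal places for coordinates on output (default 2,
#'   `NA` keeps full precision).
#' @rdname read_segments
#' @export
write_segments <- function(segs, path, digits = 2) {
  stopifnot(inherits(segs, "ibd_segments"))
  out <- as.data.frame(segs)[, c("chromosome", "start_cM", "end_cM",
                                 "ibd_state")]
  if (!is.na(digits)) {
    out$start_cM <- round(out$start_cM, digits)
    out$end_cM <- round(out$end_cM, digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the packaged fixtures
#'
#' Writes the 22-chromosome default genetic map (total 3391.36 cM), the
#' 2-chromosome toy map, and example simulated segment sets for GP, HS,
#' N and 1C at seeds derived from `seed`.
#'
#' @param outdir writable directory (created if missing).
#' @param seed base seed for the example segment sets.
#' @return invisibly, the paths written.
#' @export
generate_fixtures <- function(outdir, seed = 1L) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(outdir, "genetic_map_autosomal.tsv")
  write_genetic_map(default_genetic_map(), p); paths <- c(paths, p)
  p <- file.path(outdir, "toy_map.tsv")
  write_genetic_map(toy_genetic_map(), p); paths <- c(paths, p)
  for (rel in c("GP", "HS", "N", "1C")) {
    segs <- simulate_ibd(rel, default_genetic_map(), seed = seed)
    p <- file.path(outdir, paste0("segments_", rel, ".tsv"))
    write_segments(segs, p, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
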