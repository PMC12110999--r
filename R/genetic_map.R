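#' Genetic maps of autosomal chromosome lengths
#'
#' A `genetic_map` is a data frame with columns `chromosome` and
#' `length_cM`. The packaged default map has 22 autosomes whose lengths
#' are proportional to a published sex-averaged human linkage map,
#' rescaled so that the total is exactly 3391.36 cM (so that a
#' relationship with kappa1 = 1/2 is expected to share 1695.68 cM).
#'
#' @param lengths numeric vector of chromosome lengths in cM.
#' @param chromosome chromosome labels (default `1:length(lengths)`).
#' @return a data frame of class `genetic_map`.
#' @export
genetic_map <- function(lengths, chromosome = seq_along(lengths)) {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    validation_error("all chromosome lengths must be positive and finite")
  }
  if (length(chromosome) != length(lengths)) {
    validation_error("chromosome and lengths differ in length")
  }
  structure(data.frame(chromosome = as.character(chromosome),
                       length_cM = lengths, stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

# Sex-averaged autosomal lengths (cM), proportional to a published human
# linkage map and rescaled to total exactly 3391.36 cM. The rescale pins
# the genome-wide expectation kappa1 * 3391.36 of total IBD.
map_base_lengths <- c(
  279.4, 263.2, 224.3, 214.4, 209.2, 194.1, 187.4, 169.7, 167.2, 174.1,
  161.1, 176.3, 131.9, 125.2, 132.4, 133.8, 137.3, 126.6, 109.9, 100.8,
  62.8, 74.1)

#' @rdname genetic_map
#' @export
default_genetic_map <- function() {
  genetic_map(map_base_lengths * (3391.36 / sum(map_base_lengths)))
}

#' @rdname genetic_map
#' @details `toy_genetic_map()` is a small 2-chromosome map (100 and 50
#'   cM) for fast tests and examples.
#' @export
toy_genetic_map <- function() {
  genetic_map(c(100, 50))
}

#' Read / write a genetic map
#'
#' Tab-delimited text with header columns `chromosome` and `length_cM`.
#' The string `"fixture"` (or `"toy"`) returns the packaged maps.
#'
#' @param path file path, or `"fixture"` / `"toy"`.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  if (identical(path, "fixture")) return(default_genetic_map())
  if (identical(path, "toy")) return(toy_genetic_map())
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chromosome", "length_cM") %in% names(tab))) {
    validation_error("genetic map file needs columns 'chromosome' and 'length_cM'")
  }
  genetic_map(tab$length_cM, tab$chromosome)
}

#' @param map a [genetic_map()].
#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_genetic_map <- function(map) {
  if (inherits(map, "genetic_map")) return(map)
  if (is.character(map) && length(map) == 1L) return(read_genetic_map(map))
  if (is.numeric(map)) return(genetic_map(map))
  validation_error("cannot interpret object as a genetic map")
}
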