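#' Build a back-splice junction identifier
#'
#' Junction IDs follow the `chrom:start|end:strand` convention with 0-based,
#' half-open coordinates, so an ID round-trips losslessly through
#' [parse_junction_id()].
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start of the circularised interval.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of junction IDs.
#' @export
#' @examples
#' junction_id("chr1", 1000, 5000, "+")
junction_id <- function(chrom, start, end, strand) {
  stopifnot(all(start < end), all(start >= 0), all(strand %in% c("+", "-")))
  sprintf("%s:%d|%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Parse junction identifiers back to coordinates
#'
#' @param ids Character vector of `chrom:start|end:strand` IDs.
#' @return A data.frame with columns `junction_id`, `chrom`, `start`, `end`,
#'   `strand` (coordinates 0-based half-open).
#' @export
parse_junction_id <- function(ids) {
  m <- regmatches(ids, regexec("^([^:]+):([0-9]+)\\|([0-9]+):([+-])$", ids))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("malformed junction ID: ", ids[which(bad)[1]])
  }
  out <- data.frame(
    junction_id = ids,
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) {
    stop("junction ID with start >= end: ", out$junction_id[out$start >= out$end][1])
  }
  out
}
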