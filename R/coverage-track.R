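#' Per-base coverage track
#'
#' A `coverage_track` holds dense per-base occupancy values for each
#' chromosome of a genome, together with its processing state (`"raw"`,
#' `"rpm"` or `"smoothed"`), the total number of mapped reads used for
#' normalization, and the count of chromosome-edge reads whose dyad interval
#' was dropped (clipped) during accumulation.
#'
#' Positions are 0-based: the value at 0-based position `p` on chromosome
#' `chrom` is `values[[chrom]][p + 1]`.
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome; vector length is the chromosome length in bp.
#' @param state Processing state, one of `"raw"`, `"rpm"`, `"smoothed"`.
#' @param total_mapped Total mapped reads behind the track (used for RPM).
#' @param clipped Number of reads whose dyad interval fell off a chromosome
#'   end and was excluded from accumulation.
#'
#' @return An object of class `coverage_track`.
#' @seealso [build_coverage()], [normalize_rpm()], [smooth_track()]
#' @export
coverage_track <- function(values, state = c("raw", "rpm", "smoothed"),
                           total_mapped = NA_integer_, clipped = 0L) {
  state <- match.arg(state)
  if (!is.list(values) || is.null(names(values)) || any(names(values) == "")) {
    abort("`values` must be a named list of per-chromosome numeric vectors")
  }
  if (anyDuplicated(names(values))) abort("chromosome names must be unique")
  ok <- vapply(values, is.numeric, logical(1))
  if (!all(ok)) abort("all track values must be numeric")
  structure(
    list(values = values, state = state,
         total_mapped = total_mapped, clipped = as.integer(clipped)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  lens <- vapply(x$values, length, integer(1))
  cat(sprintf("<coverage_track> state=%s | %d chromosome(s), %s bp total\n",
              x$state, length(lens), format(sum(lens), big.mark = ",")))
  cat(sprintf("  total_mapped=%s, clipped=%d\n",
              format(x$total_mapped, big.mark = ","), x$clipped))
  invisible(x)
}

track_state <- function(track) track$state

#' Chromosome lengths of a track or genome table
#'
#' @param x A `coverage_track` or a genome tibble with columns `chrom`,
#'   `length`.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(x) {
  if (inherits(x, "coverage_track")) {
    return(vapply(x$values, length, integer(1)))
  }
  if (is.data.frame(x) && all(c("chrom", "length") %in% names(x))) {
    return(setNames(as.integer(x$length), x$chrom))
  }
  abort("cannot extract chromosome lengths from this object")
}

# Extract track values over 0-based half-open interval [start, end),
# clipping to chromosome bounds.
track_slice <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) abort(sprintf("chromosome '%s' not in track", chrom))
  start <- max(start, 0L)
  end <- min(end, length(v))
  if (end <= start) return(numeric(0))
  v[(start + 1):end]
}

#' @describeIn coverage_track Long-format view of a track.
#' @param x A `coverage_track`.
#' @param chrom Optional chromosome name(s) to restrict to.
#' @param ... Unused.
#' @method tidy coverage_track
#' @export
tidy.coverage_track <- function(x, chrom = NULL, ...) {
  keep <- if (is.null(chrom)) names(x$values) else intersect(chrom, names(x$values))
  purrr::imap(x$values[keep], function(v, nm) {
    tibble(chrom = nm, pos = seq_along(v) - 1L, value = v)
  }) |> purrr::list_rbind()
}

#' @describeIn coverage_track One-row summary of a track.
#' @method glance coverage_track
#' @export
glance.coverage_track <- function(x, ...) {
  lens <- chrom_lengths(x)
  allv <- unlist(x$values, use.names = FALSE)
  tibble(
    state = x$state,
    n_chrom = length(lens),
    genome_bp = sum(lens),
    total_mapped = x$total_mapped,
    clipped = x$clipped,
    total_coverage = sum(allv),
    max_value = if (length(allv)) max(allv) else NA_real_
  )
}
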