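#' Call nucleosome dyads as local maxima of a smoothed track
#'
#' A candidate dyad is a strict local maximum of the smoothed signal
#' (plateaus report their leftmost index). Candidates below `min_height`
#' are discarded; among candidates closer than `min_separation` the higher
#' one wins (equal heights: the leftmost). Calling on raw or RPM tracks is
#' refused — unsmoothed per-base coverage is too noisy for maxima to mean
#' dyads.
#'
#' @param track A smoothed `coverage_track`.
#' @param min_height Minimum peak height; default 0.1 x the track's 90th
#'   percentile.
#' @param min_separation Minimum distance (bp) between retained calls.
#' @return Tibble with columns `chrom`, `dyad` (0-based bp), `height`,
#'   `width_at_half_height`.
#' @export
call_peaks <- function(track, min_height = NULL, min_separation = 120) {
  if (track_state(track) != "smoothed") {
    abort("call_peaks requires a smoothed track (run smooth_track() first)")
  }
  if (is.null(min_height)) {
    allv <- unlist(track$values, use.names = FALSE)
    min_height <- 0.1 * quantile(allv, 0.9, names = FALSE)
  }
  res <- purrr::imap(track$values, function(v, cn) {
    pk <- find_peaks(v)
    if (length(pk) == 0) return(NULL)
    h <- v[pk]
    keep <- h >= min_height & h > 0
    pk <- pk[keep]; h <- h[keep]
    if (length(pk) == 0) return(NULL)
    sel <- enforce_separation(pk, h, min_separation)
    pk <- pk[sel]; h <- h[sel]
    o <- order(pk)
    pk <- pk[o]; h <- h[o]
    w <- vapply(seq_along(pk), function(i) half_height_width(v, pk[i]), numeric(1))
    tibble(chrom = cn, dyad = pk - 1L, height = h, width_at_half_height = w)
  })
  out <- purrr::list_rbind(purrr::compact(res))
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), dyad = integer(), height = numeric(),
                  width_at_half_height = numeric())
  }
  out
}

# Strict local maxima with plateau handling (leftmost index of a plateau
# higher than both flanking runs). Boundary runs are never peaks.
find_peaks <- function(v) {
  r <- rle(v)
  nr <- length(r$values)
  if (nr < 3) return(integer(0))
  idx <- cumsum(c(1L, r$lengths[-nr]))  # leftmost index of each run
  mid <- 2:(nr - 1)
  is_peak <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  idx[mid][is_peak]
}

# Greedy height-then-leftmost selection under a minimum-separation rule.
enforce_separation <- function(pos, height, min_sep) {
  o <- order(-height, pos)
  kept <- integer(0)
  sel <- logical(length(pos))
  for (i in o) {
    if (all(abs(pos[i] - kept) >= min_sep)) {
      kept <- c(kept, pos[i])
      sel[i] <- TRUE
    }
  }
  sel
}

# Width (bp) at half the peak height, measured on the smoothed signal.
half_height_width <- function(v, i, max_reach = 1000L) {
  half <- v[i] / 2
  lo <- max(1L, i - max_reach); hi <- min(length(v), i + max_reach)
  left <- i
  while (left > lo && v[left - 1L] >= half) left <- left - 1L
  right <- i
  while (right < hi && v[right + 1L] >= half) right <- right + 1L
  as.numeric(right - left + 1L)
}

#' Mean occupancy around a position
#'
#' Mean of the track over the half-open window `[position - halfwidth,
#' position + halfwidth)`, clipped to chromosome bounds.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param position 0-based bp.
#' @param halfwidth Half-width (bp), must be >= 1.
#' @return Mean occupancy (numeric scalar).
#' @export
occupancy_at <- function(track, chrom, position, halfwidth) {
  if (halfwidth < 1) abort("halfwidth must be >= 1 (empty interval)")
  v <- track_slice(track, chrom, position - halfwidth, position + halfwidth)
  if (length(v) == 0) abort("window falls entirely outside the chromosome")
  mean(v)
}

#' Detect promoter nucleosome-depleted regions
#'
#' Per gene, scans the strand-aware promoter window from 1000 bp upstream to
#' 200 bp downstream of the TSS for maximal runs of bases whose occupancy
#' falls below `rel_threshold` times the median occupancy of the gene's
#' +/-2 kb TSS window. Runs at least `min_width` bp wide qualify; the run
#' overlapping the CRE site (or, failing that, the nearest one) is reported.
#' The threshold is relative to a local median because the RPM scale varies
#' with library size.
#'
#' @param track A smoothed `coverage_track`.
#' @param genes Gene model tibble.
#' @param rel_threshold Fraction of the local median defining depletion.
#' @param min_width Minimum NDR width (bp).
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `width`, `min_value`, `threshold`; genes without a
#'   qualifying run are absent.
#' @export
detect_ndr <- function(track, genes, rel_threshold = 0.5, min_width = 80) {
  res <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    L <- length(track$values[[g$chrom]])
    if (is.null(track$values[[g$chrom]])) return(NULL)
    win <- if (g$strand == "+") c(g$tss - 1000, g$tss + 200)
           else c(g$tss - 200, g$tss + 1000)
    win <- pmin(pmax(win, 0), L)
    med_win <- track_slice(track, g$chrom, g$tss - 2000, g$tss + 2000)
    thr <- rel_threshold * median(med_win)
    x <- track_slice(track, g$chrom, win[1], win[2])
    if (length(x) == 0) return(NULL)
    r <- rle(x < thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= min_width
    if (!any(ok)) return(NULL)
    runs <- tibble(start = win[1] + starts[ok] - 1L,
                   end = win[1] + ends[ok])
    anchor <- if (is.na(g$cre_site)) g$tss else g$cre_site
    overlaps <- anchor >= runs$start & anchor < runs$end
    pick <- if (any(overlaps)) which(overlaps)[1] else {
      dist <- pmax(runs$start - anchor, anchor - (runs$end - 1L), 0)
      which.min(dist)
    }
    sel <- runs[pick, ]
    tibble(gene_id = g$gene_id, chrom = g$chrom,
           start = as.integer(sel$start), end = as.integer(sel$end),
           width = as.integer(sel$end - sel$start),
           min_value = min(track_slice(track, g$chrom, sel$start, sel$end)),
           threshold = thr)
  })
  out <- purrr::list_rbind(purrr::compact(res))
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), width = integer(),
                  min_value = numeric(), threshold = numeric())
  }
  out
}

#' Assign the +1 nucleosome to each gene
#'
#' The +1 nucleosome is the first called dyad at or downstream of the TSS in
#' the gene's transcription direction, within `search_window` bp. Genes with
#' no qualifying call get `dyad = NA` and are reported via `message()`; they
#' are dropped by downstream profile building.
#'
#' @param calls Peak calls from [call_peaks()].
#' @param genes Gene model tibble.
#' @param search_window Search window (bp) downstream of the TSS.
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `dyad`, `height`, `width_at_half_height`.
#' @export
assign_plus_one <- function(calls, genes, search_window = 300) {
  res <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cand <- calls[calls$chrom == g$chrom, ]
    if (g$strand == "+") {
      cand <- cand[cand$dyad >= g$tss & cand$dyad <= g$tss + search_window, ]
      pick <- if (nrow(cand)) which.min(cand$dyad) else NA_integer_
    } else {
      cand <- cand[cand$dyad <= g$tss & cand$dyad >= g$tss - search_window, ]
      pick <- if (nrow(cand)) which.max(cand$dyad) else NA_integer_
    }
    if (is.na(pick)) {
      tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = g$tss, dyad = NA_integer_, height = NA_real_,
             width_at_half_height = NA_real_)
    } else {
      tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = g$tss, dyad = as.integer(cand$dyad[pick]),
             height = cand$height[pick],
             width_at_half_height = cand$width_at_half_height[pick])
    }
  })
  out <- purrr::list_rbind(res)
  n_miss <- sum(is.na(out$dyad))
  if (n_miss > 0) {
    message(sprintf("%d gene(s) without a +1 call within %d bp of the TSS: %s",
                    n_miss, search_window,
                    paste(out$gene_id[is.na(out$dyad)], collapse = ", ")))
  }
  out
}
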