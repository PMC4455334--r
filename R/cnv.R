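## Five-of-seven frame scan shared by gain and loss detection.
## flags: logical vector, one per window on one sequence.
## Returns data.frame(first, last, n_support): 1-based window indices of the
## trimmed regions. A frame of `frame` consecutive windows qualifies when it
## holds >= k flagged windows; a region is the span of flagged windows
## covered by any qualifying frame, with overlapping/adjacent qualifying
## frames merged and boundaries trimmed to the outermost flagged window.
scan_frames <- function(flags, k = 5L, frame = 7L) {
  n <- length(flags)
  empty <- data.frame(first = integer(0), last = integer(0),
                      n_support = integer(0))
  if (n < frame) return(empty)
  runsum <- as.numeric(stats::filter(as.numeric(flags), rep(1, frame),
                                     sides = 1))[frame:n]
  qual <- which(runsum >= k)            # frame starting at window index qual
  if (!length(qual)) return(empty)
  covered <- logical(n)
  for (f in qual) covered[f:(f + frame - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- lapply(which(r$values), function(i) {
    idx <- which(flags[starts[i]:ends[i]]) + starts[i] - 1L
    data.frame(first = idx[1L], last = idx[length(idx)],
               n_support = length(idx))
  })
  do.call(rbind, out)
}

cnv_regions_df <- function(sample_id, sequence, track_seq, runs, onefold,
                           type, window_size) {
  if (is.null(runs) || nrow(runs) == 0L)
    return(empty_cnv_regions())
  start <- track_seq$start[runs$first]
  end <- track_seq$start[runs$last] + window_size
  mean_ratio <- vapply(seq_len(nrow(runs)), function(i)
    mean(track_seq$count[runs$first[i]:runs$last[i]]) / onefold, numeric(1))
  data.frame(sample_id = sample_id, sequence = sequence, start = start,
             end = end, type = type, n_supporting_windows = runs$n_support,
             mean_ratio = mean_ratio, stringsAsFactors = FALSE)
}

empty_cnv_regions <- function() {
  structure(data.frame(sample_id = character(0), sequence = character(0),
                       start = numeric(0), end = numeric(0),
                       type = character(0),
                       n_supporting_windows = integer(0),
                       mean_ratio = numeric(0), stringsAsFactors = FALSE),
            class = c("cnv_regions", "data.frame"))
}

as_cnv_regions <- function(df) {
  structure(df, class = c("cnv_regions", "data.frame"))
}

#' Detect CNV gain regions in one sample
#'
#' A window is elevated when its read count exceeds the per-chromosome mean
#' plus `sd_mult` standard deviations. Regions are called where at least
#' `k` of any `frame` sequential overlapping windows are elevated;
#' overlapping qualifying frames merge and region boundaries are trimmed to
#' the outermost elevated window. With the 200-bp window / 100-bp step
#' defaults this is the five-of-seven, mean + 2 SD gain rule.
#'
#' On a chromosome whose window counts are constant (SD = 0) the threshold
#' degenerates to the mean and any window strictly above it qualifies.
#'
#' @param track A [window_track()].
#' @param summary Matching [summarize_depth()]; recomputed when omitted.
#' @param k Minimum elevated windows per qualifying frame.
#' @param frame Frame length in windows.
#' @param sd_mult SD multiplier for the elevation threshold.
#' @return A `cnv_regions` data.frame: `sample_id`, `sequence`, `start`,
#'   `end` (0-based half-open), `type` (`"gain"`), `n_supporting_windows`,
#'   `mean_ratio`. Sequences with fewer than `frame` windows are skipped
#'   with a warning.
#' @export
detect_gain_regions <- function(track, summary = NULL, k = 5L, frame = 7L,
                                sd_mult = 2) {
  stopifnot(inherits(track, "window_track"))
  summary <- summary %||% summarize_depth(track, min_windows = frame)
  ws <- attr(track, "window_size")
  onefold <- summary$genome_onefold_depth
  out <- empty_cnv_regions()
  for (sq in unique(track$sequence)) {
    tr <- track[track$sequence == sq, , drop = FALSE]
    if (nrow(tr) < frame) {
      warning(sprintf("sequence '%s' has %d windows (< frame %d): skipped",
                      sq, nrow(tr), frame))
      next
    }
    ps <- summary$per_sequence
    row <- ps[ps$sequence == sq, ]
    elevated <- tr$count > row$mean + sd_mult * row$sd
    runs <- scan_frames(elevated, k = k, frame = frame)
    out <- rbind(out, cnv_regions_df(attr(track, "sample_id"), sq, tr, runs,
                                     onefold, "gain", ws))
  }
  as_cnv_regions(out)
}

#' Detect CNV loss regions across a cohort
#'
#' A window is a loss window for sample *s* when its count falls below
#' `low` times that sample's genome-wide one-fold depth while at least one
#' other sample shows normal depth there (count above `normal` times its
#' own one-fold depth); the cross-sample condition excludes regions that
#' are merely unmappable. Loss windows then pass through the same
#' `k`-of-`frame` scan and merging as gains.
#'
#' @param tracks Named list of [window_track()]s on an identical window
#'   grid (same reference, window size and step).
#' @param summaries Matching list of [summarize_depth()] results;
#'   recomputed when omitted.
#' @param k,frame Frame rule as in [detect_gain_regions()].
#' @param low Loss threshold as a fraction of the sample's one-fold depth.
#' @param normal Normal-depth threshold for the other-sample condition.
#' @return Named list of `cnv_regions` (type `"loss"`), one per sample.
#' @export
detect_loss_regions <- function(tracks, summaries = NULL, k = 5L,
                                frame = 7L, low = 0.1, normal = 0.5) {
  if (length(tracks) < 2L)
    stop("loss calling needs >= 2 samples (the cross-sample normal-depth ",
         "condition is undefined for one)")
  grids <- lapply(tracks, function(t) t[c("sequence", "start")])
  for (i in seq_along(tracks)[-1])
    if (!identical(grids[[1]], grids[[i]]))
      stop("all tracks must share an identical window grid")
  summaries <- summaries %||% lapply(tracks, summarize_depth,
                                     min_windows = frame)
  ws <- attr(tracks[[1]], "window_size")

  onefold <- vapply(summaries, `[[`, numeric(1), "genome_onefold_depth")
  counts <- vapply(tracks, `[[`, numeric(nrow(tracks[[1]])), "count")
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  is_normal <- sweep(counts, 2, normal * onefold, ">")
  n_normal <- rowSums(is_normal)

  out <- vector("list", length(tracks))
  names(out) <- names(tracks)
  for (s in seq_along(tracks)) {
    lossy <- counts[, s] < low * onefold[s] &
      (n_normal - is_normal[, s]) >= 1L
    track <- tracks[[s]]
    regions <- empty_cnv_regions()
    for (sq in unique(track$sequence)) {
      i <- which(track$sequence == sq)
      if (length(i) < frame) {
        warning(sprintf("sequence '%s' has %d windows (< frame %d): skipped",
                        sq, length(i), frame))
        next
      }
      runs <- scan_frames(lossy[i], k = k, frame = frame)
      regions <- rbind(regions,
                       cnv_regions_df(attr(track, "sample_id"), sq,
                                      track[i, , drop = FALSE], runs,
                                      onefold[s], "loss", ws))
    }
    out[[s]] <- as_cnv_regions(regions)
  }
  out
}

#' Merge nearby CNV regions of one sample
#'
#' Same-type regions on the same sequence separated by at most `max_gap` bp
#' are merged; the merged `mean_ratio` is the length-weighted mean and
#' supporting windows are summed.
#'
#' @param regions A `cnv_regions` data.frame for a single sample.
#' @param max_gap Maximum gap in bp (default: the 100-bp slide step).
#' @return Merged `cnv_regions`.
#' @export
merge_regions <- function(regions, max_gap = 100L) {
  if (nrow(regions) == 0L) return(as_cnv_regions(regions))
  if (length(unique(regions$sample_id)) > 1L)
    stop("merge_regions() merges one sample at a time")
  out <- list()
  for (ty in unique(regions$type)) for (sq in unique(regions$sequence)) {
    r <- regions[regions$type == ty & regions$sequence == sq, , drop = FALSE]
    if (nrow(r) == 0L) next
    r <- r[order(r$start), , drop = FALSE]
    reach <- cummax(r$end)   # running right edge: handles nested intervals
    grp <- cumsum(c(1L, as.integer(r$start[-1L] - reach[-nrow(r)] > max_gap)))
    merged <- lapply(split(seq_len(nrow(r)), grp), function(i) {
      w <- r$end[i] - r$start[i]
      data.frame(sample_id = r$sample_id[1L], sequence = sq,
                 start = min(r$start[i]), end = max(r$end[i]), type = ty,
                 n_supporting_windows = sum(r$n_supporting_windows[i]),
                 mean_ratio = sum(r$mean_ratio[i] * w) / sum(w),
                 stringsAsFactors = FALSE)
    })
    out <- c(out, merged)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sequence, res$start), , drop = FALSE]
  rownames(res) <- NULL
  as_cnv_regions(res)
}

#' Count CNV regions in non-overlapping megabase bins
#'
#' Regions longer than `min_region_size` bp are counted into
#' non-overlapping bins by region start, emulating the genome-wide
#' distribution of CNV gain/loss region counts in 1-Mb windows.
#'
#' @param regions A `cnv_regions` data.frame (any number of samples).
#' @param seqlengths Reference lengths (see [compute_window_depths()]).
#' @param bin Bin size in bp.
#' @param min_region_size Regions must be strictly longer than this (bp);
#'   the headline gain-region maps use > 800 bp.
#' @return data.frame `sequence`, `bin_start`, `bin_end`, `count`, with a
#'   row for every bin of every reference sequence.
#' @export
aggregate_region_counts <- function(regions, seqlengths, bin = 1e6,
                                    min_region_size = 800) {
  seqlengths <- as_seqlengths(seqlengths)
  keep <- regions[(regions$end - regions$start) > min_region_size, ,
                  drop = FALSE]
  out <- do.call(rbind, lapply(names(seqlengths), function(sq) {
    nb <- max(1L, as.integer(ceiling(seqlengths[[sq]] / bin)))
    bs <- (seq_len(nb) - 1L) * bin
    cnt <- integer(nb)
    r <- keep[keep$sequence == sq, , drop = FALSE]
    if (nrow(r)) {
      idx <- r$start %/% bin + 1L
      cnt <- tabulate(idx, nbins = nb)
    }
    data.frame(sequence = sq, bin_start = bs,
               bin_end = pmin(bs + bin, seqlengths[[sq]]), count = cnt,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.cnv_regions <- function(x, ...) {
  cat(sprintf("cnv_regions: %d region(s) (%d gain, %d loss)\n", nrow(x),
              sum(x$type == "gain"), sum(x$type == "loss")))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write CNV regions as BED and full TSV
#'
#' BED name field is `<sample>_<type>`, score is `mean_ratio` scaled by 100
#' and capped at 1000.
#'
#' @param regions A `cnv_regions` data.frame.
#' @param bed,tsv Output paths (either may be `NULL` to skip).
#' @export
write_cnv_regions <- function(regions, bed = NULL, tsv = NULL) {
  if (!is.null(tsv))
    utils::write.table(as.data.frame(regions), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    df <- data.frame(regions$sequence, as.integer(regions$start),
                     as.integer(regions$end),
                     paste0(regions$sample_id, "_", regions$type),
                     pmin(as.integer(round(regions$mean_ratio * 100)), 1000L),
                     ".")
    utils::write.table(df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(regions)
}
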