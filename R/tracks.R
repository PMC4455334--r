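#' Construct a sliding-window depth track
#'
#' A window depth track holds one sample's read counts in fixed-size sliding
#' windows over every reference sequence. Windows of `window_size` bp are
#' placed every `step` bp from position 0; a trailing stretch shorter than
#' `window_size` carries no window. Coordinates are 0-based half-open.
#'
#' @param counts Named list, one numeric vector of window counts per
#'   sequence, in window order.
#' @param seqlengths Named vector of reference sequence lengths (or anything
#'   [as_seqlengths()] understands). Must cover every sequence in `counts`.
#' @param sample_id Sample identifier.
#' @param window_size,step Window size and slide step in bp. Defaults follow
#'   the 200-bp / 100-bp convention used for goat CNV calling.
#' @return A `window_track`: data.frame with columns `sequence`, `start`,
#'   `end`, `count`, plus attributes `sample_id`, `window_size`, `step`,
#'   `seqlengths`.
#' @export
window_track <- function(counts, seqlengths, sample_id = "sample",
                         window_size = 200L, step = 100L) {
  seqlengths <- as_seqlengths(seqlengths)
  if (!all(names(counts) %in% names(seqlengths)))
    stop("sequence(s) absent from reference index: ",
         paste(setdiff(names(counts), names(seqlengths)), collapse = ", "))
  if (window_size %% step != 0L)
    stop("'window_size' must be a multiple of 'step'")
  pieces <- lapply(names(counts), function(sq) {
    st <- window_starts(seqlengths[[sq]], window_size, step)
    if (length(st) != length(counts[[sq]]))
      stop(sprintf("sequence '%s': %d counts supplied but the %g-bp sequence tiles into %d windows",
                   sq, length(counts[[sq]]), seqlengths[[sq]], length(st)))
    data.frame(sequence = rep(sq, length(st)), start = st,
               end = st + window_size, count = as.numeric(counts[[sq]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, sample_id = sample_id, window_size = as.integer(window_size),
            step = as.integer(step), seqlengths = seqlengths,
            class = c("window_track", "data.frame"))
}

track_meta <- function(track) {
  list(sample_id = attr(track, "sample_id"),
       window_size = attr(track, "window_size"),
       step = attr(track, "step"),
       seqlengths = attr(track, "seqlengths"))
}

#' @export
print.window_track <- function(x, ...) {
  m <- track_meta(x)
  cat(sprintf("window_track: sample '%s', %d windows on %d sequence(s) (window %d bp, step %d bp)\n",
              m$sample_id, nrow(x), length(unique(x$sequence)),
              m$window_size, m$step))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

## Count read start positions (0-based) into overlapping windows.
## A read is assigned to every window containing its assigned base, i.e. to
## the window_size/step windows whose span covers it.
count_positions <- function(pos0, n_windows, window_size, step) {
  counts <- numeric(n_windows)
  if (length(pos0) == 0L || n_windows == 0L) return(counts)
  per <- window_size %/% step
  base_idx <- pos0 %/% step   # 0-based index of rightmost window starting <= pos
  for (j in seq_len(per) - 1L) {
    idx <- base_idx - j
    ok <- idx >= 0L & idx < n_windows
    if (any(ok))
      counts <- counts + tabulate(idx[ok] + 1L, nbins = n_windows)
  }
  counts
}

#' Compute sliding-window read depths from alignments or per-base depth
#'
#' Converts a SAM/BAM file or a per-base depth table into a
#' [window_track()]. From alignments, a read contributes to every window
#' containing its leftmost aligned base (or its midpoint with
#' `assign = "midpoint"`); unmapped, secondary and duplicate-flagged reads
#' are excluded, as are reads below `min_mapq`. From a per-base depth table
#' (`sequence<TAB>position(1-based)<TAB>depth`; absent positions count as
#' depth 0) the window value is the mean per-base depth over the window.
#'
#' @param x Path to a SAM or BAM file, path to a per-base depth TSV, or a
#'   data.frame. A data.frame with columns `sequence`, `pos`, `depth` is
#'   treated as per-base depth; with columns `sequence`, `pos` only, as
#'   0-based read start positions.
#' @param reference_index Sequence lengths: named vector, `.fai` path,
#'   two-column data.frame or `DNAStringSet`.
#' @param window_size,step Window size and slide step (bp); `window_size`
#'   must be a multiple of `step`.
#' @param min_mapq Minimum mapping quality for a read to be counted
#'   (alignment input only).
#' @param assign Which base places a read into windows: `"leftmost"`
#'   (default) or `"midpoint"`.
#' @param sample_id Sample identifier; defaults to the file base name.
#' @return A [window_track()].
#' @export
compute_window_depths <- function(x, reference_index, window_size = 200L,
                                  step = 100L, min_mapq = 0L,
                                  assign = c("leftmost", "midpoint"),
                                  sample_id = NULL) {
  assign <- match.arg(assign)
  seqlengths <- as_seqlengths(reference_index)
  if (window_size %% step != 0L)
    stop("'window_size' must be a multiple of 'step'")

  if (is.character(x) && length(x) == 1L) {
    if (is.null(sample_id))
      sample_id <- sub("\\.(sam|bam|tsv|txt)(\\.gz)?$", "", basename(x))
    if (grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
      x <- read_alignment_starts(x, min_mapq = min_mapq, assign = assign)
    } else {
      x <- utils::read.table(x, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("sequence", "pos", "depth"))
    }
  }
  sample_id <- sample_id %||% "sample"
  bad <- setdiff(unique(as.character(x$sequence)), names(seqlengths))
  if (length(bad))
    stop("sequence(s) absent from reference index: ",
         paste(bad, collapse = ", "))

  per_base <- "depth" %in% names(x)
  if (nrow(x) == 0L)
    warning("empty input: emitting an all-zero track")

  counts <- lapply(names(seqlengths), function(sq) {
    st <- window_starts(seqlengths[[sq]], window_size, step)
    n <- length(st)
    rows <- x[as.character(x$sequence) == sq, , drop = FALSE]
    if (n == 0L) return(numeric(0))
    if (per_base) {
      depth <- numeric(seqlengths[[sq]])
      if (nrow(rows)) {
        keep <- rows$pos >= 1 & rows$pos <= seqlengths[[sq]]
        depth[rows$pos[keep]] <- rows$depth[keep]
      }
      cs <- c(0, cumsum(depth))
      (cs[st + window_size + 1L] - cs[st + 1L]) / window_size
    } else {
      count_positions(rows$pos, n, window_size, step)
    }
  })
  names(counts) <- names(seqlengths)
  window_track(counts, seqlengths, sample_id = sample_id,
               window_size = window_size, step = step)
}

## Extract filtered 0-based read anchor positions from SAM/BAM via Rsamtools.
## SAM input is converted to BAM in tempdir first.
read_alignment_starts <- function(path, min_mapq = 0L,
                                  assign = c("leftmost", "midpoint")) {
  assign <- match.arg(assign)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
                             destination = tempfile(fileext = ""),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(b$pos) & (is.na(b$mapq) | b$mapq >= min_mapq)
  pos0 <- b$pos[keep] - 1L
  if (assign == "midpoint")
    pos0 <- pos0 + ifelse(is.na(b$qwidth[keep]), 0L, b$qwidth[keep] %/% 2L)
  data.frame(sequence = as.character(b$rname[keep]), pos = pos0,
             stringsAsFactors = FALSE)
}

#' Summarize a window depth track
#'
#' Computes per-sequence mean and population standard deviation of window
#' counts, plus the genome-wide one-fold depth: the unweighted mean window
#' count over all windows, taken as the depth of the baseline (diploid) copy
#' state. Sequences with fewer than `min_windows` windows are flagged
#' unusable for region calling.
#'
#' @param track A [window_track()].
#' @param min_windows Minimum windows for a sequence to be usable (default
#'   7, one detection frame).
#' @return A `depth_summary`: list with `sample_id`, `per_sequence`
#'   (data.frame `sequence`, `n_windows`, `mean`, `sd`, `usable`) and
#'   `genome_onefold_depth`.
#' @export
summarize_depth <- function(track, min_windows = 7L) {
  stopifnot(inherits(track, "window_track"))
  if (nrow(track) == 0L) stop("track is empty")
  sq <- unique(track$sequence)
  per <- do.call(rbind, lapply(sq, function(s) {
    v <- track$count[track$sequence == s]
    n <- length(v)
    data.frame(sequence = s, n_windows = n, mean = mean(v),
               sd = sqrt(sum((v - mean(v))^2) / n),  # population SD
               usable = n >= min_windows, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  structure(list(sample_id = attr(track, "sample_id"), per_sequence = per,
                 genome_onefold_depth = mean(track$count)),
            class = "depth_summary")
}

#' @export
print.depth_summary <- function(x, ...) {
  cat(sprintf("depth_summary: sample '%s', one-fold genome depth %.3f\n",
              x$sample_id, x$genome_onefold_depth))
  print(x$per_sequence)
  invisible(x)
}

#' Per-window CNV ratio
#'
#' CNV ratio = window read count divided by the sample's genome-wide
#' one-fold depth. A ratio of 1 is the diploid baseline; a region with
#' ratios fluctuating around 2 carries two copies relative to the
#' reference.
#'
#' @param track A [window_track()].
#' @param summary The matching [summarize_depth()] result; recomputed when
#'   omitted.
#' @return A `cnv_ratio_profile`: the track with an added `ratio` column.
#' @export
cnv_ratio <- function(track, summary = NULL) {
  stopifnot(inherits(track, "window_track"))
  summary <- summary %||% summarize_depth(track)
  if (!identical(summary$sample_id, attr(track, "sample_id")))
    stop("summary is for sample '", summary$sample_id,
         "', track is '", attr(track, "sample_id"), "'")
  if (summary$genome_onefold_depth == 0)
    stop("genome one-fold depth is zero; CNV ratio undefined")
  track$ratio <- track$count / summary$genome_onefold_depth
  class(track) <- c("cnv_ratio_profile", class(track))
  track
}

#' Centered moving average over a profile
#'
#' Smooths the ratio (or count) column of a profile with a centered moving
#' average of `span_windows` windows per sequence; at the ends the span is
#' truncated to the available windows.
#'
#' @param profile A `cnv_ratio_profile` or [window_track()].
#' @param span_windows Odd span, in windows.
#' @return The profile with the smoothed column replacing the original.
#' @export
moving_average <- function(profile, span_windows) {
  stopifnot(inherits(profile, "window_track"))
  if (span_windows < 1L || span_windows %% 2L == 0L)
    stop("'span_windows' must be odd and >= 1")
  col <- if ("ratio" %in% names(profile)) "ratio" else "count"
  h <- (span_windows - 1L) %/% 2L
  for (sq in unique(profile$sequence)) {
    i <- which(profile$sequence == sq)
    v <- profile[[col]][i]
    n <- length(v)
    if (span_windows > n)
      stop(sprintf("span %d exceeds the %d windows on sequence '%s'",
                   span_windows, n, sq))
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    profile[[col]][i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  profile
}

#' Write / read a window track as TSV
#'
#' Columns `sequence`, `start0`, `end`, `count` (plus `ratio` when present).
#' A `#` header line carries sample id, window size and step so the track
#' can be read back losslessly given the reference index.
#'
#' @param track A [window_track()].
#' @param path Output path.
#' @export
write_window_track <- function(track, path) {
  m <- track_meta(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample=%s window=%d step=%d", m$sample_id,
                     m$window_size, m$step), con)
  df <- as.data.frame(track)
  names(df)[names(df) == "start"] <- "start0"
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_track
#' @param reference_index Sequence lengths (see [compute_window_depths()]).
#' @export
read_window_track <- function(path, reference_index) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, regexec("#sample=(\\S+) window=(\\d+) step=(\\d+)", hdr))[[1]]
  if (length(meta) != 4L) stop("not a window-track TSV: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          stringsAsFactors = FALSE)
  counts <- split(df$count, df$sequence)[unique(df$sequence)]
  window_track(counts, as_seqlengths(reference_index), sample_id = meta[2],
               window_size = as.integer(meta[3]), step = as.integer(meta[4]))
}

#' Write a profile as bedGraph
#'
#' Overlapping windows are emitted as-is (one bedGraph line per window);
#' genome browsers display the last value at overlapping bases.
#'
#' @param profile A `cnv_ratio_profile` or [window_track()].
#' @param path Output path.
#' @param name Track name for the header line.
#' @export
write_bedgraph <- function(profile, path, name = attr(profile, "sample_id")) {
  col <- if ("ratio" %in% names(profile)) "ratio" else "count"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  utils::write.table(data.frame(profile$sequence, profile$start, profile$end,
                                profile[[col]]),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a depth summary as TSV
#'
#' @param summary A [summarize_depth()] result.
#' @param path Output path.
#' @export
write_depth_summary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample=%s genome_onefold_depth=%.10g",
                     summary$sample_id, summary$genome_onefold_depth), con)
  utils::write.table(summary$per_sequence, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
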