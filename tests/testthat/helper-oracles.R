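# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, O(n^2) where convenient) so they do
# not share code paths with the implementation they check.

# single-sequence track whose length fits the counts exactly
make_track1 <- function(counts, window_size = 200L, step = 100L,
                        sample_id = "s1", seqname = "chr1") {
  L <- (length(counts) - 1L) * step + window_size
  window_track(stats::setNames(list(counts), seqname),
               stats::setNames(L, seqname), sample_id = sample_id,
               window_size = window_size, step = step)
}

# exhaustive k-of-frame scan over flagged windows
oracle_frame_scan <- function(flags, k = 5L, frame = 7L) {
  n <- length(flags)
  covered <- rep(FALSE, n)
  if (n >= frame) {
    for (f in 1:(n - frame + 1L)) {
      hits <- 0L
      for (j in f:(f + frame - 1L)) if (flags[j]) hits <- hits + 1L
      if (hits >= k) covered[f:(f + frame - 1L)] <- TRUE
    }
  }
  first <- integer(0); last <- integer(0); nsup <- integer(0)
  i <- 1L
  while (i <= n) {
    if (covered[i]) {
      j <- i
      while (j < n && covered[j + 1L]) j <- j + 1L
      idx <- which(flags[i:j]) + i - 1L
      first <- c(first, idx[1L])
      last <- c(last, idx[length(idx)])
      nsup <- c(nsup, length(idx))
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(first = first, last = last, n_support = nsup)
}

# naive gain regions on a single-sequence track
oracle_gain_regions <- function(counts, window_size = 200L, step = 100L,
                                k = 5L, frame = 7L, sd_mult = 2) {
  mu <- mean(counts)
  sdv <- sqrt(mean((counts - mu)^2))
  flags <- counts > mu + sd_mult * sdv
  runs <- oracle_frame_scan(flags, k, frame)
  starts <- (seq_along(counts) - 1L) * step
  data.frame(start = starts[runs$first],
             end = starts[runs$last] + window_size,
             n_support = runs$n_support)
}

# naive loss flags: count matrix (windows x samples)
oracle_loss_flags <- function(counts, onefold, low = 0.1, normal = 0.5) {
  n <- nrow(counts); S <- ncol(counts)
  out <- matrix(FALSE, n, S)
  for (w in seq_len(n)) for (s in seq_len(S)) {
    if (counts[w, s] < low * onefold[s]) {
      for (t in seq_len(S)) {
        if (t != s && counts[w, t] > normal * onefold[t]) {
          out[w, s] <- TRUE
          break
        }
      }
    }
  }
  out
}

# naive per-window read counter (0-based read starts)
oracle_count_reads <- function(pos0, L, window_size = 200L, step = 100L) {
  if (L < window_size) return(numeric(0))
  starts <- seq(0, L - window_size, by = step)
  vapply(starts, function(s) sum(pos0 >= s & pos0 < s + window_size),
         numeric(1))
}

# brute-force single-linkage components of positions at a distance cutoff
oracle_linkage <- function(tstart, cutoff) {
  n <- length(tstart)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && abs(tstart[i] - tstart[j]) <= cutoff &&
          comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

hit_row <- function(query, tstart, tend, target = "chr1", strand = "+",
                    qstart = 0, qend = tend - tstart) {
  data.frame(query = query, qstart = qstart, qend = qend, strand = strand,
             target = target, tstart = tstart, tend = tend,
             length = tend - tstart, stringsAsFactors = FALSE)
}

tempfile_with <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}

# brute-force transitive linkage of intervals at a gap cutoff
oracle_linkage_intervals <- function(start, end, max_gap) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && comp[i] != comp[j] &&
          start[j] <= end[i] + max_gap && start[i] <= end[j] + max_gap) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# minimal single-end SAM file from 0-based read starts
write_tiny_sam <- function(path, seqlengths, sequence, pos0,
                           mapq = 60L, flag = 0L, read_len = 50L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (sq in names(seqlengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", sq,
                       as.integer(seqlengths[[sq]])), con)
  if (length(pos0)) {
    o <- order(match(sequence, names(seqlengths)), pos0)
    mapq <- rep_len(mapq, length(pos0))[o]
    flag <- rep_len(flag, length(pos0))[o]
    writeLines(sprintf("r%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                       seq_along(pos0), flag, sequence[o], pos0[o] + 1L,
                       mapq, read_len,
                       strrep("A", read_len)), con)
  }
  invisible(path)
}

expect_same_regions <- function(regions, oracle) {
  expect_equal(nrow(regions), nrow(oracle))
  if (nrow(oracle)) {
    expect_equal(regions$start, oracle$start)
    expect_equal(regions$end, oracle$end)
    expect_equal(regions$n_supporting_windows, oracle$n_support)
  }
}

# reciprocal-overlap match of a truth interval against calls
recovered <- function(truth_start, truth_end, calls, min_frac = 0.5) {
  if (nrow(calls) == 0L) return(FALSE)
  ov <- pmin(calls$end, truth_end) - pmax(calls$start, truth_start)
  any(ov >= min_frac * (truth_end - truth_start) &
        ov >= min_frac * (calls$end - calls$start))
}
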