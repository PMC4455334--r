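#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generators. Depth is
#' simulated directly at window level under a count-noise model: Poisson
#' by default, or negative binomial with variance mu + dispersion * mu^2
#' for the overdispersion seen in real sequencing depth.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-identical across runs.
#' @param n_sequences Number of reference sequences.
#' @param sequence_length Length of each sequence (bp).
#' @param mean_read_count_per_window Expected window read count (lambda)
#'   at the baseline copy state.
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion Negative-binomial dispersion (ignored for Poisson).
#' @param window_size,step Window grid used by [simulate_depth_tracks()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_sequences = 1L, sequence_length = 1e6,
                       mean_read_count_per_window = 30,
                       noise_model = c("poisson", "negative_binomial"),
                       dispersion = 0.1, window_size = 200L, step = 100L) {
  noise_model <- match.arg(noise_model)
  if (mean_read_count_per_window <= 0)
    stop("'mean_read_count_per_window' must be > 0")
  if (noise_model == "negative_binomial" && dispersion <= 0)
    stop("'dispersion' must be > 0")
  structure(list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
                 sequence_length = sequence_length,
                 mean_read_count_per_window = mean_read_count_per_window,
                 noise_model = noise_model, dispersion = dispersion,
                 window_size = as.integer(window_size),
                 step = as.integer(step)),
            class = "sim_config")
}

#' Known-truth copy-number landscape for one sample
#'
#' Records where a simulated genome deviates from the baseline (diploid)
#' copy state, so that callers can be scored against truth. Events within
#' one sample must not overlap.
#'
#' @param sample_id Sample identifier.
#' @param events data.frame `sequence`, `start`, `end` (0-based
#'   half-open), `copy_number` (non-negative integer; 0 is a homozygous
#'   deletion, 4 at baseline 2 is a doubled segment). May have zero rows.
#' @param baseline_copy_number Copy number everywhere else.
#' @return A `copy_number_landscape` list.
#' @export
copy_number_landscape <- function(sample_id, events = NULL,
                                  baseline_copy_number = 2L) {
  events <- events %||% data.frame(sequence = character(0),
                                   start = numeric(0), end = numeric(0),
                                   copy_number = integer(0))
  if (nrow(events)) {
    if (any(events$start >= events$end))
      stop("event with start >= end")
    if (any(events$copy_number < 0))
      stop("copy_number must be >= 0")
    for (sq in unique(events$sequence)) {
      e <- events[events$sequence == sq, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
        stop("overlapping events on sequence '", sq, "' in sample '",
             sample_id, "'")
    }
  }
  structure(list(sample_id = sample_id, events = events,
                 baseline_copy_number = as.integer(baseline_copy_number)),
            class = "copy_number_landscape")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference genome with gene and repeat annotation
#'
#' Random nucleotide sequences with non-overlapping gene models placed
#' uniformly and repeat intervals covering roughly `repeat_fraction` of
#' each sequence. With `dir` set, writes `reference.fa` (+ `.fai`-style
#' index), `genes.gff3` and `repeats.bed`.
#'
#' @param config A [sim_config()]; `sequence_length` must be at least
#'   1 kb (shorter sequences cannot be windowed usefully).
#' @param n_genes Total gene count across the genome.
#' @param gene_length Gene length (bp).
#' @param repeat_fraction Approximate repeat coverage per sequence.
#' @param dir Optional output directory.
#' @return list: `sequences` (`DNAStringSet`), `genes`, `repeats`
#'   (data.frames, 0-based half-open), `config`, and `files` when written.
#' @export
simulate_reference <- function(config, n_genes = 50L, gene_length = 1500L,
                               repeat_fraction = 0.1, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$sequence_length < 1000)
    stop("sequence_length < 1 kb is too short to window")
  set.seed(config$seed)
  seq_names <- sprintf("chr%d", seq_len(config$n_sequences))
  sequences <- Biostrings::DNAStringSet(
    vapply(seq_names, function(x) random_dna(config$sequence_length),
           character(1)))
  names(sequences) <- seq_names

  # genes: uniform placement, resampled until non-overlapping
  per_seq <- tabulate(sample.int(config$n_sequences, n_genes,
                                 replace = TRUE),
                      nbins = config$n_sequences)
  genes <- list()
  for (i in seq_len(config$n_sequences)) {
    ng <- per_seq[i]
    if (!ng) next
    L <- config$sequence_length
    if (ng * gene_length > 0.5 * L)
      stop("gene models would cover more than half of sequence '",
           seq_names[i], "'; reduce n_genes or gene_length")
    starts <- numeric(0)
    while (length(starts) < ng) {
      cand <- sample.int(L - gene_length, 1L) - 1L
      if (!any(abs(cand - starts) < gene_length)) starts <- c(starts, cand)
    }
    starts <- sort(starts)
    genes[[i]] <- data.frame(
      gene_id = character(ng), sequence = seq_names[i], start = starts,
      end = starts + gene_length,
      strand = sample(c("+", "-"), ng, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes) %||%
    data.frame(gene_id = character(0), sequence = character(0),
               start = numeric(0), end = numeric(0), strand = character(0))
  if (nrow(genes)) genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))

  # repeats: fixed-size intervals dropped uniformly until coverage reached
  rep_len <- 500L
  repeats <- list()
  for (i in seq_len(config$n_sequences)) {
    target_bp <- repeat_fraction * config$sequence_length
    n_rep <- max(0L, as.integer(round(target_bp / rep_len)))
    if (!n_rep) next
    starts <- sort(sample.int(config$sequence_length - rep_len, n_rep)) - 1L
    repeats[[i]] <- data.frame(sequence = seq_names[i], start = starts,
                               end = starts + rep_len,
                               stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, repeats) %||%
    data.frame(sequence = character(0), start = numeric(0),
               end = numeric(0))
  out <- list(sequences = sequences, genes = genes, repeats = repeats,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(sequences, fa)
    utils::write.table(
      data.frame(names(sequences), Biostrings::width(sequences)),
      file.path(dir, "reference.fa.fai"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    write_gff3(genes, file.path(dir, "genes.gff3"))
    utils::write.table(repeats, file.path(dir, "repeats.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    out$files <- c(fasta = fa, gff3 = file.path(dir, "genes.gff3"),
                   bed = file.path(dir, "repeats.bed"))
  }
  out
}

write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes))
    utils::write.table(
      data.frame(genes$sequence, "goatcnv_sim", "gene",
                 as.integer(genes$start) + 1L, as.integer(genes$end), ".",
                 genes$strand, ".", paste0("ID=", genes$gene_id)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## per-window expected copy number: length-weighted over events, baseline
## elsewhere
window_copy_number <- function(starts, window_size, events, baseline) {
  cn <- rep(as.numeric(baseline), length(starts))
  if (is.null(events) || nrow(events) == 0L) return(cn)
  win <- IRanges::IRanges(starts + 1L, starts + window_size)
  ev <- IRanges::IRanges(events$start + 1L, events$end)
  ov <- IRanges::findOverlaps(win, ev)
  if (!length(ov)) return(cn)
  w <- IRanges::width(IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                          ev[S4Vectors::subjectHits(ov)]))
  delta <- (events$copy_number[S4Vectors::subjectHits(ov)] - baseline) * w /
    window_size
  agg <- tapply(delta, S4Vectors::queryHits(ov), sum)
  cn[as.integer(names(agg))] <- cn[as.integer(names(agg))] + agg
  cn
}

#' Simulate multi-sample window depth tracks with known copy-number truth
#'
#' For each sample, window read counts are drawn from the configured
#' noise model with mean `lambda * copy_number / baseline`, where windows
#' fully inside an event take the event's copy number and boundary
#' windows a length-weighted mean. A copy number of 0 under Poisson gives
#' exactly zero counts.
#'
#' @param reference [simulate_reference()] output, a `DNAStringSet`, or a
#'   named length vector.
#' @param landscapes List of [copy_number_landscape()]s, one per sample.
#' @param config A [sim_config()].
#' @param dir Optional directory; writes one window-track TSV per sample
#'   plus `truth.tsv`.
#' @return list: `tracks` (named list of [window_track()]), `truth`
#'   (data.frame of all events with `sample_id`), `config`.
#' @export
simulate_depth_tracks <- function(reference, landscapes, config,
                                  dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seqlengths <- if (is.list(reference) && !is.null(reference$sequences))
    as_seqlengths(reference$sequences) else as_seqlengths(reference)
  lambda0 <- config$mean_read_count_per_window
  set.seed(config$seed)
  tracks <- list()
  for (ls in landscapes) {
    stopifnot(inherits(ls, "copy_number_landscape"))
    ev <- ls$events
    if (nrow(ev)) {
      bad <- !(ev$sequence %in% names(seqlengths)) |
        ev$end > seqlengths[ev$sequence]
      if (any(bad))
        stop("event outside the reference in sample '", ls$sample_id, "'")
    }
    counts <- lapply(names(seqlengths), function(sq) {
      st <- window_starts(seqlengths[[sq]], config$window_size, config$step)
      cn <- window_copy_number(st, config$window_size,
                               ev[ev$sequence == sq, , drop = FALSE],
                               ls$baseline_copy_number)
      mu <- lambda0 * cn / ls$baseline_copy_number
      if (config$noise_model == "poisson") stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    })
    names(counts) <- names(seqlengths)
    tracks[[ls$sample_id]] <- window_track(
      counts, seqlengths, sample_id = ls$sample_id,
      window_size = config$window_size, step = config$step)
  }
  truth <- do.call(rbind, lapply(landscapes, function(ls) {
    if (!nrow(ls$events)) return(NULL)
    cbind(sample_id = ls$sample_id, ls$events)
  })) %||% data.frame(sample_id = character(0), sequence = character(0),
                      start = numeric(0), end = numeric(0),
                      copy_number = integer(0))
  out <- list(tracks = tracks, truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(tracks))
      write_window_track(tracks[[id]],
                         file.path(dir, paste0(id, ".windows.tsv")))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Spread a window track to a per-base depth TSV
#'
#' Each window's count is spread uniformly over its bases
#' (count / window_size added to every covered base), giving a per-base
#' track in the `sequence<TAB>position(1-based)<TAB>depth` format that
#' [compute_window_depths()] reads. Because sliding windows overlap,
#' re-windowing this track recovers the original counts only up to the
#' window/step overlap factor; the writer exists to exercise the per-base
#' reader, not to invert it.
#'
#' @param track A [window_track()].
#' @param path Output path.
#' @export
write_per_base_depth <- function(track, path) {
  m <- track_meta(track)
  con <- file(path, "w")
  on.exit(close(con))
  for (sq in unique(track$sequence)) {
    tr <- track[track$sequence == sq, , drop = FALSE]
    L <- m$seqlengths[[sq]]
    depth <- numeric(L)
    for (i in seq_len(nrow(tr))) {
      b <- (tr$start[i] + 1L):tr$end[i]
      depth[b] <- depth[b] + tr$count[i] / m$window_size
    }
    nz <- which(depth > 0)
    if (length(nz))
      utils::write.table(data.frame(sq, nz, depth[nz]), con, sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
  }
  invisible(path)
}

#' Simulate a fragmented assembly with alignment hits of known placement
#'
#' Partitions each reference sequence into scaffolds at random
#' breakpoints, reverse-complements a random subset, and emits an
#' alignment-hit table containing one true hit chain per scaffold (the
#' scaffold's alignment split into a few co-linear hits) plus, at
#' `spurious_hit_rate` per true hit, short spurious hits at random
#' locations. The truth table records each scaffold's chromosome, offset
#' and orientation. Without spurious hits, scaffold lengths sum exactly
#' to the reference length.
#'
#' @param reference [simulate_reference()] output, `DNAStringSet`, or
#'   named length vector (no FASTA emitted in that case).
#' @param n_scaffolds Total number of scaffolds.
#' @param spurious_hit_rate Expected spurious hits per true hit
#'   (Bernoulli per true hit).
#' @param seed Integer seed.
#' @param min_scaffold_length Minimum scaffold length (bp).
#' @param hit_span Approximate length of each true hit (bp).
#' @return list: `scaffolds` (`DNAStringSet` or named lengths), `hits`
#'   (data.frame as [read_hits()]), `truth` (data.frame `query`,
#'   `target`, `offset`, `orientation`, `length`).
#' @export
simulate_fragmented_assembly <- function(reference, n_scaffolds,
                                         spurious_hit_rate = 0,
                                         seed = 1L,
                                         min_scaffold_length = 2500,
                                         hit_span = 20000) {
  have_seq <- inherits(reference, "DNAStringSet") ||
    (is.list(reference) && !is.null(reference$sequences))
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    reference$sequences else if (have_seq) reference else NULL
  seqlengths <- if (have_seq) as_seqlengths(seqs) else as_seqlengths(reference)
  if (n_scaffolds < 1L) stop("n_scaffolds must be >= 1")
  if (n_scaffolds * min_scaffold_length > sum(seqlengths))
    stop("n_scaffolds * min_scaffold_length exceeds the reference length")
  set.seed(as.integer(seed))

  # spread scaffold count over sequences proportional to length
  n_per <- pmax(1L, as.integer(round(n_scaffolds * seqlengths /
                                       sum(seqlengths))))
  while (sum(n_per) > n_scaffolds) n_per[which.max(n_per)] <-
    n_per[which.max(n_per)] - 1L
  while (sum(n_per) < n_scaffolds) n_per[which.max(seqlengths / n_per)] <-
    n_per[which.max(seqlengths / n_per)] + 1L

  truth <- list(); hits <- list(); scaffolds <- list()
  sid <- 0L
  for (ci in seq_along(seqlengths)) {
    L <- seqlengths[[ci]]; k <- n_per[ci]
    # k pieces, each >= min_scaffold_length: sample break points in the
    # slack then add the minimum back
    slack <- L - k * min_scaffold_length
    cuts <- if (k > 1L) sort(sample.int(slack + 1L, k - 1L,
                                        replace = TRUE) - 1L) else integer(0)
    sizes <- diff(c(0, cuts, slack)) + min_scaffold_length
    offs <- cumsum(c(0, sizes[-length(sizes)]))
    for (pi in seq_len(k)) {
      sid <- sid + 1L
      q <- sprintf("scaffold%04d", sid)
      orient <- sample(c("+", "-"), 1L)
      len <- sizes[pi]; off <- offs[pi]
      truth[[sid]] <- data.frame(query = q,
                                 target = names(seqlengths)[ci],
                                 offset = off, orientation = orient,
                                 length = len, stringsAsFactors = FALSE)
      if (!is.null(seqs)) {
        s <- Biostrings::subseq(seqs[[ci]], off + 1L, off + len)
        if (orient == "-") s <- Biostrings::reverseComplement(s)
        scaffolds[[q]] <- as.character(s)
      }
      # true chain: co-linear hits every ~hit_span along the scaffold
      n_hits <- max(2L, as.integer(ceiling(len / hit_span)))
      bounds <- unique(as.integer(round(seq(0, len, length.out = n_hits + 1L))))
      qs <- bounds[-length(bounds)]; qe <- bounds[-1L]
      keep <- qe - qs >= 50L
      qs <- qs[keep]; qe <- qe[keep]
      ts <- if (orient == "+") off + qs else off + len - qe
      te <- if (orient == "+") off + qe else off + len - qs
      hits[[length(hits) + 1L]] <- data.frame(
        query = q, qstart = qs, qend = qe, strand = orient,
        target = names(seqlengths)[ci], tstart = ts, tend = te,
        length = qe - qs, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  truth <- do.call(rbind, truth)

  if (spurious_hit_rate > 0) {
    n_true <- nrow(hits)
    n_spur <- stats::rbinom(1L, n_true, spurious_hit_rate)
    if (n_spur > 0L) {
      sp_q <- sample(truth$query, n_spur, replace = TRUE)
      sp_len <- sample(100:400, n_spur, replace = TRUE)
      sp_t <- sample(names(seqlengths), n_spur, replace = TRUE)
      sp_ts <- vapply(seq_len(n_spur), function(i)
        sample.int(seqlengths[[sp_t[i]]] - sp_len[i], 1L) - 1L, numeric(1))
      sp_qs <- vapply(seq_len(n_spur), function(i) {
        ql <- truth$length[truth$query == sp_q[i]]
        sample.int(max(1L, ql - sp_len[i]), 1L) - 1L
      }, numeric(1))
      spur <- data.frame(query = sp_q, qstart = sp_qs,
                         qend = sp_qs + sp_len,
                         strand = sample(c("+", "-"), n_spur,
                                         replace = TRUE),
                         target = sp_t, tstart = sp_ts,
                         tend = sp_ts + sp_len, length = sp_len,
                         spurious = TRUE, stringsAsFactors = FALSE)
      hits$spurious <- FALSE
      hits <- rbind(hits, spur)
    }
  }
  rownames(hits) <- NULL
  rownames(truth) <- NULL
  list(scaffolds = if (!is.null(seqs))
    Biostrings::DNAStringSet(unlist(scaffolds)) else
      stats::setNames(truth$length, truth$query),
    hits = hits, truth = truth)
}

#' Build copy-number events covering selected genes
#'
#' Convenience for engineering gene-level CNVs into a
#' [copy_number_landscape()]: each selected gene span is padded by `pad` bp
#' on both sides so that every window overlapping the gene lies fully
#' inside the event. Padding is clipped at the midpoint between adjacent
#' selected genes so events never overlap.
#'
#' @param genes Gene models (data.frame with `gene_id`, `sequence`,
#'   `start`, `end`).
#' @param gene_ids Genes to cover.
#' @param copy_number Copy number per selected gene (recycled).
#' @param pad Padding in bp on each side of a gene.
#' @param seqlengths Optional reference lengths to clip events at sequence
#'   ends.
#' @return Event data.frame for [copy_number_landscape()].
#' @export
gene_events <- function(genes, gene_ids, copy_number, pad = 400,
                        seqlengths = NULL) {
  g <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id)) stop("unknown gene_id")
  g$copy_number <- rep_len(copy_number, nrow(g))
  out <- do.call(rbind, lapply(split(g, g$sequence), function(gs) {
    gs <- gs[order(gs$start), , drop = FALSE]
    n <- nrow(gs)
    mid <- if (n > 1L) floor((gs$end[-n] + gs$start[-1L]) / 2) else numeric(0)
    left <- pmax(gs$start - pad, c(0, mid))
    right <- pmin(gs$end + pad, c(mid, gs$end[n] + pad))
    data.frame(sequence = gs$sequence, start = left, end = right,
               copy_number = gs$copy_number, stringsAsFactors = FALSE)
  }))
  if (!is.null(seqlengths)) {
    sl <- as_seqlengths(seqlengths)
    out$end <- pmin(out$end, sl[out$sequence])
  }
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR Ct table with known copy numbers
#'
#' Ct values follow the exponential-amplification model
#' `Ct = base_ct - log(copies) / log(efficiency) + N(0, ct_noise_sd)`;
#' the single-copy reference gene is emitted for every sample.
#'
#' @param copy_numbers data.frame `sample`, `gene`, `copies` (true copy
#'   number per sample and target gene, all >= 1).
#' @param reference_gene Name of the reference gene.
#' @param reference_gene_copies Copy number of the reference gene.
#' @param efficiency Amplification efficiency per cycle, in (1, 2].
#' @param ct_noise_sd Gaussian Ct noise SD (cycles), >= 0.
#' @param n_replicates Technical replicates per (sample, gene).
#' @param base_ct Ct of a single-copy template without noise.
#' @param seed Integer seed.
#' @return data.frame `sample`, `gene`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(copy_numbers, reference_gene = "C7orf28b",
                          reference_gene_copies = 1, efficiency = 2,
                          ct_noise_sd = 0, n_replicates = 3L,
                          base_ct = 30, seed = 1L) {
  if (efficiency <= 1 || efficiency > 2)
    stop("'efficiency' must lie in (1, 2]")
  if (ct_noise_sd < 0) stop("'ct_noise_sd' must be >= 0")
  if (any(copy_numbers$copies < 1)) stop("copy numbers must be >= 1")
  set.seed(as.integer(seed))
  samples <- unique(copy_numbers$sample)
  full <- rbind(copy_numbers[c("sample", "gene", "copies")],
                data.frame(sample = samples, gene = reference_gene,
                           copies = reference_gene_copies))
  out <- full[rep(seq_len(nrow(full)), each = n_replicates), ]
  out$replicate <- rep(seq_len(n_replicates), nrow(full))
  out$ct <- base_ct - log(out$copies) / log(efficiency) +
    stats::rnorm(nrow(out), 0, ct_noise_sd)
  out$copies <- NULL
  rownames(out) <- NULL
  out
}

#' Write a Ct table as CSV
#'
#' @param ct data.frame `sample`, `gene`, `replicate`, `ct`.
#' @param path Output path.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(ct[c("sample", "gene", "replicate", "ct")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
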