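#' Read whole-genome alignment hits (PAF or 8-column TSV)
#'
#' PAF columns 1-12 (query, qlen, qstart, qend, strand, target, tlen,
#' tstart, tend, matches, block length, mapq) or a headerless 8-column
#' table (query, qstart, qend, strand, target, tstart, tend,
#' match_length). The format is chosen by column count. All coordinates
#' 0-based half-open.
#'
#' @param path Hit table path.
#' @return data.frame `query`, `qstart`, `qend`, `strand`, `target`,
#'   `tstart`, `tend`, `length`.
#' @export
read_hits <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(tab) >= 12L) {        # PAF
    out <- data.frame(query = tab[[1]], qstart = tab[[3]], qend = tab[[4]],
                      strand = tab[[5]], target = tab[[6]],
                      tstart = tab[[8]], tend = tab[[9]],
                      length = tab[[11]], stringsAsFactors = FALSE)
  } else if (ncol(tab) == 8L) {
    out <- stats::setNames(tab, c("query", "qstart", "qend", "strand",
                                  "target", "tstart", "tend", "length"))
  } else {
    stop("hit table must be PAF (>= 12 columns) or 8-column TSV; got ",
         ncol(tab), " columns")
  }
  out
}

#' Drop scaffolds at or below a minimum length
#'
#' Anchoring considers only scaffolds longer than `min_len` bp (strictly:
#' a 2,000-bp scaffold is dropped at the 2-kb default).
#'
#' @param scaffolds `DNAStringSet` or named length vector.
#' @param min_len Length threshold in bp.
#' @return Filtered object of the same kind.
#' @export
filter_short_scaffolds <- function(scaffolds, min_len = 2000) {
  len <- if (inherits(scaffolds, "DNAStringSet"))
    Biostrings::width(scaffolds) else as.numeric(scaffolds)
  scaffolds[len > min_len]
}

validate_hits <- function(hits) {
  bad <- hits$qstart >= hits$qend | hits$tstart >= hits$tend |
    hits$length <= 0
  if (any(bad)) {
    warning(sum(bad), " malformed hit row(s) (start >= end or length <= 0)",
            " rejected")
    hits <- hits[!bad, , drop = FALSE]
  }
  hits
}

## length-weighted majority strand of a chain's member hits
chain_strand <- function(strand, length) {
  if (sum(length[strand == "+"]) >= sum(length[strand == "-"])) "+" else "-"
}

chain_summary <- function(hits, chain_of) {
  keep <- !is.na(chain_of)
  h <- hits[keep, , drop = FALSE]
  ids <- chain_of[keep]
  out <- do.call(rbind, lapply(split(seq_len(nrow(h)), ids), function(i) {
    data.frame(chain_id = ids[i[1L]], query = h$query[i[1L]],
               target = h$target[i[1L]],
               tstart = min(h$tstart[i]), tend = max(h$tend[i]),
               total_length = sum(h$length[i]), n_hits = length(i),
               strand = chain_strand(h$strand[i], h$length[i]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$query, out$target, out$tstart), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, hits = cbind(hits, chain_id = chain_of),
            class = c("hit_chains", "data.frame"))
}

#' Cluster alignment hits into chains within 100-kb windows
#'
#' Per (query, target) pair, hits sorted by target start join one chain as
#' long as the gap between successive target starts is at most `window`
#' bp. Orphans — chains of a single hit shorter than `orphan_min` bp — are
#' discarded. Malformed rows (start >= end) are rejected with a warning.
#'
#' @param hits Hit table ([read_hits()] output or equivalent data.frame).
#' @param window Maximum target-start gap joining successive hits (bp).
#' @param orphan_min Minimum length for a single-hit chain to survive (bp).
#' @return `hit_chains` data.frame: `chain_id`, `query`, `target`,
#'   `tstart`, `tend`, `total_length`, `n_hits`, `strand` (length-weighted
#'   majority). The input hits, annotated with their `chain_id` (NA for
#'   dropped orphans), are in `attr(, "hits")`.
#' @export
cluster_hits <- function(hits, window = 1e5, orphan_min = 500) {
  hits <- validate_hits(hits)
  hits <- hits[order(hits$query, hits$target, hits$tstart), , drop = FALSE]
  rownames(hits) <- NULL
  chain_of <- rep(NA_character_, nrow(hits))
  counter <- 0L
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$query, hits$target, sep = "\r"))) {
    ts <- hits$tstart[grp]
    brk <- c(TRUE, diff(ts) > window)
    local_id <- cumsum(brk)
    for (cid in unique(local_id)) {
      i <- grp[local_id == cid]
      counter <- counter + 1L
      if (length(i) == 1L && hits$length[i] < orphan_min) next  # orphan
      chain_of[i] <- sprintf("chain%05d", counter)
    }
  }
  chain_summary(hits, chain_of)
}

#' Choose the best placement for one scaffold
#'
#' Chains are sorted by total aligned length; a scaffold is placed when it
#' has a single chain, or when the longest chain is more than `ratio`
#' times the second longest ("more than twice" is strict: a 2.0x tie is
#' ambiguous). Otherwise the scaffold is left ambiguous/unplaced.
#'
#' @param chains `hit_chains` rows for a single query.
#' @param ratio Longest-to-second dominance ratio.
#' @param query Query name used when `chains` is empty.
#' @return One-row data.frame `query`, `target`, `position` (chain target
#'   start), `orientation`, `status` (`placed`/`ambiguous`/`unplaced`),
#'   `total_length`.
#' @export
select_placement <- function(chains, ratio = 2, query = NA_character_) {
  if (nrow(chains) == 0L)
    return(data.frame(query = query, target = NA_character_,
                      position = NA_real_, orientation = NA_character_,
                      status = "unplaced", total_length = NA_real_,
                      stringsAsFactors = FALSE))
  stopifnot(length(unique(chains$query)) == 1L)
  o <- order(chains$total_length, decreasing = TRUE)
  best <- chains[o[1L], ]
  placed <- nrow(chains) == 1L ||
    best$total_length > ratio * chains$total_length[o[2L]]
  data.frame(query = best$query,
             target = if (placed) best$target else NA_character_,
             position = if (placed) best$tstart else NA_real_,
             orientation = if (placed) best$strand else NA_character_,
             status = if (placed) "placed" else "ambiguous",
             total_length = best$total_length, stringsAsFactors = FALSE)
}

#' @rdname select_placement
#' @param queries Optional query names to report even when they have no
#'   chain (status `unplaced`).
#' @export
select_placements <- function(chains, ratio = 2, queries = NULL) {
  queries <- queries %||% unique(chains$query)
  out <- do.call(rbind, lapply(queries, function(q)
    select_placement(chains[chains$query == q, , drop = FALSE],
                     ratio = ratio, query = q)))
  rownames(out) <- NULL
  out
}

#' Build pseudo-chromosomes from placements
#'
#' Placed scaffolds are concatenated per target chromosome in order of
#' position, reverse-complemented when oriented "-", and separated by
#' `gap_n` N's. The accompanying AGP v2.1 describes the FASTA exactly
#' (component rows `W`, gap rows `U` of unknown true size).
#'
#' @param placements [select_placements()] output (or compatible).
#' @param scaffolds Named `DNAStringSet` of scaffold sequences.
#' @param gap_n Gap length in N's between adjacent scaffolds.
#' @return list: `fasta` (`DNAStringSet` of pseudo-chromosomes), `agp`
#'   (data.frame of AGP rows), `unplaced` (character vector of scaffold
#'   ids that were ambiguous or unplaced).
#' @export
build_pseudochromosomes <- function(placements, scaffolds, gap_n = 100L) {
  placed <- placements[placements$status == "placed", , drop = FALSE]
  if (anyDuplicated(placed$query))
    stop("duplicate placement for scaffold(s): ",
         paste(unique(placed$query[duplicated(placed$query)]), collapse = ", "))
  missing <- setdiff(placed$query, names(scaffolds))
  if (length(missing))
    stop("placed scaffold(s) missing from FASTA: ",
         paste(missing, collapse = ", "))
  seqs <- list(); agp <- list()
  for (tg in unique(placed$target)) {
    p <- placed[placed$target == tg, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    parts <- character(nrow(p)); pos <- 0L; part_no <- 0L
    for (i in seq_len(nrow(p))) {
      if (i > 1L && gap_n > 0L) {
        part_no <- part_no + 1L
        agp[[length(agp) + 1L]] <- data.frame(
          object = tg, object_beg = pos + 1L, object_end = pos + gap_n,
          part_number = part_no, component_type = "U",
          component_id = as.character(gap_n), component_beg = "scaffold",
          component_end = "yes", orientation = "align_genus",
          stringsAsFactors = FALSE)
        pos <- pos + gap_n
        parts[i - 1L] <- paste0(parts[i - 1L], strrep("N", gap_n))
      }
      s <- scaffolds[[p$query[i]]]
      if (p$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
      len <- length(s)
      part_no <- part_no + 1L
      agp[[length(agp) + 1L]] <- data.frame(
        object = tg, object_beg = pos + 1L, object_end = pos + len,
        part_number = part_no, component_type = "W",
        component_id = p$query[i], component_beg = "1",
        component_end = as.character(len), orientation = p$orientation[i],
        stringsAsFactors = FALSE)
      pos <- pos + len
      parts[i] <- as.character(s)
    }
    seqs[[tg]] <- paste(parts, collapse = "")
  }
  fasta <- Biostrings::DNAStringSet(unlist(seqs))
  agp <- do.call(rbind, agp)
  rownames(agp) <- NULL
  list(fasta = fasta, agp = agp,
       unplaced = placements$query[placements$status != "placed"])
}

#' Write an AGP v2.1 file
#'
#' @param agp AGP data.frame from [build_pseudochromosomes()].
#' @param path Output path.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reassemble pseudo-chromosome FASTA from AGP and scaffolds
#'
#' @param agp AGP data.frame (or path to an AGP file).
#' @param scaffolds Named `DNAStringSet`.
#' @return `DNAStringSet` of assembled objects.
#' @export
assemble_from_agp <- function(agp, scaffolds) {
  if (is.character(agp))
    agp <- stats::setNames(
      utils::read.table(agp, sep = "\t", header = FALSE, skip = 1L,
                        stringsAsFactors = FALSE,
                        colClasses = "character"),
      c("object", "object_beg", "object_end", "part_number",
        "component_type", "component_id", "component_beg",
        "component_end", "orientation"))
  seqs <- vapply(unique(agp$object), function(ob) {
    rows <- agp[agp$object == ob, , drop = FALSE]
    rows <- rows[order(as.integer(rows$part_number)), , drop = FALSE]
    paste(vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$component_type %in% c("U", "N"))
        return(strrep("N", as.integer(r$component_id)))
      s <- scaffolds[[r$component_id]]
      s <- Biostrings::subseq(s, as.integer(r$component_beg),
                              as.integer(r$component_end))
      if (r$orientation == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1)), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Filter protein hits by alignment coverage
#'
#' Keeps hits covering at least `min_coverage` of the protein length
#' (strictly below is dropped: 0.59 goes, 0.60 stays).
#'
#' @param hits data.frame with a `coverage` column in `[0, 1]`.
#' @param min_coverage Coverage threshold.
#' @return Filtered data.frame.
#' @export
filter_protein_hits <- function(hits, min_coverage = 0.6) {
  if (any(hits$coverage < 0 | hits$coverage > 1))
    stop("'coverage' must lie in [0, 1]")
  hits[hits$coverage >= min_coverage, , drop = FALSE]
}

## fraction of [start, end) covered by repeat intervals (0-based half-open)
repeat_fraction <- function(repeats, sequence, start, end) {
  if (end <= start) return(0)
  r <- repeats[repeats$sequence == sequence, , drop = FALSE]
  if (!nrow(r)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
  gap <- IRanges::IRanges(start + 1L, end)
  sum(IRanges::width(IRanges::intersect(ir, gap))) / (end - start)
}

#' Cluster alignment hits with the Y-chromosome gap rules
#'
#' Successive hits on the same (query, target) merge when the gap between
#' them (target end to next target start) is below `near` bp, or when the
#' gap lies in `[near, far)` and more than `repeat_frac` of the unmapped
#' gap interval is repeat sequence (strictly more: a 50% repeat gap does
#' not merge). Without a repeat track, merges that would need the repeat
#' condition are declined with a warning.
#'
#' @param hits Hit table as for [cluster_hits()].
#' @param repeats Repeat annotation: data.frame `sequence`, `start`, `end`
#'   (0-based half-open, target coordinates), or `NULL`.
#' @param near Gap below which hits always merge (bp).
#' @param far Gap at or above which hits never merge (bp).
#' @param repeat_frac Minimum repeat fraction of the gap for a
#'   `[near, far)` merge (strict).
#' @return `hit_chains` as for [cluster_hits()] (no orphan filter).
#' @export
cluster_hits_y <- function(hits, repeats = NULL, near = 1000, far = 5000,
                           repeat_frac = 0.5) {
  hits <- validate_hits(hits)
  hits <- hits[order(hits$query, hits$target, hits$tstart), , drop = FALSE]
  rownames(hits) <- NULL
  chain_of <- rep(NA_character_, nrow(hits))
  counter <- 0L
  warned <- FALSE
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$query, hits$target, sep = "\r"))) {
    counter <- counter + 1L
    chain_of[grp[1L]] <- sprintf("chain%05d", counter)
    for (i in seq_along(grp)[-1L]) {
      gap <- hits$tstart[grp[i]] - hits$tend[grp[i - 1L]]
      merge <- if (gap < near) TRUE
      else if (gap < far) {
        if (is.null(repeats)) {
          if (!warned) {
            warning("no repeat track: declining merges with gaps in [near, far)")
            warned <- TRUE
          }
          FALSE
        } else {
          repeat_fraction(repeats, hits$target[grp[i]],
                          hits$tend[grp[i - 1L]],
                          hits$tstart[grp[i]]) > repeat_frac
        }
      } else FALSE
      if (!merge) counter <- counter + 1L
      chain_of[grp[i]] <- sprintf("chain%05d", counter)
    }
  }
  chain_summary(hits, chain_of)
}

#' Order scaffolds along a reference Y chromosome
#'
#' Picks each query's best chain via [select_placement()], then sorts
#' placed scaffolds by the reference contig order and offset, emulating
#' draft-Y construction from the alignment order on the bovine Y. When
#' scaffold sequences are supplied the ordered scaffolds are joined into a
#' single pseudo-chromosome with AGP output.
#'
#' @param chains `hit_chains` from [cluster_hits_y()] (or
#'   [cluster_hits()]).
#' @param ref_order Reference contig order: data.frame `contig`, `offset`
#'   (cumulative bp offset of each target contig on the reference
#'   chromosome), or a character vector of contigs in order.
#' @param ratio Dominance ratio for [select_placement()].
#' @param scaffolds Optional named `DNAStringSet`; when given, the result
#'   includes `fasta` and `agp` for the assembled object.
#' @param object_name Name of the assembled pseudo-chromosome.
#' @param gap_n Gap N's between adjacent scaffolds.
#' @return list: `placements` (ordered, with `rank` for placed queries),
#'   and `fasta`/`agp`/`unplaced` when `scaffolds` is given.
#' @export
order_on_reference_y <- function(chains, ref_order, ratio = 2,
                                 scaffolds = NULL, object_name = "Y",
                                 gap_n = 100L) {
  pl <- select_placements(chains, ratio = ratio)
  if (is.character(ref_order))
    ref_order <- data.frame(contig = ref_order,
                            offset = seq_along(ref_order) * 0,
                            stringsAsFactors = FALSE)
  contig_rank <- stats::setNames(seq_len(nrow(ref_order)), ref_order$contig)
  offset <- stats::setNames(ref_order$offset, ref_order$contig)
  placed <- pl$status == "placed"
  unknown <- setdiff(pl$target[placed], ref_order$contig)
  if (length(unknown))
    stop("placed target(s) absent from reference order: ",
         paste(unknown, collapse = ", "))
  key <- ifelse(placed, offset[pl$target] + pl$position, Inf)
  ord <- order(!placed, contig_rank[pl$target], key, na.last = TRUE)
  pl <- pl[ord, , drop = FALSE]
  pl$rank <- NA_integer_
  pl$rank[pl$status == "placed"] <- seq_len(sum(pl$status == "placed"))
  rownames(pl) <- NULL
  out <- list(placements = pl)
  if (!is.null(scaffolds)) {
    lin <- pl[pl$status == "placed", , drop = FALSE]
    lin$target <- object_name
    lin$position <- seq_len(nrow(lin))   # already in final order
    asm <- build_pseudochromosomes(lin, scaffolds, gap_n = gap_n)
    out$fasta <- asm$fasta
    out$agp <- asm$agp
    out$unplaced <- pl$query[pl$status != "placed"]
  }
  out
}
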