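#' Read gene models from GFF3 or BED
#'
#' From GFF3 only features of type `gene` are kept; the gene id is the `ID`
#' (or `Name`) attribute. From BED the name field is the gene id.
#' Coordinates are returned 0-based half-open.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file.
#' @return data.frame `gene_id`, `sequence`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  } else {
    id <- if (!is.null(gr$name)) as.character(gr$name)
          else paste0("gene", seq_along(gr))
  }
  if (anyDuplicated(id)) stop("duplicate gene_id in ", path)
  df <- data.frame(gene_id = id,
                   sequence = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  df
}

## indices of track windows overlapping [start, end) on `sequence`
overlapping_windows <- function(profile, sequence, start, end) {
  ws <- attr(profile, "window_size")
  which(profile$sequence == sequence &
          profile$start < end & profile$start + ws > start)
}

#' Aggregate CNV ratio over a gene span
#'
#' The per-gene CNV ratio is the median (default; configurable to the
#' mean) of the ratios of all windows overlapping the gene span. The
#' median resists the diluted boundary windows at CNV breakpoints.
#'
#' @param gene One-row data.frame with `sequence`, `start`, `end` (0-based
#'   half-open), as returned by [read_gene_models()].
#' @param profile A [cnv_ratio()] profile.
#' @param statistic `"median"` or `"mean"`.
#' @return The aggregated ratio (scalar).
#' @export
gene_ratio <- function(gene, profile, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(profile, "cnv_ratio_profile"))
  if (!gene$sequence %in% profile$sequence)
    stop("gene sequence '", gene$sequence, "' not in profile")
  idx <- overlapping_windows(profile, gene$sequence, gene$start, gene$end)
  if (!length(idx))
    stop("gene overlaps no window")
  if (gene$end - gene$start < attr(profile, "window_size"))
    warning("gene '", gene$gene_id %||% "?",
            "' is shorter than one window; ratio rests on ", length(idx),
            " covering window(s)")
  if (statistic == "median") stats::median(profile$ratio[idx])
  else mean(profile$ratio[idx])
}

gene_ratio_matrix <- function(genes, profiles, statistic = "median") {
  fun <- if (statistic == "median") stats::median else mean
  m <- matrix(NA_real_, nrow(genes), length(profiles),
              dimnames = list(genes$gene_id, names(profiles)))
  for (s in seq_along(profiles)) {
    p <- profiles[[s]]
    for (g in seq_len(nrow(genes))) {
      idx <- overlapping_windows(p, genes$sequence[g], genes$start[g],
                                 genes$end[g])
      if (!length(idx))
        stop("gene '", genes$gene_id[g], "' overlaps no window")
      m[g, s] <- fun(p$ratio[idx])
    }
  }
  m
}

#' Classify candidate deleted / duplicated genes in the domestic cohort
#'
#' A gene is a candidate deletion in domestic goats when it maps to a
#' called CNV region (if `require_cnv_overlap`) and its per-sample CNV
#' ratio is below `del_low` in *all* domestic samples while at least
#' `del_wild_min` in *all* wild samples. Candidate duplications mirror the
#' rule: ratio at least `dup_high` in all domestic samples and below
#' `dup_wild_max` in all wild samples. The duplication thresholds are this
#' package's defaults for "single copy in one species, multi-copy in the
#' other"; they are fully configurable.
#'
#' @param genes Gene models ([read_gene_models()] output).
#' @param profiles Named list of [cnv_ratio()] profiles, one per sample,
#'   on a shared window grid.
#' @param cohort_labels Named character vector mapping each sample to
#'   `"wild"` or `"domestic"`.
#' @param del_low,del_wild_min Deletion thresholds (< del_low all domestic;
#'   >= del_wild_min all wild).
#' @param dup_high,dup_wild_max Duplication thresholds (>= dup_high all
#'   domestic; < dup_wild_max all wild).
#' @param require_cnv_overlap Require a gene to overlap a called region
#'   before it can be a candidate deletion.
#' @param regions A `cnv_regions` data.frame (rbind over samples) used for
#'   the overlap requirement; ignored when `require_cnv_overlap = FALSE`.
#' @param statistic Per-gene aggregation, see [gene_ratio()].
#' @return `candidate_calls` data.frame: `gene_id`, `verdict`
#'   (`deleted_in_domestic` / `duplicated_in_domestic` / `none`),
#'   `ratio_rule`, `external_presence` (NA until
#'   [attach_external_presence()]), then one `ratio.<sample>` column per
#'   sample.
#' @export
classify_candidates <- function(genes, profiles, cohort_labels,
                                del_low = 0.2, del_wild_min = 0.5,
                                dup_high = 1.5, dup_wild_max = 1.5,
                                require_cnv_overlap = TRUE, regions = NULL,
                                statistic = "median") {
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, attr, "", "sample_id")
  lab <- cohort_labels[names(profiles)]
  if (anyNA(lab))
    stop("cohort label missing for sample(s): ",
         paste(names(profiles)[is.na(lab)], collapse = ", "))
  wild <- which(lab == "wild"); dom <- which(lab == "domestic")
  if (!length(wild) || !length(dom))
    stop("need >= 1 wild and >= 1 domestic sample")
  m <- gene_ratio_matrix(genes, profiles, statistic)

  in_region <- rep(TRUE, nrow(genes))
  if (require_cnv_overlap) {
    if (is.null(regions))
      stop("'regions' required when require_cnv_overlap = TRUE")
    in_region <- vapply(seq_len(nrow(genes)), function(g) {
      any(regions$sequence == genes$sequence[g] &
            regions$start < genes$end[g] & regions$end > genes$start[g])
    }, logical(1))
  }

  del <- in_region &
    apply(m[, dom, drop = FALSE] < del_low, 1, all) &
    apply(m[, wild, drop = FALSE] >= del_wild_min, 1, all)
  dup <- apply(m[, dom, drop = FALSE] >= dup_high, 1, all) &
    apply(m[, wild, drop = FALSE] < dup_wild_max, 1, all)
  verdict <- rep("none", nrow(genes))
  verdict[dup] <- "duplicated_in_domestic"
  verdict[del] <- "deleted_in_domestic"   # deletion rule wins on overlap

  out <- data.frame(gene_id = genes$gene_id, verdict = verdict,
                    ratio_rule = del | dup,
                    external_presence = NA, stringsAsFactors = FALSE)
  ratios <- as.data.frame(m)
  names(ratios) <- paste0("ratio.", colnames(m))
  out <- cbind(out, ratios)
  rownames(out) <- NULL
  structure(out, class = c("candidate_calls", "data.frame"))
}

#' @export
print.candidate_calls <- function(x, ...) {
  cat(sprintf("candidate_calls: %d gene(s), %d deleted, %d duplicated\n",
              nrow(x), sum(x$verdict == "deleted_in_domestic"),
              sum(x$verdict == "duplicated_in_domestic")))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Attach external presence/absence evidence to candidate calls
#'
#' Ingests a tabulated similarity-search result (gene present/absent in the
#' counterpart assembly); running the search itself is outside this
#' package. The `external_presence` flag records whether the evidence
#' supports the call (`"absent"` supports a deletion). With
#' `require_external = TRUE`, deletion verdicts lacking supporting
#' `"absent"` evidence are downgraded to `none`.
#'
#' @param calls [classify_candidates()] output.
#' @param evidence data.frame `gene_id`, `status` (`"present"`/`"absent"`),
#'   covering any subset of genes. Unknown gene ids are skipped with a
#'   warning.
#' @param require_external Downgrade unsupported deletion verdicts.
#' @return Updated `candidate_calls`.
#' @export
attach_external_presence <- function(calls, evidence,
                                     require_external = FALSE) {
  if (nrow(evidence)) {
    unknown <- setdiff(evidence$gene_id, calls$gene_id)
    if (length(unknown)) {
      warning("unknown gene_id in evidence table, skipped: ",
              paste(unknown, collapse = ", "))
      evidence <- evidence[!evidence$gene_id %in% unknown, , drop = FALSE]
    }
    i <- match(evidence$gene_id, calls$gene_id)
    calls$external_presence[i] <- evidence$status == "absent"
  }
  if (require_external) {
    downgrade <- calls$verdict == "deleted_in_domestic" &
      !calls$external_presence %in% TRUE
    calls$verdict[downgrade] <- "none"
  }
  calls
}

#' Read a qPCR Ct table
#'
#' @param path CSV with columns `sample,gene,replicate,ct`.
#' @return data.frame with those columns.
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Estimate relative copy number from qPCR Ct values
#'
#' Standard delta-delta-Ct: per sample, the target gene's mean Ct is
#' normalized to a single-copy reference gene (dCt = mean Ct(target) -
#' mean Ct(reference)), then to a calibrator sample (ddCt = dCt -
#' dCt(calibrator)); relative copy number = `calibrator_copies` *
#' 2^(-ddCt). With the diploid default the calibrator carries 2 copies, so
#' ddCt = -1 reads as 4 copies.
#'
#' @param ct Ct table (data.frame or CSV path, see [read_ct_csv()]).
#' @param reference_gene Single-copy reference gene (e.g. `C7orf28b`),
#'   required for every sample.
#' @param calibrator_sample Sample assumed to carry `calibrator_copies`
#'   copies of each target.
#' @param calibrator_copies Copy number assigned to the calibrator.
#' @return data.frame `sample`, `gene`, `mean_delta_ct`, `delta_delta_ct`,
#'   `relative_copy_number` for every target gene / sample.
#' @export
estimate_copy_number_qpcr <- function(ct, reference_gene,
                                      calibrator_sample,
                                      calibrator_copies = 2) {
  if (is.character(ct) && length(ct) == 1L) ct <- read_ct_csv(ct)
  mean_ct <- stats::aggregate(ct$ct, list(sample = ct$sample,
                                          gene = ct$gene), mean)
  ref <- mean_ct[mean_ct$gene == reference_gene, ]
  samples <- unique(mean_ct$sample)
  missing_ref <- setdiff(samples, ref$sample)
  if (length(missing_ref))
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(missing_ref, collapse = ", "))
  if (!calibrator_sample %in% samples)
    stop("calibrator sample '", calibrator_sample, "' not in Ct table")
  tgt <- mean_ct[mean_ct$gene != reference_gene, , drop = FALSE]
  tgt$mean_delta_ct <- tgt$x - ref$x[match(tgt$sample, ref$sample)]
  for (g in unique(tgt$gene)) {
    cal <- tgt$mean_delta_ct[tgt$gene == g & tgt$sample == calibrator_sample]
    if (!length(cal))
      stop("calibrator sample '", calibrator_sample,
           "' has no Ct values for gene '", g, "'")
    tgt$delta_delta_ct[tgt$gene == g] <-
      tgt$mean_delta_ct[tgt$gene == g] - cal
  }
  tgt$relative_copy_number <- calibrator_copies * 2^(-tgt$delta_delta_ct)
  out <- tgt[order(tgt$gene, tgt$sample),
             c("sample", "gene", "mean_delta_ct", "delta_delta_ct",
               "relative_copy_number")]
  rownames(out) <- NULL
  out
}
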