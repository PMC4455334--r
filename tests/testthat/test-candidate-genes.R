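make_profile <- function(ratios, sample_id) {
  tr <- make_track1(ratios * 30, sample_id = sample_id)
  cnv_ratio(tr, structure(list(sample_id = sample_id,
                               per_sequence = NULL,
                               genome_onefold_depth = 30),
                          class = "depth_summary"))
}

test_that("gene ratio aggregates overlapping windows by median", {
  p <- make_profile(rep(1, 100), "s1")
  gene <- data.frame(gene_id = "g1", sequence = "chr1", start = 1000,
                     end = 2500, strand = "+")
  expect_equal(gene_ratio(gene, p), 1.0)

  # median of {0.0, 0.1, 0.1} is 0.1
  r <- rep(1, 100); r[10:12] <- c(0.0, 0.1, 0.1)
  p2 <- make_profile(r, "s1")
  # windows 10..12 are starts 900,1000,1100; a gene covering exactly those
  g2 <- data.frame(gene_id = "g2", sequence = "chr1", start = 1050,
                   end = 1150, strand = "+")
  expect_warning(val <- gene_ratio(g2, p2), "shorter than one window")
  expect_equal(val, 0.1)

  expect_error(gene_ratio(data.frame(gene_id = "gx", sequence = "chrZ",
                                     start = 0, end = 100), p),
               "chrZ")

  # a gene inside a simulated doubled segment reads ~2 copies worth
  cfg <- sim_config(seed = 500, sequence_length = 200100,
                    mean_read_count_per_window = 30)
  ls <- copy_number_landscape("d", data.frame(
    sequence = "chr1", start = 50000, end = 56000, copy_number = 4L))
  sim <- simulate_depth_tracks(c(chr1 = 200100), list(ls), cfg)
  prof <- cnv_ratio(sim$tracks$d)
  g3 <- data.frame(gene_id = "g3", sequence = "chr1", start = 51000,
                   end = 55000)
  expect_lt(abs(gene_ratio(g3, prof) - 2), 0.25)
})

test_that("candidate classification applies the all-sample threshold rules", {
  genes <- data.frame(gene_id = c("gDel", "gHalf", "gDup", "gNone"),
                      sequence = "chr1",
                      start = c(1000, 3000, 5000, 7000),
                      end = c(2500, 4500, 6500, 8500), strand = "+")
  base <- rep(1, 100)
  prof_for <- function(del = NULL, half = NULL, dup = NULL, id) {
    r <- base
    if (!is.null(del)) r[11:25] <- del
    if (!is.null(half)) r[31:45] <- half
    if (!is.null(dup)) r[51:65] <- dup
    make_profile(r, id)
  }
  dom_ids <- paste0("dom", 1:4)
  profiles <- c(
    lapply(dom_ids, function(id) prof_for(del = 0.05, half = 0.05,
                                          dup = 2.0, id = id)),
    list(prof_for(id = "wild1"), prof_for(id = "wild2")))
  names(profiles) <- c(dom_ids, "wild1", "wild2")
  # one domestic sample at 0.4 breaks the all-domestic condition for gHalf
  profiles$dom3 <- prof_for(del = 0.05, half = 0.4, dup = 2.0, id = "dom3")
  labels <- c(stats::setNames(rep("domestic", 4), dom_ids),
              wild1 = "wild", wild2 = "wild")
  regions <- data.frame(sample_id = "dom1", sequence = "chr1",
                        start = c(900, 2900), end = c(2600, 4600),
                        type = "loss", n_supporting_windows = 10L,
                        mean_ratio = 0.05)
  calls <- classify_candidates(genes, profiles, labels, regions = regions)
  v <- stats::setNames(calls$verdict, calls$gene_id)
  expect_equal(unname(v["gDel"]), "deleted_in_domestic")
  expect_equal(unname(v["gHalf"]), "none")   # 0.4 >= del_low in one sample
  expect_equal(unname(v["gDup"]), "duplicated_in_domestic")
  expect_equal(unname(v["gNone"]), "none")

  # classification is invariant to sample order
  calls2 <- classify_candidates(genes, rev(profiles), labels,
                                regions = regions)
  expect_equal(calls2$verdict[match(calls$gene_id, calls2$gene_id)],
               calls$verdict)

  # deletion requires region overlap when asked for
  no_overlap <- within(regions, {start <- start + 50000
                                 end <- end + 50000})
  calls3 <- classify_candidates(genes, profiles, labels,
                                regions = no_overlap)
  expect_equal(calls3$verdict[calls3$gene_id == "gDel"], "none")
  calls4 <- classify_candidates(genes, profiles, labels,
                                require_cnv_overlap = FALSE)
  expect_equal(calls4$verdict[calls4$gene_id == "gDel"],
               "deleted_in_domestic")

  expect_error(classify_candidates(genes, profiles,
                                   stats::setNames(rep("domestic", 6),
                                                   names(profiles)),
                                   require_cnv_overlap = FALSE),
               "wild")
})

test_that("external presence evidence is attached and can gate deletions", {
  calls <- structure(data.frame(gene_id = c("g1", "g2"),
                                verdict = c("deleted_in_domestic",
                                            "deleted_in_domestic"),
                                ratio_rule = TRUE, external_presence = NA,
                                stringsAsFactors = FALSE),
                     class = c("candidate_calls", "data.frame"))
  ev <- data.frame(gene_id = c("g1", "g2"),
                   status = c("absent", "present"))
  out <- attach_external_presence(calls, ev)
  expect_identical(out$external_presence, c(TRUE, FALSE))
  expect_equal(out$verdict, calls$verdict)   # flags only, verdicts kept

  out2 <- attach_external_presence(calls, ev, require_external = TRUE)
  expect_equal(out2$verdict, c("deleted_in_domestic", "none"))

  expect_warning(attach_external_presence(calls,
                                          data.frame(gene_id = "gX",
                                                     status = "absent")),
                 "unknown")
  out3 <- attach_external_presence(calls, ev[0, ])
  expect_equal(out3$verdict, calls$verdict)
})

test_that("delta-delta-Ct estimation is exact without noise", {
  ct <- rbind(
    data.frame(sample = "cal", gene = "G1", replicate = 1:2,
               ct = c(28, 28)),
    data.frame(sample = "cal", gene = "C7orf28b", replicate = 1:2,
               ct = c(29, 29)),
    data.frame(sample = "s2", gene = "G1", replicate = 1:2,
               ct = c(27, 27)),
    data.frame(sample = "s2", gene = "C7orf28b", replicate = 1:2,
               ct = c(29, 29)))
  est <- estimate_copy_number_qpcr(ct, "C7orf28b", "cal")
  expect_equal(est$relative_copy_number[est$sample == "cal"], 2)  # ddCt 0
  expect_equal(est$relative_copy_number[est$sample == "s2"], 4)   # ddCt -1

  expect_error(estimate_copy_number_qpcr(ct[ct$gene != "C7orf28b", ],
                                         "C7orf28b", "cal"),
               "missing for sample")
  expect_error(estimate_copy_number_qpcr(ct, "C7orf28b", "nope"),
               "calibrator")

  # simulated 3 copies, noise 0.05, 6 replicates: estimate within [2.7, 3.3]
  cn <- data.frame(sample = c("cal", "s2"), gene = "G1", copies = c(2, 3))
  sim <- simulate_qpcr(cn, ct_noise_sd = 0.05, n_replicates = 6, seed = 23)
  est2 <- estimate_copy_number_qpcr(sim, "C7orf28b", "cal")
  val <- est2$relative_copy_number[est2$sample == "s2"]
  expect_gte(val, 2.7)
  expect_lte(val, 3.3)
})

test_that("an end-to-end synthetic cohort recovers engineered candidates", {
  # 2 wild + 4 domestic samples, 20 genes, 3 domestic-private deletions and
  # 2 duplications engineered into every domestic sample
  cfg <- sim_config(seed = 2718, sequence_length = 200100,
                    mean_read_count_per_window = 30)
  ref <- simulate_reference(cfg, n_genes = 20, gene_length = 1500)
  genes <- ref$genes
  del_genes <- genes$gene_id[c(2, 9, 15)]
  dup_genes <- genes$gene_id[c(5, 18)]
  events <- gene_events(genes, c(del_genes, dup_genes),
                        c(rep(0L, 3), rep(4L, 2)),
                        seqlengths = ref$sequences)
  landscapes <- c(
    lapply(paste0("dom", 1:4), copy_number_landscape, events = events),
    lapply(paste0("wild", 1:2), copy_number_landscape))
  sim <- simulate_depth_tracks(ref, landscapes, cfg)
  summaries <- lapply(sim$tracks, summarize_depth)
  profiles <- Map(cnv_ratio, sim$tracks, summaries)
  regions <- do.call(rbind, c(
    unname(Map(detect_gain_regions, sim$tracks, summaries)),
    unname(detect_loss_regions(sim$tracks, summaries))))
  labels <- c(stats::setNames(rep("domestic", 4), paste0("dom", 1:4)),
              stats::setNames(rep("wild", 2), paste0("wild", 1:2)))
  calls <- classify_candidates(genes, profiles, labels, regions = regions)
  expect_setequal(calls$gene_id[calls$verdict == "deleted_in_domestic"],
                  del_genes)
  expect_setequal(calls$gene_id[calls$verdict == "duplicated_in_domestic"],
                  dup_genes)
})
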