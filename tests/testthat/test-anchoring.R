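test_that("scaffold length filter is strictly 'longer than'", {
  lens <- c(a = 1999, b = 2000, c = 2001)
  expect_equal(names(filter_short_scaffolds(lens)), "c")
  expect_length(filter_short_scaffolds(numeric(0)), 0)
})

test_that("hits cluster within 100-kb target-start windows", {
  h <- rbind(hit_row("s1", 0, 5000), hit_row("s1", 50000, 55000),
             hit_row("s1", 120000, 125000))
  ch <- cluster_hits(h)   # successive gaps 50 kb and 70 kb: one chain
  expect_equal(nrow(ch), 1)
  expect_equal(ch$n_hits, 3)
  expect_equal(ch$total_length, 15000)

  h2 <- rbind(hit_row("s1", 0, 5000), hit_row("s1", 155000, 160000))
  expect_equal(nrow(cluster_hits(h2)), 2)

  # orphan: single short hit in its own window is discarded
  h3 <- rbind(hit_row("s1", 0, 5000), hit_row("s1", 300000, 300400))
  ch3 <- cluster_hits(h3)
  expect_equal(nrow(ch3), 1)
  expect_equal(ch3$tstart, 0)
  # a long single-hit chain survives
  expect_equal(nrow(cluster_hits(hit_row("s1", 0, 5000))), 1)

  expect_warning(ch4 <- cluster_hits(rbind(hit_row("s1", 0, 5000),
                                           hit_row("s1", 9000, 8000))),
                 "malformed")
  expect_equal(ch4$n_hits, 1)

  # strand is the length-weighted majority of members
  h5 <- rbind(hit_row("s1", 0, 8000, strand = "-"),
              hit_row("s1", 10000, 13000, strand = "+"))
  expect_equal(cluster_hits(h5)$strand, "-")
})

test_that("clustering equals brute-force single-linkage at the window", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    ts <- sort(sample.int(2e6, n))
    h <- do.call(rbind, lapply(seq_len(n), function(j)
      hit_row("q", ts[j], ts[j] + 1000)))
    ch <- cluster_hits(h, window = 1e5, orphan_min = 0)
    comp <- oracle_linkage(ts, 1e5)
    expect_equal(nrow(ch), length(unique(comp)))
    for (cmp in unique(comp)) {
      expect_true(any(ch$tstart == min(ts[comp == cmp]) &
                        ch$n_hits == sum(comp == cmp)))
    }
  }
})

test_that("the longest-more-than-twice rule decides placements strictly", {
  two <- function(l1, l2) rbind(
    cbind(cluster_hits(hit_row("s1", 0, l1, target = "chrA"))),
    cbind(cluster_hits(hit_row("s1", 5e5, 5e5 + l2, target = "chrB"))))
  p1 <- select_placement(two(10000, 4000))
  expect_equal(p1$status, "placed")
  expect_equal(p1$target, "chrA")
  # exactly 2.0x is not 'more than twice': ambiguous
  expect_equal(select_placement(two(10000, 5000))$status, "ambiguous")
  expect_equal(select_placement(two(10000, 6000))$status, "ambiguous")
  expect_equal(select_placement(
    cluster_hits(hit_row("s1", 0, 3000)))$status, "placed")
  expect_equal(select_placement(hit_row("q", 0, 10)[0, ],
                                query = "q")$status, "unplaced")

  # raising the dominance ratio never converts ambiguous to placed
  for (l2 in c(3000, 4999, 5000, 8000)) {
    placed_at <- vapply(c(2, 3, 5), function(r)
      select_placement(two(10000, l2), ratio = r)$status == "placed",
      logical(1))
    expect_true(all(diff(as.integer(placed_at)) <= 0))
  }
})

test_that("pseudo-chromosome assembly writes AGP that reproduces the FASTA", {
  set.seed(31)
  s1 <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  scaffolds <- Biostrings::DNAStringSet(c(sA = s1, sB = s2))
  pl <- data.frame(query = c("sA", "sB"), target = "chr1",
                   position = c(0, 50000), orientation = c("+", "-"),
                   status = "placed", total_length = 1)
  asm <- build_pseudochromosomes(pl, scaffolds, gap_n = 100)
  expect_equal(unname(Biostrings::width(asm$fasta)), 20100)
  # the reverse-complemented scaffold occupies the tail
  tail_seq <- substring(as.character(asm$fasta[["chr1"]]), 10101, 20100)
  expect_equal(tail_seq, as.character(
    Biostrings::reverseComplement(scaffolds[["sB"]])))

  # AGP round trip through the file format is byte-identical
  agp_path <- tempfile(fileext = ".agp")
  write_agp(asm$agp, agp_path)
  re <- assemble_from_agp(agp_path, scaffolds)
  expect_identical(as.character(re), as.character(asm$fasta))

  # liftover of random scaffold positions returns the original bases
  agp <- asm$agp
  w <- agp[agp$component_type == "W", ]
  for (i in 1:100) {
    row <- w[sample(nrow(w), 1), ]
    off <- sample.int(10000, 1)
    base_obj <- substring(as.character(asm$fasta[[row$object]]),
                          row$object_beg + off - 1, row$object_beg + off - 1)
    sc <- scaffolds[[row$component_id]]
    base_sc <- if (row$orientation == "+")
      as.character(Biostrings::subseq(sc, off, off))
    else as.character(Biostrings::complement(
      Biostrings::subseq(sc, length(sc) - off + 1, length(sc) - off + 1)))
    expect_equal(base_obj, base_sc)
  }

  expect_error(build_pseudochromosomes(rbind(pl, pl[1, ]), scaffolds),
               "duplicate")
})

test_that("protein hits filter at 60% coverage exactly", {
  h <- data.frame(protein = c("p1", "p2", "p3"),
                  coverage = c(0.59, 0.60, 0.61))
  kept <- filter_protein_hits(h)
  expect_setequal(kept$protein, c("p2", "p3"))
  expect_equal(nrow(filter_protein_hits(h[0, ])), 0)
  expect_error(filter_protein_hits(data.frame(coverage = 1.2)), "0, 1")
})

test_that("Y-chromosome clustering applies the 1 kb / 5 kb repeat gap rules", {
  reps <- function(frac, gap_start = 5000, gap_len = 3000) {
    if (frac == 0) return(data.frame(sequence = character(0),
                                     start = numeric(0), end = numeric(0)))
    data.frame(sequence = "chr1", start = gap_start,
               end = gap_start + frac * gap_len)
  }
  pair <- function(gap) rbind(hit_row("s1", 0, 5000),
                              hit_row("s1", 5000 + gap, 9000 + gap))
  # gap 500 bp: always merged
  expect_equal(nrow(cluster_hits_y(pair(500))), 1)
  # gap 3 kb with 60% repeat: merged
  expect_equal(nrow(cluster_hits_y(pair(3000), reps(0.6))), 1)
  # gap 3 kb with 20% repeat: not merged
  expect_equal(nrow(cluster_hits_y(pair(3000), reps(0.2))), 2)
  # exactly 50% repeat: '>50%' is strict, not merged
  expect_equal(nrow(cluster_hits_y(pair(3000), reps(0.5))), 2)
  # gap 6 kb: never merged
  expect_equal(nrow(cluster_hits_y(pair(6000), reps(1.0, gap_len = 6000))), 2)
  # no repeat track: mid-range merges declined with a warning
  expect_warning(ch <- cluster_hits_y(pair(3000)), "repeat")
  expect_equal(nrow(ch), 2)
})

test_that("scaffolds order along the reference Y by contig order and offset", {
  h <- rbind(hit_row("sA", 10000, 14000, target = "ctg2"),
             hit_row("sB", 200000, 206000, target = "ctg2"),
             hit_row("sC", 500, 3000, target = "ctg1", strand = "-"))
  chains <- cluster_hits_y(h)
  ref_order <- data.frame(contig = c("ctg1", "ctg2"),
                          offset = c(0, 1e6))
  out <- order_on_reference_y(chains, ref_order)
  placed <- out$placements[out$placements$status == "placed", ]
  expect_equal(placed$query, c("sC", "sA", "sB"))
  expect_equal(placed$orientation, c("-", "+", "+"))
  expect_equal(placed$rank, 1:3)
})

test_that("zero-noise fragmented assemblies are anchored perfectly", {
  cfg <- sim_config(seed = 8, n_sequences = 2, sequence_length = 2e5)
  ref <- simulate_reference(cfg, n_genes = 5)
  fr <- simulate_fragmented_assembly(ref, n_scaffolds = 12, seed = 21)
  chains <- cluster_hits(fr$hits)
  pl <- select_placements(chains, queries = fr$truth$query)
  expect_true(all(pl$status == "placed"))
  m <- match(pl$query, fr$truth$query)
  expect_equal(pl$target, fr$truth$target[m])
  expect_equal(pl$position, fr$truth$offset[m])
  expect_equal(pl$orientation, fr$truth$orientation[m])

  # per-chromosome scaffold order equals the truth order
  asm <- build_pseudochromosomes(pl, fr$scaffolds)
  for (sq in unique(fr$truth$target)) {
    tt <- fr$truth[fr$truth$target == sq, ]
    agp_w <- asm$agp[asm$agp$object == sq &
                       asm$agp$component_type == "W", ]
    expect_equal(agp_w$component_id, tt$query[order(tt$offset)])
  }
  # and the pseudo-chromosome reproduces the reference around each join
  expect_equal(sum(Biostrings::width(asm$fasta)),
               sum(Biostrings::width(ref$sequences)) +
                 100 * (nrow(fr$truth) - 2))
})

test_that("short spurious hits do not disturb placements at 20% noise", {
  cfg <- sim_config(seed = 9, n_sequences = 2, sequence_length = 3e5)
  fr <- simulate_fragmented_assembly(c(chr1 = 3e5, chr2 = 3e5),
                                     n_scaffolds = 16,
                                     spurious_hit_rate = 0.2, seed = 33)
  chains <- cluster_hits(fr$hits)
  pl <- select_placements(chains, queries = fr$truth$query)
  expect_true(all(pl$status == "placed"))
  m <- match(pl$query, fr$truth$query)
  expect_equal(pl$target, fr$truth$target[m])
  expect_equal(pl$orientation, fr$truth$orientation[m])
  # a spurious hit merging into the true chain may shift the chain start,
  # but never beyond the clustering window, and never the scaffold order
  expect_true(all(abs(pl$position - fr$truth$offset[m]) < 1e5))
  for (sq in unique(fr$truth$target)) {
    p <- pl[pl$target == sq, ]
    tt <- fr$truth[fr$truth$target == sq, ]
    expect_equal(p$query[order(p$position)], tt$query[order(tt$offset)])
  }
})

test_that("PAF and 8-column hit tables read identically", {
  f8 <- tempfile(fileext = ".tsv")
  write.table(hit_row("s1", 100, 900)[, c("query", "qstart", "qend",
                                          "strand", "target", "tstart",
                                          "tend", "length")],
              f8, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  h8 <- read_hits(f8)
  expect_equal(h8$tstart, 100)
  expect_equal(h8$length, 800)

  paf <- tempfile(fileext = ".paf")
  writeLines("s1\t1000\t0\t800\t+\tchr1\t5000\t100\t900\t780\t800\t60", paf)
  hp <- read_hits(paf)
  expect_equal(hp$tstart, 100)
  expect_equal(hp$tend, 900)
  expect_equal(hp$length, 800)
  expect_error(read_hits(tempfile_with("a\tb\tc\n")), "columns")
})
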