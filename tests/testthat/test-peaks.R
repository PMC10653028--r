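# Window peak caller, annotation and location distributions.

test_that("identical IP and input tracks yield no peaks", {
  set.seed(1)
  depth <- rpois(20000, 20)
  track <- meripdm:::rle_track(depth, "chr1")
  peaks <- call_enriched_windows(track, track)
  expect_equal(nrow(peaks), 0)
})

test_that("planted 200-nt 6x blocks are recovered as single merged peaks", {
  sim <- simulate_coverage_tracks(seed = 17, n_peaks = 50)
  peaks <- call_enriched_windows(sim$ip, sim$input)
  # recall: a truth block is recovered if one called peak overlaps it
  hits <- vapply(seq_len(nrow(sim$truth)), function(i) {
    ov <- peaks$contig == sim$truth$contig[i] &
      peaks$start < sim$truth$end[i] & peaks$end > sim$truth$start[i]
    sum(ov)
  }, double(1))
  expect_gte(mean(hits >= 1), 0.95)
  expect_true(all(hits <= 1))          # each block one merged peak
  # precision: called peaks overlapping some truth block
  prec <- mean(vapply(seq_len(nrow(peaks)), function(i) {
    any(sim$truth$start < peaks$end[i] & sim$truth$end > peaks$start[i])
  }, logical(1)))
  expect_gte(prec, 0.9)
})

test_that("called peaks are disjoint, in-bounds, and deterministic", {
  sim <- simulate_coverage_tracks(seed = 23, n_peaks = 20,
                                  contig_length = 60000)
  p1 <- call_enriched_windows(sim$ip, sim$input)
  p2 <- call_enriched_windows(sim$ip, sim$input)
  expect_identical(p1, p2)
  expect_true(all(p1$start < p1$end))
  expect_true(all(p1$start >= 0))
  expect_true(all(p1$end <= max(sim$ip$end)))
  ord <- order(p1$start)
  expect_true(all(p1$start[ord][-1] >= p1$end[ord][-nrow(p1)]))
})

test_that("a strongly enriched window is called (Poisson tail)", {
  # one 100-bp window at depth 50 reads over an expected 10
  base <- rep(10, 10000)
  ip <- base
  ip[3001:3100] <- 50
  peaks <- call_enriched_windows(meripdm:::rle_track(ip, "c"),
                                 meripdm:::rle_track(base, "c"))
  expect_equal(nrow(peaks), 1)
  expect_lt(peaks$p_min, 1e-15)
  expect_true(peaks$start <= 3000 && peaks$end >= 3100)
})

test_that("empty tracks warn and return an empty result", {
  empty <- tibble::tibble(contig = character(), start = integer(),
                          end = integer(), depth = double())
  expect_warning(out <- call_enriched_windows(empty, empty), "empty")
  expect_equal(nrow(out), 0)
})

models <- tibble::tibble(
  transcript_id = rep("tx1", 5),
  gene_id = rep("gene1", 5),
  feature = c("transcript", "5UTR", "CDS", "3UTR", "intron"),
  contig = "chr1",
  start = c(100, 100, 200, 600, 400),
  end = c(1000, 200, 400, 1000, 600),
  strand = "+")

test_that("peak annotation assigns category by overlap and precedence", {
  peaks <- tibble::tibble(
    contig = "chr1",
    start = c(700, 550, 5000, 150),
    end = c(800, 700, 5100, 250),
    peak_id = c("pA", "pB", "pC", "pD"))
  ann <- annotate_peaks(peaks, models)
  expect_equal(ann$category[ann$peak_id == "pA"], "3UTR")   # wholly inside
  # pB: 50 bp intron vs 100 bp 3UTR -> larger overlap wins
  expect_equal(ann$category[ann$peak_id == "pB"], "3UTR")
  expect_equal(ann$category[ann$peak_id == "pC"], "intergenic")
  # pD: 50 bp 5UTR vs 50 bp CDS tie -> 5UTR by precedence
  expect_equal(ann$category[ann$peak_id == "pD"], "5UTR")
  expect_equal(ann$gene_id[ann$peak_id == "pA"], "gene1")
})

test_that("annotation is shift-invariant", {
  peaks <- tibble::tibble(contig = "chr1", start = c(150, 650),
                          end = c(260, 790),
                          peak_id = c("p1", "p2"))
  k <- 1234
  shifted_peaks <- dplyr::mutate(peaks, start = start + k, end = end + k)
  shifted_models <- dplyr::mutate(models, start = start + k, end = end + k)
  a1 <- annotate_peaks(peaks, models)
  a2 <- annotate_peaks(shifted_peaks, shifted_models)
  expect_equal(a1$category, a2$category)
  expect_equal(a1$gene_id, a2$gene_id)
  expect_equal(a1$overlap_length, a2$overlap_length)
})

test_that("malformed gene models are rejected by transcript name", {
  bad <- models
  bad$end[bad$feature == "3UTR"] <- 2000   # beyond the transcript span
  peaks <- tibble::tibble(contig = "chr1", start = 150, end = 260,
                          peak_id = "p1")
  expect_error(annotate_peaks(peaks, bad), "tx1")
})

test_that("location distributions: degenerate and simulated group differences", {
  all3 <- tibble::tibble(category = rep("3UTR", 5), group = "g1")
  d <- location_distribution(all3)
  expect_equal(d$proportion[d$category == "3UTR"], 1)

  two <- tibble::tibble(category = rep(c("3UTR", "intron"), 20),
                        group = rep(c("a", "b"), each = 20))
  # identical distributions -> chi-square statistic 0, p ~ 1
  ident <- tibble::tibble(category = rep(c("3UTR", "CDS"), times = 2),
                          group = rep(c("a", "b"), each = 2))
  t_ident <- attr(location_distribution(ident), "test")
  expect_equal(unname(t_ident$statistic), 0)
  expect_equal(t_ident$p.value, 1)

  set.seed(9)
  grp <- tibble::tibble(
    category = c(sample(c("3UTR", "CDS"), 500, TRUE, c(0.6, 0.4)),
                 sample(c("3UTR", "CDS"), 500, TRUE, c(0.3, 0.7))),
    group = rep(c("a", "b"), each = 500))
  t_diff <- attr(location_distribution(grp), "test")
  expect_lt(t_diff$p.value, 0.01)
  props <- location_distribution(grp) %>%
    dplyr::group_by(group) %>% dplyr::summarise(s = sum(proportion))
  expect_equal(props$s, c(1, 1))

  expect_error(location_distribution(tibble::tibble(category = character(),
                                                    group = character())),
               ">= 1 peak")
})
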