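test_that("short genes get a single flanked piece", {
  pieces <- make_gene_pieces(data.frame(chrom = "1", start = 100000,
                                        end = 140000, name = "G"))
  expect_length(pieces, 1)
  expect_equal(pieces[[1]]$start, 95000)
  expect_equal(pieces[[1]]$end, 145000)
  expect_equal(pieces[[1]]$piece_index, 0L)
})

test_that("long genes split into equal pieces within the length bounds", {
  # flanked length 160 kb -> 2 abutting pieces of 80 kb
  p <- make_gene_pieces(data.frame(chrom = "1", start = 10001, end = 160000,
                                   name = "G"))
  expect_length(p, 2)
  sizes <- vapply(p, function(r) r$end - r$start + 1, 0)
  expect_equal(sizes, c(80000, 80000))
  expect_equal(p[[1]]$end + 1, p[[2]]$start)
  expect_equal(p[[1]]$start, 5001)
  expect_equal(p[[2]]$end, 165000)

  # flanked length 310 kb -> 4 pieces of 77.5 kb
  p4 <- make_gene_pieces(data.frame(chrom = "2", start = 100001, end = 400000,
                                    name = "H"))
  expect_length(p4, 4)
  expect_equal(vapply(p4, function(r) r$end - r$start + 1, 0), rep(77500, 4))
})

test_that("gene-piece partitions cover the flanked interval with valid sizes", {
  set.seed(202)
  lens <- sample.int(2000000, 300)
  for (L in lens) {
    start <- 50000
    p <- make_gene_pieces(data.frame(chrom = "1", start = start,
                                     end = start + L - 1, name = "G"))
    sizes <- vapply(p, function(r) r$end - r$start + 1, 0)
    flanked <- L + 10000
    expect_equal(sum(sizes), flanked)
    starts <- vapply(p, function(r) r$start, 0)
    ends <- vapply(p, function(r) r$end, 0)
    expect_equal(starts[1], start - 5000)
    expect_equal(ends[length(p)], start + L - 1 + 5000)
    if (length(p) > 1) {
      expect_true(all(starts[-1] == ends[-length(p)] + 1)) # contiguous, disjoint
      expect_true(all(sizes >= 50000 & sizes <= 100000))
      expect_equal(length(p), ceiling(flanked / 100000))
    } else {
      expect_lte(flanked, 150000)
    }
  }
})

test_that("flanked start is floored at position 1 and bad genes error", {
  p <- make_gene_pieces(data.frame(chrom = "1", start = 2000, end = 30000,
                                   name = "G"))
  expect_equal(p[[1]]$start, 1)
  expect_error(make_gene_pieces(data.frame(chrom = "1", start = 10, end = 5,
                                           name = "B")), "end < start")
})

test_that("windows chunk variants evenly with at most 30 per window", {
  gm <- toy_genotypes(matrix(rbinom(10 * 65, 2, 0.1), nrow = 10))
  r <- region("1", 1, 1e6, "G", 0L, 1:65)
  wnd <- make_windows(r, gm)
  expect_length(wnd, 3)
  expect_equal(vapply(wnd, function(x) length(x$variant_idx), 0L),
               c(22L, 22L, 21L))
  expect_equal(unlist(lapply(wnd, `[[`, "variant_idx")), 1:65)

  r31 <- region("1", 1, 1e6, "G", 0L, 1:31)
  expect_equal(vapply(make_windows(r31, gm), function(x)
    length(x$variant_idx), 0L), c(16L, 15L))

  r30 <- region("1", 1, 1e6, "G", 0L, 1:30)
  expect_length(make_windows(r30, gm), 1)
  expect_length(make_windows(region("1", 1, 2, "G", 0L, integer(0)), gm), 0)
})

test_that("window partitions preserve order and bound on random regions", {
  set.seed(7)
  for (i in 1:200) {
    v <- sample.int(200, 1)
    gm <- toy_genotypes(matrix(0, nrow = 2, ncol = v))
    r <- region("1", 1, 1e9, "G", 0L, seq_len(v))
    wnd <- make_windows(r, gm)
    sizes <- vapply(wnd, function(x) length(x$variant_idx), 0L)
    expect_true(all(sizes <= 30))
    expect_true(diff(range(sizes)) <= 1)
    expect_equal(unlist(lapply(wnd, `[[`, "variant_idx")), seq_len(v))
    # window bounds equal first/last variant positions
    expect_equal(wnd[[1]]$start, gm$variants$pos[1])
  }
})

test_that("variants carried by fewer than min_carriers individuals are removed", {
  # col 1: 3 hets (removed), col 2: 4 hets (kept), col 3: 2 homs (removed: 2 carriers)
  m <- cbind(c(1, 1, 1, 0, 0, 0, 0, 0),
             c(1, 1, 1, 1, 0, 0, 0, 0),
             c(2, 2, 0, 0, 0, 0, 0, 0))
  sv <- single_variant_regions(toy_genotypes(m))
  expect_length(sv, 1)
  expect_equal(sv[[1]]$variant_idx, 2L)
})

test_that("carrier filtering matches a brute-force count on random data", {
  set.seed(31)
  m <- matrix(rbinom(50 * 10, 2, 0.08), nrow = 50)
  gm <- toy_genotypes(m)
  sv <- single_variant_regions(gm)
  brute <- sum(apply(gm$dosages, 2, function(g) sum(g > 0) >= 4))
  expect_length(sv, brute)
})

test_that("rare-variant filter is strict at the cutoff", {
  gm <- toy_genotypes(matrix(0, nrow = 2, ncol = 3))
  gm$variants$maf <- c(0.01, 0.05, 0.049)
  r <- region("1", 1, 1e6, "G", 0L, 1:3)
  out <- filter_rare(gm, list(r))
  expect_equal(out[[1]]$variant_idx, c(1L, 3L))
  all_kept <- filter_rare(gm, list(r), maf_cutoff = 1.0)
  expect_equal(all_kept[[1]]$variant_idx, 1:3)
  expect_error(filter_rare(gm, list(r), maf_source = "external"), "external")
})

test_that("rare filter and carrier filter commute on hard genotypes", {
  set.seed(13)
  m <- matrix(rbinom(200 * 15, 2, runif(15, 0.005, 0.2)), nrow = 200, byrow = TRUE)
  gm <- toy_genotypes(m)
  # order A: carrier filter then rare filter
  a <- filter_rare(gm, single_variant_regions(gm))
  surv_a <- sort(unname(unlist(lapply(a, `[[`, "variant_idx"))))
  # order B: rare filter on the all-variant region, then carrier filter on
  # the surviving variants
  all_r <- filter_rare(gm, list(region("1", 1, 1e9, "A", 0L,
                                       seq_len(ncol(m)))))[[1]]
  carriers <- colSums(gm$dosages > 0.5)
  surv_b <- sort(unname(all_r$variant_idx[carriers[all_r$variant_idx] >= 4]))
  expect_equal(surv_a, surv_b)
})

test_that("assign_variants respects interval bounds and ordering", {
  gm <- toy_genotypes(matrix(0, 2, 5), pos = c(100, 200, 300, 400, 500))
  r <- assign_variants(list(region("1", 150, 450, "G")), gm)[[1]]
  expect_equal(r$variant_idx, 2:4)
})
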