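mk_track <- function(centers, lens, role, chrom = "chr1") {
  coloc_track(data.frame(chrom = chrom, start = centers - lens / 2,
                         end = centers + lens / 2), role = role)
}

test_that("merge interleaves by center with A-before-B on ties", {
  A <- mk_track(c(10, 30), c(2, 2), "A")
  B <- mk_track(20, 2, "B")
  expect_equal(merge_and_label(A, B, "chr1")$label, c("A", "B", "A"))
  A2 <- mk_track(10, 2, "A"); B2 <- mk_track(10, 2, "B")
  expect_equal(merge_and_label(A2, B2, "chr1")$label, c("A", "B"))
  A3 <- mk_track(c(10, 20), c(2, 2), "A")
  B3 <- mk_track(c(30, 40), c(2, 2), "B")
  expect_equal(merge_and_label(A3, B3, "chr1")$label, c("A", "A", "B", "B"))
  expect_equal(nrow(merge_and_label(A3, B3, "chrX")), 0L)
})

test_that("ABA/BAB extraction pairs middles with the nearer flank", {
  p <- extract_pairs(mk_seq(c("A", "B", "A"), c(10, 18, 30)))
  expect_equal(nrow(p), 1L)
  expect_equal(p$pair_class, "ABA_BAB")
  expect_equal(p$L, 8)
  expect_equal(p$a_start, 10)  # middle B paired with nearer flank A@10
})

test_that("mutual selections deduplicate; boundary elements are not middles", {
  p <- extract_pairs(mk_seq(c("A", "B", "A", "B"), c(10, 20, 25, 100)))
  expect_equal(nrow(p), 1L)
  expect_equal(p$pair_class, "ABA_BAB")
  expect_equal(p$a_start, 25)
  expect_equal(p$b_start, 20)
  expect_equal(p$L, 5)
})

test_that("AABB/BBAA junction pairs form at run boundaries and chromosome ends", {
  p <- extract_pairs(mk_seq(c("A", "B", "B", "A", "A", "B"),
                            c(10, 20, 30, 40, 50, 70)))
  expect_equal(sum(p$pair_class == "ABA_BAB"), 0L)
  aabb <- p[p$pair_class == "AABB_BBAA", ]
  expect_equal(nrow(aabb), 3L)
  expect_equal(aabb$a_start, c(10, 40, 50))
  expect_equal(aabb$b_start, c(20, 30, 70))
})

test_that("equidistant flanks tie-break to the upstream flank", {
  p <- extract_pairs(mk_seq(c("A", "B", "A"), c(10, 20, 30)))
  expect_equal(p$a_start, 10)
})

test_that("pair classes are disjoint and middles pair at most once (random inputs)", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(5:80, 1)
    sq <- mk_seq(sample(c("A", "B"), n, replace = TRUE),
                 sort(runif(n, 0, 1e6)))
    p <- extract_pairs(sq)
    if (nrow(p) == 0) next
    key <- paste(p$a_start, p$b_start)
    expect_false(any(duplicated(key)))  # no pair in both classes, no dups
    # each element participates in at most one ABA_BAB pair as middle:
    aba <- p[p$pair_class == "ABA_BAB", ]
    expect_lte(nrow(aba), n)
  }
})

test_that("pair extraction is invariant under coordinate reflection", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(6:60, 1)
    lab <- sample(c("A", "B"), n, replace = TRUE)
    ctr <- sort(runif(n, 0, 1e6))
    p1 <- extract_pairs(mk_seq(lab, ctr))
    p2 <- extract_pairs(mk_seq(rev(lab), sort(1e6 - ctr)))
    expect_equal(nrow(p1), nrow(p2))
    expect_equal(sort(p1$L), sort(p2$L), tolerance = 1e-9)
    expect_equal(table(p1$pair_class), table(p2$pair_class))
  }
})

test_that("track_pairs works per chromosome and never across", {
  A <- coloc_track(data.frame(chrom = c("chr1", "chr2"), start = c(0, 0),
                              end = c(10, 10)), role = "A")
  B <- coloc_track(data.frame(chrom = c("chr1", "chr1", "chr3"),
                              start = c(20, 40, 0), end = c(30, 50, 10)),
                   role = "B")
  p <- track_pairs(A, B)
  expect_true(all(p$chrom == "chr1"))
})

test_that("class share counts distinct participating elements of a track", {
  A <- mk_track(c(10, 30, 100), c(2, 2, 2), "A")
  B <- mk_track(20, 2, "B")
  p <- track_pairs(A, B)  # B@20 is a middle (A10, A30 flanks)
  sh <- class_share(p, B, "B")
  expect_equal(unname(sh["ABA_BAB"]), 1)
  expect_equal(unname(sh["AABB_BBAA"]), 0)
})

test_that("chromosome natural ordering puts chr2 before chr10", {
  ch <- c("chr10", "chr2", "chrX", "chr1", "chrM")
  expect_equal(ch[order_chromosomes(ch)],
               c("chr1", "chr2", "chr10", "chrM", "chrX"))
})
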