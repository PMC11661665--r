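# Contact-map protocol: persistence, stable contacts, Hamming metric, UPGMA,
# pseudoknots, spans and dot-bracket overlap.

test_that("contact maps normalize pairs and range-check indices", {
  empty <- contact_map(matrix(integer(0), ncol = 2), 10)
  expect_equal(nrow(empty$contacts), 0L)
  m <- contact_map(rbind(c(9, 0), c(0, 9), c(2, 7)), 10)
  expect_equal(m$contacts, rbind(c(0L, 9L), c(2L, 7L)))
  expect_error(contact_map(rbind(c(3, 12)), 10), "out of range")
  # renormalizing an already-normal map is the identity
  expect_equal(contact_map(m$contacts, 10)$contacts, m$contacts)
})

test_that("persistence counts frame fractions per pair", {
  maps <- c(replicate(3, contact_map(rbind(c(0, 9), c(2, 7)), 10),
                      simplify = FALSE),
            replicate(7, contact_map(rbind(c(0, 9)), 10), simplify = FALSE))
  ser <- contact_series(maps, 10)
  p <- persistence(ser)
  expect_equal(p$fraction[p$i == 0 & p$j == 9], 1.0)
  expect_equal(p$fraction[p$i == 2 & p$j == 7], 0.3)
  expect_false(any(p$i == 1))   # absent pairs don't appear
})

test_that("stable contacts apply the strict over-threshold rule", {
  # a pair in exactly half the frames is NOT conserved 'over 50%'
  maps <- c(replicate(5, contact_map(rbind(c(0, 9), c(1, 8)), 10),
                      simplify = FALSE),
            replicate(5, contact_map(rbind(c(1, 8)), 10), simplify = FALSE))
  st <- stable_contacts(contact_series(maps, 10), 0.5)
  expect_equal(st$contacts, rbind(c(1L, 8L)))
})

test_that("stable contacts equal a brute-force counting filter", {
  probs <- expand.grid(i = 0:6, j = 0:6)
  probs <- probs[probs$i < probs$j, ]
  probs$prob <- capsidfield:::with_seed(17, stats::runif(nrow(probs)))
  ser <- make_contact_series(7, probs, frames = 200, seed = 5)
  st <- stable_contacts(ser, 0.5)
  for (k in seq_len(nrow(probs))) {
    cnt <- count_pair_frames(ser, probs$i[k], probs$j[k])
    in_st <- any(st$contacts[, 1] == probs$i[k] & st$contacts[, 2] == probs$j[k])
    expect_equal(in_st, cnt / 200 > 0.5)
  }
})

test_that("stable contacts shrink monotonically with the threshold", {
  probs <- data.frame(i = c(0, 1, 2, 3), j = c(9, 8, 7, 6),
                      prob = c(0.9, 0.6, 0.4, 0.1))
  ser <- make_contact_series(10, probs, frames = 300, seed = 9)
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(t) nrow(stable_contacts(ser, t)$contacts), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("the Hamming distance is the symmetric-difference size", {
  a <- contact_map(rbind(c(0, 5), c(1, 4), c(2, 9), c(3, 8)), 12)
  b <- contact_map(rbind(c(0, 6), c(1, 7), c(2, 10), c(3, 11), c(4, 8),
                         c(5, 9), c(6, 11)), 12)   # 7 pairs, disjoint from a
  expect_equal(hamming_distance(a, a), 0L)
  expect_equal(hamming_distance(a, b), 11L)
  expect_equal(hamming_distance(a, b), hamming_distance(b, a))
  expect_error(hamming_distance(a, contact_map(rbind(c(0, 5)), 13)),
               "lengths differ")
})

test_that("the Hamming distance satisfies the metric axioms", {
  maps <- lapply(1:6, function(s) random_contact_map(15, 8, seed = s))
  for (x in maps) expect_equal(hamming_distance(x, x), 0L)
  for (a in maps) for (b in maps) {
    expect_equal(hamming_distance(a, b), hamming_distance(b, a))
    for (cc in maps) {
      expect_lte(hamming_distance(a, cc),
                 hamming_distance(a, b) + hamming_distance(b, cc))
    }
  }
})

test_that("the pairwise distance matrix is a strided symmetric metric", {
  probs <- data.frame(i = c(0, 2, 4), j = c(9, 7, 5), prob = c(0.5, 0.5, 0.5))
  ser <- make_contact_series(10, probs, frames = 10, seed = 3)
  D <- pairwise_distance_matrix(ser, stride = 2)
  expect_equal(dim(D), c(5L, 5L))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  same <- contact_series(replicate(4, contact_map(rbind(c(0, 9)), 10),
                                   simplify = FALSE), 10)
  expect_true(all(pairwise_distance_matrix(same) == 0))
  # normalized variant divides by n(n-1)/2
  expect_equal(pairwise_distance_matrix(ser, normalized = TRUE),
               pairwise_distance_matrix(ser) / 45)
})

test_that("average linkage reproduces simple constructions", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  den <- average_linkage(d2)
  expect_equal(nrow(den$merges), 1L)
  expect_equal(den$merges$height, 3)

  # two tight triplets far apart: first four merges are all tight
  pts <- rbind(matrix(stats::runif(6, 0, 0.4), 3, 2),
               matrix(10 + stats::runif(6, 0, 0.4), 3, 2))
  D <- as.matrix(dist(pts))
  den2 <- average_linkage(D)
  expect_true(all(den2$merges$height[1:4] <= 1))
  expect_gt(den2$merges$height[5], 9)
  expect_true(all(diff(den2$merges$height) >= 0))
  expect_equal(den2$merges$size[5], 6L)
})

test_that("average linkage merge heights match the reference UPGMA", {
  for (seed in 1:6) {
    n <- 5 + seed %% 4
    pts <- capsidfield:::with_seed(seed, matrix(stats::rnorm(2 * n), n, 2))
    D <- as.matrix(dist(pts))
    mine <- average_linkage(D)
    ref <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(mine$merges$height, ref$height, tolerance = 1e-12)
  }
})

test_that("average linkage rejects malformed inputs", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(average_linkage(bad), "symmetric")
})

test_that("dendrograms export as balanced Newick text", {
  D <- as.matrix(dist(c(0, 1, 5)))
  nwk <- dendrogram_newick(average_linkage(D))
  expect_match(nwk, "^\\(.*\\);$")
  expect_equal(lengths(regmatches(nwk, gregexpr("L[0-9]+", nwk))), 3L)
})

test_that("crossing pairs implement the interleaving criterion", {
  nested <- contact_map(rbind(c(0, 9), c(1, 8), c(2, 7)), 10)
  expect_equal(nrow(crossing_pairs(nested)), 0L)
  pk <- contact_map(rbind(c(1, 10), c(5, 15)), 16)
  x <- crossing_pairs(pk)
  expect_equal(nrow(x), 1L)
  expect_equal(unlist(x[1, ], use.names = FALSE), c(1L, 10L, 5L, 15L))
})

test_that("crossing pairs equal brute-force enumeration on random maps", {
  for (seed in 1:4) {
    m <- random_contact_map(40, 50, seed = seed + 100)
    expect_equal(nrow(crossing_pairs(m)), crossings_brute(m$contacts))
  }
})

test_that("crossing detection is invariant under contact re-ordering", {
  m <- random_contact_map(30, 20, seed = 7)
  shuf <- capsidfield:::with_seed(8, m$contacts[sample(nrow(m$contacts)), ])
  m2 <- contact_map(shuf, 30)
  expect_equal(crossing_pairs(m), crossing_pairs(m2))
})

test_that("contact spans count sequence separations", {
  m <- contact_map(rbind(c(0, 9), c(2, 7)), 10)
  sp <- contact_span_distribution(m)
  expect_equal(sp$count[sp$span == 9], 1L)
  expect_equal(sp$count[sp$span == 5], 1L)
  stem <- contact_map(cbind(0:4, 20 - (0:4)), 21)
  sps <- contact_span_distribution(stem)
  expect_equal(sort(sps$span), c(12L, 14L, 16L, 18L, 20L))
  expect_true(all(sps$count == 1L))
  expect_equal(nrow(contact_span_distribution(contact_map(matrix(integer(0),
    ncol = 2), 5))), 0L)
})

test_that("dot-bracket structures parse across bracket tiers", {
  p <- parse_dotbracket("((..))")
  expect_equal(p, rbind(c(0L, 5L), c(1L, 4L)))
  pk <- parse_dotbracket(".((..[[..))..]]")
  expect_equal(nrow(pk), 4L)
  expect_equal(nrow(crossing_pairs(contact_map(pk, 15))), 4L)
  expect_error(parse_dotbracket("(()"), "unbalanced '\\(' at position 1")
  expect_error(parse_dotbracket("())"), "unbalanced '\\)' at position 3")
})

test_that("dot-bracket overlap is the recovered fraction of reference pairs", {
  s <- "((((......))))......"
  ref <- parse_dotbracket(s)
  full <- contact_map(ref, 20)
  expect_equal(dotbracket_overlap(full, s), 1.0)
  expect_equal(dotbracket_overlap(contact_map(matrix(integer(0), ncol = 2), 20), s), 0.0)
  # 2 of 10 reference pairs shared
  s10 <- "((((((((((..........))))))))))"
  ref10 <- parse_dotbracket(s10)
  partial <- contact_map(rbind(ref10[1:2, ], c(2, 3), c(14, 16)), 30)
  expect_equal(dotbracket_overlap(partial, s10), 0.2)
  expect_error(dotbracket_overlap(full, "..."), "length")
})

test_that("chord data export carries pairs and weights", {
  probs <- data.frame(i = c(0, 1), j = c(9, 8), prob = c(1, 0.2))
  ser <- make_contact_series(10, probs, frames = 50, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  export_chord_json(ser, f)
  dat <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(dat$n, 10L)
  expect_equal(nrow(dat$contacts), 1L)   # only the persistent pair
  expect_equal(dat$contacts$fraction, 1)
})
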