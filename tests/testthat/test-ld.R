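test_that("pairwise r2 matches hand calculation and its invariances", {
  # worked 6-animal pair, Pearson correlation computed from raw sums
  x <- c(0, 1, 2, 1, 0, 2)
  z <- c(0, 1, 1, 1, 0, 2)
  n <- 6
  sxy <- sum(x * z) - sum(x) * sum(z) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  szz <- sum(z^2) - sum(z)^2 / n
  r2_hand <- sxy^2 / (sxx * szz)
  g <- toy_genotypes(cbind(x, z), pos = c(1e5, 2e5))
  rec <- pairwise_r2(g)
  expect_equal(rec$r2, r2_hand, tolerance = 1e-12)
  expect_equal(rec$dist_bp, 1e5)
  # a SNP against its own copy has r2 = 1
  g1 <- toy_genotypes(cbind(x, x), pos = c(1e5, 2e5))
  expect_equal(pairwise_r2(g1)$r2, 1, tolerance = 1e-12)
  # allele-label swap (dosage -> 2 - dosage) leaves r2 unchanged
  g2 <- toy_genotypes(cbind(x, 2 - z), pos = c(1e5, 2e5))
  expect_equal(pairwise_r2(g2)$r2, r2_hand, tolerance = 1e-12)
  # monomorphic SNPs are skipped with a warning
  g3 <- toy_genotypes(cbind(x, rep(1, 6)), pos = c(1e5, 2e5))
  expect_warning(out <- pairwise_r2(g3), "monomorphic")
  expect_equal(nrow(out), 0)
})

test_that("independent SNPs show near-zero r2 at large n", {
  set.seed(10)
  means <- replicate(200, {
    g <- toy_genotypes(cbind(rbinom(1000, 2, 0.3), rbinom(1000, 2, 0.4)),
                       pos = c(1e5, 2e5))
    pairwise_r2(g)$r2
  })
  expect_lt(mean(means), 0.02)
})

test_that("same-chromosome restriction and distance cap are enforced", {
  set.seed(11)
  d <- matrix(rbinom(40 * 4, 2, 0.4), 40, 4)
  g <- toy_genotypes(d, chr = c("1", "1", "2", "2"),
                     pos = c(1e5, 9e5, 1e5, 2e6))
  rec <- pairwise_r2(g, max_distance_bp = 1e6)
  expect_equal(nrow(rec), 1)   # only the chr1 pair is within range
  expect_equal(rec$chr, "1")
})

test_that("ld decay bins average correctly and track the generator", {
  one <- data.frame(snp1 = "a", snp2 = "b", chr = "1",
                    dist_bp = 250000, r2 = 0.12)
  dec <- ld_decay(one, bin_width_bp = 1e5)
  expect_equal(dec$mean_r2, 0.12)
  expect_equal(dec$bin_start, 2e5)
  expect_equal(dec$n_pairs, 1)
  # duplicated records double the count but not the mean
  dec2 <- ld_decay(rbind(one, one), bin_width_bp = 1e5)
  expect_equal(dec2$mean_r2, 0.12)
  expect_equal(dec2$n_pairs, 2)
  # calibrated generator: mean r2 decreases with distance
  herd <- shared_herd()
  coh <- herd$ped$animal[herd$ped$cohort]
  g <- impute_median(herd$geno[coh[1:300], herd$geno$map$snp[1:340]])
  rec <- suppressWarnings(pairwise_r2(g, max_distance_bp = 2e6))
  dec3 <- ld_decay(rec, bin_width_bp = 2e5)
  expect_lt(cor(dec3$bin_start, dec3$mean_r2, method = "spearman"), 0)
  expect_true(all(diff(dec3$bin_start) > 0))
})

test_that("windows are position +/- half-width, clamped at the chromosome start", {
  map <- data.frame(snp = c("rs133046994", "rs135638125", "edge"),
                    chr = c("10", "10", "1"),
                    pos = c(18129602L, 18147174L, 100000L))
  w <- snp_windows(c("rs133046994", "edge"), map)
  expect_equal(w$start[1], 17879602)
  expect_equal(w$end[1], 18379602)
  expect_equal(w$start[2], 1)        # clamped
  expect_equal(w$end[2], 350000)
  # two selected SNPs 17,572 bp apart share overlapping windows
  w2 <- snp_windows(c("rs133046994", "rs135638125"), map)
  expect_true(w2$start[2] <= w2$end[1])
  # translation consistency away from the clamp
  map_s <- transform(map, pos = pos + 1000L)
  ws <- snp_windows("rs133046994", map_s)
  expect_equal(ws$start, w$start[1] + 1000)
  expect_equal(ws$end, w$end[1] + 1000)
  expect_error(snp_windows("nope", map), "not in map")
})

test_that("window annotation matches brute-force interval intersection", {
  # toy: 2 windows, 5 features, exactly 3 intersections
  w <- data.frame(snp = c("s1", "s2"), chr = c("1", "2"),
                  pos = c(5e5, 5e5), start = c(25e4, 25e4),
                  end = c(75e4, 75e4))
  f <- data.frame(feature = paste0("g", 1:5), kind = "gene",
                  chr = c("1", "1", "1", "2", "3"),
                  start = c(1e5, 6e5, 80e4, 74e4, 3e5),
                  end = c(3e5, 7e5, 90e4, 80e4, 4e5))
  ann <- annotate_windows(w, f)
  expect_equal(nrow(ann), 3)
  expect_setequal(ann$feature, c("g1", "g2", "g4"))
  # a feature identical to the window overlaps over its full length
  f2 <- data.frame(feature = "exact", chr = "1", start = 25e4, end = 75e4)
  a2 <- annotate_windows(w[1, ], f2)
  expect_equal(a2$overlap_bp, 75e4 - 25e4 + 1)
  # a feature ending 1 bp before the window start is not reported
  f3 <- data.frame(feature = "before", chr = "1", start = 1e5,
                   end = 25e4 - 1)
  expect_equal(nrow(annotate_windows(w[1, ], f3)), 0)
  # chr labels normalize across dialects
  f4 <- data.frame(feature = "pref", chr = "chr1", start = 26e4, end = 27e4)
  expect_equal(nrow(annotate_windows(w[1, ], f4)), 1)
  # malformed intervals are rejected
  expect_error(annotate_windows(w, data.frame(feature = "bad", chr = "1",
                                              start = 10, end = 5)),
               "start > end")
})

test_that("annotation equals brute force on randomized instances", {
  set.seed(12)
  for (rep in 1:10) {
    nw <- sample(1:20, 1); nf <- sample(1:200, 1)
    w <- data.frame(snp = paste0("s", 1:nw),
                    chr = as.character(sample(1:3, nw, TRUE)),
                    pos = sample(1e6, nw))
    w$start <- pmax(1, w$pos - 5e4)
    w$end <- w$pos + 5e4
    fs <- sample(1e6, nf)
    f <- data.frame(feature = paste0("g", 1:nf),
                    chr = as.character(sample(1:3, nf, TRUE)),
                    start = fs, end = fs + sample(2e4, nf))
    ann <- annotate_windows(w, f)
    brute <- 0L
    for (i in seq_len(nw)) for (j in seq_len(nf)) {
      if (w$chr[i] == f$chr[j] && w$start[i] <= f$end[j] &&
          f$start[j] <= w$end[i]) brute <- brute + 1L
    }
    expect_equal(nrow(ann), brute)
  }
})

test_that("bed and gff3 features read through the standard importer", {
  skip_if_not_installed("rtracklayer")
  bed <- withr::local_tempfile(fileext = ".bed")
  # BED is 0-based half-open: [99, 300) -> 1-based inclusive [100, 300]
  writeLines("chr1\t99\t300\tgeneA\t0\t+", bed)
  f <- read_features(bed, kind = "gene")
  expect_equal(f$start, 100)
  expect_equal(f$end, 300)
  expect_equal(f$feature, "geneA")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t300\t.\t+\t.\tID=geneB;Name=geneB"),
             gff)
  f2 <- read_features(gff, kind = "gene")
  expect_equal(f2$start, 100)
  expect_equal(f2$end, 300)
  expect_equal(f2$feature, "geneB")
})
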