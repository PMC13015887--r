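test_that("read fractions follow the weighted normalization exactly", {
  # 26-fold reference:target disparity, equal efficiencies -> 1/27
  f <- read_fractions(data.frame(template = c("ACTB", "FGFR3"),
                                 ratio = c(26, 1), efficiency = c(1, 1)))
  expect_equal(unname(f["FGFR3"]), 1 / 27)

  # two templates, equal everything -> 50/50
  expect_equal(unname(read_fractions(
    data.frame(ratio = c(1, 1), efficiency = c(0.5, 0.5)), cycles = 10)),
    c(0.5, 0.5))

  # three-template case against a hand-normalized oracle
  pool <- data.frame(ratio = c(5, 2, 1), efficiency = c(0.2, 0.6, 1))
  n <- 12
  w <- pool$ratio * (1 + pool$efficiency)^n
  expect_equal(unname(read_fractions(pool, cycles = n)), w / sum(w))

  # tuning efficiencies against the ratios equalizes representation
  eq <- read_fractions(data.frame(ratio = c(26, 1),
                                  efficiency = c(0, 1)),
                       cycles = log2(26) / log2(2))
  expect_equal(unname(eq), c(0.5, 0.5), tolerance = 1e-9)
  expect_error(read_fractions(data.frame(ratio = c(1, -1),
                                         efficiency = c(1, 1))), "> 0")
})

test_that("detection limits reproduce the expected-read rule at both depths", {
  cands <- c(3e-4, 1e-3, 1e-2, 1e-1)
  # conventional amplification: target captures 3.7% of reads
  expect_equal(detection_limit(1e4, cands, target_fraction = 1 / 27), 0.1)
  # equalized representation: 50% of reads
  expect_equal(detection_limit(1e4, cands, target_fraction = 0.5), 1e-3)
  expect_equal(detection_limit(1e5, cands, target_fraction = 1 / 27), 1e-2)

  # unbounded depth detects the smallest candidate
  expect_equal(detection_limit(1e12, cands, target_fraction = 1 / 27), 3e-4)

  # none detectable is an explicit result
  none <- detection_limit(100, cands, target_fraction = 1 / 27)
  expect_true(is.na(none))
  expect_identical(attr(none, "message"), "none detectable")
  expect_error(detection_limit(1e4, rev(cands), 0.5), "sorted")
})

test_that("raising the threshold or cutting depth never improves the limit", {
  cands <- c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2, 3e-2, 1e-1)
  lim <- function(depth, thr) {
    detection_limit(depth, cands, target_fraction = 0.2, threshold = thr)
  }
  for (thr in c(1, 2, 5, 10, 20)) {
    expect_lte(lim(1e5, thr), lim(1e4, thr))  # more depth: limit not worse
  }
  lims <- vapply(c(1, 2, 5, 10, 20), function(t) lim(1e4, t), 0)
  expect_true(all(diff(lims) >= 0))           # higher bar: limit not better
})

test_that("binomial Monte-Carlo mode approaches the expected-count rule", {
  cands <- c(1e-3, 1e-2, 1e-1)
  # generous power margin: expected counts 37 >> 5 at the limit
  expect_equal(
    detection_limit(1e4, cands, 1 / 27, mode = "binomial", seed = 3),
    0.1)
})

test_that("archives encode deterministically with the documented layout", {
  files <- list(alpha = as.raw(c(1:40)), beta = as.raw(200:255))
  arch <- encode_archive(files, block_size = 8)
  # block count = ceil(bytes / payload bytes)
  expect_equal(arch$schema$n_blocks$alpha, ceiling(40 / 8))
  expect_equal(arch$schema$n_blocks$beta, ceiling(56 / 8))
  pt <- arch$schema$primer_table
  ol <- arch$oligos
  # every oligo is FP + address + payload + RP
  for (i in seq_len(nrow(ol))) {
    pr <- pt[pt$file == ol$file[i], ]
    expect_identical(
      ol$sequence[i],
      paste0(pr$fwd, ol$address[i], ol$payload[i], pr$rev))
  }
  expect_false(any(duplicated(paste(ol$file, ol$address))))
  expect_identical(encode_archive(files, block_size = 8)$oligos, ol)
  expect_error(encode_archive(files, block_size = 8, address_width = 1),
               "overflow")
  expect_error(encode_archive(list(as.raw(1))), "named")
})

test_that("encode -> access -> decode is the identity without noise", {
  set.seed(99)
  files <- list(doc = as.raw(sample(0:255, 123, replace = TRUE)),
                img = as.raw(sample(0:255, 64, replace = TRUE)))
  arch <- encode_archive(files, block_size = 8)
  reads <- simulate_access(arch, c(doc = 1, img = 1), cycles = 10,
                           total_reads = 8000, seed = 7)
  dec <- decode_archive(reads, arch$schema, reference = arch)
  expect_equal(unname(dec$accuracy), c(1, 1))
  expect_identical(dec$files$doc, files$doc)
  expect_identical(dec$files$img, files$img)
})

test_that("differential efficiencies skew read allocation as (1+e)^n", {
  arch <- encode_archive(list(x = as.raw(1:64), y = as.raw(1:64)),
                         block_size = 8)
  reads <- simulate_access(arch, c(x = 1, y = 0), cycles = 12,
                           total_reads = 4e4, seed = 5)
  pt <- arch$schema$primer_table
  nx <- sum(startsWith(reads, pt$fwd[pt$file == "x"]))
  ny <- length(reads) - nx
  expect_gt(ny, 0)
  expect_equal(log2(nx / ny), 12, tolerance = 0.15 * 12)

  # equal efficiencies: shares proportional to block counts
  arch2 <- encode_archive(list(x = as.raw(1:96), y = as.raw(1:32)),
                          block_size = 8)
  r2 <- simulate_access(arch2, c(x = 0.5, y = 0.5), cycles = 12,
                        total_reads = 3e4, seed = 6)
  n2 <- sum(startsWith(r2, arch2$schema$primer_table$fwd[1]))
  expect_equal(n2 / length(r2), 0.75, tolerance = 0.03)
})

test_that("zero coverage gives a blank, zero-accuracy reconstruction", {
  files <- list(only = as.raw(1:32))
  arch <- encode_archive(files, block_size = 8)
  dec <- decode_archive(character(0), arch$schema, reference = arch)
  expect_equal(unname(dec$accuracy), 0)
  expect_identical(dec$files$only, as.raw(rep(0, 32)))
})

test_that("decoding accuracy rises with coverage under read noise", {
  set.seed(17)
  files <- list(f = as.raw(sample(0:255, 160, replace = TRUE)))
  arch <- encode_archive(files, block_size = 8)
  acc_at <- function(reads_n, seed) {
    r <- simulate_access(arch, c(f = 1), cycles = 8, total_reads = reads_n,
                         seed = seed, error_rate = 0.01)
    decode_archive(r, arch$schema, occurrence_threshold = 2,
                   reference = arch)$accuracy
  }
  lo <- mean(vapply(1:4, function(s) acc_at(60, s), 0))
  hi <- mean(vapply(1:4, function(s) acc_at(2000, s), 0))
  expect_gt(hi, lo)
  expect_gt(hi, 0.95)
})

test_that("majority vote respects the occurrence threshold and tie-break", {
  files <- list(f = as.raw(1:8))
  arch <- encode_archive(files, block_size = 8)
  oligo <- arch$oligos$sequence[1]
  # a single read falls below the default occurrence threshold of 2
  dec1 <- decode_archive(oligo, arch$schema, reference = arch)
  expect_equal(unname(dec1$accuracy), 0)
  dec2 <- decode_archive(rep(oligo, 2), arch$schema, reference = arch)
  expect_equal(unname(dec2$accuracy), 1)

  # tie between two payloads resolves to the lexicographically smallest
  pt <- arch$schema$primer_table
  fake_payload <- paste(rep("T", 32), collapse = "")
  fake <- paste0(pt$fwd[1], arch$oligos$address[1], fake_payload, pt$rev[1])
  true_payload <- arch$oligos$payload[1]
  dec3 <- decode_archive(c(rep(oligo, 2), rep(fake, 2)), arch$schema,
                         reference = arch)
  expect_equal(unname(dec3$accuracy),
               as.numeric(true_payload < fake_payload))
})
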