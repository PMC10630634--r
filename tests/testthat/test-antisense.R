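test_that("pairing is strand-aware with inclusive 10% overlap on the antisense length", {
  g <- transcript_set("g1", "chr1", 1900, 5000, "+")
  a <- transcript_set("a1", "chr1", 1000, 2000, "-", biotype = "antisense")
  p <- find_antisense_pairs(a, g)
  expect_equal(nrow(p), 1L)
  expect_equal(p$overlap_bp, 100)
  expect_equal(p$overlap_fraction, 0.10)   # boundary inclusive

  # 99 bp overlap: fraction 0.099 < 0.10 -> dropped
  a99 <- transcript_set("a1", "chr1", 1000, 2000, "-", biotype = "antisense")
  g99 <- transcript_set("g1", "chr1", 1901, 5000, "+")
  expect_equal(nrow(find_antisense_pairs(a99, g99)), 0L)

  # same-strand overlap never pairs
  same <- transcript_set("s1", "chr1", 1900, 2100, "+")
  expect_equal(nrow(find_antisense_pairs(same, g)), 0L)

  # containment -> nested, fraction 1
  inside <- transcript_set("a2", "chr1", 2500, 3000, "-",
                           biotype = "antisense")
  p2 <- find_antisense_pairs(inside, g)
  expect_equal(p2$overlap_fraction, 1)
  expect_equal(p2$topology, "nested")

  # tail-to-tail partial overlap -> convergent
  conv <- transcript_set("a3", "chr1", 4000, 6000, "-",
                         biotype = "antisense")
  expect_equal(find_antisense_pairs(conv, g)$topology, "convergent")
  # head-to-head -> divergent
  expect_equal(p$topology, "divergent")
})

test_that("overlap_bp equals the base-membership oracle on random pairs", {
  set.seed(21)
  for (rep in 1:300) {
    s1 <- sample.int(500, 1); e1 <- s1 + sample.int(300, 1)
    s2 <- sample.int(500, 1); e2 <- s2 + sample.int(300, 1)
    g <- transcript_set("g", "chr1", s1, e1, "+")
    a <- transcript_set("a", "chr1", s2, e2, "-")
    p <- find_antisense_pairs(a, g, min_fraction = 1e-9)
    want <- oracle_overlap_bp(s1, e1, s2, e2)
    if (want == 0) expect_equal(nrow(p), 0L)
    else expect_equal(p$overlap_bp, want)
  }
})

test_that("raising min_fraction never adds pairs", {
  set.seed(22)
  gen <- make_toy_genome(100, antisense_fraction = 0.5,
                         overlap_range = c(0.05, 0.95), seed = 23)
  tx <- gen$transcripts
  genes <- tx[tx$biotype == "coding", ]
  counts <- vapply(c(0.01, 0.1, 0.3, 0.6, 0.9),
                   function(f) nrow(find_antisense_pairs(tx, genes, f)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("pair fold-change correlation matches closed forms and a permutation oracle", {
  pairs <- data.frame(sense_id = paste0("g", 1:10),
                      antisense_id = paste0("a", 1:10))
  fc <- rnorm(10)
  de_same <- data.frame(feature = c(paste0("g", 1:10), paste0("a", 1:10)),
                        log2FC = c(fc, fc))
  expect_equal(correlate_pairs(pairs, de_same)$pearson_r, 1)
  de_opp <- data.frame(feature = de_same$feature, log2FC = c(fc, -fc))
  expect_equal(correlate_pairs(pairs, de_opp)$pearson_r, -1)
  expect_error(correlate_pairs(pairs[1:2, ], de_same), "3 pairs")
  expect_error(correlate_pairs(data.frame(sense_id = "gX",
                                          antisense_id = "a1")[rep(1, 3), ],
                               de_same), "missing")

  # planted correlation 0.5, permutation oracle on the p-value
  set.seed(24)
  n <- 50
  x <- rnorm(n); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  pr <- data.frame(sense_id = paste0("g", 1:n),
                   antisense_id = paste0("a", 1:n))
  de <- data.frame(feature = c(pr$sense_id, pr$antisense_id),
                   log2FC = c(x, y))
  res <- correlate_pairs(pr, de)
  expect_lt(abs(res$pearson_r - 0.5), 0.25)
  B <- 4000
  robs <- abs(res$pearson_r)
  hits <- sum(vapply(seq_len(B), function(i)
    abs(cor(x, sample(y))) >= robs - 1e-12, TRUE))
  p_perm <- (hits + 1) / (B + 1)
  expect_lt(abs(res$p_value - p_perm),
            0.02 + 3 * sqrt(max(p_perm, 1e-4) * (1 - p_perm) / B))
})

test_that("ASRG/NARG classification follows the sign pattern of DE members", {
  pairs <- data.frame(sense_id = c("s1", "s2", "s3"),
                      antisense_id = c("a1", "a2", "a3"))
  de <- data.frame(feature = c("s1", "a1", "s2", "a2", "s3", "a3"),
                   log2FC = c(-1.0, 2.5, 1.2, 1.4, 0.1, 2.0),
                   status = c("down", "up", "up", "up", "not_DE", "up"))
  cl <- classify_regulation(pairs, de)
  expect_equal(cl$regulation_class, c("ASRG", "NARG", "not_regulated"))

  # global sign flip preserves classes
  de_neg <- de
  de_neg$log2FC <- -de$log2FC
  de_neg$status <- c("up", "down", "down", "down", "not_DE", "down")
  expect_equal(classify_regulation(pairs, de_neg)$regulation_class,
               cl$regulation_class)

  # order invariance
  expect_equal(classify_regulation(pairs[3:1, ], de)$regulation_class,
               rev(cl$regulation_class))

  # directional mode needs only one DE member
  expect_equal(classify_regulation(pairs, de,
                                   mode = "directional")$regulation_class,
               c("ASRG", "NARG", "NARG"))

  expect_error(classify_regulation(data.frame(sense_id = "sX",
                                              antisense_id = "a1"), de),
               "missing")
})

test_that("HRE scan finds RCGTG on both strands, never through N", {
  expect_equal(nrow(scan_hre("TTTTTT")), 0L)
  hit <- scan_hre("TTACGTGAA")
  expect_equal(hit$position, 2)
  expect_equal(hit$strand, "+")
  expect_equal(hit$match, "ACGTG")
  rc <- scan_hre("TTCACGTAA")
  expect_equal(rc$position, 2)
  expect_equal(rc$strand, "-")
  expect_equal(nrow(scan_hre("TTNCGTGAA")), 0L)
  expect_error(scan_hre("TTXCGTG"), "characters")
  expect_equal(scan_hre("TTACGTGAA", offset = 1000)$position, 1002)

  # regex oracle on random sequences, overlapping hits included
  set.seed(25)
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE,
                      prob = c(0.3, 0.2, 0.3, 0.15, 0.05)), collapse = "")
    hits <- scan_hre(s)
    plus_hits <- hits$position[hits$strand == "+"]
    want_plus <- which(vapply(seq_len(nchar(s) - 4), function(i)
      grepl("^[AG]CGTG$", substr(s, i, i + 4)), TRUE)) - 1
    expect_equal(plus_hits, want_plus)
    # every minus hit's 5-mer must reverse-complement to RCGTG
    minus <- hits[hits$strand == "-", ]
    if (nrow(minus)) {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      for (k in seq_len(nrow(minus))) {
        five <- substr(s, minus$position[k] + 1, minus$position[k] + 5)
        rcv <- paste(rev(comp[strsplit(five, "")[[1]]]), collapse = "")
        expect_true(grepl("^[AG]CGTG$", rcv))
      }
    }
  }
})
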