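test_that("log-odds scores follow the background model", {
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  uni <- rag_pwm(matrix(0.25, nrow = 4, ncol = 2), background = bg)
  expect_equal(score_window(uni, "AA"), 2 * log2(0.25 / 0.3),
               tolerance = 1e-12)
  expect_equal(score_window(uni, "CG"), 2 * log2(0.25 / 0.2),
               tolerance = 1e-12)
  # a PWM equal to the background scores exactly 0 everywhere
  bgm <- rag_pwm(matrix(bg, nrow = 4, ncol = 5), background = bg)
  withr::with_seed(4, {
    for (i in 1:10) {
      w <- paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = "")
      expect_equal(score_window(bgm, w), 0, tolerance = 1e-12)
    }
  })
  # N contributes exactly zero
  hept <- default_rag_pwms()$heptamer
  expect_equal(score_window(hept, "CACNGTG"),
               score_window(hept, "CACAGTG") -
                 log2(unname(hept$probs["A", 4]) / 0.3),
               tolerance = 1e-12)
  expect_error(score_window(hept, "CACA"), "width")
})

test_that("consensus attains the maximum score over all windows", {
  hept <- default_rag_pwms()$heptamer
  words <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), 7))
  scores <- apply(words, 1, function(w) {
    score_window(hept, paste(w, collapse = ""))
  })
  expect_equal(max(scores), score_window(hept, "CACAGTG"),
               tolerance = 1e-12)
})

test_that("DP p-values equal brute-force enumeration", {
  # heptamer: all 4^7 windows, weighted by the background
  hept <- default_rag_pwms()$heptamer
  tab <- score_pvalue_table(hept, granularity = 1e-3)
  grid <- do.call(expand.grid, rep(list(1:4), 7))
  L <- log2(hept$probs / hept$background)
  scores <- rowSums(matrix(
    L[cbind(as.vector(as.matrix(grid)), rep(1:7, each = nrow(grid)))],
    nrow = nrow(grid)))
  wprob <- apply(grid, 1, function(w) prod(hept$background[w]))
  expect_equal(sum(wprob), 1, tolerance = 1e-12)
  eps <- 7 * 1e-3  # discretisation slack: one bin per position
  for (q in quantile(scores, c(0, 0.1, 0.4, 0.7, 0.9, 0.99, 1))) {
    p_lo <- sum(wprob[scores >= q + eps])
    p_hi <- sum(wprob[scores >= q - eps])
    p_dp <- pwm_pvalue(tab, q)
    expect_gte(p_dp, p_lo)
    expect_lte(p_dp, p_hi)
  }
  # a random seeded width-4 matrix, exact comparison on its own grid
  withr::with_seed(9, {
    pm <- rag_pwm(matrix(runif(16, 0.05, 1), nrow = 4), name = "rand")
  })
  t2 <- score_pvalue_table(pm, granularity = 1e-4)
  g2 <- do.call(expand.grid, rep(list(1:4), 4))
  L2 <- log2(pm$probs / pm$background)
  s2 <- rowSums(matrix(
    L2[cbind(as.vector(as.matrix(g2)), rep(1:4, each = 256))], nrow = 256))
  w2 <- apply(g2, 1, function(w) prod(pm$background[w]))
  for (q in sort(unique(s2))) {
    # one discretisation bin of slack per position plus lookup rounding
    # (and a float-summation epsilon)
    expect_gte(pwm_pvalue(t2, q), sum(w2[s2 >= q + 4e-4]) - 1e-9)
    expect_lte(pwm_pvalue(t2, q), sum(w2[s2 >= q - 4e-4]) + 1e-9)
  }
})

test_that("p-values are monotone, bounded, and thresholdable", {
  hept <- default_rag_pwms()$heptamer
  tab <- score_pvalue_table(hept)
  expect_true(all(diff(tab$pvals) <= 1e-12))      # non-increasing
  expect_equal(tab$pvals[1], 1)                   # p(min score) = 1
  expect_true(all(tab$pvals > 0 & tab$pvals <= 1))
  s_star <- pwm_hit_threshold(tab, 1e-4)
  expect_true(is.finite(s_star))
  expect_lt(pwm_pvalue(tab, s_star), 1e-4)
  # background-equal PWM: every window scores 0 with p = 1; nothing can
  # pass any threshold below 1
  bgm <- rag_pwm(matrix(c(0.3, 0.2, 0.2, 0.3), nrow = 4, ncol = 6))
  t0 <- score_pvalue_table(bgm)
  expect_equal(pwm_pvalue(t0, 0), 1)
  expect_identical(pwm_hit_threshold(t0, 0.5), Inf)
  expect_error(score_pvalue_table(hept, granularity = 0), "granularity")
})

test_that("full RSS composition has background spacers and additive scores", {
  pw <- default_rag_pwms()
  f12 <- compose_full_rss(pw$heptamer, pw$nonamer, 12L)
  f23 <- compose_full_rss(pw$heptamer, pw$nonamer, 23L)
  expect_equal(f12$width, 28L)
  expect_equal(f23$width, 39L)
  expect_error(compose_full_rss(pw$heptamer, pw$nonamer, 15), "12 or 23")
  # spacer columns contribute exactly zero: full score decomposes into
  # heptamer + nonamer sub-window scores
  withr::with_seed(21, {
    for (i in 1:25) {
      w <- paste(sample(c("A", "C", "G", "T"), 39, TRUE), collapse = "")
      expect_equal(
        score_window(f23, w),
        score_window(pw$heptamer, substr(w, 1, 7)) +
          score_window(pw$nonamer, substr(w, 31, 39)),
        tolerance = 1e-12)
    }
  })
})

test_that("scan_flank reports planted motifs with signed offsets", {
  motifs <- prepare_motifs(rss_motif_set())
  withr::with_seed(31, {
    bgseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                      prob = c(0.3, 0.2, 0.2, 0.3)),
                               collapse = "")
    # heptamer starting at the 3rd interior base of the left flank
    left <- paste0(bgseq(52), "CACAGTG", bgseq(42))
    hits <- scan_flank(left, motifs, breakpoint_offset = 50, side = "left")
    h <- hits[hits$motif == "heptamer", ]
    expect_equal(nrow(h), 1L)
    expect_equal(h$strand, "+")
    expect_equal(h$offset, 3L)
    # reverse-complemented plant: same position, minus strand
    left_rc <- paste0(substr(left, 1, 52), "CACTGTG",
                      substr(left, 60, 101))
    h2 <- scan_flank(left_rc, motifs, breakpoint_offset = 50,
                     side = "left")
    h2 <- h2[h2$motif == "heptamer", ]
    expect_equal(h2$strand, "-")
    expect_equal(h2$offset, 3L)
    # right side: interior is leftward, flush match has offset +1
    right <- paste0(bgseq(43), "CACAGTG", bgseq(50))
    h3 <- scan_flank(right, motifs, breakpoint_offset = 50,
                     side = "right")
    h3 <- h3[h3$motif == "heptamer", ]
    expect_equal(h3$offset, 1L)
    expect_equal(h3$strand, "+")
  })
  # sequences shorter than the smallest motif give an empty result
  expect_equal(nrow(scan_flank("ACGT", motifs, breakpoint_offset = 2,
                               side = "left")), 0L)
})

test_that("scanning is strand-symmetric", {
  motifs <- prepare_motifs(rss_motif_set())
  withr::with_seed(32, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
      # plant a consensus heptamer somewhere interior
      at <- sample(55:100, 1)
      substr(s, at, at + 6) <- "CACAGTG"
      a <- scan_flank(s, motifs, breakpoint_offset = 50, side = "left")
      b <- scan_flank(oracle_revcomp(s), motifs,
                      breakpoint_offset = nchar(s) - 50, side = "right")
      key <- function(h) {
        h <- h[order(h$motif, h$offset, h$strand), ]
        paste(h$motif, h$offset, round(h$score, 6))
      }
      expect_identical(key(a), key(b))
      swap <- c("+" = "-", "-" = "+")
      expect_identical(
        unname(swap[a$strand[order(a$motif, a$offset, a$strand)]]),
        b$strand[order(b$motif, b$offset, b$strand)])
    }
  })
})

test_that("false-hit rate in background sequence matches the exact p-mass", {
  motifs <- prepare_motifs(rss_motif_set()["heptamer"])
  tab <- motifs$heptamer$pvalue_table
  # effective per-window pass probability = p-value mass below 1e-4
  s_star <- pwm_hit_threshold(tab, 1e-4)
  alpha_eff <- pwm_pvalue(tab, s_star)
  n_seq <- 1000
  n_win <- 101 - 7 + 1
  hits <- withr::with_seed(33, {
    vapply(seq_len(n_seq), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 101, TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
      nrow(scan_flank(s, motifs, breakpoint_offset = 50, side = "left"))
    }, numeric(1))
  })
  expected <- n_seq * n_win * 2 * alpha_eff
  sd3 <- 3 * sqrt(expected)   # Poisson-scale tolerance
  expect_lt(abs(sum(hits) - expected), sd3 + 1)
})

test_that("collapse keeps the single best hit per motif", {
  hits <- tibble::tibble(
    motif = c("heptamer", "heptamer", "nonamer"),
    strand = c("+", "-", "+"), start = c(10L, 20L, 30L),
    width = c(7L, 7L, 9L), offset = c(5L, -2L, 4L),
    score = c(10, 12, 8), pvalue = c(1e-5, 1e-6, 2e-5))
  cc <- collapse_hits(hits)
  expect_equal(nrow(cc), 2L)
  expect_equal(cc$offset[cc$motif == "heptamer"], -2L)  # lowest p wins
  # tie on p: smaller |offset|, then interior preferred
  tie <- tibble::tibble(
    motif = "heptamer", strand = c("+", "+", "-"),
    start = c(1L, 2L, 3L), width = 7L, offset = c(-3L, 3L, 8L),
    score = 10, pvalue = 1e-5)
  expect_equal(collapse_hits(tie)$offset, 3L)
})
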