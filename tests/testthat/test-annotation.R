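test_that("target status uses the inclusive 1000 bp buffer", {
  regions <- tibble::tibble(chrom = "chr14", start = 10000L, end = 20000L,
                            label = "IgH")
  del <- function(l, r, ch = "chr14") {
    tibble::tibble(patient_id = "P01", chrom = ch, left_bp = l,
                   right_bp = r, vaf = 0.3, junction_insert = NA)
  }
  # breakpoint inside the locus
  expect_equal(classify_target_status(del(15000L, 60000L), regions),
               "ig_tcr")
  # both breakpoints more than 1000 bp away
  expect_equal(classify_target_status(del(30000L, 60000L), regions),
               "off_target")
  # exactly 1000 bp from the region edge: buffer is inclusive
  expect_equal(classify_target_status(del(9000L, 9500L), regions),
               "ig_tcr")
  expect_equal(classify_target_status(del(7000L, 8999L), regions),
               "off_target")
  # chromosome absent from the region set -> off-target, with a note
  expect_message(
    st <- classify_target_status(del(15000L, 60000L, ch = "chrX"),
                                 regions),
    "absent")
  expect_equal(st, "off_target")
})

test_that("target status agrees with a brute-force base-overlap check", {
  withr::with_seed(41, {
    for (trial in 1:40) {
      nr <- sample(1:4, 1)
      regions <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), nr, TRUE),
        start = sample(0:5000, nr))
      regions$end <- regions$start + sample(50:800, nr, TRUE)
      regions$label <- paste0("L", seq_len(nr))
      buffer <- sample(c(0L, 100L, 1000L), 1)
      n <- 25
      del <- tibble::tibble(
        patient_id = "P", chrom = sample(c("chr1", "chr2"), n, TRUE),
        left_bp = sample(0:8000, n))
      del$right_bp <- del$left_bp + sample(10:2000, n, TRUE)
      got <- classify_target_status(del, regions, buffer)
      inside <- function(ch, p) {
        any(regions$chrom == ch & p >= regions$start - buffer &
              p < regions$end + buffer)
      }
      want <- vapply(seq_len(n), function(i) {
        hit <- inside(del$chrom[i], del$left_bp[i]) ||
          inside(del$chrom[i], del$right_bp[i] - 1L)
        if (hit) "ig_tcr" else "off_target"
      }, character(1))
      expect_identical(got, want)
    }
  })
})

test_that("flank windows are centred on breakpoints and flagged", {
  genome <- random_genome(3000, seed = 5)
  del <- tibble::tibble(patient_id = "P01", chrom = "chr1",
                        left_bp = 1000L, right_bp = 2000L, vaf = 0.3,
                        junction_insert = NA)
  fl <- extract_flanks(del, genome, flank = 50)
  expect_equal(nrow(fl), 2L)
  left <- fl[fl$side == "left", ]
  right <- fl[fl$side == "right", ]
  expect_equal(left$seq, substr(genome, 951, 1050))    # [950, 1050)
  expect_equal(right$seq, substr(genome, 1951, 2050))  # [1950, 2050)
  expect_equal(left$breakpoint_offset, 50L)
  expect_false(any(fl$truncated))
  expect_false(any(fl$interior_overlap))
  # short deletion: interior windows overlap, both still returned
  d2 <- del
  d2$right_bp <- 1060L
  fl2 <- extract_flanks(d2, genome, flank = 50)
  expect_true(all(fl2$interior_overlap))
  expect_equal(nrow(fl2), 2L)
  # breakpoint closer than flank to the contig start: truncated window
  d3 <- del
  d3$left_bp <- 30L
  fl3 <- extract_flanks(d3, genome, flank = 50)
  expect_true(fl3$truncated[fl3$side == "left"])
  expect_equal(fl3$breakpoint_offset[fl3$side == "left"], 30L)
  # wider windows for decay profiling
  fl4 <- extract_flanks(del, genome, flank = 200)
  expect_equal(unname(nchar(fl4$seq)), c(400L, 400L))
})

test_that("RAG classes are mutually exclusive and exhaustive", {
  hit <- function(motif, offset = 5L, strand = "+") {
    tibble::tibble(motif = motif, strand = strand, start = 1L,
                   width = 7L, offset = offset, score = 10,
                   pvalue = 1e-5)
  }
  none <- hit(character(0))
  expect_equal(classify_rag(hit("rss_full_12"), none), "full_one")
  expect_equal(classify_rag(hit("rss_full_23"), hit("rss_full_12")),
               "full_both")
  expect_equal(classify_rag(none, none), "none")
  expect_equal(classify_rag(hit("heptamer"), hit("heptamer")),
               "heptamer_only")
  expect_equal(classify_rag(hit("nonamer"), none), "nonamer_only")
  # heptamer evidence outranks nonamer evidence
  expect_equal(classify_rag(hit("heptamer"), hit("nonamer")),
               "heptamer_only")
  # full RSS on one side plus heptamer on the other is still full_one
  expect_equal(classify_rag(hit("rss_full_12"), hit("heptamer")),
               "full_one")
})

test_that("excision-circle orientation is a strand-by-side rule", {
  expect_true(check_orientation("+", "left", 5L))
  expect_false(check_orientation("-", "left", 5L))
  expect_true(check_orientation("-", "right", 5L))
  expect_false(check_orientation("+", "right", 5L))
  # exterior hits have undefined orientation, not FALSE
  expect_true(is.na(check_orientation("+", "left", -3L)))
})

test_that("interior hits beyond the segment midpoint are clipped", {
  # a 60 bp deletion with one consensus heptamer planted 40 bp interior
  # to the left breakpoint: past the midpoint (30), so it must not count
  # for the left side, while a 10 bp-interior plant must
  genome <- random_genome(2000, seed = 6)
  regions <- tibble::tibble(chrom = "chr1", start = 1900L, end = 1950L,
                            label = "IgH")
  for (off1 in c(40L, 10L)) {
    g <- genome
    substr(g, 1000L + off1, 1000L + off1 + 6L) <- "CACAGTG"
    del <- tibble::tibble(patient_id = "P01", chrom = "chr1",
                          left_bp = 1000L, right_bp = 1060L, vaf = 0.3,
                          junction_insert = NA)
    ann <- annotate_deletions(del, g, regions)
    hl <- ann$left_hits[[1]]
    if (off1 == 40L) {
      expect_false(any(hl$motif == "heptamer" & hl$offset > 0))
    } else {
      expect_true(any(hl$motif == "heptamer" & hl$offset == 10L))
    }
  }
})

test_that("decay profiles are monotone and reflect single hits", {
  mk_ann <- function(offsets_left, offsets_right = integer(0)) {
    hits <- function(off) {
      tibble::tibble(motif = rep("rss_full_12", length(off)),
                     strand = "+", start = 1L, width = 28L,
                     offset = off, score = 10, pvalue = 1e-6)
    }
    tibble::tibble(
      deletion_id = "d1", patient_id = "P01", chrom = "chr1",
      left_bp = 0L, right_bp = 1000L, length = 1000L,
      target_status = "off_target", rag_class = "full_one",
      rag_mediated = TRUE,
      left_hits = list(hits(offsets_left)),
      right_hits = list(hits(offsets_right)))
  }
  d <- decay_profile(mk_ann(10L), distances = c(5, 10, 15, 50))
  di <- d[d$side == "interior", ]
  expect_equal(di$proportion, c(0, 1, 1, 1))
  expect_equal(d$proportion[d$side == "exterior"], rep(0, 4))
  # an exterior hit at -20 shows up only in the exterior curve
  d2 <- decay_profile(mk_ann(integer(0), -20L),
                      distances = c(10, 20, 30))
  expect_equal(d2$proportion[d2$side == "exterior"], c(0, 1, 1))
  expect_equal(d2$proportion[d2$side == "interior"], rep(0, 3))
  # empty annotation set -> empty profile
  expect_equal(nrow(decay_profile(mk_ann(1L)[0, ])), 0L)
  # cohort curves are monotone non-decreasing on both sides
  co <- shared_cohort()
  dc <- decay_profile(co$annotations, distances = seq(5, 50, by = 5))
  for (s in c("interior", "exterior")) {
    expect_true(all(diff(dc$proportion[dc$side == s]) >= 0))
  }
})

test_that("interior decay is consistent with RAG classification at the scan flank", {
  co <- shared_cohort()
  dc <- decay_profile(co$annotations, distances = 50)
  interior50 <- dc$proportion[dc$side == "interior"]
  full_any_prop <- mean(co$annotations$full_any)
  # every deletion counted at d = flank has a full-RSS hit, so the
  # interior curve is bounded by the classification proportion and
  # accounts for most of it (plants are interior; the gap is exterior
  # false positives)
  expect_lte(interior50, full_any_prop)
  expect_gt(interior50, 0.8 * full_any_prop)
})
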