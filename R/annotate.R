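#' Classify deletions as Ig/TCR (on-target) or off-target
#'
#' A deletion is `off_target` iff neither breakpoint lies within any
#' Ig/TCR region expanded by `buffer` bp on both sides (distance to a
#' region edge of exactly `buffer` still counts as on-target). Breakpoint
#' positions are taken as the first and last deleted bases. Deletions on
#' chromosomes absent from the region set are off-target (a note is
#' emitted).
#'
#' @param deletions tibble of deletion calls (see [read_deletions()]).
#' @param regions tibble of Ig/TCR intervals (see [read_regions()]).
#' @param buffer expansion in bp (default 1000).
#' @return character vector, `"ig_tcr"` or `"off_target"` per deletion.
#' @export
classify_target_status <- function(deletions, regions, buffer = 1000) {
  if (nrow(deletions) == 0L) return(character(0))
  missing_chr <- setdiff(unique(deletions$chrom), unique(regions$chrom))
  if (length(missing_chr)) {
    inform(paste0("chromosome(s) absent from region set, treated as ",
                  "off-target: ", paste(missing_chr, collapse = ", ")))
  }
  reg <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(pmax(regions$start + 1L - buffer, 1L),
                     regions$end + buffer)
  )
  pts <- GenomicRanges::GRanges(
    rep(deletions$chrom, 2L),
    IRanges::IRanges(c(deletions$left_bp + 1L, deletions$right_bp), width = 1L)
  )
  # disjoint seqlevels are expected (already noted above), not an error
  ov <- suppressWarnings(GenomicRanges::countOverlaps(pts, reg)) > 0
  n <- nrow(deletions)
  if_else(ov[seq_len(n)] | ov[n + seq_len(n)], "ig_tcr", "off_target")
}

#' Extract breakpoint flank windows
#'
#' For each breakpoint returns the window covering `flank` bases on both
#' sides of the boundary (interior = into the deleted segment: rightward
#' at the left breakpoint, leftward at the right breakpoint). Windows are
#' truncated at contig ends (flagged), and when the deletion is shorter
#' than `2 * flank` the two interior windows overlap (flagged; interior
#' hits are later clipped at the segment midpoint).
#'
#' @param deletions tibble of deletion calls.
#' @param genome named character vector of chromosome sequences.
#' @param flank half-window size in bp (default 50).
#' @return tibble with one row per deletion side: `deletion_id`, `side`,
#'   `seq`, `breakpoint_offset` (bases before the boundary), `truncated`,
#'   `interior_overlap`.
#' @export
extract_flanks <- function(deletions, genome, flank = 50) {
  if (!"deletion_id" %in% names(deletions)) {
    deletions$deletion_id <- sprintf("del%05d", seq_len(nrow(deletions)))
  }
  chrlen <- nchar(genome)
  one_side <- function(bp, chrom, side) {
    len <- chrlen[chrom]
    if (any(is.na(len))) {
      rs_abort(paste0("chromosome absent from genome: ",
                      chrom[is.na(len)][1]))
    }
    w0 <- pmax(bp - flank, 0L)
    w1 <- pmin(bp + flank, len)
    tibble(
      deletion_id = deletions$deletion_id, side = side,
      seq = substr(genome[chrom], w0 + 1L, w1),
      breakpoint_offset = as.integer(bp - w0),
      truncated = (w0 > bp - flank) | (w1 < bp + flank)
    )
  }
  out <- bind_rows(
    one_side(deletions$left_bp, deletions$chrom, "left"),
    one_side(deletions$right_bp, deletions$chrom, "right")
  )
  ov <- (deletions$right_bp - deletions$left_bp) < 2L * flank
  out$interior_overlap <- rep(ov, 2L)
  out |> arrange(.data$deletion_id, .data$side)
}

#' Excision-circle orientation of an interior heptamer hit
#'
#' True iff the heptamer's 5'-CAC end faces the junction, the orientation
#' in which typical V(D)J recombination deletes the signal ends as an
#' excision circle: at the left breakpoint the match must be on the plus
#' strand (reading 5'->3' into the deletion), at the right breakpoint on
#' the minus strand. Exterior or boundary-straddling hits have no defined
#' orientation (`NA`).
#'
#' @param strand `"+"` or `"-"` (vectorised).
#' @param side `"left"` or `"right"` (vectorised or scalar).
#' @param offset signed breakpoint-relative offset of the hit; only
#'   `offset > 0` (interior) hits are evaluated.
#' @return logical vector (`NA` for non-interior hits).
#' @export
check_orientation <- function(strand, side, offset = 1L) {
  ok <- if_else(side == "left", strand == "+", strand == "-")
  if_else(offset > 0, ok, NA)
}

#' Classify the RAG evidence of one deletion from its motif hits
#'
#' `full_both`/`full_one` record a full RSS hit (either spacer variant) at
#' both or exactly one breakpoint; deletions with those classes are
#' "putatively RAG-mediated". Otherwise `heptamer_only` (some heptamer
#' hit, no full RSS anywhere), `nonamer_only` (nonamer hits only), or
#' `none`. Classes are mutually exclusive and exhaustive; heptamer
#' evidence outranks nonamer evidence when both are present.
#'
#' @param left_hits,right_hits hit tibbles for the two breakpoints
#'   ([scan_flank()] output, collapsed or not).
#' @return one of `"full_both"`, `"full_one"`, `"heptamer_only"`,
#'   `"nonamer_only"`, `"none"`.
#' @export
classify_rag <- function(left_hits, right_hits) {
  full <- c("rss_full_12", "rss_full_23")
  fl <- any(left_hits$motif %in% full)
  fr <- any(right_hits$motif %in% full)
  if (fl && fr) return("full_both")
  if (fl || fr) return("full_one")
  if (any(c(left_hits$motif, right_hits$motif) == "heptamer")) {
    return("heptamer_only")
  }
  if (any(c(left_hits$motif, right_hits$motif) == "nonamer")) {
    return("nonamer_only")
  }
  "none"
}

#' Annotate a deletion callset with RSS motif evidence
#'
#' The main per-deletion analysis: extracts breakpoint flanks, scans both
#' strands for the motif set (heptamer, nonamer, both full-RSS spacer
#' variants) at the exact-p-value threshold, assigns target status and
#' RAG class, per-motif indicator columns, and excision-circle
#' orientation flags for interior heptamers.
#'
#' For deletions shorter than `2 * flank`, interior hits extending beyond
#' the segment midpoint are discarded on each side so a single interior
#' motif cannot satisfy both breakpoints.
#'
#' @inheritParams classify_target_status
#' @inheritParams extract_flanks
#' @param motifs motif list (default [rss_motif_set()]).
#' @param threshold match p-value cutoff (default 1e-4).
#' @param granularity DP score discretisation (default 1e-3 bits).
#' @return tibble, one row per deletion: identifiers and coordinates,
#'   `target_status`, `rag_class`, indicator columns (`full_left`,
#'   `full_right`, `full_any`, `full_both`, same for `hept`/`nona`),
#'   `rag_mediated`, `orientation_ok_left`/`_right`, and list-columns
#'   `left_hits`/`right_hits` holding the collapsed hits.
#' @export
annotate_deletions <- function(deletions, genome, regions,
                               motifs = rss_motif_set(), flank = 50,
                               threshold = 1e-4, buffer = 1000,
                               granularity = 1e-3) {
  n <- nrow(deletions)
  if (!"deletion_id" %in% names(deletions)) {
    deletions$deletion_id <- sprintf("del%05d", seq_len(n))
  }
  motifs <- prepare_motifs(motifs, granularity)
  status <- classify_target_status(deletions, regions, buffer)
  flanks <- extract_flanks(deletions, genome, flank)
  fl_left <- flanks[flanks$side == "left", ]
  fl_right <- flanks[flanks$side == "right", ]
  fl_left <- fl_left[match(deletions$deletion_id, fl_left$deletion_id), ]
  fl_right <- fl_right[match(deletions$deletion_id, fl_right$deletion_id), ]
  len <- deletions$right_bp - deletions$left_bp
  half <- pmax(len %/% 2L, 0L)

  scan_side <- function(i, fl, side) {
    h <- scan_flank(fl$seq[i], motifs, threshold, fl$breakpoint_offset[i],
                    side)
    if (nrow(h) && len[i] < 2L * flank) {
      keep <- !(h$offset > 0 & (h$offset + h$width - 1L) > half[i])
      h <- h[keep, , drop = FALSE]
    }
    collapse_hits(h)
  }

  full <- c("rss_full_12", "rss_full_23")
  left_hits <- vector("list", n)
  right_hits <- vector("list", n)
  ind <- matrix(FALSE, nrow = n, ncol = 6,
                dimnames = list(NULL, c("full_left", "full_right",
                                        "hept_left", "hept_right",
                                        "nona_left", "nona_right")))
  rag_class <- character(n)
  orient_l <- rep(NA, n)
  orient_r <- rep(NA, n)
  for (i in seq_len(n)) {
    hl <- scan_side(i, fl_left, "left")
    hr <- scan_side(i, fl_right, "right")
    left_hits[[i]] <- hl
    right_hits[[i]] <- hr
    ind[i, ] <- c(any(hl$motif %in% full), any(hr$motif %in% full),
                  any(hl$motif == "heptamer"), any(hr$motif == "heptamer"),
                  any(hl$motif == "nonamer"), any(hr$motif == "nonamer"))
    rag_class[i] <- classify_rag(hl, hr)
    hli <- hl[hl$motif == "heptamer" & hl$offset > 0, ]
    hri <- hr[hr$motif == "heptamer" & hr$offset > 0, ]
    if (nrow(hli)) orient_l[i] <- check_orientation(hli$strand[1], "left",
                                                    hli$offset[1])
    if (nrow(hri)) orient_r[i] <- check_orientation(hri$strand[1], "right",
                                                    hri$offset[1])
  }
  tibble(
    deletion_id = deletions$deletion_id,
    patient_id = deletions$patient_id,
    chrom = deletions$chrom, left_bp = deletions$left_bp,
    right_bp = deletions$right_bp, length = len,
    target_status = status, rag_class = rag_class,
    rag_mediated = rag_class %in% c("full_both", "full_one"),
    full_left = ind[, "full_left"], full_right = ind[, "full_right"],
    full_any = ind[, "full_left"] | ind[, "full_right"],
    full_both = ind[, "full_left"] & ind[, "full_right"],
    hept_left = ind[, "hept_left"], hept_right = ind[, "hept_right"],
    hept_any = ind[, "hept_left"] | ind[, "hept_right"],
    hept_both = ind[, "hept_left"] & ind[, "hept_right"],
    nona_left = ind[, "nona_left"], nona_right = ind[, "nona_right"],
    nona_any = ind[, "nona_left"] | ind[, "nona_right"],
    nona_both = ind[, "nona_left"] & ind[, "nona_right"],
    orientation_ok_left = orient_l, orientation_ok_right = orient_r,
    left_hits = left_hits, right_hits = right_hits
  )
}

#' Motif signal decay with distance from the breakpoint
#'
#' For each distance `d` in `distances`, the proportion of deletions with
#' at least one hit of the requested motifs whose signed offset falls in
#' `(0, d]` (interior) or `[-d, 0)` (exterior), pooling both breakpoints.
#' Both curves are monotone non-decreasing in `d` by construction.
#'
#' @param annotations output of [annotate_deletions()] (run with `flank`
#'   at least `max(distances)` for a complete profile).
#' @param distances distance grid in bp (default `seq(5, 200, by = 5)`).
#' @param motifs motif names to count (default the two full-RSS
#'   variants).
#' @return tibble with columns `distance`, `side`
#'   (`"interior"`/`"exterior"`), `proportion`, `n`.
#' @export
decay_profile <- function(annotations, distances = seq(5, 200, by = 5),
                          motifs = c("rss_full_12", "rss_full_23")) {
  n <- nrow(annotations)
  if (n == 0L) {
    return(tibble(distance = integer(), side = character(),
                  proportion = numeric(), n = integer()))
  }
  offs <- purrr::map2(annotations$left_hits, annotations$right_hits,
                      function(l, r) {
                        c(l$offset[l$motif %in% motifs],
                          r$offset[r$motif %in% motifs])
                      })
  per_d <- function(d, interior) {
    hit <- purrr::map_lgl(offs, function(o) {
      if (interior) any(o > 0 & o <= d) else any(o < 0 & o >= -d)
    })
    mean(hit)
  }
  bind_rows(
    tibble(distance = distances, side = "interior",
           proportion = purrr::map_dbl(distances, per_d, interior = TRUE),
           n = n),
    tibble(distance = distances, side = "exterior",
           proportion = purrr::map_dbl(distances, per_d, interior = FALSE),
           n = n)
  )
}

#' Cohort-level excision-circle orientation summary
#'
#' Counts interior heptamer hits (one collapsed hit per breakpoint) and
#' the fraction in correct excision-circle orientation, overall and by
#' target status.
#'
#' @param annotations output of [annotate_deletions()].
#' @return tibble with `target_status` (including `"all"`), `n_interior`,
#'   `n_correct`, `prop_correct`.
#' @export
orientation_summary <- function(annotations) {
  flags <- c(annotations$orientation_ok_left,
             annotations$orientation_ok_right)
  status <- rep(annotations$target_status, 2L)
  one <- function(f) {
    f <- f[!is.na(f)]
    tibble(n_interior = length(f), n_correct = sum(f),
           prop_correct = if (length(f)) mean(f) else NA_real_)
  }
  bind_rows(
    mutate(one(flags), target_status = "all", .before = 1),
    mutate(one(flags[status == "ig_tcr"]), target_status = "ig_tcr",
           .before = 1),
    mutate(one(flags[status == "off_target"]), target_status = "off_target",
           .before = 1)
  )
}
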