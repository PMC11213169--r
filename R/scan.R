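#' Attach exact p-value tables to a motif set
#'
#' Precomputes the DP score-to-p-value table for each motif once, so that
#' repeated flank scans only do score lookups.
#'
#' @param motifs named list of [rag_pwm] objects (e.g. [rss_motif_set()]).
#' @param granularity discretisation step passed to [score_pvalue_table()].
#' @return the same list with `pvalue_table`, `logodds` and `rc_logodds`
#'   attached to each motif.
#' @export
prepare_motifs <- function(motifs, granularity = 1e-3) {
  lapply(motifs, function(m) {
    if (is.null(m$pvalue_table)) {
      m$pvalue_table <- score_pvalue_table(m, granularity)
      m$logodds <- pwm_logodds(m)
      m$rc_logodds <- pwm_logodds(pwm_revcomp(m))
    }
    m
  })
}

#' Breakpoint-relative signed offset of motif matches
#'
#' Offsets are signed 1-based distances from the breakpoint boundary to
#' the junction-proximal base of the match: positive = interior to the
#' deletion (a match flush against the junction has offset +1), negative =
#' exterior. A match that straddles the boundary gets offset 0. At the
#' left breakpoint interior is rightward; at the right breakpoint,
#' leftward.
#'
#' @param a,e 1-based start/end of the match within the scanned sequence.
#' @param B number of sequence bases before the breakpoint boundary.
#' @param side `"left"` or `"right"`.
#' @noRd
hit_offset <- function(a, e, B, side) {
  if (side == "left") {
    if_else(a >= B + 1L, a - B, if_else(e <= B, e - B - 1L, 0L))
  } else {
    if_else(e <= B, B - e + 1L, if_else(a >= B + 1L, -(a - B), 0L))
  }
}

#' Scan a breakpoint flank for motif matches on both strands
#'
#' Every window whose exact match p-value is below `threshold` is
#' reported, on both strands, with its breakpoint-relative signed offset
#' (see Details). Hits are sorted by p-value then |offset|.
#'
#' Minus-strand matches are found by scanning the sequence with the
#' reverse-complemented matrix, so reported coordinates always refer to
#' the plus strand of the input sequence.
#'
#' @param seq nucleotide string (a window around one breakpoint).
#' @param motifs prepared motif list from [prepare_motifs()] (a plain
#'   motif list is prepared on the fly).
#' @param threshold match p-value cutoff (default 1e-4).
#' @param breakpoint_offset number of bases of `seq` that lie before the
#'   breakpoint boundary (for a window covering `flank` bases on each
#'   side, this is `flank`).
#' @param side which breakpoint the window belongs to: `"left"` (interior
#'   of the deletion is rightward) or `"right"` (interior leftward).
#' @return tibble with columns `motif`, `strand`, `start`, `width`,
#'   `offset`, `score`, `pvalue`. Zero rows when the sequence is shorter
#'   than every motif or nothing passes.
#' @export
scan_flank <- function(seq, motifs, threshold = 1e-4, breakpoint_offset,
                       side = c("left", "right")) {
  side <- match.arg(side)
  if (is.null(motifs[[1]]$pvalue_table)) motifs <- prepare_motifs(motifs)
  codes <- encode_seq(seq)
  B <- as.integer(breakpoint_offset)
  motif_v <- character(0); strand_v <- character(0)
  start_v <- integer(0); width_v <- integer(0)
  score_v <- numeric(0); pval_v <- numeric(0)
  for (m in motifs) {
    for (strand in c("+", "-")) {
      L <- if (strand == "+") m$logodds else m$rc_logodds
      sc <- score_all_windows(m, codes, logodds = L)
      if (!length(sc)) next
      pv <- pwm_pvalue(m$pvalue_table, sc)
      hit <- which(pv < threshold)
      if (!length(hit)) next
      nh <- length(hit)
      motif_v <- c(motif_v, rep.int(m$name, nh))
      strand_v <- c(strand_v, rep.int(strand, nh))
      start_v <- c(start_v, hit)
      width_v <- c(width_v, rep.int(m$width, nh))
      score_v <- c(score_v, sc[hit])
      pval_v <- c(pval_v, pv[hit])
    }
  }
  off_v <- hit_offset(start_v, start_v + width_v - 1L, B, side)
  ord <- order(pval_v, abs(off_v))
  tibble(motif = motif_v[ord], strand = strand_v[ord],
         start = start_v[ord], width = width_v[ord], offset = off_v[ord],
         score = score_v[ord], pvalue = pval_v[ord])
}

#' Collapse overlapping hits to the single best hit per motif
#'
#' For each motif keeps the hit with the lowest p-value, breaking ties by
#' smallest |offset| and then by interior (positive offset) position.
#' Deletions are counted as having "a" motif, so hit multiplicity within
#' one breakpoint window carries no information.
#'
#' @param hits tibble from [scan_flank()].
#' @return tibble with at most one row per motif name.
#' @export
collapse_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$pvalue, abs(hits$offset), -sign(hits$offset))
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$motif), , drop = FALSE]
}
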