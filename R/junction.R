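#' Longest shared sequence ending at both breakpoints (microhomology)
#' @noRd
mh_length <- function(chromseq, left_bp, right_bp, cap = 25L) {
  m_max <- min(cap, left_bp, right_bp - left_bp)
  m <- 0L
  while (m < m_max) {
    a <- substr(chromseq, left_bp - m, left_bp - m)        # 0-based left_bp-1-m
    b <- substr(chromseq, right_bp - m, right_bp - m)
    if (a != b) break
    m <- m + 1L
  }
  m
}

#' Longest prefix of x matching the reference from 0-based position `at`
#' @noRd
match_forward <- function(x, chromseq, at, cap) {
  k <- 0L
  while (k < cap &&
         substr(x, k + 1L, k + 1L) ==
           substr(chromseq, at + k + 1L, at + k + 1L)) {
    k <- k + 1L
  }
  k
}

#' Longest suffix of x matching the reference ending at 0-based `end - 1`
#' @noRd
match_backward <- function(x, chromseq, end, cap) {
  k <- 0L
  nx <- nchar(x)
  while (k < cap &&
         substr(x, nx - k, nx - k) == substr(chromseq, end - k, end - k)) {
    k <- k + 1L
  }
  k
}

#' Resolve deletion junctions into NTN, microhomology or blunt joins
#'
#' When a tumor-observed junction insert is present, its longest prefix
#' matching the reference continuation past the left breakpoint and its
#' longest suffix matching the reference preceding the right breakpoint
#' are stripped (they are templated; the breakpoints are correspondingly
#' re-normalised); the remaining middle bases are non-templated
#' nucleotides (NTN). When the insert is empty, the junction is
#' classified by microhomology: the longest exact match (capped at 25 bp)
#' between the bases ending at the left breakpoint and those ending at
#' the right breakpoint; a zero-length match is a blunt join. Missing
#' inserts are `unresolved`.
#'
#' @param deletions tibble with `chrom`, `left_bp`, `right_bp` and
#'   `junction_insert` (`NA` = not reported, `""` = no inserted bases).
#' @param genome named character vector of chromosome sequences.
#' @param mh_cap microhomology search cap in bp (default 25).
#' @return tibble with one row per deletion: `status` (`ntn`,
#'   `microhomology`, `blunt`, `unresolved`), `ntn_seq`, `ntn_len`,
#'   `mh_len`, and breakpoint re-normalisation shifts `shift_left`,
#'   `shift_right`.
#' @export
resolve_junction <- function(deletions, genome, mh_cap = 25L) {
  n <- nrow(deletions)
  status <- character(n)
  ntn_seq <- character(n)
  mh <- integer(n)
  sh_l <- integer(n)
  sh_r <- integer(n)
  ins_all <- deletions$junction_insert
  bad <- !is.na(ins_all) & grepl("[^ACGTNacgtn]", ins_all)
  if (any(bad)) {
    rs_abort(sprintf("record %d: junction insert contains non-ACGTN characters",
                     which(bad)[1]))
  }
  for (i in seq_len(n)) {
    ins <- ins_all[i]
    chromseq <- genome[[deletions$chrom[i]]]
    lb <- deletions$left_bp[i]
    rb <- deletions$right_bp[i]
    if (is.na(ins)) {
      status[i] <- "unresolved"
      ntn_seq[i] <- NA_character_
      mh[i] <- NA_integer_
      next
    }
    ins <- toupper(ins)
    if (nchar(ins) > 0L) {
      len <- rb - lb
      p <- match_forward(ins, chromseq, lb, cap = min(nchar(ins), len))
      rest <- substr(ins, p + 1L, nchar(ins))
      s <- 0L
      if (nchar(rest) > 0L) {
        s <- match_backward(rest, chromseq, rb, cap = min(nchar(rest),
                                                          len - p))
      }
      mid <- substr(rest, 1L, nchar(rest) - s)
      sh_l[i] <- p
      sh_r[i] <- s
      if (nchar(mid) > 0L) {
        status[i] <- "ntn"
        ntn_seq[i] <- mid
      } else {
        m <- mh_length(chromseq, lb + p, rb - s, cap = mh_cap)
        mh[i] <- m
        status[i] <- if (m > 0L) "microhomology" else "blunt"
        ntn_seq[i] <- ""
      }
    } else {
      m <- mh_length(chromseq, lb, rb, cap = mh_cap)
      mh[i] <- m
      status[i] <- if (m > 0L) "microhomology" else "blunt"
      ntn_seq[i] <- ""
    }
  }
  n_shift <- sum(sh_l > 0 | sh_r > 0)
  if (n_shift > 0) {
    inform(sprintf(
      "%d junction insert(s) partly templated; breakpoints re-normalised",
      n_shift))
  }
  tibble(
    status = status, ntn_seq = ntn_seq,
    ntn_len = if_else(is.na(ntn_seq), NA_integer_, nchar(ntn_seq)),
    mh_len = mh, shift_left = sh_l, shift_right = sh_r
  )
}

#' Attach junction results to annotated deletions
#'
#' @param annotations output of [annotate_deletions()].
#' @param deletions the deletion tibble the annotations were built from
#'   (carries `junction_insert`).
#' @param genome named character vector of chromosome sequences.
#' @inheritParams resolve_junction
#' @return `annotations` with columns `junction_status`, `ntn_seq`,
#'   `ntn_len`, `mh_len` appended.
#' @export
annotate_junctions <- function(annotations, deletions, genome,
                               mh_cap = 25L) {
  if (!"deletion_id" %in% names(deletions)) {
    deletions$deletion_id <- sprintf("del%05d", seq_len(nrow(deletions)))
  }
  ord <- match(annotations$deletion_id, deletions$deletion_id)
  if (any(is.na(ord))) rs_abort("annotations refer to unknown deletions")
  jr <- resolve_junction(deletions[ord, , drop = FALSE], genome, mh_cap)
  annotations$junction_status <- jr$status
  annotations$ntn_seq <- jr$ntn_seq
  annotations$ntn_len <- jr$ntn_len
  annotations$mh_len <- jr$mh_len
  annotations
}

#' NTN proportion by RAG class
#'
#' Proportions of junctions containing non-templated nucleotides among
#' resolved junctions, grouped as full-RSS-at-both-breakpoints, full RSS
#' at one breakpoint, and everything else. Total counts are reported
#' alongside; classes with no resolved junction get `NA` proportions.
#'
#' @param annotations output of [annotate_junctions()].
#' @return tibble with `class_group`, `n_total`, `n_resolved`, `n_ntn`,
#'   `prop_ntn`.
#' @export
ntn_by_class <- function(annotations) {
  grp <- dplyr::case_when(
    annotations$rag_class == "full_both" ~ "full_both",
    annotations$rag_class == "full_one" ~ "full_one",
    TRUE ~ "other"
  )
  tibble(class_group = factor(grp, levels = c("full_both", "full_one",
                                              "other")),
         status = annotations$junction_status) |>
    group_by(.data$class_group, .drop = FALSE) |>
    summarise(
      n_total = n(),
      n_resolved = sum(.data$status != "unresolved"),
      n_ntn = sum(.data$status == "ntn"),
      prop_ntn = if_else(.data$n_resolved > 0,
                         .data$n_ntn / .data$n_resolved, NA_real_),
      .groups = "drop"
    ) |>
    mutate(class_group = as.character(.data$class_group))
}
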