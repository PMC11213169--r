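#' Position-weight matrices for RSS motif scanning
#'
#' A `rag_pwm` holds per-position probabilities over A/C/G/T together with
#' the 0-order background model used for log-odds scoring. The default
#' background is the one used for all breakpoint scans: A/T 0.3, C/G 0.2.
#'
#' @param probs numeric matrix, 4 rows (A, C, G, T) by width columns.
#'   Columns are normalised to sum to 1; zero cells are replaced by
#'   `pseudocount` before normalisation.
#' @param name motif name, e.g. `"heptamer"`.
#' @param background named numeric vector of length 4 over A, C, G, T.
#' @param pseudocount value substituted for zero cells before column
#'   renormalisation (default 0.01).
#' @return an object of class `rag_pwm`.
#' @examples
#' m <- consensus_pwm("CACAGTG", name = "heptamer")
#' m$width
#' @export
rag_pwm <- function(probs, name = "motif", background = default_background(),
                    pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) rs_abort("`probs` must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 1L) rs_abort("PWM width must be at least 1")
  if (any(probs < 0)) rs_abort("PWM cells must be nonnegative")
  cs <- colSums(probs)
  if (any(cs == 0)) rs_abort("PWM column sums to 0")
  probs[probs == 0] <- pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  rownames(probs) <- DNA_BASES4
  background <- background[DNA_BASES4]
  if (abs(sum(background) - 1) > 1e-9) rs_abort("background must sum to 1")
  structure(
    list(name = name, width = ncol(probs), probs = probs,
         background = background),
    class = "rag_pwm"
  )
}

#' @export
print.rag_pwm <- function(x, ...) {
  cat("<rag_pwm>", x$name, " width", x$width, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Consensus-weighted PWM from a consensus sequence
#'
#' Builds a matrix giving `weight` to the consensus base at each position
#' and `(1 - weight)/3` to the other three bases.
#'
#' @param consensus consensus nucleotide string.
#' @param weight probability of the consensus base per position.
#' @inheritParams rag_pwm
#' @return a `rag_pwm`.
#' @export
consensus_pwm <- function(consensus, name = consensus, weight = 0.8,
                          background = default_background()) {
  codes <- encode_seq(consensus)
  if (any(codes == 5L)) rs_abort("consensus must be over A/C/G/T")
  w <- length(codes)
  probs <- matrix((1 - weight) / 3, nrow = 4, ncol = w)
  probs[cbind(codes, seq_len(w))] <- weight
  rag_pwm(probs, name = name, background = background)
}

#' Default RSS heptamer and nonamer matrices
#'
#' Consensus-weighted matrices centred on the canonical RSS heptamer
#' CACAGTG and nonamer ACAAAAACC with 0.8 consensus-base weight. These are
#' overridable defaults: matrices from the literature can be supplied via
#' [read_pwm()] wherever a motif set is accepted.
#'
#' @param weight consensus-base weight (default 0.8).
#' @param background 0-order background probabilities.
#' @return named list with elements `heptamer` and `nonamer`.
#' @export
default_rag_pwms <- function(weight = 0.8, background = default_background()) {
  list(
    heptamer = consensus_pwm("CACAGTG", name = "heptamer", weight = weight,
                             background = background),
    nonamer = consensus_pwm("ACAAAAACC", name = "nonamer", weight = weight,
                            background = background)
  )
}

#' Log-odds matrix in bits, with an all-zero fifth row for N
#' @noRd
pwm_logodds <- function(pwm) {
  L <- log2(pwm$probs / pwm$background)
  rbind(L, N = rep(0, pwm$width))
}

#' Reverse-complemented PWM (scan the minus strand of a sequence)
#' @noRd
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[4:1, pwm$width:1, drop = FALSE]
  rownames(probs) <- DNA_BASES4
  out <- pwm
  out$probs <- probs
  out
}

#' Log-odds score of one window under a PWM
#'
#' The score is \eqn{\sum_i \log_2(p_i(b_i)/q(b_i))} in bits, where
#' \eqn{p_i} is the column probability and \eqn{q} the background. An `N`
#' base contributes exactly 0 (neither reward nor penalty).
#'
#' @param pwm a [rag_pwm].
#' @param window nucleotide string of length `pwm$width`.
#' @return log-odds score in bits.
#' @examples
#' score_window(consensus_pwm("CACAGTG"), "CACAGTG")
#' @export
score_window <- function(pwm, window) {
  codes <- encode_seq(window)
  if (length(codes) != pwm$width) {
    rs_abort(sprintf("window length %d != PWM width %d",
                     length(codes), pwm$width))
  }
  L <- pwm_logodds(pwm)
  sum(L[cbind(codes, seq_along(codes))])
}

#' Scores of every window of an encoded sequence (internal fast path)
#' @param codes integer codes from encode_seq()
#' @return numeric vector of length length(codes) - width + 1 (empty if
#'   shorter than the motif)
#' @noRd
score_all_windows <- function(pwm, codes, logodds = NULL) {
  w <- pwm$width
  nwin <- length(codes) - w + 1L
  if (nwin < 1L) return(numeric(0))
  L <- logodds %||% pwm_logodds(pwm)
  idx <- outer(seq_len(w) - 1L, seq_len(nwin), "+")
  contrib <- L[cbind(as.vector(codes[idx]), rep.int(seq_len(w), nwin))]
  colSums(matrix(contrib, nrow = w))
}

#' Exact score-to-p-value table for a PWM
#'
#' Computes, by dynamic programming over discretised per-position score
#' contributions, the exact distribution of the log-odds score of a window
#' drawn from the 0-order background, and returns the upper-tail mapping
#' p(s) = P(score >= s). This is the FIMO-style match p-value: monotone
#' non-increasing in the score, equal to 1 at the minimum attainable score.
#'
#' @param pwm a [rag_pwm].
#' @param granularity score discretisation step in bits (default 1e-3;
#'   rounding error is bounded by `width * granularity / 2`).
#' @return an object of class `rag_pvalue_table`.
#' @seealso [pwm_pvalue()], [pwm_hit_threshold()]
#' @export
score_pvalue_table <- function(pwm, granularity = 1e-3) {
  if (granularity <= 0) rs_abort("granularity must be > 0")
  L <- log2(pwm$probs / pwm$background)
  K <- matrix(as.integer(round(L / granularity)), nrow = 4)
  bg <- pwm$background
  p <- 1
  cur_min <- 0L
  for (j in seq_len(pwm$width)) {
    kj <- K[, j]
    mink <- min(kj); maxk <- max(kj)
    len <- length(p)
    newp <- numeric(len + (maxk - mink))
    for (b in 1:4) {
      pos <- (kj[b] - mink) + seq_len(len)
      newp[pos] <- newp[pos] + p * bg[b]
    }
    p <- newp
    cur_min <- cur_min + mink
  }
  pvals <- rev(cumsum(rev(p)))
  pvals <- pmin(pvals, 1)
  structure(
    list(name = pwm$name, granularity = granularity, min_int = cur_min,
         pvals = pvals),
    class = "rag_pvalue_table"
  )
}

#' Look up the exact p-value of a score
#'
#' @param table a `rag_pvalue_table` from [score_pvalue_table()].
#' @param score numeric vector of log-odds scores in bits.
#' @return p-values in (0, 1], vectorised over `score`.
#' @export
pwm_pvalue <- function(table, score) {
  i <- as.integer(round(score / table$granularity)) - table$min_int + 1L
  i <- pmin(pmax(i, 1L), length(table$pvals))
  table$pvals[i]
}

#' Smallest score whose exact p-value is below a threshold
#'
#' @inheritParams pwm_pvalue
#' @param alpha p-value threshold (default 1e-4).
#' @return the minimal score s with p(s) < alpha, or `Inf` when no
#'   attainable score passes.
#' @export
pwm_hit_threshold <- function(table, alpha = 1e-4) {
  hit <- which(table$pvals < alpha)
  if (length(hit) == 0L) return(Inf)
  (table$min_int + hit[1] - 1L) * table$granularity
}

#' Compose a full RSS matrix from heptamer, spacer and nonamer
#'
#' The full recombination signal sequence is heptamer + 12- or 23-nt
#' spacer + nonamer. The spacer columns equal the background distribution,
#' so they contribute exactly zero to every window's log-odds score and
#' the full-matrix score decomposes as heptamer score + nonamer score of
#' the corresponding sub-windows.
#'
#' @param heptamer `rag_pwm` of width 7.
#' @param nonamer `rag_pwm` of width 9.
#' @param spacer_len 12 or 23.
#' @return a `rag_pwm` of width 28 or 39 named `rss_full_12`/`rss_full_23`.
#' @export
compose_full_rss <- function(heptamer, nonamer, spacer_len) {
  if (!spacer_len %in% c(12L, 23L)) {
    rs_abort("spacer_len must be 12 or 23")
  }
  if (heptamer$width != 7L) rs_abort("heptamer must have width 7")
  if (nonamer$width != 9L) rs_abort("nonamer must have width 9")
  if (any(abs(heptamer$background - nonamer$background) > 1e-9)) {
    rs_abort("heptamer and nonamer must share a background")
  }
  bg <- heptamer$background
  spacer <- matrix(bg, nrow = 4, ncol = spacer_len)
  rag_pwm(cbind(heptamer$probs, spacer, nonamer$probs),
          name = paste0("rss_full_", spacer_len), background = bg)
}

#' Full default motif set used by the breakpoint scan
#'
#' Heptamer, nonamer and both full-RSS spacer variants built from
#' [default_rag_pwms()] (or a user-supplied heptamer/nonamer pair).
#'
#' @param pwms named list with `heptamer` and `nonamer` entries.
#' @return named list of four `rag_pwm` objects: `heptamer`, `nonamer`,
#'   `rss_full_12`, `rss_full_23`.
#' @export
rss_motif_set <- function(pwms = default_rag_pwms()) {
  list(
    heptamer = pwms$heptamer,
    nonamer = pwms$nonamer,
    rss_full_12 = compose_full_rss(pwms$heptamer, pwms$nonamer, 12L),
    rss_full_23 = compose_full_rss(pwms$heptamer, pwms$nonamer, 23L)
  )
}

#' Read motifs from a MEME-format motif file
#'
#' Parses MEME minimal motif format (letter-probability matrix blocks over
#' the A/C/G/T alphabet, with optional background frequency line). Zero
#' cells are replaced by `pseudocount` and columns renormalised.
#'
#' @param path motif file path.
#' @param name optional motif name; when given, only that motif is
#'   returned as a single `rag_pwm`.
#' @param pseudocount substituted for zero probability cells.
#' @param background used when the file carries no background line.
#' @return a single `rag_pwm` if the file holds one motif (or `name` was
#'   given), otherwise a named list of `rag_pwm` objects.
#' @export
read_pwm <- function(path, name = NULL, pseudocount = 0.01,
                     background = default_background()) {
  if (!file.exists(path)) rs_abort(paste0("no such motif file: ", path))
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    background <- vals[DNA_BASES4]
  }
  motif_i <- grep("^MOTIF\\s+", lines)
  if (!length(motif_i)) rs_abort("no MOTIF blocks found")
  out <- list()
  for (mi in motif_i) {
    mname <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr <- mi + which(grepl("^letter-probability matrix",
                            lines[(mi + 1):length(lines)]))[1]
    if (is.na(hdr)) rs_abort(paste0("motif ", mname, " has no matrix"))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    if (is.na(w) || w < 1) rs_abort(paste0("motif ", mname, " has width 0"))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4), USE.NAMES = FALSE))
    out[[mname]] <- rag_pwm(t(mat), name = mname, background = background,
                            pseudocount = pseudocount)
  }
  if (!is.null(name)) {
    if (is.null(out[[name]])) rs_abort(paste0("motif not in file: ", name))
    return(out[[name]])
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Write motifs to a MEME-format motif file
#'
#' @param pwms a `rag_pwm` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "rag_pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6g", DNA_BASES4, bg), collapse = " "), ""
  )
  for (p in pwms) {
    out <- c(out,
      paste("MOTIF", p$name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              p$width),
      apply(p$probs, 2, function(col) paste(sprintf("%.6f", col),
                                            collapse = " ")),
      "")
  }
  writeLines(out, path)
  invisible(path)
}
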