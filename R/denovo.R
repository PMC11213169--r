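#' Replace soft-masked (lowercase) bases by N
#'
#' Repeat-masked positions carry no motif information; masked bases are
#' set to `N` so they are excluded from k-mer counting (and contribute
#' zero to PWM scores).
#'
#' @param flanks character vector of sequences with lowercase soft
#'   masking.
#' @param repeat_mask apply the mask (default `TRUE`); when `FALSE`
#'   sequences are uppercased unchanged.
#' @return character vector of uppercase sequences.
#' @export
masked_sequences <- function(flanks, repeat_mask = TRUE) {
  if (repeat_mask) flanks <- gsub("[acgtn]", "N", flanks)
  toupper(flanks)
}

#' Dinucleotide-preserving shuffle of one sequence
#'
#' Altschul-Erickson shuffle: generates a uniformly random sequence with
#' exactly the same dinucleotide (and hence mononucleotide) counts as the
#' input, by drawing a random Eulerian path in the dinucleotide transition
#' multigraph (random last-edge arborescence into the final vertex, then
#' random edge orderings).
#'
#' @param seq nucleotide string (length >= 2; shorter strings are
#'   returned unchanged).
#' @return shuffled string with identical dinucleotide composition.
#' @export
shuffle_dinucleotide <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(x)
  if (n < 3L) return(seq)
  verts <- unique(x)
  nv <- length(verts)
  code <- match(x, verts)
  from <- code[-n]
  to <- code[-1]
  final <- code[n]
  edges <- split(to, from)           # outgoing edge targets per vertex
  present <- as.integer(names(edges))
  # pick a random last edge per non-final vertex until they form an
  # arborescence into the final vertex
  for (attempt in 1:1000) {
    last_to <- rep(NA_integer_, nv)
    for (v in present) {
      if (v != final) last_to[v] <- sample(edges[[as.character(v)]], 1L)
    }
    ok <- TRUE
    for (v in present) {
      if (v == final) next
      seen <- integer(0)
      cur <- v
      while (!is.na(last_to[cur]) && cur != final) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_to[cur]
      }
      if (!ok || cur != final) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(seq)  # pathological composition; keep input
  # order edges: random permutation, with the chosen last edge last
  ordered <- vector("list", nv)
  for (v in present) {
    e <- edges[[as.character(v)]]
    if (v != final) {
      drop1 <- match(last_to[v], e)
      rest <- e[-drop1]
      ordered[[v]] <- c(if (length(rest)) sample(rest, length(rest)),
                        last_to[v])
    } else {
      ordered[[v]] <- if (length(e) > 1L) sample(e, length(e)) else e
    }
  }
  ptr <- rep(1L, nv)
  out <- integer(n)
  out[1] <- code[1]
  cur <- code[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(verts[out], collapse = "")
}

#' Canonical k-mers present in one sequence (ZOOPS, both strands)
#' @noRd
kmers_present <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) rs_abort(sprintf("sequence shorter than k = %d", k))
  km <- substring(seq, 1:(L - k + 1L), k:L)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(character(0))
  unique(pmin(km, revcomp(km)))
}

#' Agnostic k-mer enrichment at breakpoint flanks
#'
#' A simplified de novo motif search: every canonical k-mer (a k-mer and
#' its reverse complement count as one motif) is scored by a one-sided
#' conditional binomial test of its ZOOPS presence count in the target
#' sequences (each sequence counts once however many occurrences it has,
#' on either strand) against its presence count in the background: given
#' `x + b` sequences containing the k-mer among `n_t` targets and `n_b`
#' background sequences, `x` is referred to Binomial(x + b,
#' n_t/(n_t + n_b)). Conditioning on the total removes the sampling
#' noise of the estimated background frequency, which would otherwise
#' make rare k-mers anti-conservative under a finite shuffled
#' background. The default background is a seeded
#' dinucleotide-preserving shuffle of the targets, `n_shuffle` copies
#' each, which keeps local composition while destroying motifs.
#'
#' @param targets character vector of target sequences (e.g. breakpoint
#'   flank windows, repeat-masked).
#' @param background optional character vector of background sequences;
#'   built by shuffling when `NULL`.
#' @param k motif length, 5..12 (default 7).
#' @param n_shuffle background size multiplier when shuffling
#'   (default 10).
#' @param seed RNG seed for the shuffle.
#' @return tibble ranked by ascending p-value: `kmer` (canonical form),
#'   `target_count`, `target_freq`, `background_freq`, `log10_p`,
#'   `p_bonferroni`, `rank`; attribute `n_tested` carries the Bonferroni
#'   family size.
#' @export
discover_kmers <- function(targets, background = NULL, k = 7,
                           n_shuffle = 10, seed = 1) {
  if (!(k >= 5 && k <= 12)) rs_abort("k must be in 5..12")
  targets <- toupper(targets)
  if (is.null(background)) {
    background <- withr::with_seed(seed, {
      unlist(lapply(seq_len(n_shuffle), function(j) {
        vapply(targets, shuffle_dinucleotide, character(1),
               USE.NAMES = FALSE)
      }))
    })
  }
  if (!length(background)) rs_abort("background must be nonempty")
  background <- toupper(background)
  tgt_sets <- lapply(targets, kmers_present, k = k)
  bg_sets <- lapply(background, kmers_present, k = k)
  n_t <- length(targets)
  n_b <- length(background)
  tab_t <- table(unlist(tgt_sets))
  tab_b <- table(unlist(bg_sets))
  kmer <- names(tab_t)
  x <- as.integer(tab_t)
  bcount <- as.integer(tab_b[kmer])
  bcount[is.na(bcount)] <- 0L
  log_p <- pbinom(x - 1L, x + bcount, n_t / (n_t + n_b),
                  lower.tail = FALSE, log.p = TRUE)
  m <- length(kmer)
  out <- tibble(
    kmer = kmer, target_count = x, target_freq = x / n_t,
    background_freq = bcount / n_b,
    log10_p = log_p / log(10),
    p_bonferroni = pmin(1, exp(pmin(log_p + log(m), 0)))
  ) |>
    arrange(.data$log10_p, dplyr::desc(.data$target_freq), .data$kmer) |>
    mutate(rank = row_number())
  attr(out, "n_tested") <- m
  out
}
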