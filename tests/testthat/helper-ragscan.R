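# Shared fixtures, built in code. The full-size cohort is expensive to
# annotate, so it is generated once per test run and memoised.

.rs_cache <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.rs_cache$cohort)) {
    co <- simulate_rag_cohort(seed = 7)
    ann <- annotate_deletions(co$deletions, co$genome, co$regions)
    ann <- annotate_junctions(ann, co$deletions, co$genome)
    co$annotations <- ann
    .rs_cache$cohort <- co
  }
  .rs_cache$cohort
}

random_genome <- function(len = 2000, seed = 1, chroms = "chr1") {
  withr::with_seed(seed, {
    out <- vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    }, character(1))
    out
  })
}

# independent string reverse-complement for oracles (no package code)
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA",
                     strsplit(toupper(s), "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins, sum hypergeometric probabilities <= observed (with the usual
# relative tolerance for ties)
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force exact two-sided Wilcoxon rank-sum p for tiny samples:
# enumerate all assignments of ranks to group 1
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  w_all <- apply(combs, 2, function(idx) {
    sum(rank(c(x, y))[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * (length(y)) / 2
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
}
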