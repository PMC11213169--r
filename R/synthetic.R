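#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions the analysis is designed for:
#' 18 high- and 17 low-exposure patients; negative-binomial per-patient
#' deletion counts whose group means (22, 10) give about 566 deletions in
#' total with an overall median near 12; 45% of deletions touching Ig/TCR
#' loci; off-target RAG-mediated (full RSS detected within 50 bp)
#' fractions 0.41 vs 0.21 by exposure group on the conditional (random
#' intercept = 0) scale, with a 0.5-SD per-patient logit intercept; 93%
#' of on-target deletions RAG-mediated; NTN probabilities 0.92 / 0.79 /
#' 0.65 by RAG class; interior RSS offsets geometric with mean 15 bp
#' (truncated so the motif fits inside the 50-bp scan window); 12-nt
#' spacers with a 30% share of 23-nt spacers.
#'
#' @param ... named overrides of any default listed below.
#' @return a `ragscan_config` list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_high = 18L, n_low = 17L,
    mu_deletions = c(high = 22, low = 10), nb_size = 8,
    p_ontarget = 0.45,
    p_rag_high = 0.41, p_rag_low = 0.21,
    p_rag_ontarget = 0.93,
    patient_intercept_sd = 0,
    p_full_both_given_rag = c(high = 0.23, low = 0.11),
    p_full_both_ontarget = 0.6,
    spacer23_frac = 0.3,
    interior_offset_mean = 15,
    p_ntn_by_class = c(full_both = 0.92, full_one = 0.79, other = 0.65),
    ntn_len_mean = 4,
    n_chroms = 2L, chrom_length = 3e6, background = default_background(),
    locus_length = 1e5,
    offtarget_len_range = c(1e3, 1e6),
    ontarget_len_range = c(1e3, 2e5),
    age_range = c(0.5, 14),
    pwm_weight = 0.8,
    flank = 50L, threshold = 1e-4, buffer = 1000L, granularity = 1e-3,
    plant_sequences = TRUE, consensus_plant = FALSE,
    plant_min_pvalue = 1e-4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    rs_abort(paste0("unknown config field(s): ",
                    paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, over)
  probs <- c(cfg$p_ontarget, cfg$p_rag_high, cfg$p_rag_low,
             cfg$p_rag_ontarget, cfg$p_full_both_given_rag,
             cfg$p_full_both_ontarget, cfg$p_ntn_by_class,
             cfg$spacer23_frac)
  if (any(probs < 0 | probs > 1)) rs_abort("probabilities must be in [0,1]")
  if (cfg$n_high < 1 || cfg$n_low < 1) rs_abort("need >= 1 patient per group")
  structure(cfg, class = "ragscan_config")
}

#' Generate a random reference genome with labelled Ig/TCR loci
#'
#' Chromosome sequences are drawn base by base from the configured
#' 0-order background (A/T 0.3, C/G 0.2 by default, matching the scan
#' background). Six labelled loci (IgH, IgK, IgL, TRB, TRA_TRD, TRG) are
#' placed non-overlapping, evenly spread across chromosomes with jitter.
#'
#' @param cfg a [synthetic_config()].
#' @param seed RNG seed (mandatory; identical seeds give byte-identical
#'   output).
#' @return list with `genome` (named character vector) and `regions`
#'   (tibble: `chrom`, `start`, `end`, `label`).
#' @export
generate_genome <- function(cfg = synthetic_config(), seed) {
  if (missing(seed)) rs_abort("seed is mandatory")
  labels <- c("IgH", "IgK", "IgL", "TRB", "TRA_TRD", "TRG")
  withr::with_seed(child_seed(seed, 1), {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    genome <- vapply(chroms, function(ch) {
      paste(sample_bases(cfg$chrom_length, cfg$background), collapse = "")
    }, character(1))
    per_chrom <- split(labels,
                       rep_len(seq_len(cfg$n_chroms), length(labels)))
    regions <- bind_rows(lapply(seq_along(per_chrom), function(ci) {
      labs <- per_chrom[[ci]]
      k <- length(labs)
      centers <- (seq_len(k) / (k + 1)) * cfg$chrom_length
      centers <- centers + runif(k, -0.03, 0.03) * cfg$chrom_length
      start <- pmax(round(centers - cfg$locus_length / 2), cfg$buffer + 1)
      end <- start + cfg$locus_length
      if (any(end > cfg$chrom_length - cfg$buffer)) {
        rs_abort("loci exceed genome length; enlarge chrom_length")
      }
      if (k > 1 && any(diff(start) < cfg$locus_length + 2 * cfg$buffer)) {
        rs_abort("loci overlap after jitter; enlarge chrom_length")
      }
      tibble(chrom = chroms[ci], start = as.integer(start),
             end = as.integer(end), label = labs)
    }))
    list(genome = genome, regions = regions |>
           arrange(.data$chrom, .data$start))
  })
}

#' Sample one motif instance from a PWM, optionally detection-gated
#'
#' Draws each base from the PWM column probabilities. When
#' `min_pvalue < 1` the draw is repeated (up to 50 times) until the
#' instance's exact match p-value passes, so that planted motifs are
#' retrievable by the scan that defines the planted class fractions; the
#' consensus is used if no draw passes.
#' @noRd
sample_instance <- function(pwm, ptab, min_pvalue = 1e-4,
                            consensus = FALSE, orient_pwm = NULL) {
  if (consensus) {
    return(paste(DNA_BASES4[apply(pwm$probs, 2, which.max)], collapse = ""))
  }
  for (i in 1:50) {
    inst <- paste(apply(pwm$probs, 2, function(p) {
      sample(DNA_BASES4, 1L, prob = p)
    }), collapse = "")
    if (!is.null(orient_pwm)) {
      # the RSS heptamer is palindromic except its central base, so an
      # instance reading better in reverse is not planted "in
      # excision-circle orientation"; require strict forward preference
      hsub <- substr(inst, 1L, orient_pwm$width)
      if (score_window(orient_pwm, hsub) <=
            score_window(orient_pwm, revcomp(hsub))) next
    }
    if (min_pvalue >= 1) return(inst)
    if (pwm_pvalue(ptab, score_window(pwm, inst)) < min_pvalue) return(inst)
  }
  paste(DNA_BASES4[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Truncated geometric interior offset (1-based distance)
#' @noRd
sample_offset <- function(mean_bp, o_max) {
  if (o_max < 1L) return(1L)
  for (i in 1:100) {
    o <- 1L + rgeom(1L, prob = 1 / mean_bp)
    if (o <= o_max) return(o)
  }
  1L
}

#' Generate a synthetic deletion cohort with planted RSS motifs
#'
#' Draws the patient table and per-patient deletion counts, assigns each
#' deletion its target status and true RAG class from the configured
#' probabilities (with a per-patient random intercept on the logit
#' scale), places deletions on the genome (off-target deletions keep both
#' breakpoints outside the buffered Ig/TCR loci; on-target deletions
#' anchor one breakpoint inside a locus), writes sampled full-RSS
#' instances into the genome interior to each designated breakpoint in
#' excision-circle orientation at truncated-geometric offsets, and
#' appends non-templated nucleotides to the junction insert with
#' class-specific probability (NTN end bases are resampled so they are
#' genuinely non-templated).
#'
#' @param cfg a [synthetic_config()].
#' @param genome,regions output of [generate_genome()].
#' @param seed RNG seed (mandatory).
#' @return list with `genome` (with planted motifs), `regions`,
#'   `patients`, `deletions` (the callset as read by [read_deletions()])
#'   and `truth` (one row per deletion with every planted attribute).
#' @export
generate_cohort <- function(cfg = synthetic_config(), genome, regions,
                            seed) {
  if (missing(seed)) rs_abort("seed is mandatory")
  motifs <- prepare_motifs(rss_motif_set(default_rag_pwms(
    weight = cfg$pwm_weight, background = cfg$background)),
    cfg$granularity)
  chroms <- names(genome)
  chrlen <- nchar(genome)
  margin <- 300L
  # forbidden zones for off-target breakpoints: loci +/- buffer + margin
  forb <- split(regions, regions$chrom)

  withr::with_seed(child_seed(seed, 2), {
    patients <- tibble(
      patient_id = sprintf("P%02d", seq_len(cfg$n_high + cfg$n_low)),
      exposure_group = c(rep("high", cfg$n_high), rep("low", cfg$n_low)),
      age_at_dx = round(runif(cfg$n_high + cfg$n_low, cfg$age_range[1],
                              cfg$age_range[2]), 1)
    )
    b_i <- rnorm(nrow(patients), 0, cfg$patient_intercept_sd)

    off_ok <- function(chrom, bp) {
      f <- forb[[chrom]]
      if (is.null(f)) return(TRUE)
      all(bp < f$start - cfg$buffer - margin |
            bp >= f$end + cfg$buffer + margin)
    }
    place_off <- function() {
      lr <- log(cfg$offtarget_len_range)
      for (i in 1:200) {
        ch <- sample(chroms, 1L, prob = chrlen)
        len <- round(exp(runif(1L, lr[1], lr[2])))
        if (len + 2L * margin >= chrlen[ch]) next
        lb <- sample.int(chrlen[ch] - len - 2L * margin, 1L) + margin
        if (off_ok(ch, lb) && off_ok(ch, lb + len)) {
          return(list(chrom = ch, left_bp = as.integer(lb),
                      right_bp = as.integer(lb + len)))
        }
      }
      rs_abort("could not place off-target deletion outside buffered Ig/TCR loci")
    }
    place_on <- function() {
      lr <- log(cfg$ontarget_len_range)
      for (i in 1:200) {
        ri <- sample.int(nrow(regions), 1L)
        reg <- regions[ri, ]
        len <- round(exp(runif(1L, lr[1], lr[2])))
        anchor <- reg$start + sample.int(reg$end - reg$start, 1L) - 1L
        rightward <- runif(1L) < 0.5
        lb <- if (rightward) anchor else anchor - len
        rb <- lb + len
        if (lb > margin && rb < chrlen[reg$chrom] - margin) {
          return(list(chrom = reg$chrom, left_bp = as.integer(lb),
                      right_bp = as.integer(rb)))
        }
      }
      rs_abort("could not place on-target deletion inside chromosome bounds")
    }

    rows <- list()
    for (pi in seq_len(nrow(patients))) {
      n_del <- max(rnbinom(1L, mu = unname(
        cfg$mu_deletions[patients$exposure_group[pi]]), size = cfg$nb_size),
        1L)
      for (j in seq_len(n_del)) {
        ontarget <- runif(1L) < cfg$p_ontarget
        pos <- if (ontarget) place_on() else place_off()
        p_rag0 <- if (ontarget) cfg$p_rag_ontarget else
          if (patients$exposure_group[pi] == "high") cfg$p_rag_high else
            cfg$p_rag_low
        p_rag <- plogis(qlogis(p_rag0) + b_i[pi])
        rag <- runif(1L) < p_rag
        p_both <- if (ontarget) cfg$p_full_both_ontarget else
          unname(cfg$p_full_both_given_rag[patients$exposure_group[pi]])
        rag_class <- if (!rag) "none" else
          if (runif(1L) < p_both) "full_both" else "full_one"
        one_side <- if (rag_class == "full_one") {
          sample(c("left", "right"), 1L)
        } else NA_character_
        rows[[length(rows) + 1L]] <- tibble(
          patient_id = patients$patient_id[pi], chrom = pos$chrom,
          left_bp = pos$left_bp, right_bp = pos$right_bp,
          vaf = round(0.11 + 0.49 * rbeta(1L, 2, 3), 3),
          target_truth = if (ontarget) "ig_tcr" else "off_target",
          rag_class_truth = rag_class,
          plant_left = rag_class == "full_both" ||
            (rag_class == "full_one" && one_side == "left"),
          plant_right = rag_class == "full_both" ||
            (rag_class == "full_one" && one_side == "right")
        )
      }
    }
    truth <- bind_rows(rows)
    truth$deletion_id <- sprintf("del%05d", seq_len(nrow(truth)))

    # plant full-RSS instances interior to the designated breakpoints
    truth$offset_left <- NA_integer_
    truth$offset_right <- NA_integer_
    truth$spacer_left <- NA_integer_
    truth$spacer_right <- NA_integer_
    if (cfg$plant_sequences) {
      for (i in seq_len(nrow(truth))) {
        for (side in c("left", "right")) {
          if (!truth[[paste0("plant_", side)]][i]) next
          spacer <- if (runif(1L) < cfg$spacer23_frac) 23L else 12L
          pwm <- motifs[[paste0("rss_full_", spacer)]]
          inst <- sample_instance(pwm, pwm$pvalue_table,
                                  min_pvalue = cfg$plant_min_pvalue,
                                  consensus = cfg$consensus_plant,
                                  orient_pwm = motifs$heptamer)
          w <- nchar(inst)
          o_max <- max(cfg$flank - w + 1L, 1L)
          o <- sample_offset(cfg$interior_offset_mean, o_max)
          ch <- truth$chrom[i]
          if (side == "left") {
            g0 <- truth$left_bp[i] + (o - 1L)
            substr(genome[[ch]], g0 + 1L, g0 + w) <- inst
            truth$offset_left[i] <- o
            truth$spacer_left[i] <- spacer
          } else {
            g0 <- truth$right_bp[i] - (o - 1L) - w
            substr(genome[[ch]], g0 + 1L, g0 + w) <- revcomp(inst)
            truth$offset_right[i] <- o
            truth$spacer_right[i] <- spacer
          }
        }
      }
    }

    # junction inserts: class-conditional NTN, ends forced non-templated
    grp_class <- dplyr::case_when(
      truth$rag_class_truth == "full_both" ~ "full_both",
      truth$rag_class_truth == "full_one" ~ "full_one",
      TRUE ~ "other")
    p_ntn <- unname(cfg$p_ntn_by_class[grp_class])
    truth$ntn_truth <- runif(nrow(truth)) < p_ntn
    truth$junction_insert <- ""
    for (i in which(truth$ntn_truth)) {
      len <- 1L + rgeom(1L, prob = 1 / cfg$ntn_len_mean)
      ntn <- sample_bases(len, cfg$background)
      ch <- truth$chrom[i]
      left_next <- substr(genome[[ch]], truth$left_bp[i] + 1L,
                          truth$left_bp[i] + 1L)
      right_prev <- substr(genome[[ch]], truth$right_bp[i],
                           truth$right_bp[i])
      while (ntn[1] == left_next) {
        ntn[1] <- sample_bases(1L, cfg$background)
      }
      while (ntn[len] == right_prev || (len == 1L && ntn[1] == left_next)) {
        ntn[len] <- sample_bases(1L, cfg$background)
      }
      truth$junction_insert[i] <- paste(ntn, collapse = "")
    }

    deletions <- truth |>
      select("patient_id", "chrom", "left_bp", "right_bp", "vaf",
             "junction_insert", "deletion_id")
    list(genome = genome, regions = regions, patients = patients,
         deletions = deletions, truth = truth)
  })
}

#' Generate genome and cohort in one call
#'
#' @inheritParams generate_cohort
#' @param seed RNG seed driving both stages.
#' @return the [generate_cohort()] list.
#' @export
simulate_rag_cohort <- function(cfg = synthetic_config(), seed) {
  g <- generate_genome(cfg, seed)
  generate_cohort(cfg, g$genome, g$regions, seed)
}

#' Write every cohort artifact to a directory
#'
#' Writes `genome.fa`, `igtcr_loci.bed`, `deletions.vcf`,
#' `deletions.tsv`, `patients.tsv` and `truth.tsv`.
#'
#' @param cohort output of [simulate_rag_cohort()] /
#'   [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(cohort$genome, file.path(dir, "genome.fa"))
  write_regions(cohort$regions, file.path(dir, "igtcr_loci.bed"))
  write_deletions(cohort$deletions, file.path(dir, "deletions.vcf"),
                  format = "vcf", genome = cohort$genome)
  write_deletions(cohort$deletions, file.path(dir, "deletions.tsv"))
  readr::write_tsv(cohort$patients, file.path(dir, "patients.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
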