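#' Read somatic deletion calls
#'
#' Reads a deletion callset and normalises every record to the internal
#' coordinate convention: 0-based half-open deleted segments
#' `[left_bp, right_bp)`. Records with `vaf <= vaf_min` are excluded and
#' counted (`attr(x, "n_vaf_excluded")`); records with missing VAF are
#' kept.
#'
#' Formats:
#' * `tsv` — columns `patient_id`, `chrom`, `left_bp`, `right_bp`, `vaf`,
#'   optional `junction_insert` (already 0-based half-open).
#' * `vcf` — VCF 4.x with `SVTYPE=DEL` and `END` in INFO; `POS`/`END` are
#'   1-based and the deleted bases are the inclusive range `[POS, END]`,
#'   so `left_bp = POS - 1`, `right_bp = END`. Optional INFO keys `VAF`,
#'   `PATIENT` and `INSSEQ` (observed junction insert).
#' * `bedpe` — headerless, breakpoint intervals in columns 1-6 with the
#'   deleted segment spanning `[start1, end2)`; columns 11-13 carry
#'   `patient_id`, `vaf` and junction insert (`.` for none).
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"vcf"`, `"bedpe"` (default guessed from
#'   the file extension).
#' @param vaf_min exclusive VAF lower bound for keeping a call
#'   (default 0.10).
#' @return tibble with columns `patient_id`, `chrom`, `left_bp`,
#'   `right_bp`, `vaf`, `junction_insert` (`NA` when not reported), plus
#'   attribute `n_vaf_excluded`.
#' @export
read_deletions <- function(path, format = c("guess", "tsv", "vcf", "bedpe"),
                           vaf_min = 0.10) {
  format <- match.arg(format)
  if (!file.exists(path)) rs_abort(paste0("no such file: ", path))
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vcf = "vcf", bedpe = "bedpe", "tsv")
  }
  out <- switch(format,
    tsv = read_deletions_tsv(path),
    vcf = read_deletions_vcf(path),
    bedpe = read_deletions_bedpe(path)
  )
  bad <- which(out$right_bp - out$left_bp < 1)
  if (length(bad)) {
    rs_abort(sprintf("record %d: deletion end precedes start (%s:%d-%d)",
                     bad[1], out$chrom[bad[1]], out$left_bp[bad[1]],
                     out$right_bp[bad[1]]))
  }
  keep <- is.na(out$vaf) | out$vaf > vaf_min
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    inform(sprintf("excluded %d call(s) with VAF <= %.2f", n_excl, vaf_min))
  }
  out <- out[keep, , drop = FALSE]
  out$junction_insert[!is.na(out$junction_insert) &
                        out$junction_insert %in% c("", ".")] <- ""
  attr(out, "n_vaf_excluded") <- n_excl
  out
}

read_deletions_tsv <- function(path) {
  # empty junction_insert ("" = resolved, no inserted bases) is distinct
  # from a missing one (NA), so the empty string is not an NA marker
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = "NA")
  need <- c("patient_id", "chrom", "left_bp", "right_bp", "vaf")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    rs_abort(paste0("deletion TSV lacks column(s): ",
                    paste(miss, collapse = ", ")))
  }
  if (!"junction_insert" %in% names(x)) x$junction_insert <- NA_character_
  tibble(
    patient_id = as.character(x$patient_id), chrom = as.character(x$chrom),
    left_bp = as.integer(x$left_bp), right_bp = as.integer(x$right_bp),
    vaf = as.numeric(x$vaf),
    junction_insert = as.character(x$junction_insert)
  )
}

read_deletions_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_meta <- length(v@meta) + 1L  # header lines before the first record
  svtype <- vcfR::extract.info(v, "SVTYPE")
  keep <- which(!is.na(svtype) & svtype == "DEL")
  if (!length(keep)) {
    rs_abort("VCF contains no SVTYPE=DEL records")
  }
  end <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  pos <- as.integer(fix$POS)
  bad <- keep[is.na(end[keep])]
  if (length(bad)) {
    rs_abort(sprintf("line %d: SVTYPE=DEL record without END",
                     n_meta + bad[1]))
  }
  bad <- keep[end[keep] < pos[keep]]
  if (length(bad)) {
    rs_abort(sprintf("line %d: END < POS", n_meta + bad[1]))
  }
  vaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "VAF")))
  patient <- vcfR::extract.info(v, "PATIENT")
  insseq <- vcfR::extract.info(v, "INSSEQ")
  tibble(
    patient_id = as.character(patient[keep]),
    chrom = as.character(fix$CHROM[keep]),
    left_bp = pos[keep] - 1L, right_bp = end[keep],
    vaf = vaf[keep], junction_insert = as.character(insseq[keep])
  )
}

read_deletions_bedpe <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 12) {
    rs_abort("BEDPE needs >= 12 columns (incl. patient_id and vaf)")
  }
  if (any(x[[1]] != x[[4]])) {
    bad <- which(x[[1]] != x[[4]])[1]
    rs_abort(sprintf("line %d: interchromosomal record is not a deletion",
                     bad))
  }
  ins <- if (ncol(x) >= 13) as.character(x[[13]]) else NA_character_
  tibble(
    patient_id = as.character(x[[11]]), chrom = as.character(x[[1]]),
    left_bp = as.integer(x[[2]]), right_bp = as.integer(x[[6]]),
    vaf = as.numeric(x[[12]]), junction_insert = ins
  )
}

#' Write deletion calls as TSV or VCF
#'
#' Inverse of [read_deletions()]: the TSV carries internal 0-based
#' half-open coordinates; the VCF writes `POS = left_bp + 1`,
#' `END = right_bp` (deleted bases = 1-based inclusive `[POS, END]`) with
#' INFO keys `SVTYPE=DEL`, `END`, `VAF`, `PATIENT` and `INSSEQ`.
#'
#' @param deletions tibble as returned by [read_deletions()].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param genome optional named character vector of chromosome sequences,
#'   used to fill the VCF REF column (otherwise `N`).
#' @return `path`, invisibly.
#' @export
write_deletions <- function(deletions, path, format = c("tsv", "vcf"),
                            genome = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(deletions, path, progress = FALSE)
    return(invisible(path))
  }
  ref <- rep("N", nrow(deletions))
  if (!is.null(genome)) {
    ref <- substr(genome[deletions$chrom], deletions$left_bp + 1L,
                  deletions$left_bp + 1L)
  }
  info <- sprintf(
    "SVTYPE=DEL;END=%d;VAF=%s;PATIENT=%s%s",
    deletions$right_bp, format(deletions$vaf, digits = 6, trim = TRUE),
    deletions$patient_id,
    if_else(is.na(deletions$junction_insert) | deletions$junction_insert == "",
            "", paste0(";INSSEQ=", deletions$junction_insert))
  )
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ragscan",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"1-based last deleted base\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient id\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Junction insert sequence\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  )
  body <- sprintf("%s\t%d\tdel%05d\t%s\t<DEL>\t.\tPASS\t%s",
                  deletions$chrom, deletions$left_bp + 1L,
                  seq_len(nrow(deletions)), ref, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read locus annotation from a BED file
#'
#' Intervals are returned 0-based half-open, sorted per chromosome;
#' overlapping intervals sharing a label are merged. Labels (BED name
#' column) identify loci such as IgH/TRB.
#'
#' @param path BED file (3+ columns).
#' @return tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) rs_abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1)) {
    rs_abort("BED interval with start >= end")
  }
  lab <- gr$name %||% rep(NA_character_, length(gr))
  if (is.null(gr$name)) lab <- rep(NA_character_, length(gr))
  key <- if_else(is.na(lab), "", lab)
  merged <- lapply(split(gr, key), GenomicRanges::reduce)
  out <- bind_rows(lapply(names(merged), function(k) {
    g <- merged[[k]]
    tibble(chrom = as.character(GenomicRanges::seqnames(g)),
           start = GenomicRanges::start(g) - 1L,
           end = GenomicRanges::end(g),
           label = if (k == "") NA_character_ else k)
  }))
  out |> arrange(.data$chrom, .data$start)
}

#' Write locus annotation as BED
#'
#' @param regions tibble with `chrom`, `start`, `end`, `label`
#'   (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  lab <- if_else(is.na(regions$label), ".", regions$label)
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                     regions$end, lab), path)
  invisible(path)
}

#' Read patient metadata
#'
#' @param path TSV with columns `patient_id`, `exposure_group`
#'   (`high`/`low`) and `age_at_dx` (years).
#' @return tibble with those columns.
#' @export
read_patients <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "exposure_group", "age_at_dx")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    rs_abort(paste0("patient table lacks column(s): ",
                    paste(miss, collapse = ", ")))
  }
  if (!all(x$exposure_group %in% c("high", "low"))) {
    rs_abort("exposure_group must be 'high' or 'low'")
  }
  tibble(patient_id = as.character(x$patient_id),
         exposure_group = x$exposure_group,
         age_at_dx = as.numeric(x$age_at_dx))
}

#' Read a reference genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return named character vector, one uppercase-preserving string per
#'   sequence record.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 80L)
  invisible(path)
}
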