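#' @section Coordinate conventions:
#' All genomic coordinates in this package are 1-based inclusive, matching
#' the convention of printed locus tables. Readers for half-open 0-based
#' formats (BED) convert on input. The biological 5' terminus of a
#' plus-strand locus is its `start`; of a minus-strand locus its `end`.
#' @name profiling-conventions
#' @keywords internal
NULL

validate_annotation <- function(ann) {
  req <- c("locus_id", "chrom", "start", "end", "strand", "class")
  if (!is.data.frame(ann) || !all(req %in% names(ann))) {
    stop("annotation must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$locus_id)) stop("duplicate locus_id", call. = FALSE)
  if (any(ann$end < ann$start)) stop("annotation has end < start", call. = FALSE)
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("annotation strand must be '+' or '-'", call. = FALSE)
  }
  invisible(ann)
}

validate_reads <- function(reads) {
  req <- c("read_id", "chrom", "start", "end", "strand", "sample_id")
  if (!is.data.frame(reads) || !all(req %in% names(reads))) {
    stop("reads must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(reads) && any(reads$end < reads$start)) {
    stop("malformed read: end < start", call. = FALSE)
  }
  if (nrow(reads) && any(is.na(reads$sample_id) | reads$sample_id == "")) {
    stop("missing sample_id", call. = FALSE)
  }
  if (is.null(reads$length)) reads$length <- reads$end - reads$start + 1L
  reads
}

# 5' terminus of each record given its strand
five_prime_pos <- function(start, end, strand) {
  ifelse(strand == "+", start, end)
}

#' Classify a single aligned read against the locus annotation
#'
#' A read is accepted for a locus iff its length is within `length_range`
#' (default 30-34 nt), its strand matches, and its biological 5' terminus
#' lies within `tol` nt of the locus's 5' terminus. A read matching several
#' (e.g. paralogous) loci is assigned to all of them.
#'
#' @param read one-row data frame (read_id, chrom, start, end, strand,
#'   sample_id).
#' @param annotation locus table.
#' @param tol allowed 5'-terminus offset in nt (default 0, strict anchoring).
#' @param length_range allowed read lengths, inclusive.
#' @return list with `assigned` (character vector of locus ids, possibly
#'   empty) and `reason` (NA if assigned, else one of "length", "strand",
#'   "position", "no_overlap").
#' @export
classify_read <- function(read, annotation, tol = 0,
                          length_range = c(30L, 34L)) {
  validate_annotation(annotation)
  read <- validate_reads(as.data.frame(read))
  stopifnot(nrow(read) == 1L)
  res <- classify_reads_(read, annotation, tol, length_range)
  list(assigned = res$assigned[[1]], reason = res$reason[1])
}

# Vectorized classifier shared by classify_read / count_fragments /
# five_prime_fraction. Returns list(assigned = list of locus-id vectors,
# reason = character).
classify_reads_ <- function(reads, ann, tol, length_range) {
  n <- nrow(reads)
  assigned <- vector("list", n)
  reason <- rep(NA_character_, n)
  len_ok <- reads$length >= length_range[1] & reads$length <= length_range[2]
  r5 <- five_prime_pos(reads$start, reads$end, reads$strand)
  a5 <- five_prime_pos(ann$start, ann$end, ann$strand)
  for (i in seq_len(n)) {
    ov <- which(ann$chrom == reads$chrom[i] &
                  ann$start <= reads$end[i] & ann$end >= reads$start[i])
    if (!len_ok[i]) {
      reason[i] <- "length"
      assigned[[i]] <- character(0)
      next
    }
    if (!length(ov)) {
      reason[i] <- "no_overlap"
      assigned[[i]] <- character(0)
      next
    }
    strand_ok <- ov[ann$strand[ov] == reads$strand[i]]
    if (!length(strand_ok)) {
      reason[i] <- "strand"
      assigned[[i]] <- character(0)
      next
    }
    hit <- strand_ok[abs(a5[strand_ok] - r5[i]) <= tol]
    if (!length(hit)) {
      reason[i] <- "position"
      assigned[[i]] <- character(0)
    } else {
      assigned[[i]] <- ann$locus_id[hit]
    }
  }
  list(assigned = assigned, reason = reason)
}

#' Count 5'-anchored fragment reads per locus per sample
#'
#' Applies [classify_read()] to every read; each accepted read increments
#' every matching locus by one in its sample's column. Bookkeeping is
#' conserved: assigned reads plus per-reason rejections equal the input.
#'
#' @param reads aligned read table.
#' @param annotation locus table.
#' @inheritParams classify_read
#' @return object of class `fragment_counts`: list with `counts` (locus x
#'   sample integer matrix), `lib_sizes` (per-sample column sums),
#'   `rejections` (sample x reason table), `n_reads` (input reads per
#'   sample), `tol`, `length_range`.
#' @export
count_fragments <- function(reads, annotation, tol = 0,
                            length_range = c(30L, 34L)) {
  validate_annotation(annotation)
  if (nrow(annotation) == 0L) stop("annotation is empty", call. = FALSE)
  reads <- validate_reads(reads)
  samples <- sort(unique(reads$sample_id))
  if (!length(samples)) samples <- "S1"
  counts <- matrix(0L, nrow(annotation), length(samples),
                   dimnames = list(annotation$locus_id, samples))
  reasons <- c("length", "strand", "position", "no_overlap")
  rej <- matrix(0L, length(samples), length(reasons),
                dimnames = list(samples, reasons))
  if (nrow(reads)) {
    cl <- classify_reads_(reads, annotation, tol, length_range)
    for (i in seq_len(nrow(reads))) {
      s <- reads$sample_id[i]
      if (length(cl$assigned[[i]])) {
        counts[cl$assigned[[i]], s] <- counts[cl$assigned[[i]], s] + 1L
      } else {
        rej[s, cl$reason[i]] <- rej[s, cl$reason[i]] + 1L
      }
    }
  }
  n_reads <- if (nrow(reads)) {
    tab <- table(factor(reads$sample_id, levels = samples))
    setNames(as.integer(tab), samples)
  } else {
    setNames(integer(length(samples)), samples)
  }
  structure(list(counts = counts, lib_sizes = colSums(counts),
                 rejections = rej, n_reads = n_reads,
                 tol = tol, length_range = length_range),
            class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(sprintf("fragment_counts: %d loci x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:", paste(x$lib_sizes, collapse = ", "), "\n")
  cat("rejections by reason:\n")
  print(colSums(x$rejections))
  invisible(x)
}

#' Fraction of in-range reads anchored at the 5' terminus
#'
#' Among reads of allowed length that overlap loci of the requested class on
#' the matching strand, the fraction whose 5' terminus coincides (within
#' `tol`) with the locus 5' terminus. This is the summary statistic behind
#' the observation that essentially all 30-34 nt tRNA/YRNA-derived reads are
#' 5' halves/fragments.
#'
#' @param reads aligned read table.
#' @param annotation locus table.
#' @param class "tRNA" or "YRNA".
#' @inheritParams classify_read
#' @return proportion in `[0, 1]`.
#' @export
five_prime_fraction <- function(reads, annotation, class = c("tRNA", "YRNA"),
                                tol = 0, length_range = c(30L, 34L)) {
  class <- match.arg(class)
  validate_annotation(annotation)
  reads <- validate_reads(reads)
  ann <- annotation[annotation$class == class, , drop = FALSE]
  if (!nrow(ann)) stop("no loci of class ", class, call. = FALSE)
  cl <- classify_reads_(reads, ann, tol, length_range)
  # qualifying = in length range, overlapping a same-strand locus of class
  qualifying <- is.na(cl$reason) | cl$reason == "position"
  if (!any(qualifying)) {
    stop("no qualifying reads for class ", class, call. = FALSE)
  }
  sum(is.na(cl$reason)[qualifying]) / sum(qualifying)
}

#' Exact-substring alignment of reads to locus reference sequences
#'
#' A deliberately minimal aligner used on synthetic data: a read is placed
#' wherever its sequence occurs as an exact substring of a reference
#' sequence (both in biological 5'->3' orientation). Locus-relative offsets
#' are converted to genomic coordinates through the annotation, with
#' strand-aware mapping of the 5' terminus.
#'
#' @param reads named character vector of read sequences, or path to a
#'   FASTA/FASTQ file.
#' @param reference named character vector of locus sequences (names =
#'   locus_id), or path to a FASTA file.
#' @param annotation locus table supplying genomic coordinates.
#' @param sample_id sample label for the emitted alignments.
#' @return list with `alignments` (read table as accepted by
#'   [count_fragments()]; a read matching several references yields several
#'   rows) and `n_unaligned`.
#' @export
align_exact <- function(reads, reference, annotation, sample_id = "S1") {
  validate_annotation(annotation)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    reference <- as.character(Biostrings::readDNAStringSet(reference))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  if (anyDuplicated(names(reference))) {
    stop("duplicate locus_ids in reference", call. = FALSE)
  }
  if (!all(names(reference) %in% annotation$locus_id)) {
    stop("reference sequences not described by the annotation", call. = FALSE)
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read_%05d", seq_along(reads))
  refs <- Biostrings::DNAStringSet(reference)
  ann <- annotation[match(names(reference), annotation$locus_id), ]
  out <- list()
  n_unaligned <- 0L
  for (i in seq_along(reads)) {
    hits <- Biostrings::vmatchPattern(reads[[i]], refs)
    starts <- Biostrings::startIndex(hits)
    placed <- FALSE
    for (r in seq_along(starts)) {
      if (is.null(starts[[r]])) next
      for (off1 in starts[[r]]) {     # 1-based offset within the gene
        len <- nchar(reads[[i]])
        if (ann$strand[r] == "+") {
          gstart <- ann$start[r] + off1 - 1L
          gend <- gstart + len - 1L
        } else {
          gend <- ann$end[r] - off1 + 1L
          gstart <- gend - len + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          read_id = names(reads)[i], chrom = ann$chrom[r],
          start = gstart, end = gend, strand = ann$strand[r],
          length = len, sample_id = sample_id, locus_hint = ann$locus_id[r],
          stringsAsFactors = FALSE
        )
        placed <- TRUE
      }
    }
    if (!placed) n_unaligned <- n_unaligned + 1L
  }
  alignments <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               length = integer(0), sample_id = character(0),
               locus_hint = character(0))
  list(alignments = alignments, n_unaligned = n_unaligned)
}

#' Read a locus annotation table (BED-like TSV)
#'
#' Expects columns locus_id, chrom, start, end, strand, class with 1-based
#' inclusive coordinates (the package's native table layout). Standard
#' 0-based half-open 6-column BED is supported via `format = "bed"`; the
#' locus class is then parsed from the name prefix ("tRNA"/"YRNA").
#'
#' @param path file path.
#' @param format "tsv" (native) or "bed".
#' @return annotation data frame.
#' @export
read_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ann <- read_tsv_report(path)
  } else {
    bed <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    ann <- data.frame(
      locus_id = bed[[4]], chrom = bed[[1]],
      start = bed[[2]] + 1L,            # 0-based half-open -> 1-based inclusive
      end = bed[[3]],
      strand = bed[[6]],
      class = ifelse(grepl("^tRNA", bed[[4]], ignore.case = TRUE), "tRNA", "YRNA"),
      stringsAsFactors = FALSE
    )
  }
  validate_annotation(ann)
  ann
}

#' Read aligned reads from a BED-like table or SAM/BAM file
#'
#' BED input (6 columns: chrom, start, end, name, score, strand; 0-based
#' half-open) is converted to the package's 1-based inclusive convention;
#' `sample_id` must then be supplied. SAM/BAM input requires the Rsamtools
#' package; SAM text is converted to BAM on the fly.
#'
#' @param path file path (.bed / .tsv / .sam / .bam).
#' @param sample_id sample label (BED input).
#' @return aligned read data frame.
#' @export
read_aligned_reads <- function(path, sample_id = "S1") {
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("SAM/BAM input requires the Rsamtools package", call. = FALSE)
    }
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "qwidth", "strand")
    ))[[1]]
    keep <- !is.na(res$pos)
    data.frame(
      read_id = res$qname[keep], chrom = as.character(res$rname)[keep],
      start = res$pos[keep], end = res$pos[keep] + res$qwidth[keep] - 1L,
      strand = as.character(res$strand)[keep],
      length = res$qwidth[keep], sample_id = sample_id,
      stringsAsFactors = FALSE
    )
  } else {
    bed <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    data.frame(
      read_id = bed[[4]], chrom = bed[[1]], start = bed[[2]] + 1L,
      end = bed[[3]], strand = bed[[6]],
      length = bed[[3]] - bed[[2]], sample_id = sample_id,
      stringsAsFactors = FALSE
    )
  }
}

#' Write reads as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' QC summary of a fragment count run
#'
#' @param fc a `fragment_counts` object.
#' @return data frame with one row per sample: input reads, assigned
#'   increments, library size, rejection tallies, and the conservation check
#'   (assigned reads + rejected = input).
#' @export
fragment_qc_summary <- function(fc) {
  stopifnot(inherits(fc, "fragment_counts"))
  rej <- fc$rejections
  data.frame(
    sample_id = rownames(rej),
    n_reads = as.integer(fc$n_reads[rownames(rej)]),
    assigned_reads = as.integer(fc$n_reads[rownames(rej)] - rowSums(rej)),
    lib_size = as.integer(fc$lib_sizes[rownames(rej)]),
    rej_length = rej[, "length"], rej_strand = rej[, "strand"],
    rej_position = rej[, "position"], rej_no_overlap = rej[, "no_overlap"],
    stringsAsFactors = FALSE, row.names = NULL
  )
}
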