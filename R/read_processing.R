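#' Default sequencing adapter (read-through) sequence
#'
#' TruSeq-style adapter observed at the 3' end of read 1 when the cDNA insert
#' is shorter than the read length.
#' @return Character string.
#' @export
default_adapter <- function() "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

hamming <- function(a, b) {
  # equal-length character scalars
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Trim adapter read-through from reads
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' at most one mismatch per 10 matched nucleotides, provided the overlap is at
#' least `min_overlap`. Reads without a qualifying suffix are returned
#' unchanged; a read that is pure adapter trims to the empty string.
#'
#' @param reads Character vector of reads (A/C/G/T).
#' @param adapter Adapter sequence, non-empty.
#' @param min_overlap Minimum read/adapter overlap to trim (default 5).
#' @return Character vector of trimmed reads.
#' @examples
#' trim_adapter("ACGTACGTAGATCGGAAG", "AGATCGGAAGAGC")
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nzchar(adapter),
            min_overlap >= 1L)
  uq <- unique(reads)
  na <- nchar(adapter)
  trimmed <- vapply(uq, function(r) {
    len <- nchar(r)
    if (len < min_overlap) return(r)
    # longest suffix first: smallest start s
    for (s in seq_len(len - min_overlap + 1L)) {
      ov <- len - s + 1L
      if (ov > na) next
      mm <- hamming(substr(r, s, len), substr(adapter, 1L, ov))
      if (mm <= ov %/% 10L) return(substr(r, 1L, s - 1L))
    }
    r
  }, character(1), USE.NAMES = TRUE)
  unname(trimmed[match(reads, uq)])
}

iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(chartr("U", "T", toupper(pattern)), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  paste0("^", paste0("[", map[chars], "]", collapse = ""), "$")
}

#' Separate reads into (+) and (-) channels by handle sequence
#'
#' The leading bases of read 1 carry a channel handle (an IUPAC pattern, e.g.
#' `"RRRY"` for the reagent-treated channel and `"YYYR"` for the solvent
#' control). Reads matching exactly one pattern are assigned to that channel
#' and the handle bases are removed; reads matching neither or both patterns
#' are left `unassigned` (ambiguous matches are additionally tallied).
#'
#' @param read1 Character vector of read-1 sequences.
#' @param plus_handle,minus_handle Equal-length IUPAC patterns.
#' @return A data.frame with columns `channel` (factor: `plus`, `minus`,
#'   `unassigned`) and `read1` (handle stripped when assigned), plus an
#'   attribute `n_ambiguous`.
#' @export
demux_by_handle <- function(read1, plus_handle = "RRRY", minus_handle = "YYYR") {
  if (nchar(plus_handle) != nchar(minus_handle)) {
    stop("handle patterns must have equal length")
  }
  hl <- nchar(plus_handle)
  lead <- substr(read1, 1L, hl)
  long_enough <- nchar(read1) > hl
  p <- grepl(iupac_regex(plus_handle), lead) & long_enough
  m <- grepl(iupac_regex(minus_handle), lead) & long_enough
  ambiguous <- p & m
  channel <- rep("unassigned", length(read1))
  channel[p & !m] <- "plus"
  channel[m & !p] <- "minus"
  stripped <- ifelse(channel == "unassigned", read1,
                     substr(read1, hl + 1L, nchar(read1)))
  out <- data.frame(
    channel = factor(channel, levels = c("plus", "minus", "unassigned")),
    read1 = stripped, stringsAsFactors = FALSE
  )
  attr(out, "n_ambiguous") <- sum(ambiguous)
  out
}

scan_hits <- function(read, targets_dna, max_mismatches, min_anchor = 12L) {
  # placements of `read` against each target at the lowest mismatch stratum;
  # placements may overhang the target 3' end (the unmatched read tail is
  # adapter read-through too short for the trimmer), anchored on at least
  # `min_anchor` target nucleotides
  nr <- nchar(read)
  all_hits <- NULL
  for (tn in names(targets_dna)) {
    subj <- targets_dna[[tn]]
    len <- nchar(subj)
    if (nr <= len) {
      m <- Biostrings::matchPattern(read, subj,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      if (length(m)) {
        starts <- Biostrings::start(m)
        # drop partial edge matches; overhangs are handled below
        starts <- starts[starts >= 1L & starts + nr - 1L <= len]
        if (length(starts)) {
          mm <- vapply(starts, function(p) {
            hamming(read, substr(subj, p, p + nr - 1L))
          }, integer(1))
          all_hits <- rbind(all_hits, data.frame(target = tn, start = starts,
                                                 mm = mm,
                                                 stringsAsFactors = FALSE))
        }
      }
    }
    # 3'-overhanging placements ending exactly at the target end
    p_min <- max(1L, len - nr + 2L)
    p_max <- len - min_anchor + 1L
    if (p_max >= p_min) {
      for (p in p_min:p_max) {
        ov <- len - p + 1L
        mm <- hamming(substr(read, 1L, ov), substr(subj, p, len))
        if (mm <= max_mismatches) {
          all_hits <- rbind(all_hits, data.frame(target = tn, start = p,
                                                 mm = mm,
                                                 stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(all_hits)) return(NULL)
  all_hits[all_hits$mm == min(all_hits$mm), , drop = FALSE]
}

#' Align reads to targets and infer the RT stop site
#'
#' Reads (handle-stripped, adapter-trimmed, in target sense orientation) are
#' placed on the targets by exact/mismatch-tolerant matching. Because every
#' genuine cDNA ends at the target's 3' end, placements may overhang the 3'
#' end (soft-clipping adapter remnants too short for the trimmer) as long as
#' at least `min_anchor` nucleotides anchor on the target. With `p` the
#' 1-based target position of the 5'-most base covered by the cDNA, the
#' modification site is `p - 1` (reverse transcription halts one nucleotide
#' before the modification); `p = 1` denotes a full-length cDNA, encoded as
#' stop site `0`. Reads placing ambiguously (several equally good placements,
#' within or across targets), with more than `max_mismatches` mismatches,
#' empty after trimming, or starting 3' of the first non-probed position
#' (no valid modification site) are no-hits (`NA`).
#'
#' @param reads Character vector of processed reads.
#' @param targets List of [target_rna()] objects.
#' @param max_mismatches Maximum mismatches for a placement (default 1).
#' @param min_anchor Minimum target-anchored nucleotides for a 3'-overhanging
#'   placement (default 12).
#' @return A data.frame with columns `target` (character, `NA` for no-hit)
#'   and `stop_site` (integer; `0` = full length, `NA` = no hit).
#' @export
align_and_infer_stop <- function(reads, targets, max_mismatches = 1L,
                                 min_anchor = 12L) {
  if (inherits(targets, "target_rna")) targets <- list(targets)
  names(targets) <- vapply(targets, `[[`, character(1), "name")
  targets_dna <- lapply(targets, target_dna)
  n_probed <- vapply(targets, probed_length, integer(1))
  uq <- unique(reads)
  utab <- lapply(uq, function(r) {
    if (!nzchar(r)) return(list(target = NA_character_, stop = NA_integer_))
    hits <- scan_hits(r, targets_dna, max_mismatches, min_anchor)
    if (is.null(hits) || nrow(hits) != 1L) {
      return(list(target = NA_character_, stop = NA_integer_))
    }
    p <- hits$start[1L]
    stop_site <- p - 1L
    if (stop_site > n_probed[[hits$target[1L]]]) {
      # placement starts inside/beyond the primer site: not a valid RT stop
      return(list(target = NA_character_, stop = NA_integer_))
    }
    list(target = hits$target[1L], stop = stop_site)
  })
  idx <- match(reads, uq)
  data.frame(
    target = vapply(utab, `[[`, character(1), "target")[idx],
    stop_site = vapply(utab, `[[`, integer(1), "stop")[idx],
    stringsAsFactors = FALSE
  )
}

#' Per-target, per-channel RT-stop counts
#'
#' The sufficient statistic of a probing channel: `X[k]` counts cDNAs whose
#' RT stopped at modification site `k` (1-based, probed region), `X_full`
#' counts full-length cDNAs (coverage of position 1).
#'
#' @param target Target identifier.
#' @param channel `"plus"` or `"minus"`.
#' @param X Integer vector of length `n` (stops at sites `1..n`).
#' @param X_full Integer full-length count.
#' @return Object of class `fragment_counts`.
#' @export
fragment_counts <- function(target, channel = c("plus", "minus"), X, X_full) {
  channel <- match.arg(channel)
  X <- as.integer(X)
  X_full <- as.integer(X_full)
  if (any(is.na(X)) || any(X < 0) || is.na(X_full) || X_full < 0) {
    stop("counts must be non-negative integers")
  }
  structure(list(target = target, channel = channel, X = X, X_full = X_full),
            class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat("<fragment_counts>", x$target, sprintf("(%s)", x$channel),
      "n =", length(x$X), " total =", sum(x$X) + x$X_full,
      " full-length =", x$X_full, "\n")
  invisible(x)
}

#' Tabulate stop observations into fragment counts
#'
#' @param stop_sites Integer vector of stop sites for one target and channel
#'   (`0` denotes full length). Sites outside `[0, n]` signal an upstream
#'   aligner/coordinate bug and raise an error.
#' @param target A [target_rna()] object.
#' @param channel `"plus"` or `"minus"`.
#' @return A [fragment_counts()] object; `X_full + sum(X)` equals
#'   `length(stop_sites)`.
#' @export
tabulate_stops <- function(stop_sites, target, channel = c("plus", "minus")) {
  channel <- match.arg(channel)
  n <- probed_length(target)
  stop_sites <- as.integer(stop_sites)
  if (any(is.na(stop_sites)) || any(stop_sites < 0L) || any(stop_sites > n)) {
    stop("stop site outside [0, n]: aligner/coordinate bug for target ",
         target$name)
  }
  fragment_counts(target$name, channel,
                  X = tabulate(stop_sites, nbins = n),
                  X_full = sum(stop_sites == 0L))
}

is_ligation_dimer_one <- function(read, primers, adapter, max_total_mismatch = 1L) {
  len <- nchar(read)
  for (p in primers) {
    np <- nchar(p)
    if (len <= np) next
    tail_len <- len - np
    if (tail_len > nchar(adapter)) next
    mm <- hamming(substr(read, 1L, np), p) +
      hamming(substr(read, np + 1L, len), substr(adapter, 1L, tail_len))
    if (mm <= max_total_mismatch) return(TRUE)
  }
  FALSE
}

#' Classify reads as RT-primer/adapter ligation dimers
#'
#' A ligation dimer is a contaminant molecule in which the RT primer ligated
#' directly to the sequencing adapter with no target-derived insert. Such a
#' read consists of an RT-primer sequence immediately followed by the adapter
#' (at most one mismatch in total).
#'
#' @param read1 Character vector of raw read-1 sequences.
#' @param rt_primers Character vector of sense-strand primer-site sequences
#'   (see [rt_primer_region_dna()]).
#' @param adapter Adapter sequence.
#' @return Logical vector.
#' @export
is_ligation_dimer <- function(read1, rt_primers, adapter = default_adapter()) {
  uq <- unique(read1)
  flag <- vapply(uq, is_ligation_dimer_one, logical(1),
                 primers = rt_primers, adapter = adapter)
  unname(flag[match(read1, uq)])
}

#' Fraction of ligation-dimer reads
#'
#' @inheritParams is_ligation_dimer
#' @return Dimer fraction in `[0, 1]`.
#' @export
ligation_dimer_fraction <- function(read1, rt_primers, adapter = default_adapter()) {
  if (length(read1) == 0L) stop("dimer fraction undefined for an empty read set")
  mean(is_ligation_dimer(read1, rt_primers, adapter))
}

#' Run the full read-processing pipeline
#'
#' Classifies ligation dimers, demultiplexes the remaining reads into
#' (+)/(-) channels by handle, trims adapter read-through, aligns to the
#' targets, infers RT stop sites and tabulates per-target per-channel
#' fragment counts. Read 1 carries the handle and the target-derived
#' sequence; read 2, when given, is not used for counting (single-end
#' operation is fully supported).
#'
#' @param read1 Character vector of raw read-1 sequences.
#' @param targets List of [target_rna()] objects.
#' @param plus_handle,minus_handle IUPAC channel handle patterns.
#' @param adapter Adapter sequence.
#' @param max_mismatches Alignment mismatch tolerance.
#' @return List with `counts` (list of [fragment_counts()], named
#'   `<target>.<channel>`) and `qc` (dimer fraction, unassigned fraction,
#'   ambiguous-handle count, per-target/channel aligned read counts,
#'   no-hit count).
#' @export
process_reads <- function(read1, targets,
                          plus_handle = "RRRY", minus_handle = "YYYR",
                          adapter = default_adapter(), max_mismatches = 1L) {
  if (inherits(targets, "target_rna")) targets <- list(targets)
  names(targets) <- vapply(targets, `[[`, character(1), "name")
  primers <- vapply(targets, rt_primer_region_dna, character(1))

  dimer <- is_ligation_dimer(read1, primers, adapter)
  kept <- read1[!dimer]
  dm <- demux_by_handle(kept, plus_handle, minus_handle)
  assigned <- dm$channel != "unassigned"
  trimmed <- trim_adapter(dm$read1[assigned], adapter)
  aln <- align_and_infer_stop(trimmed, targets, max_mismatches)
  aln$channel <- as.character(dm$channel[assigned])
  ok <- !is.na(aln$target)

  counts <- list()
  for (tn in names(targets)) {
    for (ch in c("plus", "minus")) {
      sel <- ok & aln$target == tn & aln$channel == ch
      counts[[paste(tn, ch, sep = ".")]] <-
        tabulate_stops(aln$stop_site[sel], targets[[tn]], ch)
    }
  }
  aligned_counts <- vapply(counts, function(fc) sum(fc$X) + fc$X_full, integer(1))
  qc <- list(
    n_reads = length(read1),
    dimer_fraction = mean(dimer),
    unassigned_fraction = if (length(kept)) mean(!assigned) else 0,
    n_ambiguous_handle = attr(dm, "n_ambiguous"),
    n_no_hit = sum(!ok),
    aligned = as.list(aligned_counts)
  )
  list(counts = counts, qc = qc)
}

#' Write / read stop-count tables
#'
#' Tab-separated table with columns `target`, `channel`, `site` (1-based
#' modification site, `"FULL"` for full-length) and `count`.
#'
#' @param counts List of [fragment_counts()] objects.
#' @param path Output file.
#' @return `write_stop_counts` returns `path` invisibly; `read_stop_counts`
#'   returns a list of `fragment_counts`.
#' @export
write_stop_counts <- function(counts, path) {
  if (inherits(counts, "fragment_counts")) counts <- list(counts)
  rows <- do.call(rbind, lapply(counts, function(fc) {
    data.frame(target = fc$target, channel = fc$channel,
               site = c(as.character(seq_along(fc$X)), "FULL"),
               count = c(fc$X, fc$X_full), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stop_counts
#' @export
read_stop_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "character", "integer"))
  out <- list()
  for (key in unique(paste(df$target, df$channel, sep = "."))) {
    sub <- df[paste(df$target, df$channel, sep = ".") == key, ]
    full <- sub$count[sub$site == "FULL"]
    body <- sub[sub$site != "FULL", ]
    X <- integer(max(as.integer(body$site)))
    X[as.integer(body$site)] <- body$count
    out[[key]] <- fragment_counts(sub$target[1L], sub$channel[1L], X, full)
  }
  out
}

#' Write a QC summary as JSON
#'
#' @param qc The `qc` element returned by [process_reads()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(qc, path) {
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read paired (or single-end) FASTQ files
#'
#' @param r1 Path to the read-1 FASTQ (optionally gzipped).
#' @param r2 Optional path to the read-2 FASTQ.
#' @return A data.frame with columns `read1` and (if given) `read2`.
#' @export
read_fastq_pairs <- function(r1, r2 = NULL) {
  s1 <- as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
  out <- data.frame(read1 = unname(s1), stringsAsFactors = FALSE)
  if (!is.null(r2)) {
    out$read2 <- unname(as.character(
      Biostrings::readDNAStringSet(r2, format = "fastq")))
    if (nrow(out) && length(out$read2) != nrow(out)) {
      stop("read-1/read-2 files differ in record count")
    }
  }
  out
}
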