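#' Probed RNA target
#'
#' A target RNA is a named sequence with 1-based coordinates where position 1
#' is the transcription start. The probed region `[1, n]` lies strictly 5' of
#' the reverse-transcription (RT) primer annealing site; RT extends from the
#' primer toward position 1, so modification sites are encountered in the
#' order n, n-1, ..., 1.
#'
#' @param name Unique target identifier.
#' @param sequence RNA sequence (characters `A`, `C`, `G`, `U`; `T` is
#'   accepted and converted to `U`), written 5' to 3'.
#' @param probed_region Inclusive 1-based interval `c(1, n)` of probed
#'   positions. Defaults to everything 5' of the primer site.
#' @param rt_primer_site Inclusive 1-based interval where the RT primer
#'   anneals. Defaults to the last `primer_length` nucleotides.
#' @param primer_length Used only when `rt_primer_site` is `NULL`.
#' @return An object of class `target_rna` with fields `name`, `sequence`,
#'   `probed_region` and `rt_primer_site`.
#' @examples
#' tg <- target_rna("demo", "GGACUGCUAAGCUAGGCUUAAGGCAUCGAU", primer_length = 10)
#' probed_length(tg)
#' @export
target_rna <- function(name, sequence, probed_region = NULL,
                       rt_primer_site = NULL, primer_length = 20L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(gsub("\\s", "", sequence))
  sequence <- chartr("T", "U", sequence)
  if (!grepl("^[ACGU]+$", sequence)) {
    stop("sequence must contain only A, C, G, U (or T)")
  }
  len <- nchar(sequence)
  if (is.null(rt_primer_site)) {
    if (primer_length >= len) stop("primer_length must be shorter than the sequence")
    rt_primer_site <- c(len - primer_length + 1L, len)
  }
  rt_primer_site <- as.integer(rt_primer_site)
  if (is.null(probed_region)) probed_region <- c(1L, rt_primer_site[1L] - 1L)
  probed_region <- as.integer(probed_region)
  if (probed_region[1L] != 1L || probed_region[2L] < probed_region[1L]) {
    stop("probed_region must be an interval [1, n] with n >= 1")
  }
  if (probed_region[2L] >= rt_primer_site[1L]) {
    stop("probed_region must lie strictly 5' of rt_primer_site")
  }
  if (rt_primer_site[2L] > len || rt_primer_site[1L] > rt_primer_site[2L]) {
    stop("rt_primer_site out of range")
  }
  structure(
    list(name = name, sequence = sequence,
         probed_region = probed_region, rt_primer_site = rt_primer_site),
    class = "target_rna"
  )
}

#' @export
print.target_rna <- function(x, ...) {
  cat("<target_rna>", x$name, "\n",
      " length:", nchar(x$sequence),
      " probed: [", x$probed_region[1], ",", x$probed_region[2], "]",
      " primer: [", x$rt_primer_site[1], ",", x$rt_primer_site[2], "]\n")
  invisible(x)
}

#' Number of probed nucleotides of a target
#'
#' @param target A [target_rna()] object.
#' @return Integer `n`, the length of the probed region.
#' @export
probed_length <- function(target) {
  stopifnot(inherits(target, "target_rna"))
  target$probed_region[2L] - target$probed_region[1L] + 1L
}

#' Target sequence as DNA (sequencing-read alphabet)
#' @param target A [target_rna()] object.
#' @return Character string over A/C/G/T.
#' @export
target_dna <- function(target) chartr("U", "T", target$sequence)

#' Sense-strand DNA of the RT-primer annealing site
#' @param target A [target_rna()] object.
#' @return Character string over A/C/G/T.
#' @export
rt_primer_region_dna <- function(target) {
  substr(target_dna(target), target$rt_primer_site[1L], target$rt_primer_site[2L])
}

#' Read probing targets from a FASTA file
#'
#' Each record becomes a [target_rna()]. Primer coordinates are either taken
#' from `primer_sites` (a named list of `c(start, end)` intervals) or default
#' to the terminal `primer_length` nucleotides.
#'
#' @param path FASTA file (DNA or RNA alphabet).
#' @param primer_sites Optional named list of RT-primer intervals.
#' @param primer_length Default primer length when `primer_sites` is missing
#'   an entry.
#' @return Named list of `target_rna` objects.
#' @export
read_targets_fasta <- function(path, primer_sites = NULL, primer_length = 20L) {
  seqs <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) stop("target names must be unique")
  out <- lapply(seq_along(seqs), function(i) {
    target_rna(nms[i], as.character(seqs[[i]]),
               rt_primer_site = primer_sites[[nms[i]]],
               primer_length = primer_length)
  })
  names(out) <- nms
  out
}

#' Read a run configuration file
#'
#' YAML configuration describing a probing run: a `targets` FASTA path,
#' optional per-target `rt_primer_sites`, channel `handles` (`plus`/`minus`,
#' IUPAC patterns), and the sequencing `adapter`.
#'
#' @param path YAML file.
#' @return List with elements `targets` (list of `target_rna`), `handles`,
#'   `adapter` and any further fields verbatim.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$targets)) stop("config must name a 'targets' FASTA file")
  fasta <- cfg$targets
  if (!file.exists(fasta)) {
    fasta <- file.path(dirname(path), cfg$targets)
  }
  primer_sites <- lapply(cfg$rt_primer_sites, function(x) as.integer(unlist(x)))
  cfg$targets <- read_targets_fasta(fasta, primer_sites = primer_sites,
                                    primer_length = cfg$primer_length %||% 20L)
  cfg$handles <- c(plus = cfg$handles$plus %||% "RRRY",
                   minus = cfg$handles$minus %||% "YYYR")
  cfg$adapter <- cfg$adapter %||% "AGATCGGAAGAGC"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
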