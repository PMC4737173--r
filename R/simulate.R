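with_seed <- function(seed, expr) {
  # run expr under a local RNG stream without disturbing the caller's state
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Ground truth of a simulated probing experiment
#'
#' Encodes the single-hit modification model: at each site the reverse
#' transcriptase stops with the natural drop-off probability `gamma_true[k]`
#' in both channels, plus -- in the reagent (+) channel only -- with the
#' modification-induced probability `1 - exp(-theta_true[k])`, i.e.
#' `theta_true` holds per-site Poisson modification intensities, so the
#' drop-off-corrected estimator recovers `theta_true / sum(theta_true)`
#' exactly in expectation.
#'
#' When `theta_true`/`gamma_true` are omitted they are drawn reproducibly
#' from `seed`: sparse gamma-distributed intensities scaled to total 0.5
#' (single-hit regime), and natural drop-off uniform in `[0.001, 0.01]` per
#' site.
#'
#' @param target A [target_rna()].
#' @param theta_true Per-site modification intensities (non-negative; the
#'   induced per-encounter stop probabilities `1-exp(-theta_true)` lie in
#'   `[0, 1)`).
#' @param gamma_true Per-site natural drop-off probabilities in `[0, 1)`.
#' @param depth_plus,depth_minus Reads per channel.
#' @param dimer_rate Fraction of total reads that are ligation dimers.
#' @param seed Integer seed controlling all randomness.
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(target, theta_true = NULL, gamma_true = NULL,
                             depth_plus = 1e5, depth_minus = 1e5,
                             dimer_rate = 0, seed = 1L) {
  n <- probed_length(target)
  if (is.null(theta_true) || is.null(gamma_true)) {
    drawn <- with_seed(seed + 1L, {
      list(theta = { x <- stats::rgamma(n, shape = 0.5); 0.5 * x / sum(x) },
           gamma = stats::runif(n, 0.001, 0.01))
    })
    if (is.null(theta_true)) theta_true <- drawn$theta
    if (is.null(gamma_true)) gamma_true <- drawn$gamma
  }
  stopifnot(length(theta_true) == n, length(gamma_true) == n,
            all(theta_true >= 0), all(gamma_true >= 0), all(gamma_true < 1),
            depth_plus > 0, depth_minus > 0,
            dimer_rate >= 0, dimer_rate < 1)
  structure(list(target = target, theta_true = as.numeric(theta_true),
                 gamma_true = as.numeric(gamma_true),
                 depth_plus = as.integer(depth_plus),
                 depth_minus = as.integer(depth_minus),
                 dimer_rate = dimer_rate, seed = as.integer(seed)),
            class = "simulation_truth")
}

stop_site_distribution <- function(stop_prob) {
  # RT walks sites n -> 1; returns P(stop at 1..n) and P(full length)
  n <- length(stop_prob)
  p <- numeric(n)
  reach <- 1
  for (k in n:1) {
    p[k] <- reach * stop_prob[k]
    reach <- reach * (1 - stop_prob[k])
  }
  c(p, reach)
}

#' Simulate RT-stop counts for both channels
#'
#' Each read performs the RT walk from site `n` toward site 1, stopping at
#' site `k` with the channel's per-encounter stop probability; surviving
#' walks emit a full-length cDNA. Counts are drawn in one multinomial step
#' per channel and are reproducible given the truth's seed.
#'
#' @param truth A [simulation_truth()].
#' @return List with elements `plus` and `minus` ([fragment_counts()]).
#' @export
simulate_stop_counts <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  s <- 1 - exp(-truth$theta_true)
  g <- truth$gamma_true
  p_plus <- stop_site_distribution(g + (1 - g) * s)
  p_minus <- stop_site_distribution(g)
  n <- length(g)
  with_seed(truth$seed, {
    cp <- stats::rmultinom(1L, truth$depth_plus, p_plus)[, 1L]
    cm <- stats::rmultinom(1L, truth$depth_minus, p_minus)[, 1L]
    list(plus = fragment_counts(truth$target$name, "plus", cp[1:n], cp[n + 1L]),
         minus = fragment_counts(truth$target$name, "minus", cm[1:n], cm[n + 1L]))
  })
}

expand_handle <- function(pattern, n_reads) {
  map <- Biostrings::IUPAC_CODE_MAP
  cols <- lapply(strsplit(chartr("U", "T", pattern), "")[[1]], function(code) {
    allowed <- strsplit(map[[code]], "")[[1]]
    allowed[sample.int(length(allowed), n_reads, replace = TRUE)]
  })
  do.call(paste0, cols)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired sequencing reads from fragment counts
#'
#' Every stop observation becomes a read pair: read 1 carries a concrete
#' instance of the channel handle followed by target-derived sequence
#' starting at the 5'-most covered position (`stop_site + 1`), running into
#' the adapter when the fragment is shorter than the read length; read 2 is
#' the reverse complement from the adapter side. A `dimer_rate` fraction of
#' the total output are RT-primer/adapter ligation dimers carrying no handle
#' and no insert.
#'
#' @param counts List with `plus` and `minus` [fragment_counts()] (as from
#'   [simulate_stop_counts()]).
#' @param target The [target_rna()] the counts belong to.
#' @param plus_handle,minus_handle IUPAC handle patterns.
#' @param adapter Adapter sequence.
#' @param read_length Read length in nucleotides (default 35).
#' @param dimer_rate Fraction of total reads that are ligation dimers.
#' @param seed Integer seed.
#' @return Data.frame with columns `read1`, `read2`, `channel` (truth label),
#'   `stop_site` (truth; `0` = full length, `NA` for dimers) and `is_dimer`.
#' @export
simulate_reads <- function(counts, target,
                           plus_handle = "RRRY", minus_handle = "YYYR",
                           adapter = default_adapter(), read_length = 35L,
                           dimer_rate = 0, seed = 1L) {
  if (read_length < nchar(plus_handle) + 1L) {
    stop("read_length must exceed the handle length")
  }
  tdna <- target_dna(target)
  # enough adapter copies that every read reaches full read_length
  pad <- strrep(adapter, ceiling(read_length / nchar(adapter)) + 1L)

  make_channel <- function(fc, handle) {
    stops <- rep(c(seq_along(fc$X), 0L), c(fc$X, fc$X_full))
    if (!length(stops)) {
      return(data.frame(read1 = character(0), read2 = character(0),
                        channel = character(0), stop_site = integer(0),
                        is_dimer = logical(0), stringsAsFactors = FALSE))
    }
    frag <- substr(rep(tdna, length(stops)), stops + 1L, nchar(tdna))
    insert <- paste0(expand_handle(handle, length(stops)), frag, pad)
    data.frame(read1 = substr(insert, 1L, read_length),
               read2 = substr(revcomp(insert), 1L, read_length),
               channel = fc$channel, stop_site = stops,
               is_dimer = FALSE, stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    reads <- rbind(make_channel(counts$plus, plus_handle),
                   make_channel(counts$minus, minus_handle))
    n_real <- nrow(reads)
    n_dimer <- round(dimer_rate / (1 - dimer_rate) * n_real)
    if (n_dimer > 0) {
      dimer_insert <- paste0(rt_primer_region_dna(target), pad)
      dimers <- data.frame(
        read1 = rep(substr(dimer_insert, 1L, read_length), n_dimer),
        read2 = rep(substr(revcomp(dimer_insert), 1L, read_length), n_dimer),
        channel = NA_character_, stop_site = NA_integer_, is_dimer = TRUE,
        stringsAsFactors = FALSE)
      reads <- rbind(reads, dimers)
    }
    reads[sample.int(nrow(reads)), , drop = FALSE]
  })
}

#' Write simulated read pairs as FASTQ
#'
#' @param reads Data.frame from [simulate_reads()].
#' @param r1,r2 Output FASTQ paths.
#' @return Invisibly, `c(r1, r2)`.
#' @export
write_fastq_pairs <- function(reads, r1, r2) {
  ids <- sprintf("sim_%06d", seq_len(nrow(reads)))
  wr <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  wr(reads$read1, r1)
  wr(reads$read2, r2)
  invisible(c(r1, r2))
}

#' Write a simulation truth table
#'
#' TSV with columns `site`, `theta_true`, `gamma_true`, preceded by comment
#' header lines recording the simulation parameters.
#'
#' @param truth A [simulation_truth()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# target=%s depth_plus=%d depth_minus=%d dimer_rate=%g seed=%d",
    truth$target$name, truth$depth_plus, truth$depth_minus,
    truth$dimer_rate, truth$seed), con)
  utils::write.table(
    data.frame(site = seq_along(truth$theta_true),
               theta_true = truth$theta_true, gamma_true = truth$gamma_true),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recovery metrics of an estimated theta profile against the truth
#'
#' The truth is normalized to the simplex (the estimator is scale-free) and
#' compared positionwise. Rank correlation (Spearman) is computed over sites
#' with positive true signal.
#'
#' @param theta_hat A [theta_profile()].
#' @param truth A [simulation_truth()].
#' @return List with `max_abs_error`, `rmse`, `rank_correlation`.
#' @export
recovery_metrics <- function(theta_hat, truth) {
  th <- if (inherits(theta_hat, "theta_profile")) theta_hat$theta else theta_hat
  tt <- truth$theta_true
  if (length(th) != length(tt)) stop("length mismatch between estimate and truth")
  tt <- tt / sum(tt)
  err <- th - tt
  pos <- tt > 0
  list(max_abs_error = max(abs(err)),
       rmse = sqrt(mean(err^2)),
       rank_correlation = suppressWarnings(
         stats::cor(th[pos], tt[pos], method = "spearman")))
}

#' Deterministic synthetic probing target
#'
#' Generates a reproducible random-sequence target whose fragment prefixes
#' (every possible processed read) place uniquely on the sequence, so that
#' simulated reads round-trip exactly through the pipeline. Seeds are
#' advanced until the uniqueness check passes (deterministic for fixed
#' arguments).
#'
#' @param name Target name.
#' @param n Probed-region length (default 60, a typical 5' UTR probing
#'   window).
#' @param primer_length RT-primer site length (default 20).
#' @param read_length Read length the uniqueness check assumes.
#' @param handle_length Handle length carried by read 1.
#' @param seed Base seed.
#' @return A [target_rna()].
#' @export
synthetic_target <- function(name = "synthRNA", n = 60L, primer_length = 20L,
                             read_length = 35L, handle_length = 4L,
                             seed = 42L) {
  len <- n + primer_length
  max_read <- read_length - handle_length
  for (try in 0:100) {
    seqs <- with_seed(seed + try, {
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
    })
    tg <- target_rna(name, seqs, rt_primer_site = c(n + 1L, len))
    tdna <- target_dna(tg)
    ok <- TRUE
    for (p in 1:(n + 1L)) {
      frag <- substr(tdna, p, min(p + max_read - 1L, len))
      hits <- gregexpr(frag, tdna, fixed = TRUE)[[1]]
      if (length(hits) != 1L || hits[1L] != p) { ok <- FALSE; break }
    }
    if (ok) return(tg)
  }
  stop("could not generate a uniquely alignable target")
}

#' Synthetic riboregulator-like ON/OFF reactivity fixture
#'
#' Deterministic reactivity profiles emulating a cis-repressed 5' UTR whose
#' ribosome binding site (RBS, positions 36-41) is occluded by a hairpin in
#' the OFF state and exposed by an antisense partner in the ON state: the
#' hairpin loop (22-35) is reactive alone and protected in the complex, the
#' RBS switches from weakly reactive (0.3) to highly reactive (1.9), and the
#' coding region stays weakly reactive throughout.
#'
#' @param n Profile length (default 60).
#' @return List with numeric vectors `on`, `off` and the `rbs_window`
#'   `c(36, 41)`.
#' @export
synthetic_rbs_profiles <- function(n = 60L) {
  stopifnot(n >= 47L)
  off <- rep(0.4, n)
  on <- rep(0.4, n)
  off[4:12] <- 1.5; on[4:12] <- 1.5        # unstructured 5' tail
  off[22:35] <- 1.2; on[22:35] <- 0.5      # loop: reactive alone, bound in ON
  off[36:41] <- 0.3; on[36:41] <- 1.9      # RBS: occluded -> exposed
  off[45:n] <- 0.3; on[45:n] <- 0.35       # start codon + CDS
  list(on = on, off = off, rbs_window = c(36L, 41L))
}
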