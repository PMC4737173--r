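#' Run the probing analysis end to end
#'
#' Convenience driver for a whole run: reads a YAML run configuration (see
#' [read_run_config()]) and a FASTQ file, produces per-target per-channel
#' stop-count tables, theta/rho reactivity tables and a QC summary in
#' `out_dir`. This is the function the command-line wrapper
#' (`inst/scripts/incell-shapeseq.R`) calls.
#'
#' @param config Path to the YAML run configuration, or the list returned by
#'   [read_run_config()].
#' @param fastq1 Read-1 FASTQ path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `counts`, `profiles` (per target: theta and
#'   rho profiles) and `qc`.
#' @export
run_pipeline <- function(config, fastq1, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- read_fastq_pairs(fastq1)
  res <- process_reads(reads$read1, cfg$targets,
                       plus_handle = cfg$handles[["plus"]],
                       minus_handle = cfg$handles[["minus"]],
                       adapter = cfg$adapter)
  write_stop_counts(res$counts, file.path(out_dir, "stop_counts.tsv"))
  write_qc_summary(res$qc, file.path(out_dir, "qc_summary.json"))
  profiles <- list()
  for (tg in cfg$targets) {
    plus <- res$counts[[paste(tg$name, "plus", sep = ".")]]
    minus <- res$counts[[paste(tg$name, "minus", sep = ".")]]
    theta <- estimate_theta(plus, minus)
    rho <- theta_to_rho(theta)
    write_reactivity_table(tg, theta, rho,
                           file.path(out_dir, paste0(tg$name, "_reactivity.tsv")))
    profiles[[tg$name]] <- list(theta = theta, rho = rho)
  }
  invisible(list(counts = res$counts, profiles = profiles, qc = res$qc))
}
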