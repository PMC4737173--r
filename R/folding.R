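#' Pseudo-free-energy parameters
#'
#' Slope/intercept of the reactivity-to-energy transform
#' \eqn{\Delta G_i = m \ln(\rho_i + 1) + b} (kcal/mol) that penalizes base
#' pairing at reactive positions during free-energy minimization. The
#' defaults `m = 1.1`, `b = -0.3` are the values used for in-cell probing
#' data on this platform.
#'
#' @param m Slope in kcal/mol.
#' @param b Intercept in kcal/mol.
#' @return Object of class `pseudo_energy_params`.
#' @export
pseudo_energy_params <- function(m = 1.1, b = -0.3) {
  stopifnot(is.finite(m), is.finite(b))
  structure(list(m = m, b = b), class = "pseudo_energy_params")
}

#' Per-nucleotide pseudo-free-energy terms
#'
#' @param rho A [rho_profile()] or non-negative numeric vector (NA = missing).
#' @param params A [pseudo_energy_params()].
#' @return Numeric vector of energies in kcal/mol; missing positions
#'   contribute 0.
#' @examples
#' pseudo_energy_terms(c(0, exp(1) - 1, 1))
#' @export
pseudo_energy_terms <- function(rho, params = pseudo_energy_params()) {
  v <- if (inherits(rho, "rho_profile")) {
    x <- rho$rho
    x[!rho$observed] <- NA_real_
    x
  } else {
    as.numeric(rho)
  }
  if (any(v < 0, na.rm = TRUE)) stop("rho must be non-negative")
  out <- params$m * log1p(v) + params$b
  out[is.na(v)] <- 0
  out
}

#' Write / read a SHAPE constraint file
#'
#' One line per position, `"index value"`, 1-based, with `-999` marking
#' missing values. This is the standard per-nucleotide reactivity exchange
#' format accepted by thermodynamic folding engines.
#'
#' @param rho A [rho_profile()] or numeric vector (NA = missing).
#' @param path Output file.
#' @return `write_shape_file` returns `path` invisibly; `read_shape_file`
#'   returns a numeric vector with `NA` at missing positions.
#' @export
write_shape_file <- function(rho, path) {
  v <- if (inherits(rho, "rho_profile")) {
    x <- rho$rho
    x[!rho$observed] <- NA_real_
    x
  } else {
    as.numeric(rho)
  }
  lines <- if (length(v)) {
    paste(seq_along(v), ifelse(is.na(v), "-999", as.character(v)))
  } else {
    character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_shape_file
#' @export
read_shape_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(numeric(0))
  parts <- strsplit(trimws(lines), "\\s+")
  idx <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
  val <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
  out <- rep(NA_real_, max(idx))
  out[idx] <- val
  out[out == -999] <- NA_real_
  out
}

#' RNA secondary structure model
#'
#' @param sequence RNA sequence.
#' @param dotbracket Balanced dot-bracket string of the same length.
#' @param free_energy Free energy in kcal/mol.
#' @param constrained Whether probing constraints were applied.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(sequence, dotbracket, free_energy,
                            constrained = FALSE) {
  if (nchar(sequence) != nchar(dotbracket)) {
    stop("sequence and dot-bracket lengths differ")
  }
  dotbracket_pairs(dotbracket)  # validates balance
  structure(list(sequence = sequence, dotbracket = dotbracket,
                 free_energy = free_energy, constrained = constrained),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket,
      sprintf(" (%.2f kcal/mol%s)\n", x$free_energy,
              if (x$constrained) ", probing-constrained" else ""), sep = "")
  invisible(x)
}

#' Base pairs of a dot-bracket string
#'
#' @param dotbracket Dot-bracket string (`.`, `(`, `)`).
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per pair.
#' @export
dotbracket_pairs <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) stop("invalid dot-bracket characters")
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  pairs
}

rnafold_path <- function() {
  path <- Sys.which("RNAfold")
  if (!nzchar(path)) {
    stop("RNAfold (ViennaRNA) not found on PATH; install ViennaRNA or add ",
         "it to PATH to use the folding module")
  }
  path
}

#' Minimum-free-energy fold, optionally reactivity-constrained
#'
#' Delegates thermodynamic free-energy minimization to the ViennaRNA
#' `RNAfold` engine (Turner nearest-neighbor parameters). When a reactivity
#' profile is supplied, per-nucleotide pseudo-free-energy terms
#' \eqn{m \ln(\rho+1) + b} are applied through the engine's standard SHAPE
#' restraint mechanism (per stacked nucleotide); missing reactivities are
#' passed as `-999` and ignored by the engine.
#'
#' @param sequence RNA sequence (length >= 4; `T` accepted as `U`).
#' @param rho Optional [rho_profile()] or numeric reactivity vector of the
#'   same length.
#' @param params [pseudo_energy_params()] used when `rho` is given.
#' @return A [structure_model()]; the `engine` attribute records the engine
#'   name and version.
#' @export
fold_mfe <- function(sequence, rho = NULL, params = pseudo_energy_params()) {
  sequence <- chartr("T", "U", toupper(gsub("\\s", "", sequence)))
  if (!grepl("^[ACGU]+$", sequence)) stop("invalid characters in sequence")
  if (nchar(sequence) < 4L) stop("sequence must be at least 4 nt")
  exe <- rnafold_path()
  dir <- tempfile("fold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fa <- file.path(dir, "in.fa")
  writeLines(c(">q", sequence), fa)
  args <- c("--noPS", "-i", fa)
  if (!is.null(rho)) {
    v <- if (inherits(rho, "rho_profile")) rho$rho else as.numeric(rho)
    if (length(v) != nchar(sequence)) {
      stop("reactivity vector length does not match the sequence")
    }
    shp <- file.path(dir, "in.shape")
    write_shape_file(rho, shp)
    args <- c(args, paste0("--shape=", shp),
              sprintf("--shapeMethod=Dm%gb%g", params$m, params$b))
  }
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RNAfold failed: ", paste(out, collapse = "\n"))
  }
  line <- grep("[().]+\\s*\\(\\s*-?[0-9.]+\\)\\s*$", out, value = TRUE)
  if (!length(line)) stop("could not parse RNAfold output")
  line <- line[length(line)]
  db <- sub("^([().]+).*$", "\\1", line)
  dg <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  model <- structure_model(sequence, db, dg, constrained = !is.null(rho))
  ver <- tryCatch(system2(exe, "--version", stdout = TRUE)[1L],
                  error = function(e) "RNAfold")
  attr(model, "engine") <- ver
  model
}

#' MFE free energy of a target subsequence folded in isolation
#'
#' @param target A [target_rna()] (or plain sequence string).
#' @param interval Inclusive 1-based `c(start, end)`.
#' @return Free energy in kcal/mol of the extracted interval's MFE fold.
#' @export
subsequence_mfe_energy <- function(target, interval) {
  seqs <- if (inherits(target, "target_rna")) target$sequence else target
  interval <- as.integer(interval)
  if (length(interval) != 2L || interval[1L] > interval[2L] ||
      interval[1L] < 1L || interval[2L] > nchar(seqs)) {
    stop("invalid interval")
  }
  fold_mfe(substr(seqs, interval[1L], interval[2L]))$free_energy
}

#' Compare two secondary structure models
#'
#' @param a,b [structure_model()] objects (or dot-bracket strings) of equal
#'   length.
#' @return List with `bp_distance` (size of the symmetric difference of the
#'   base-pair sets) and `agreement` (fraction of positions with identical
#'   paired/unpaired status).
#' @export
structure_agreement <- function(a, b) {
  db <- function(x) if (inherits(x, "structure_model")) x$dotbracket else x
  da <- db(a); dbb <- db(b)
  if (nchar(da) != nchar(dbb)) stop("structures have different lengths")
  pa <- dotbracket_pairs(da)
  pb <- dotbracket_pairs(dbb)
  key <- function(p) if (nrow(p)) paste(p[, 1], p[, 2]) else character(0)
  ka <- key(pa); kb <- key(pb)
  bp_distance <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  paired <- function(d) strsplit(d, "")[[1]] != "."
  agreement <- mean(paired(da) == paired(dbb))
  list(bp_distance = bp_distance, agreement = agreement)
}

#' Write / read dot-bracket files
#'
#' Plain-text records: a `>name` header, the sequence, and the dot-bracket
#' line with the free energy in parentheses.
#'
#' @param model A [structure_model()].
#' @param path File path.
#' @param name Record name.
#' @return `write_dotbracket` returns `path` invisibly; `read_dotbracket`
#'   returns a `structure_model`.
#' @export
write_dotbracket <- function(model, path, name = "structure") {
  writeLines(c(paste0(">", name), model$sequence,
               sprintf("%s (%.2f)", model$dotbracket, model$free_energy)),
             path)
  invisible(path)
}

#' @rdname write_dotbracket
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (startsWith(lines[1L], ">")) lines <- lines[-1L]
  db <- sub("\\s+\\(\\s*-?[0-9.]+\\)\\s*$", "", lines[2L])
  dg <- suppressWarnings(
    as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", lines[2L])))
  structure_model(lines[1L], db, if (is.na(dg)) NA_real_ else dg)
}

#' Read a connectivity-table (CT) file
#'
#' Parses the first structure of a CT file into a [structure_model()]
#' (pseudoknot-free pairs only are representable in dot-bracket).
#'
#' @param path CT file path.
#' @return A `structure_model` (free energy taken from the header when
#'   present).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  header <- lines[1L]
  n <- as.integer(strsplit(trimws(header), "\\s+")[[1]][1L])
  dg <- suppressWarnings(
    as.numeric(sub("^.*[Ee]nergy[ =:]+(-?[0-9.]+).*$", "\\1", header)))
  body <- lines[2:(n + 1L)]
  fields <- lapply(strsplit(trimws(body), "\\s+"), identity)
  bases <- vapply(fields, `[[`, character(1), 2L)
  pairto <- vapply(fields, function(f) as.integer(f[5L]), integer(1))
  db <- rep(".", n)
  for (i in seq_len(n)) {
    j <- pairto[i]
    if (j > i) { db[i] <- "("; db[j] <- ")" }
  }
  structure_model(chartr("T", "U", paste(bases, collapse = "")),
                  paste(db, collapse = ""),
                  if (is.na(dg)) NA_real_ else dg)
}
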