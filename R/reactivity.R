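#' Per-site RT stop frequencies with drop-off correction
#'
#' Reverse transcription proceeds 3' to 5' along the target, so it encounters
#' modification site `n` first. A cDNA that stopped at site `k` covers
#' positions `k+1 .. 3'` end; the transcripts that *reached* site `k` (and so
#' could have stopped there) are those that stopped at any site `i <= k` or
#' ran to full length. The maximum-likelihood per-encounter stop frequency is
#' therefore
#' \deqn{f_k = X_k / (\sum_{i \le k} X_i + X_{full}).}
#' Sites whose denominator is zero were never reached by any cDNA and are
#' flagged unobserved (frequency 0).
#'
#' @param counts A [fragment_counts()] object.
#' @return List with `freq` (numeric vector in `[0, 1]`) and `observed`
#'   (logical vector; `FALSE` where no transcript reached the site).
#' @export
stop_frequencies <- function(counts) {
  stopifnot(inherits(counts, "fragment_counts"))
  denom <- cumsum(counts$X) + counts$X_full
  observed <- denom > 0
  freq <- ifelse(observed, counts$X / denom, 0)
  list(freq = freq, observed = observed)
}

#' Per-nucleotide modification probability profile
#'
#' @param target Target identifier.
#' @param theta Numeric vector on the probability simplex (or all zero when
#'   degenerate).
#' @param observed Logical vector flagging sites reached by at least one cDNA.
#' @param degenerate `TRUE` when no site carried positive signal.
#' @return Object of class `theta_profile`.
#' @export
theta_profile <- function(target, theta, observed = rep(TRUE, length(theta)),
                          degenerate = FALSE) {
  theta <- as.numeric(theta)
  if (any(theta < 0)) stop("theta must be non-negative")
  if (!degenerate && abs(sum(theta) - 1) > 1e-9) {
    stop("non-degenerate theta must sum to 1")
  }
  structure(list(target = target, theta = theta, observed = observed,
                 degenerate = degenerate),
            class = "theta_profile")
}

#' Estimate modification probabilities from (+)/(-) channel counts
#'
#' Implements the drop-off-corrected maximum-likelihood estimator. With
#' per-site stop frequencies \eqn{\beta_k} in the reagent (+) channel and
#' \eqn{\gamma_k} in the control (-) channel (see [stop_frequencies()]), the
#' reagent-attributable modification intensity at site `k` is
#' \deqn{raw_k = \max(0, \ln(1-\gamma_k) - \ln(1-\beta_k)),}
#' the natural-drop-off-corrected log survival deficit, and
#' \eqn{\theta = raw / \sum raw} is its normalization onto the probability
#' simplex. If every `raw_k` is zero the profile is degenerate (all zeros,
#' flagged). Frequencies of exactly 1 (every surviving transcript stopped)
#' are clamped to `1 - 1e-6` with a warning.
#'
#' @param plus,minus [fragment_counts()] for the same target and region.
#' @return A [theta_profile()].
#' @export
estimate_theta <- function(plus, minus) {
  stopifnot(inherits(plus, "fragment_counts"), inherits(minus, "fragment_counts"))
  if (length(plus$X) != length(minus$X)) {
    stop("(+) and (-) counts cover different numbers of sites")
  }
  if (!identical(plus$target, minus$target)) {
    stop("(+) and (-) counts belong to different targets")
  }
  beta <- stop_frequencies(plus)
  gamma <- stop_frequencies(minus)
  clamp <- function(f) {
    if (any(f >= 1)) {
      warning("stop frequency of 1 clamped to 1 - 1e-6 (all surviving ",
              "transcripts stopped at a site)")
      f <- pmin(f, 1 - 1e-6)
    }
    f
  }
  b <- clamp(beta$freq)
  g <- clamp(gamma$freq)
  raw <- pmax(0, log1p(-g) - log1p(-b))
  observed <- beta$observed & gamma$observed
  total <- sum(raw)
  if (total == 0) {
    return(theta_profile(plus$target, rep(0, length(raw)), observed,
                         degenerate = TRUE))
  }
  theta_profile(plus$target, raw / total, observed)
}

#' Normalized reactivity profile
#'
#' @param target Target identifier.
#' @param rho Non-negative numeric vector with mean 1 over probed positions
#'   (all zero when degenerate).
#' @param observed Logical vector of site observability.
#' @param degenerate Degeneracy flag carried from the theta profile.
#' @param n_replicates Number of replicates the profile summarizes.
#' @return Object of class `rho_profile`.
#' @export
rho_profile <- function(target, rho, observed = rep(TRUE, length(rho)),
                        degenerate = FALSE, n_replicates = 1L) {
  rho <- as.numeric(rho)
  if (any(rho[!is.na(rho)] < 0)) stop("rho must be non-negative")
  if (!degenerate && abs(mean(rho, na.rm = TRUE) - 1) > 1e-9) {
    stop("non-degenerate rho must have mean 1")
  }
  structure(list(target = target, rho = rho, observed = observed,
                 degenerate = degenerate, n_replicates = as.integer(n_replicates)),
            class = "rho_profile")
}

#' Convert a theta profile to a rho reactivity profile
#'
#' `rho = n * theta`, so that a non-degenerate profile has mean 1 across the
#' `n` probed positions. This mean-1 scale is what the reactivity class
#' thresholds (1.25 / 0.5) refer to.
#'
#' @param theta A [theta_profile()].
#' @return A [rho_profile()].
#' @export
theta_to_rho <- function(theta) {
  stopifnot(inherits(theta, "theta_profile"))
  n <- length(theta$theta)
  rho_profile(theta$target, n * theta$theta, theta$observed, theta$degenerate)
}

#' Classify reactivities
#'
#' Reactivities greater than `high` (default 1.25) are highly reactive,
#' values in `[weak, high]` moderately reactive, values below `weak`
#' (default 0.5) weakly reactive. The boundaries themselves are moderate.
#'
#' @param rho Non-negative numeric vector (NA allowed for missing sites).
#' @param weak,high Class boundaries on the mean-1 rho scale.
#' @return Factor with levels `weak`, `moderate`, `high`.
#' @export
classify_reactivity <- function(rho, weak = 0.5, high = 1.25) {
  if (any(rho < 0, na.rm = TRUE)) stop("rho must be non-negative")
  cls <- ifelse(is.na(rho), NA_character_,
                ifelse(rho > high, "high",
                       ifelse(rho < weak, "weak", "moderate")))
  factor(cls, levels = c("weak", "moderate", "high"))
}

#' Aggregate replicate reactivity profiles
#'
#' Positionwise arithmetic mean and sample standard deviation (n - 1
#' denominator) across independent replicate profiles of the same target.
#'
#' @param profiles List of at least two [rho_profile()] objects (or plain
#'   numeric vectors) of equal length.
#' @return Object of class `replicate_set` with fields `target`, `mean`,
#'   `sd`, `n_replicates` and `profiles` (matrix, replicates in rows).
#' @export
aggregate_replicates <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least two replicate profiles")
  vecs <- lapply(profiles, function(p) if (inherits(p, "rho_profile")) p$rho else as.numeric(p))
  lens <- vapply(vecs, length, integer(1))
  if (length(unique(lens)) != 1L) stop("replicate profiles have unequal lengths")
  mat <- do.call(rbind, vecs)
  tg <- if (inherits(profiles[[1L]], "rho_profile")) profiles[[1L]]$target else NA_character_
  structure(list(target = tg,
                 mean = colMeans(mat),
                 sd = apply(mat, 2L, stats::sd),
                 n_replicates = nrow(mat),
                 profiles = mat),
            class = "replicate_set")
}

#' One-sided Welch's t-test
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, one-sided. `direction = "greater"` tests the alternative that
#' group A has the larger mean; `"less"` the opposite. When both groups are
#' constant and equal the statistic is undefined and `p = 0.5` is returned
#' with a warning.
#'
#' @param a,b Numeric vectors of replicate values (at least 2 each).
#' @param direction Alternative hypothesis for `mean(a) - mean(b)`.
#' @return One-sided p-value.
#' @export
welch_one_sided <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both groups with equal means; p = 0.5")
      return(0.5)
    }
    warning("zero variance in both groups; degenerate p-value")
    d <- mean(a) - mean(b)
    return(if ((direction == "greater") == (d > 0)) 0 else 1)
  }
  stats::t.test(a, b, alternative = direction, var.equal = FALSE)$p.value
}

#' Positionwise one-sided Welch tests between two replicate sets
#'
#' @param set_a,set_b [aggregate_replicates()] results over the same region.
#' @param direction Alternative for `mean(a) - mean(b)` at each position.
#' @return Numeric vector of one-sided p-values.
#' @export
positionwise_welch <- function(set_a, set_b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(set_a, "replicate_set"), inherits(set_b, "replicate_set"))
  if (ncol(set_a$profiles) != ncol(set_b$profiles)) stop("length mismatch")
  vapply(seq_len(ncol(set_a$profiles)), function(i) {
    suppressWarnings(
      welch_one_sided(set_a$profiles[, i], set_b$profiles[, i], direction))
  }, numeric(1))
}

#' Mask reactivities by nucleotide identity
#'
#' Dimethyl sulfate (DMS) probing reports mainly on A and C bases; positions
#' whose base is not in `keep_bases` are set to missing (`NA`, distinct from
#' a reactivity of 0) so SHAPE- and DMS-mode profiles can be compared on a
#' common support.
#'
#' @param profile A [rho_profile()] (or numeric vector).
#' @param target The [target_rna()] providing the sequence.
#' @param keep_bases Character vector, subset of `c("A","C","G","U")`.
#' @return Same type as `profile`, with masked positions `NA`.
#' @export
mask_by_base <- function(profile, target, keep_bases = c("A", "C")) {
  keep_bases <- toupper(keep_bases)
  if (length(keep_bases) == 0L || !all(keep_bases %in% c("A", "C", "G", "U"))) {
    stop("keep_bases must be a non-empty subset of A, C, G, U")
  }
  rho <- if (inherits(profile, "rho_profile")) profile$rho else as.numeric(profile)
  n <- length(rho)
  if (n != probed_length(target)) {
    stop("profile length does not match the probed region")
  }
  bases <- strsplit(substr(target$sequence, 1L, n), "")[[1]]
  rho[!(bases %in% keep_bases)] <- NA_real_
  if (inherits(profile, "rho_profile")) {
    profile$rho <- rho
    profile
  } else {
    rho
  }
}

#' Write / read a reactivity table
#'
#' Tab-separated per-nucleotide table with columns `target`, `position`,
#' `base`, `theta`, `rho`, `class`, `mean`, `sd`, `n_reps`. Missing values
#' (unobserved or masked sites) are written with the sentinel `-999`.
#'
#' @param target A [target_rna()].
#' @param theta A [theta_profile()].
#' @param rho A [rho_profile()].
#' @param replicates Optional [aggregate_replicates()] result.
#' @param path Output file.
#' @return `write_reactivity_table` returns `path` invisibly;
#'   `read_reactivity_table` returns the data.frame with sentinels restored
#'   to `NA`.
#' @export
write_reactivity_table <- function(target, theta, rho, path, replicates = NULL) {
  n <- probed_length(target)
  sentinel <- function(v) ifelse(is.na(v), -999, v)
  rho_out <- rho$rho
  rho_out[!rho$observed] <- NA_real_
  theta_out <- theta$theta
  theta_out[!theta$observed] <- NA_real_
  df <- data.frame(
    target = target$name,
    position = seq_len(n),
    base = strsplit(substr(target$sequence, 1L, n), "")[[1]],
    theta = sentinel(theta_out),
    rho = sentinel(rho_out),
    class = as.character(classify_reactivity(ifelse(is.na(rho_out), NA, rho_out))),
    mean = sentinel(if (is.null(replicates)) rep(NA_real_, n) else replicates$mean),
    sd = sentinel(if (is.null(replicates)) rep(NA_real_, n) else replicates$sd),
    n_reps = if (is.null(replicates)) rho$n_replicates else replicates$n_replicates,
    stringsAsFactors = FALSE
  )
  df$class[is.na(df$class)] <- "-999"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reactivity_table
#' @export
read_reactivity_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("theta", "rho", "mean", "sd")) {
    df[[col]][df[[col]] == -999] <- NA_real_
  }
  df$class[df$class == "-999"] <- NA_character_
  df
}
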