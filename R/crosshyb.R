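.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# best ungapped match count of integer-coded probe p against reference r,
# over all offsets where the windows fully overlap (shorter of the two slides)
.best_ungapped <- function(p, r) {
  m <- length(p); n <- length(r)
  if (n >= m) {
    best <- 0L
    for (o in 0:(n - m)) {
      h <- sum(p == r[(o + 1):(o + m)])
      if (h > best) best <- h
      if (best == m) break
    }
    best
  } else {
    .best_ungapped(r, p)
  }
}

#' Allosomal cross-hybridization value of a probe
#'
#' The cross-hybridization value h of a probe is the number of matching
#' bases of its best alignment to the sex-chromosome reference sequences.
#' The default is an exhaustive ungapped offset scan of the probe (and, with
#' `both_strands = TRUE`, its reverse complement) against every reference,
#' which is exact and deterministic; `gapped = TRUE` instead counts the
#' matched bases of the optimal Smith-Waterman local alignment
#' (match +1, mismatch -1, gap open 2 / extend 1).
#'
#' @param probe_sequence Probe sequence (A/C/G/T), typically a 50-mer.
#' @param allosome_sequences Named character vector of reference sequences
#'   (e.g. decoy X and Y contigs).
#' @param both_strands Also scan the reverse-complement orientation
#'   (default TRUE).
#' @param gapped Use gapped local alignment instead of the ungapped scan.
#' @return Integer h, `0 <= h <= nchar(probe_sequence)`.
#' @export
crosshyb_value <- function(probe_sequence, allosome_sequences,
                           both_strands = TRUE, gapped = FALSE) {
  if (is.na(probe_sequence) || nchar(probe_sequence) < 1)
    stop("probe sequence must have length >= 1")
  if (length(allosome_sequences) == 0 || any(nchar(allosome_sequences) == 0))
    stop("allosome reference must be non-empty")
  probes <- probe_sequence
  if (both_strands) probes <- c(probes, .revcomp(probe_sequence))
  if (gapped) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    best <- 0L
    for (p in probes) for (r in allosome_sequences) {
      al <- Biostrings::pairwiseAlignment(p, r, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 2, gapExtension = 1)
      best <- max(best, Biostrings::nmatch(al))
    }
    return(as.integer(best))
  }
  code <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  refs <- lapply(allosome_sequences, code)
  best <- 0L
  for (p in lapply(probes, code)) for (r in refs) {
    best <- max(best, .best_ungapped(p, r))
    if (best == length(p)) return(as.integer(best))
  }
  as.integer(best)
}

#' Cross-hybridization values for an annotation table
#'
#' Batch version of [crosshyb_value()] for the default ungapped scan,
#' computed by one-hot matrix products (all reference windows against all
#' probes at once, both probe orientations), which gives results identical
#' to the per-probe scan at array scale. With `gapped = TRUE` it falls back
#' to per-probe gapped alignment.
#'
#' @param annotation Probe annotation with `probe_id` and `probe_sequence`
#'   columns; probes without a sequence are skipped.
#' @param allosome_sequences Named character vector of reference sequences.
#' @param both_strands Also scan the reverse-complement orientation.
#' @param gapped Use gapped local alignment (slow path).
#' @param chunk_size Probes per matrix-product chunk (memory knob).
#' @return Data.frame (`probe_id`, `h`).
#' @export
crosshyb_table <- function(annotation, allosome_sequences,
                           both_strands = TRUE, gapped = FALSE,
                           chunk_size = 2000) {
  has <- !is.na(annotation$probe_sequence)
  ids <- annotation$probe_id[has]
  seqs <- annotation$probe_sequence[has]
  if (length(allosome_sequences) == 0 || any(nchar(allosome_sequences) == 0))
    stop("allosome reference must be non-empty")
  if (gapped) {
    h <- vapply(seqs, crosshyb_value, integer(1),
                allosome_sequences = allosome_sequences,
                both_strands = both_strands, gapped = TRUE, USE.NAMES = FALSE)
    return(data.frame(probe_id = ids, h = h, stringsAsFactors = FALSE))
  }
  m <- unique(nchar(seqs))
  if (length(m) != 1)
    stop("batch scan requires equal-length probe sequences")
  onehot <- function(codes, len) {
    # rows = sequences, cols = len positions x 4 bases
    M <- matrix(0, nrow(codes), len * 4L)
    idx <- cbind(rep(seq_len(nrow(codes)), len),
                 (rep(seq_len(len), each = nrow(codes)) - 1L) * 4L + as.vector(codes))
    M[idx] <- 1
    M
  }
  code <- function(ss) {
    t(vapply(strsplit(ss, ""), function(x)
      match(x, c("A", "C", "G", "T")), integer(m)))
  }
  P1 <- code(seqs)
  probes_oh <- list(onehot(P1, m))
  if (both_strands) probes_oh <- c(probes_oh, list(onehot(5L - P1[, m:1, drop = FALSE], m)))
  h <- rep(0L, length(ids))
  for (ref in allosome_sequences) {
    rc <- match(strsplit(ref, "")[[1]], c("A", "C", "G", "T"))
    n <- length(rc)
    if (n < m) {
      # reference shorter than probe: defer to the per-probe scan
      hh <- vapply(seqs, crosshyb_value, integer(1),
                   allosome_sequences = ref, both_strands = both_strands,
                   USE.NAMES = FALSE)
      h <- pmax(h, hh)
      next
    }
    n_off <- n - m + 1L
    W <- matrix(rc[outer(seq_len(n_off) - 1L, seq_len(m), `+`)], n_off, m)
    Woh <- onehot(W, m)
    for (Poh in probes_oh) {
      for (s in seq(1, nrow(Poh), by = chunk_size)) {
        e <- min(s + chunk_size - 1, nrow(Poh))
        H <- Woh %*% t(Poh[s:e, , drop = FALSE])    # n_off x chunk match counts
        h[s:e] <- pmax(h[s:e], as.integer(round(apply(H, 2, max))))
      }
    }
  }
  data.frame(probe_id = ids, h = h, stringsAsFactors = FALSE)
}

#' Exclude probes by cross-hybridization value
#'
#' Removes probes whose cross-hybridization value is strictly larger than
#' the threshold (default 40, the point at which enrichment of sex
#' associations sets in). The summary reports how many removed probes were
#' significant sex associations and the corresponding percentage.
#'
#' @param records Data.frame with `probe_id` and `h` ([crosshyb_table()]).
#' @param threshold Exclusion threshold; probes with `h > threshold` are
#'   removed (default 40).
#' @param significant_ids Optional probe ids significant in the association
#'   analysis, used for the accounting summary.
#' @return List with `kept`, `removed` (probe id vectors) and `summary`
#'   (`n_removed`, `n_removed_significant`, `pct_removed_significant`).
#' @export
filter_crosshyb <- function(records, threshold = 40, significant_ids = NULL) {
  if (any(records$h < 0) || any(records$h > 50))
    stop("cross-hybridization values must be in [0, probe length]")
  removed <- records$probe_id[records$h > threshold]
  kept <- records$probe_id[records$h <= threshold]
  n_sig <- if (is.null(significant_ids)) NA_integer_
           else length(intersect(removed, significant_ids))
  list(kept = kept, removed = removed,
       summary = list(
         n_removed = length(removed),
         n_removed_significant = n_sig,
         pct_removed_significant = crosshyb_removed_pct(n_sig, length(removed))))
}

#' Percentage of removed probes that were significant
#'
#' @param n_significant Number of removed probes with significant sex
#'   associations.
#' @param n_removed Total number of removed probes.
#' @return Percentage (0-100), `NA` when `n_removed` is 0 or counts missing.
#' @export
crosshyb_removed_pct <- function(n_significant, n_removed) {
  if (is.na(n_significant) || n_removed == 0) return(NA_real_)
  100 * n_significant / n_removed
}

#' Permutation test for association of |SMA| with cross-hybridization
#'
#' Tests whether the absolute sex-methylation association increases with the
#' cross-hybridization value. The statistic is the Spearman (default) or
#' Pearson correlation of |SMA| with h; the empirical one-sided p-value over
#' `n_perm` permutations of h uses the add-one estimator
#' `(1 + #{perm >= obs}) / (n_perm + 1)` so it can never be exactly zero.
#'
#' @param sma_values Per-probe correlation estimates (signed; the absolute
#'   value is used).
#' @param h_values Per-probe cross-hybridization values, same length.
#' @param n_perm Number of permutations (default 3000).
#' @param seed Optional integer seed for reproducibility.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `statistic`, `p`, `n_perm`, `degenerate`.
#' @export
permutation_association_test <- function(sma_values, h_values, n_perm = 3000,
                                         seed = NULL,
                                         method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(sma_values) != length(h_values)) stop("vectors must be paired")
  if (length(sma_values) < 3) stop("need at least 3 probes")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- abs(sma_values)
  y <- h_values
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(statistic = NA_real_, p = 1, n_perm = n_perm, degenerate = TRUE))
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  obs <- stats::cor(x, y)
  n_ge <- 0L
  for (b in seq_len(n_perm))
    if (stats::cor(x, sample(y)) >= obs) n_ge <- n_ge + 1L
  list(statistic = obs, p = (1 + n_ge) / (n_perm + 1), n_perm = n_perm,
       degenerate = FALSE)
}

#' Remove blocklisted (known cross-reactive) probes
#'
#' @param probe_ids Probe ids under analysis.
#' @param blocklist Either a character vector of probe ids or a path to a
#'   one-column text file of probe ids (no header).
#' @return Character vector of kept probe ids, with attribute `n_removed`.
#' @export
apply_blocklist <- function(probe_ids, blocklist) {
  ids <- if (length(blocklist) == 1 && !is.na(blocklist) && file.exists(blocklist))
    readLines(blocklist) else as.character(blocklist)
  ids <- ids[nzchar(ids)]
  kept <- setdiff(probe_ids, ids)
  if (length(kept) == 0) warning("blocklist removed every probe")
  attr(kept, "n_removed") <- length(probe_ids) - length(kept)
  kept
}
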